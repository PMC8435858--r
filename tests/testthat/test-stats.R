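test_that("two-sample t matches the closed-form pooled statistic", {
    x <- c(1, 2, 3); y <- c(4, 5, 6)
    tt <- twoSampleT(x, y, equalVar = TRUE)
    # hand computation: pooled variance 1, se = sqrt(2/3)
    sp2 <- ((2) * var(x) + (2) * var(y)) / 4
    tHand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    expect_equal(tt$t, tHand, tolerance = 1e-12)
    expect_equal(tt$t, -3.674235, tolerance = 1e-6)
    expect_equal(tt$p, 2 * pt(tHand, 4), tolerance = 1e-12)
    same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    shifted <- twoSampleT(x + 17.5, y + 17.5)
    expect_equal(shifted$t, tt$t, tolerance = 1e-12)
    expect_error(twoSampleT(c(1), c(2, 3)), "at least 2")
})

test_that("occupancy tests flag the planted discriminative state", {
    set.seed(1)
    counts <- cbind(rpois(20, 30), rpois(20, 25),
                    c(rpois(10, 40), rpois(10, 10)))  # state 3 differs
    occ <- makeOccupancy(counts, rep(c("normal", "case"), each = 10))
    res <- stateOccupancyTests(occ)
    expect_equal(nrow(res), 3)
    expect_true(all(res$p >= 0 & res$p <= 1))
    expect_identical(res$state[res$discriminative], 3L)
    expect_identical(which.min(res$p), 3L)
    # degenerate single state: counts constant (all equal W) -> skipped
    occ1 <- makeOccupancy(matrix(95L, 20, 1),
                          rep(c("normal", "case"), each = 10))
    expect_warning(res1 <- stateOccupancyTests(occ1), "constant")
    expect_true(is.na(res1$p))
})

test_that("per-state type-I error is nominal under the null", {
    # identical group dynamics; occupancy of true states, many replicates
    set.seed(2)
    tm <- defaultTransitionMatrices(3, stayProb = 0.8, alteredState = NULL)
    reps <- 200
    pvals <- replicate(reps, {
        counts <- t(sapply(seq_len(20), function(i)
            tabulate(sampleChain(tm$normal, 60), 3)))
        occ <- makeOccupancy(counts, rep(c("normal", "case"), each = 10))
        stateOccupancyTests(occ)$p
    })
    rate <- mean(pvals < 0.05)
    n <- length(pvals)
    se <- sqrt(0.05 * 0.95 / n)
    expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("window-difference selection applies the mean-exceedance rule", {
    # identical assignments in both groups -> nothing selected
    am <- matrix(rep(c(1L, 2L, 1L, 2L), 6), 6, 4, byrow = TRUE)
    grp <- rep(c("normal", "case"), each = 3)
    prof <- windowDifferenceSelection(am, grp, targetState = 1)
    expect_true(all(prof$difference == 0))
    expect_false(any(prof$selected))
    # hand-built profile d = (0, 0, 0, 10): mean 2.5, only window 4 passes
    am2 <- rbind(
        matrix(rep(c(1L, 1L, 2L, 1L), 10), 10, 4, byrow = TRUE),  # normal
        matrix(rep(c(1L, 1L, 2L, 2L), 10), 10, 4, byrow = TRUE))  # case
    grp2 <- rep(c("normal", "case"), each = 10)
    prof2 <- windowDifferenceSelection(am2, grp2, targetState = 1)
    expect_equal(prof2$difference, c(0, 0, 0, 10))
    expect_identical(prof2$window[prof2$selected], 4L)
    # duplicating every subject doubles d but keeps the selected set
    prof3 <- windowDifferenceSelection(rbind(am2, am2), rep(grp2, 2), 1)
    expect_equal(prof3$difference, 2 * prof2$difference)
    expect_identical(prof3$selected, prof2$selected)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
    bhOracle <- function(p) {
        m <- length(p)
        o <- order(p)
        adj <- numeric(m)
        for (i in seq_len(m))
            adj[o[i]] <- min(vapply(i:m, function(j)
                m * p[o[j]] / j, numeric(1)), 1)
        adj
    }
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    expect_equal(bhOracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(3)
    for (r in 1:5) {
        p <- runif(50)^2
        expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-15)
    }
})

test_that("connection tests find planted shifts and respect the null", {
    set.seed(4)
    E <- 10  # 5 components
    mkFeat <- function(shift3) {
        f <- matrix(runif(4 * E, -0.3, 0.3), 4, E)
        f[, 3] <- f[, 3] + shift3
        f
    }
    normalSubj <- lapply(1:10, function(i) mkFeat(0.6))
    caseSubj <- lapply(1:10, function(i) mkFeat(-0.6))
    fcw <- makeTestFCW(c(normalSubj, caseSubj),
                       rep(c("normal", "case"), each = 10))
    res <- connectionGroupTests(fcw, selectedWindows = 1:4,
                                threshold = 1e-4)
    expect_equal(nrow(res), E)
    expect_true(res$significant[3])
    expect_false(any(res$significant[-3]))
    expect_true(all(res$p_adj >= res$p))
    expect_identical(res$higher_group[3], "normal")
    # consistency with the scalar t-test on per-subject window means
    means <- t(sapply(c(normalSubj, caseSubj), function(f) colMeans(f)))
    tt <- twoSampleT(means[1:10, 3], means[11:20, 3])
    expect_equal(res$t[3], tt$t, tolerance = 1e-10)
    expect_equal(res$p[3], tt$p, tolerance = 1e-10)
    # identical groups -> nothing significant
    fcwNull <- makeTestFCW(c(normalSubj, normalSubj),
                           rep(c("normal", "case"), each = 10))
    resNull <- connectionGroupTests(fcwNull, selectedWindows = 1:4)
    expect_false(any(resNull$significant))
    expect_error(connectionGroupTests(fcw, integer(0)), "no windows")
})

test_that("network-pair summaries recount the significant connections", {
    tab <- data.frame(
        i = c(1, 1, 2, 3, 4), j = c(2, 3, 3, 5, 5),
        t = 0, p = 1, p_adj = 1,
        significant = c(TRUE, TRUE, FALSE, TRUE, FALSE),
        higher_group = c("normal", "case", "normal", "normal", "case"))
    icmap <- c("1" = "DDMN", "2" = "DDMN", "3" = "ASN", "4" = "VN",
               "5" = "DDMN")
    out <- summarizeNetworkPairs(tab, icNetworks = icmap)
    pn <- out$perNetwork
    expect_equal(pn$total[pn$network == "DDMN"], 3)
    expect_equal(pn$total[pn$network == "ASN"], 2)
    expect_equal(pn$total[pn$network == "VN"], 0)
    expect_identical(out$topNetwork, "DDMN")
    expect_equal(pn$higher_normal[pn$network == "DDMN"], 2)
    pp <- out$perPair
    expect_equal(pp$total[pp$network_pair == "ASN-DDMN"], 2)
    # no significant connections -> all zero
    tab$significant <- FALSE
    out0 <- summarizeNetworkPairs(tab, icNetworks = icmap)
    expect_true(all(out0$perNetwork$total == 0))
    expect_identical(out0$topNetwork, NA_character_)
    expect_error(summarizeNetworkPairs(tab, icNetworks = icmap[-1]),
                 "unmapped")
})

test_that("the significant-connection graph round-trips through Pajek", {
    tab <- data.frame(
        i = c(1, 1, 2), j = c(2, 3, 3), t = 0, p = 0, p_adj = 0,
        significant = c(TRUE, TRUE, TRUE),
        higher_group = c("normal", "case", "normal"))
    f <- withr::local_tempfile(fileext = ".net")
    writePajek(tab, f, higherGroup = "normal")
    expect_true(file.exists(f))
    g <- igraph::read_graph(f, format = "pajek")
    expect_equal(igraph::gorder(g), 3)
    expect_equal(igraph::gsize(g), 3)
    expect_setequal(igraph::E(g)$weight, c(1, -1, 1))
})
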