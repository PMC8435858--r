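test_that("k = 1 reduces to the column-mean centroid with closed-form SSE", {
    set.seed(1)
    x <- matrix(rnorm(30 * 4), 30, 4)
    m <- fitStateModel(x, k = 1, seed = 2, nInit = 3)
    expect_equal(as.numeric(stateCentroids(m)), colMeans(x))
    expect_equal(m@sse, sum(sweep(x, 2, colMeans(x))^2))
    expect_true(all(trainingLabels(m) == 1L))
})

test_that("k = 2 on six separated points matches the exhaustive optimum", {
    set.seed(2)
    x <- rbind(matrix(rnorm(9, 0, 0.2), 3),   # triple near 0
               matrix(rnorm(9, 10, 0.2), 3))  # triple near 10
    m <- fitStateModel(x, k = 2, seed = 4, nInit = 10)
    # oracle: brute force over all 2-partitions of 6 points
    bestSSE <- Inf
    for (mask in 1:(2^6 - 2)) {
        part <- as.logical(bitwAnd(mask, 2^(0:5)))
        if (!any(part) || all(part)) next
        sse <- sum(sweep(x[part, , drop = FALSE], 2,
                         colMeans(x[part, , drop = FALSE]))^2) +
               sum(sweep(x[!part, , drop = FALSE], 2,
                         colMeans(x[!part, , drop = FALSE]))^2)
        bestSSE <- min(bestSSE, sse)
    }
    expect_equal(m@sse, bestSSE, tolerance = 1e-10)
    expect_length(unique(trainingLabels(m)[1:3]), 1)
    expect_length(unique(trainingLabels(m)[4:6]), 1)
    expect_false(trainingLabels(m)[1] == trainingLabels(m)[4])
})

test_that("duplicating every point doubles SSE and keeps the centroids", {
    set.seed(3)
    x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
    m1 <- fitStateModel(x, k = 2, seed = 5, nInit = 10)
    m2 <- fitStateModel(rbind(x, x), k = 2, seed = 5, nInit = 10)
    srt <- function(m) stateCentroids(m)[order(stateCentroids(m)[, 1]), ]
    expect_equal(srt(m1), srt(m2), tolerance = 1e-10)
    expect_equal(m2@sse, 2 * m1@sse, tolerance = 1e-10)
})

test_that("labels are post-hoc consistent and SSE is monotone in k", {
    set.seed(4)
    x <- matrix(rnorm(200 * 6), 200, 6)
    sse <- c()
    for (k in 1:6) {
        m <- fitStateModel(x, k = k, seed = 6, nInit = 10)
        d2 <- outer(rowSums(x^2), rowSums(stateCentroids(m)^2), "+") -
            2 * x %*% t(stateCentroids(m))
        expect_identical(trainingLabels(m),
                         as.integer(max.col(-d2, ties.method = "first")))
        sse <- c(sse, m@sse)
    }
    expect_true(all(diff(sse) <= 1e-8 * sse[1]))
    expect_error(fitStateModel(x, k = 201, seed = 1), "exceeds")
})

test_that("the elbow rule finds the knee of a three-blob mixture", {
    set.seed(5)
    x <- do.call(rbind, lapply(c(0, 8, 16), function(mu)
        matrix(rnorm(40 * 3, mu, 0.4), 40, 3)))
    m <- selectStatesElbow(x, kMin = 1, kMax = 8, seed = 7, nInit = 10)
    expect_identical(nStates(m), 3L)
    expect_length(sseCurve(m), 8)
    expect_true(all(diff(sseCurve(m)) <= 1e-8 * sseCurve(m)[1]))
})

test_that("a structureless point mass falls back to the smallest k", {
    x <- matrix(rep(c(1, 2, 3), each = 20), 20, 3)
    m <- selectStatesElbow(x, kMin = 1, kMax = 4, seed = 8, nInit = 3)
    expect_identical(nStates(m), 1L)
    expect_error(selectStatesElbow(x, kMin = 2, kMax = 3), "kMax")
})

test_that("five well-separated synthetic states are recovered", {
    fix <- recoveryFixture()
    expect_identical(nStates(fix$model), 5L)
    skip_if_not_installed("mclust")
    # ground truth: the generating state at each window's central TR
    centers <- windowStarts(215, 25, 2) + 13
    truth <- unlist(lapply(trueStates(fix$cohort), function(z) z[centers]))
    ari <- mclust::adjustedRandIndex(truth, trainingLabels(fix$model))
    expect_gte(ari, 0.8)
})

test_that("new windows are assigned to the nearest centroid", {
    cen <- rbind(c(0, 0), c(2, 0), c(4, 0))
    model <- new("StateModel", k = 3L, centroids = cen, sse = 0,
                 sseCurve = setNames(numeric(0), character(0)),
                 trainingLabels = integer(0), seed = 1L, nInit = 1L)
    expect_identical(assignStates(model, cen), c(1L, 2L, 3L))  # fixed points
    expect_identical(assignStates(model, c(1, 0)), 1L)  # tie 1 vs 2 -> 1
    expect_identical(assignStates(model, c(3, 5)), 2L)  # tie 2 vs 3 -> 2
    set.seed(9)
    pts <- matrix(rnorm(40, 2, 3), 20, 2)
    d <- as.matrix(dist(rbind(pts, cen)))[1:20, 21:23]
    expect_identical(assignStates(model, pts),
                     as.integer(apply(d, 1, which.min)))
    expect_error(assignStates(model, matrix(0, 2, 5)), "dimension")
})

test_that("occupancy counts tally windows per state and sum to W", {
    co <- smallCohort()
    fcw <- slidingWindowFC(co, width = 20, step = 2)
    W <- countWindows(60, 20, 2)
    n <- ncol(fcw)
    allThree <- rep(3L, n)
    occ <- occupancyCounts(fcw, allThree, k = 5)
    expect_true(all(occupancyMatrix(occ)[, 3] == W))
    expect_true(all(occupancyMatrix(occ)[, -3] == 0))
    set.seed(10)
    labels <- sample.int(4, n, replace = TRUE)
    occ <- occupancyCounts(fcw, labels, k = 4)
    expect_equal(unname(rowSums(occupancyMatrix(occ))), rep(W, 6))
    cd <- SummarizedExperiment::colData(fcw)
    for (id in subjectIDs(fcw))  # independent recount
        expect_equal(unname(occupancyMatrix(occ)[id, ]),
                     unname(tabulate(labels[cd$subject_id == id], 4)))
    expect_error(occupancyCounts(fcw, labels, k = 3), "1..k")
})

test_that("subject order permutes outputs without changing them", {
    co <- smallCohort()
    ids <- subjectIDs(co)
    rev_ids <- rev(ids)
    co2 <- new("FCCohort",
        subjects = co@subjects[rev_ids],
        subjectData = co@subjectData[match(rev_ids, ids), ],
        trueStates = co@trueStates[rev_ids],
        config = co@config)
    f1 <- slidingWindowFC(co, width = 20, step = 2)
    f2 <- slidingWindowFC(co2, width = 20, step = 2)
    model <- fitStateModel(f1, k = 3, seed = 11, nInit = 5)
    o1 <- occupancyCounts(f1, assignStates(model, f1), k = 3)
    o2 <- occupancyCounts(f2, assignStates(model, f2), k = 3)
    expect_equal(occupancyMatrix(o1)[ids, ], occupancyMatrix(o2)[ids, ])
})
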