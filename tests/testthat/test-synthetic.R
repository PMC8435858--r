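test_that("state covariances are SPD correlation matrices", {
    covs <- makeStateCovariances(5, 44, separation = 4, seed = 3)
    expect_length(covs, 5)
    for (S in covs) {
        expect_equal(dim(S), c(44L, 44L))
        expect_equal(diag(S), rep(1, 44))
        expect_lt(max(abs(S - t(S))), 1e-12)
        expect_no_error(chol(S))  # Cholesky succeeds iff SPD
    }
    one <- makeStateCovariances(1, 6, separation = 2, seed = 1)
    expect_length(one, 1)
    expect_equal(diag(one[[1]]), rep(1, 6))
    expect_error(makeStateCovariances(3, 6, separation = 0), "positive")
})

test_that("state separation controls pairwise correlation-pattern distance", {
    frob <- function(covs) {
        d <- c()
        for (a in seq_along(covs)) for (b in seq_along(covs))
            if (a < b) d <- c(d, sqrt(sum((covs[[a]] - covs[[b]])^2)))
        d
    }
    tiny <- frob(makeStateCovariances(4, 8, separation = 1e-9, seed = 2))
    expect_lt(max(tiny), 1e-6)
    lo <- frob(makeStateCovariances(4, 8, separation = 0.5, seed = 2))
    hi <- frob(makeStateCovariances(4, 8, separation = 6, seed = 2))
    expect_true(all(hi > lo))
})

test_that("configuration invariants are enforced", {
    P <- defaultTransitionMatrices(3)
    expect_equal(rowSums(P$normal), rep(1, 3), tolerance = 1e-14)
    expect_equal(rowSums(P$case), rep(1, 3), tolerance = 1e-14)
    bad <- P
    bad$case[1, 1] <- bad$case[1, 1] + 1e-6
    expect_error(syntheticConfig(nPerGroup = 2, nComponents = 4,
                                 nStates = 3, transitionMatrices = bad),
                 "sum to 1")
    sing <- replicate(2, matrix(1, 4, 4), simplify = FALSE)  # rank 1
    expect_error(syntheticConfig(nPerGroup = 2, nComponents = 4, nStates = 2,
                                 stateCovariances = sing),
                 "positive-definite")
})

test_that("simulation is seed-deterministic and shape-correct", {
    cfg <- syntheticConfig(nPerGroup = 2, nComponents = 5, nTimepoints = 50,
                           nStates = 2, seed = 42)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(a@subjects, b@subjects)
    expect_identical(trueStates(a), trueStates(b))
    expect_length(subjectIDs(a), 4)
    expect_equal(dim(timeCourses(a, "sub001")), c(50L, 5L))
    expect_true(all(vapply(trueStates(a), length, 1L) == 50L))
    expect_setequal(levels(groups(a)), c("normal", "case"))
})

test_that("identity transition matrices freeze each subject in one state", {
    I2 <- diag(2)
    cfg <- syntheticConfig(nPerGroup = 3, nComponents = 4, nTimepoints = 40,
                           nStates = 2,
                           transitionMatrices = list(normal = I2, case = I2),
                           seed = 9)
    co <- simulateCohort(cfg)
    for (z in trueStates(co))
        expect_length(unique(z), 1)
})

test_that("empirical dwell fractions match the chains' stationary laws", {
    # strongly different per-group stay probabilities
    Pn <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
    Pc <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, byrow = TRUE)
    cfg <- syntheticConfig(nPerGroup = 30, nComponents = 3, nTimepoints = 400,
                           nStates = 2,
                           transitionMatrices = list(normal = Pn, case = Pc),
                           separation = 2, seed = 21)
    co <- simulateCohort(cfg)
    grp <- groups(co)
    frac1 <- vapply(trueStates(co), function(z) mean(z == 1), numeric(1))
    for (g in c("normal", "case")) {
        P <- cfg$transitionMatrices[[g]]
        target <- stationaryDistribution(P)[1]
        f <- frac1[grp == g]
        se <- stats::sd(f) / sqrt(length(f))
        expect_lt(abs(mean(f) - target), 3 * se + 1e-12)
    }
})

test_that("per-state empirical correlation converges to the state pattern", {
    covs <- makeStateCovariances(2, 5, separation = 6, seed = 4)
    dist_at_T <- function(Tn) {
        cfg <- syntheticConfig(nPerGroup = 5, nComponents = 5,
                               nTimepoints = Tn, nStates = 2,
                               stateCovariances = covs, noiseSD = 0,
                               seed = 8)
        co <- simulateCohort(cfg)
        pooled <- do.call(rbind, lapply(subjectIDs(co), function(id)
            timeCourses(co, id)[trueStates(co)[[id]] == 1, , drop = FALSE]))
        sqrt(sum((stats::cor(pooled) - covs[[1]])^2))
    }
    expect_lt(dist_at_T(3000), dist_at_T(150))
})

test_that("cohorts round-trip through plain-text files", {
    co <- smallCohort()
    dir <- withr::local_tempdir()
    manifest <- writeCohort(co, dir)
    # 6 subjects + labels + states + config
    expect_length(manifest, 9)
    expect_true(all(file.exists(manifest)))
    back <- readCohort(dir)
    expect_identical(subjectIDs(back), subjectIDs(co))
    expect_identical(as.character(groups(back)), as.character(groups(co)))
    for (id in subjectIDs(co))
        expect_equal(timeCourses(back, id), timeCourses(co, id),
                     tolerance = 1e-8)
    expect_identical(trueStates(back), trueStates(co))
})

test_that("an empty cohort writes metadata files only", {
    empty <- new("FCCohort",
        subjects = structure(list(), names = character(0)),
        subjectData = S4Vectors::DataFrame(
            subject_id = character(0),
            group = factor(character(0), levels = c("normal", "case"))),
        trueStates = list(), config = list())
    dir <- withr::local_tempdir()
    manifest <- writeCohort(empty, dir)
    expect_setequal(names(manifest), c("labels", "states", "config"))
    expect_true(all(file.exists(manifest)))
})
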