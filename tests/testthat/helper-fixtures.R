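# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# High-separation 5-state cohort (10 per group, C = 10, T = 215) plus its
# windowed features and the elbow-selected state model. Used by the state
# recovery, elbow and classification tests.
recoveryFixture <- function() {
    if (is.null(.fixtures$recovery)) {
        cfg <- syntheticConfig(nPerGroup = 10, nComponents = 10,
                               nTimepoints = 215, nStates = 5,
                               separation = 8, seed = 11)
        cohort <- simulateCohort(cfg)
        fcw <- slidingWindowFC(cohort, width = 25, step = 2)
        model <- selectStatesElbow(fcw, kMin = 2, kMax = 9,
                                   seed = 1, nInit = 20)
        .fixtures$recovery <- list(cohort = cohort, fcw = fcw, model = model)
    }
    .fixtures$recovery
}

# Small cohort for cheap structural tests.
smallCohort <- function(seed = 5) {
    simulateCohort(syntheticConfig(nPerGroup = 3, nComponents = 5,
                                   nTimepoints = 60, nStates = 2,
                                   separation = 4, seed = seed))
}

# Build an FCWindows directly from per-subject W x E feature matrices;
# lets tests plant exact feature values.
makeTestFCW <- function(featuresBySubject, group, width = 10L, step = 2L) {
    ids <- names(featuresBySubject)
    if (is.null(ids)) {
        ids <- sprintf("sub%03d", seq_along(featuresBySubject))
        names(featuresBySubject) <- ids
    }
    E <- ncol(featuresBySubject[[1]])
    C <- as.integer(round((1 + sqrt(1 + 8 * E)) / 2))
    a <- do.call(cbind, lapply(featuresBySubject, t))
    cd <- do.call(rbind, lapply(seq_along(ids), function(s)
        data.frame(subject_id = ids[s], group = group[s],
                   window_index = seq_len(nrow(featuresBySubject[[s]])),
                   window_start = (seq_len(nrow(featuresBySubject[[s]])) - 1L) *
                       step)))
    cd$group <- factor(cd$group, levels = c("normal", "case"))
    pairs <- upperPairs(C)
    rownames(a) <- paste0("c", pairs$i, "_", pairs$j)
    colnames(a) <- paste0(cd$subject_id, ".w", cd$window_index)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fc = a),
        rowData = S4Vectors::DataFrame(pairs),
        colData = S4Vectors::DataFrame(cd),
        metadata = list(width = width, step = step, n_components = C,
                        n_timepoints = NA_integer_))
    new("FCWindows", se)
}

# Occupancy object built directly from a count matrix.
makeOccupancy <- function(counts, group) {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("sub%03d", seq_len(nrow(counts)))
    colnames(counts) <- paste0("state", seq_len(ncol(counts)))
    new("StateOccupancy", counts = counts,
        group = factor(group, levels = c("normal", "case")))
}

# Sample a Markov state sequence (used by simulation-based null tests).
sampleChain <- function(P, n, init = NULL) {
    K <- nrow(P)
    pi0 <- if (is.null(init)) stationaryDistribution(P) else init
    z <- integer(n)
    z[1] <- sample.int(K, 1, prob = pi0)
    for (t in seq_len(n - 1)) z[t + 1] <- sample.int(K, 1, prob = P[z[t], ])
    z
}
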