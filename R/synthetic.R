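#' Generate distinguishable SPD state covariance matrices
#'
#' Builds \code{nStates} symmetric positive-definite covariance matrices
#' representing recurring connectivity regimes. Each state covariance is a
#' convex combination of one shared random SPD matrix and one state-specific
#' random SPD matrix; \code{separation} controls the weight of the
#' state-specific part, so pairwise distances between the states'
#' correlation patterns grow with \code{separation} and vanish as
#' \code{separation} approaches 0. Matrices are returned in correlation form
#' (unit diagonal).
#'
#' @param nStates number of states (>= 1).
#' @param nComponents matrix dimension C (>= 2).
#' @param separation positive scalar; the state-specific weight is
#'   \code{separation / (1 + separation)}.
#' @param seed integer RNG seed.
#' @return list of \code{nStates} C x C SPD correlation matrices.
#' @examples
#' covs <- makeStateCovariances(5, 10, separation = 4, seed = 1)
#' all(vapply(covs, function(s) all(diag(s) == 1), logical(1)))
#' @export
makeStateCovariances <- function(nStates, nComponents, separation, seed = 1L) {
    if (nStates < 1L) stop("nStates must be >= 1")
    if (nComponents < 2L) stop("nComponents must be >= 2")
    if (!is.numeric(separation) || length(separation) != 1L || separation <= 0)
        stop("separation must be a positive scalar")
    set.seed(as.integer(seed))
    C <- as.integer(nComponents)
    rspd <- function() {
        A <- matrix(stats::rnorm(C * C), C, C)
        crossprod(A) / C + diag(C) * 0.1
    }
    shared <- rspd()
    w <- separation / (1 + separation)
    lapply(seq_len(nStates), function(k) {
        S <- (1 - w) * shared + w * rspd()
        stats::cov2cor(S)
    })
}

#' Assemble a synthetic-cohort configuration
#'
#' Defines the generative model for [simulateCohort()]: per group, subjects'
#' hidden connectivity states follow a first-order Markov chain over
#' \code{nStates} regimes; at each time point the C-vector of component
#' amplitudes is drawn from the active state's covariance plus isotropic
#' Gaussian observation noise. Defaults mirror a typical resting-state IC
#' analysis: 44 components, 215 retained time points, 5 states, ~40 subjects
#' per group, with the case group dwelling less in the final state.
#'
#' @param nPerGroup subjects per group.
#' @param nComponents number of components C.
#' @param nTimepoints number of time points T.
#' @param nStates number of hidden states.
#' @param transitionMatrices named list with elements \code{normal} and
#'   \code{case}, each a row-stochastic nStates x nStates matrix (rows sum
#'   to 1 within 1e-12). Defaults to [defaultTransitionMatrices()].
#' @param stateCovariances list of nStates SPD C x C matrices; defaults to
#'   [makeStateCovariances()] with \code{separation}.
#' @param separation state separation used when covariances are generated
#'   here.
#' @param noiseSD standard deviation of the isotropic observation noise.
#' @param seed integer RNG seed.
#' @return a validated configuration list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nPerGroup = 40L, nComponents = 44L,
                            nTimepoints = 215L, nStates = 5L,
                            transitionMatrices = NULL,
                            stateCovariances = NULL,
                            separation = 4, noiseSD = 0.2, seed = 1L) {
    if (nPerGroup < 1L) stop("nPerGroup must be >= 1")
    if (nTimepoints < 2L) stop("nTimepoints must be >= 2")
    if (is.null(transitionMatrices))
        transitionMatrices <- defaultTransitionMatrices(nStates)
    if (!identical(sort(names(transitionMatrices)), c("case", "normal")))
        stop("transitionMatrices must be a named list: normal, case")
    for (g in names(transitionMatrices)) {
        P <- transitionMatrices[[g]]
        if (!is.matrix(P) || any(dim(P) != nStates))
            stop("transition matrix for group '", g, "' must be ",
                 nStates, " x ", nStates)
        if (any(P < 0))
            stop("transition probabilities must be non-negative (group '",
                 g, "')")
        if (any(abs(rowSums(P) - 1) > 1e-12))
            stop("each transition-matrix row must sum to 1 within 1e-12 ",
                 "(group '", g, "')")
    }
    if (is.null(stateCovariances))
        stateCovariances <- makeStateCovariances(nStates, nComponents,
                                                 separation, seed = seed)
    if (length(stateCovariances) != nStates)
        stop("need one covariance per state")
    for (k in seq_len(nStates)) {
        S <- stateCovariances[[k]]
        if (!is.matrix(S) || any(dim(S) != nComponents))
            stop("state ", k, " covariance must be ", nComponents, " x ",
                 nComponents)
        if (max(abs(S - t(S))) > 1e-10)
            stop("state ", k, " covariance is not symmetric")
        ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
        if (!ok)
            stop("state ", k, " covariance is not positive-definite")
    }
    if (noiseSD < 0) stop("noiseSD must be >= 0")
    structure(list(
        nPerGroup = as.integer(nPerGroup),
        nComponents = as.integer(nComponents),
        nTimepoints = as.integer(nTimepoints),
        nStates = as.integer(nStates),
        transitionMatrices = transitionMatrices,
        stateCovariances = stateCovariances,
        noiseSD = noiseSD,
        seed = as.integer(seed)
    ), class = "SyntheticConfig")
}

#' Default per-group Markov transition matrices
#'
#' Both groups switch slowly among states (stay probability
#' \code{stayProb}, off-diagonal mass spread uniformly); the case group's
#' dwell in one altered state (by default the last) is shortened by lowering
#' that state's stay probability to \code{alteredStay}, planting a
#' group-differential state occupancy for downstream stages to detect.
#'
#' @param nStates number of states.
#' @param stayProb diagonal stay probability shared by all states.
#' @param alteredState index of the state whose dynamics differ in the case
#'   group; \code{NULL} disables the group difference.
#' @param alteredStay the case group's stay probability for the altered
#'   state.
#' @return named list with row-stochastic matrices \code{normal} and
#'   \code{case}.
#' @export
defaultTransitionMatrices <- function(nStates = 5L, stayProb = 0.98,
                                      alteredState = nStates,
                                      alteredStay = 0.90) {
    stopifnot(nStates >= 1L, stayProb > 0, stayProb <= 1)
    mk <- function(diagv) {
        P <- matrix(0, nStates, nStates)
        for (i in seq_len(nStates)) {
            P[i, ] <- if (nStates == 1L) 1 else (1 - diagv[i]) / (nStates - 1)
            P[i, i] <- diagv[i]
        }
        P
    }
    dn <- rep(stayProb, nStates)
    dc <- dn
    if (!is.null(alteredState) && nStates > 1L)
        dc[alteredState] <- alteredStay
    list(normal = mk(dn), case = mk(dc))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P row-stochastic square matrix.
#' @return stationary probability vector (left eigenvector for eigenvalue 1,
#'   normalized).
#' @export
stationaryDistribution <- function(P) {
    stopifnot(is.matrix(P), nrow(P) == ncol(P))
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    v / sum(v)
}

#' Simulate a two-group cohort of IC time courses
#'
#' For each subject, a hidden state sequence of length T is sampled from the
#' subject's group-specific Markov chain (initial state drawn from the
#' chain's stationary distribution), and each time point's C-vector is drawn
#' from the active state's multivariate Gaussian plus isotropic observation
#' noise. Fully reproducible under the configuration seed.
#'
#' @param config a configuration from [syntheticConfig()].
#' @return an [FCCohort-class] with ground-truth state sequences attached.
#' @examples
#' cfg <- syntheticConfig(nPerGroup = 2, nComponents = 5, nTimepoints = 50,
#'                        nStates = 2, seed = 7)
#' cohort <- simulateCohort(cfg)
#' cohort
#' @export
simulateCohort <- function(config) {
    if (!inherits(config, "SyntheticConfig"))
        config <- do.call(syntheticConfig, config)
    set.seed(config$seed)
    K <- config$nStates
    Tn <- config$nTimepoints
    C <- config$nComponents
    chols <- lapply(seq_len(K), function(k) {
        tryCatch(chol(config$stateCovariances[[k]]),
            error = function(e)
                stop("state ", k, " covariance is singular; cannot simulate"))
    })
    groups <- rep(c("normal", "case"), each = config$nPerGroup)
    ids <- sprintf("sub%03d", seq_along(groups))
    subjects <- vector("list", length(ids))
    states <- vector("list", length(ids))
    for (s in seq_along(ids)) {
        P <- config$transitionMatrices[[groups[s]]]
        pi0 <- pmax(stationaryDistribution(P), 0)
        pi0 <- pi0 / sum(pi0)
        z <- integer(Tn)
        z[1] <- sample.int(K, 1L, prob = pi0)
        for (t in seq_len(Tn - 1L))
            z[t + 1L] <- sample.int(K, 1L, prob = P[z[t], ])
        y <- matrix(0, Tn, C)
        for (k in unique(z)) {
            idx <- which(z == k)
            y[idx, ] <- matrix(stats::rnorm(length(idx) * C),
                               length(idx), C) %*% chols[[k]]
        }
        if (config$noiseSD > 0)
            y <- y + matrix(stats::rnorm(Tn * C, sd = config$noiseSD), Tn, C)
        subjects[[s]] <- y
        states[[s]] <- z
    }
    names(subjects) <- ids
    names(states) <- ids
    new("FCCohort",
        subjects = subjects,
        subjectData = S4Vectors::DataFrame(
            subject_id = ids,
            group = factor(groups, levels = c("normal", "case"))),
        trueStates = states,
        config = unclass(config))
}

#' Write a cohort to plain-text files
#'
#' Writes one header-less TSV per subject (T rows x C tab-separated values),
#' a labels CSV (\code{subject_id,group}), a ground-truth state CSV
#' (\code{subject_id,t,state}; empty body when no ground truth), and a JSON
#' configuration echo. Returns a manifest of all files written.
#'
#' @param cohort an [FCCohort-class].
#' @param directory output directory (created if needed).
#' @param digits significant digits for the time-course TSVs.
#' @return named character vector of file paths (invisibly a manifest):
#'   elements \code{labels}, \code{states}, \code{config} and one per
#'   subject id.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, directory, digits = 10L) {
    stopifnot(is(cohort, "FCCohort"))
    if (!dir.exists(directory) &&
        !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", directory)
    if (file.access(directory, 2L) != 0L)
        stop("directory not writable: ", directory)
    ids <- subjectIDs(cohort)
    paths <- character(0)
    for (id in ids) {
        p <- file.path(directory, paste0(id, ".tsv"))
        utils::write.table(signif(cohort@subjects[[id]], digits), p,
            sep = "\t", row.names = FALSE, col.names = FALSE)
        paths[id] <- p
    }
    lab <- file.path(directory, "labels.csv")
    utils::write.csv(data.frame(subject_id = ids,
                                group = as.character(groups(cohort))),
                     lab, row.names = FALSE, quote = FALSE)
    st <- file.path(directory, "true_states.csv")
    if (length(trueStates(cohort))) {
        tab <- do.call(rbind, lapply(ids, function(id)
            data.frame(subject_id = id,
                       t = seq_along(cohort@trueStates[[id]]),
                       state = cohort@trueStates[[id]])))
    } else {
        tab <- data.frame(subject_id = character(0), t = integer(0),
                          state = integer(0))
    }
    utils::write.csv(tab, st, row.names = FALSE, quote = FALSE)
    cfgp <- file.path(directory, "config.json")
    cfg <- cohort@config
    jsonlite::write_json(cfg, cfgp, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
    paths["labels"] <- lab
    paths["states"] <- st
    paths["config"] <- cfgp
    invisible(paths)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param directory directory containing subject TSVs, \code{labels.csv} and
#'   optionally \code{true_states.csv}.
#' @return an [FCCohort-class].
#' @export
readCohort <- function(directory) {
    lab <- utils::read.csv(file.path(directory, "labels.csv"),
                           stringsAsFactors = FALSE)
    ids <- as.character(lab$subject_id)
    subjects <- lapply(ids, function(id) {
        p <- file.path(directory, paste0(id, ".tsv"))
        if (!file.exists(p)) stop("missing subject file: ", p)
        as.matrix(utils::read.table(p, sep = "\t", header = FALSE))
    })
    names(subjects) <- ids
    subjects <- lapply(subjects, function(m) {
        dimnames(m) <- NULL
        m
    })
    states <- list()
    stp <- file.path(directory, "true_states.csv")
    if (file.exists(stp)) {
        st <- utils::read.csv(stp, stringsAsFactors = FALSE)
        if (nrow(st)) {
            states <- lapply(split(st$state, st$subject_id), as.integer)
            states <- states[ids]
        }
    }
    new("FCCohort",
        subjects = subjects,
        subjectData = S4Vectors::DataFrame(
            subject_id = ids,
            group = factor(lab$group, levels = c("normal", "case"))),
        trueStates = states,
        config = list())
}
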