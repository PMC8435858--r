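#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

#' FCCohort: a cohort of IC time-course matrices
#'
#' Container for a two-group cohort of subjects, each carrying a T x C matrix
#' of independent-component (IC) time courses (rows = time points, columns =
#' components). When the cohort was simulated, the hidden state sequence that
#' generated each subject is retained as ground truth.
#'
#' @slot subjects named list of numeric T x C matrices, one per subject.
#' @slot subjectData \code{DataFrame} with columns \code{subject_id} and
#'   \code{group} (factor with exactly two levels, conventionally
#'   \code{"normal"} and \code{"case"}).
#' @slot trueStates named list of integer vectors (length T each) of
#'   generating state labels, or an empty list for real data.
#' @slot config list echoing the simulation configuration (empty for real
#'   data).
#'
#' @seealso [simulateCohort()], [slidingWindowFC()]
#' @export
setClass("FCCohort",
    representation(
        subjects = "list",
        subjectData = "DataFrame",
        trueStates = "list",
        config = "list"
    )
)

setValidity("FCCohort", function(object) {
    msg <- NULL
    sd <- object@subjectData
    if (!all(c("subject_id", "group") %in% colnames(sd)))
        msg <- c(msg, "subjectData must have columns 'subject_id' and 'group'")
    else {
        if (length(object@subjects) != nrow(sd))
            msg <- c(msg, "one time-course matrix per subjectData row required")
        if (!identical(as.character(names(object@subjects)),
                       as.character(sd$subject_id)))
            msg <- c(msg, "names(subjects) must equal subjectData$subject_id")
        if (!is.factor(sd$group) || nlevels(sd$group) != 2L)
            msg <- c(msg, "group must be a factor with exactly two levels")
    }
    dims <- vapply(object@subjects, function(m) dim(m), integer(2))
    if (length(object@subjects) > 1L &&
        (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L))
        msg <- c(msg, "all subjects must share the same T x C dimensions")
    if (any(vapply(object@subjects, function(m) anyNA(m), logical(1))))
        msg <- c(msg, "time courses must not contain missing values")
    if (length(object@trueStates)) {
        if (!identical(names(object@trueStates), names(object@subjects)))
            msg <- c(msg, "trueStates must be named like subjects")
        ok <- mapply(function(s, m) length(s) == nrow(m),
                     object@trueStates, object@subjects)
        if (!all(ok))
            msg <- c(msg, "each true state sequence must have length T")
    }
    if (is.null(msg)) TRUE else msg
})

#' FCWindows: sliding-window connectivity features for a cohort
#'
#' Extends \code{SummarizedExperiment}. The single assay \code{"fc"} is an
#' E x N matrix of vectorized window-wise Pearson correlations, where
#' E = C(C-1)/2 is the number of component pairs (rows) and N is the total
#' number of windows pooled over subjects (columns). \code{rowData} records
#' the component pair (i, j) of each connection; \code{colData} records
#' \code{subject_id}, \code{group}, \code{window_index} (1-based) and
#' \code{window_start} (0-based TR). Window geometry lives in
#' \code{metadata()} (\code{width}, \code{step}, \code{n_components},
#' \code{n_timepoints}).
#'
#' @seealso [slidingWindowFC()], [subjectFeatures()], [fitStateModel()]
#' @export
setClass("FCWindows", contains = "SummarizedExperiment")

setValidity("FCWindows", function(object) {
    msg <- NULL
    if (!"fc" %in% assayNames(object))
        msg <- c(msg, "assay 'fc' required")
    else {
        a <- assay(object, "fc")
        if (any(a < -1 - 1e-8 | a > 1 + 1e-8))
            msg <- c(msg, "correlation features must lie in [-1, 1]")
    }
    need <- c("subject_id", "group", "window_index", "window_start")
    if (!all(need %in% colnames(colData(object))))
        msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
    if (!all(c("i", "j") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain component indices 'i' and 'j'")
    if (is.null(msg)) TRUE else msg
})

#' StateModel: fitted k-means connectivity-state model
#'
#' Centroids of k recurring connectivity states over pooled window features,
#' together with the SSE-versus-k curve used for elbow model selection (when
#' available) and the training-window labels.
#'
#' @slot k integer, number of states.
#' @slot centroids k x E numeric matrix of state centroids.
#' @slot sse total within-cluster sum of squares of the fit.
#' @slot sseCurve named numeric vector mapping candidate k to SSE (empty if
#'   the model was fit at a fixed k).
#' @slot trainingLabels integer vector of state labels (1..k) for the pooled
#'   windows the model was fit on.
#' @slot seed,nInit RNG seed and number of k-means++ restarts used.
#'
#' @seealso [fitStateModel()], [selectStatesElbow()], [assignStates()]
#' @export
setClass("StateModel",
    representation(
        k = "integer",
        centroids = "matrix",
        sse = "numeric",
        sseCurve = "numeric",
        trainingLabels = "integer",
        seed = "integer",
        nInit = "integer"
    )
)

setValidity("StateModel", function(object) {
    msg <- NULL
    if (length(object@k) != 1L || object@k < 1L)
        msg <- c(msg, "k must be a single positive integer")
    if (nrow(object@centroids) != object@k)
        msg <- c(msg, "centroids must have k rows")
    if (length(object@trainingLabels) &&
        (min(object@trainingLabels) < 1L || max(object@trainingLabels) > object@k))
        msg <- c(msg, "training labels must lie in 1..k")
    if (is.null(msg)) TRUE else msg
})

#' StateOccupancy: per-subject state-occupancy count features
#'
#' For each subject, the number of sliding windows assigned to each
#' connectivity state: the 1 x k feature vector used for group
#' classification. Counts for a subject sum to that subject's window count W.
#'
#' @slot counts n_subjects x k integer matrix, rownames = subject ids.
#' @slot group factor of length n_subjects with two levels.
#'
#' @seealso [occupancyCounts()], [crossvalDecisionTree()],
#'   [stateOccupancyTests()]
#' @export
setClass("StateOccupancy",
    representation(counts = "matrix", group = "factor")
)

setValidity("StateOccupancy", function(object) {
    msg <- NULL
    if (nrow(object@counts) != length(object@group))
        msg <- c(msg, "one group label per subject row required")
    if (any(object@counts < 0))
        msg <- c(msg, "occupancy counts must be non-negative")
    if (is.null(rownames(object@counts)))
        msg <- c(msg, "counts must have subject ids as rownames")
    if (is.null(msg)) TRUE else msg
})

#' NetworkAtlas: binary resting-state-network template masks
#'
#' An ordered set of named binary 3-D masks on a common voxel grid, used to
#' allocate IC spatial maps to resting-state networks by maximal spatial
#' correlation. Ties in the allocation are broken by atlas order.
#'
#' @slot masks named list of 3-D arrays (0/1 or logical), all with identical
#'   dimensions; each mask non-empty.
#'
#' @seealso [assignComponents()], [readVolumes()]
#' @export
setClass("NetworkAtlas", representation(masks = "list"))

setValidity("NetworkAtlas", function(object) {
    msg <- NULL
    if (!length(object@masks) || is.null(names(object@masks)))
        msg <- c(msg, "masks must be a non-empty named list")
    else {
        dims <- lapply(object@masks, dim)
        if (any(vapply(dims, length, 1L) != 3L))
            msg <- c(msg, "each mask must be a 3-D array")
        else if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
            msg <- c(msg, "all masks must share the same grid dimensions")
        if (any(!vapply(object@masks, function(m) any(m != 0), logical(1))))
            msg <- c(msg, "each mask must contain at least one voxel")
    }
    if (is.null(msg)) TRUE else msg
})
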