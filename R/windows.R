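#' Number of sliding windows
#'
#' Window-count convention: \code{W = floor((T - width) / step)}, with
#' 0-based starts \code{0, step, ..., (W-1)*step} and half-open spans
#' \code{[start, start + width)}. With T = 215, width = 25 and step = 2 this
#' yields exactly 95 full windows. Note the fencepost-inclusive count would
#' be W + 1; the adopted convention keeps every window full and matches the
#' dimensioning used throughout the package.
#'
#' @param T number of time points.
#' @param width window length in TR.
#' @param step stride in TR.
#' @return integer number of windows.
#' @examples
#' countWindows(215, 25, 2)  # 95
#' @export
countWindows <- function(T, width = 25L, step = 2L) {
    if (width < 1L || width > T)
        stop("window width must satisfy 1 <= width <= T (T = ", T,
             ", width = ", width, ")")
    if (step < 1L) stop("step must be >= 1")
    as.integer((T - width) %/% step)
}

#' 0-based window start indices
#' @inheritParams countWindows
#' @return integer vector of 0-based start TRs.
#' @export
windowStarts <- function(T, width = 25L, step = 2L) {
    W <- countWindows(T, width, step)
    if (W == 0L) integer(0) else (seq_len(W) - 1L) * as.integer(step)
}

#' Component-pair index table
#'
#' Strictly-upper-triangular pairs (i, j), i < j, in row-major order — the
#' order in which [vectorizeUpper()] lays out connections.
#'
#' @param C number of components.
#' @return data.frame with integer columns \code{i} and \code{j} and
#'   \code{C(C-1)/2} rows.
#' @export
upperPairs <- function(C) {
    idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    data.frame(i = as.integer(idx[, "row"]), j = as.integer(idx[, "col"]))
}

#' Vectorize the upper triangle of a correlation matrix
#'
#' Extracts the strictly-upper-triangular entries of a symmetric
#' unit-diagonal matrix in row-major order (i < j), producing the length
#' C(C-1)/2 connection vector. [devectorizeUpper()] inverts the operation
#' exactly.
#'
#' @param corr square symmetric matrix with unit diagonal.
#' @param tol symmetry/diagonal tolerance.
#' @return numeric vector of length C(C-1)/2.
#' @examples
#' vectorizeUpper(diag(3))              # c(0, 0, 0)
#' length(vectorizeUpper(diag(44)))     # 946
#' @export
vectorizeUpper <- function(corr, tol = 1e-10) {
    if (!is.matrix(corr) || nrow(corr) != ncol(corr))
        stop("input must be a square matrix")
    if (max(abs(corr - t(corr))) > tol)
        stop("matrix is not symmetric within tolerance ", tol)
    if (max(abs(diag(corr) - 1)) > tol)
        stop("matrix must have unit diagonal within tolerance ", tol)
    t(corr)[lower.tri(corr)]
}

#' Reconstruct a correlation matrix from its vectorized upper triangle
#'
#' @param v vector of length C(C-1)/2 as produced by [vectorizeUpper()].
#' @return C x C symmetric matrix with unit diagonal.
#' @export
devectorizeUpper <- function(v) {
    E <- length(v)
    C <- (1 + sqrt(1 + 8 * E)) / 2
    if (abs(C - round(C)) > 1e-8)
        stop("length ", E, " is not C(C-1)/2 for any integer C")
    C <- as.integer(round(C))
    m <- diag(C)
    m[lower.tri(m)] <- v
    m <- t(m)
    m[lower.tri(m)] <- v
    t(m)
}

.windowFeatures <- function(mat, width, step, subject_id = "subject") {
    Tn <- nrow(mat)
    C <- ncol(mat)
    starts <- windowStarts(Tn, width, step)
    E <- C * (C - 1L) / 2L
    out <- matrix(NA_real_, length(starts), E)
    for (w in seq_along(starts)) {
        slice <- mat[(starts[w] + 1L):(starts[w] + width), , drop = FALSE]
        sds <- apply(slice, 2L, stats::sd)
        if (any(sds == 0))
            stop("zero-variance component in subject '", subject_id,
                 "', window ", w, ", component ",
                 paste(which(sds == 0), collapse = ", "))
        out[w, ] <- vectorizeUpper(stats::cor(slice), tol = 1e-8)
    }
    list(starts = starts, features = out)
}

#' Sliding-window functional connectivity
#'
#' For each subject, slides a rectangular (untapered) window of \code{width}
#' TR across the T x C time-course matrix in strides of \code{step} TR,
#' computes the Pearson correlation matrix of each windowed slice, and
#' vectorizes its strictly upper triangle ([vectorizeUpper()]). A T = 215,
#' C = 44 subject with the default 25/2 geometry yields a 95 x 946 feature
#' matrix. No Fisher z-transform is applied.
#'
#' The matrix method returns a list with elements \code{starts} (0-based)
#' and \code{features} (W x E). The [FCCohort-class] method pools all
#' subjects into an [FCWindows-class] object (connections x windows).
#'
#' @param x a numeric T x C matrix or an [FCCohort-class].
#' @param width window length in TR (default 25).
#' @param step stride in TR (default 2).
#' @param ... unused.
#' @return see Details.
#' @examples
#' cfg <- syntheticConfig(nPerGroup = 2, nComponents = 5, nTimepoints = 60,
#'                        nStates = 2, seed = 3)
#' fcw <- slidingWindowFC(simulateCohort(cfg), width = 20, step = 2)
#' fcw
#' @export
#' @rdname slidingWindowFC
setMethod("slidingWindowFC", "matrix", function(x, width = 25L, step = 2L, ...) {
    .windowFeatures(x, as.integer(width), as.integer(step))
})

#' @rdname slidingWindowFC
#' @export
setMethod("slidingWindowFC", "FCCohort", function(x, width = 25L, step = 2L, ...) {
    width <- as.integer(width)
    step <- as.integer(step)
    ids <- subjectIDs(x)
    grp <- groups(x)
    feats <- vector("list", length(ids))
    cd <- vector("list", length(ids))
    for (s in seq_along(ids)) {
        wf <- .windowFeatures(x@subjects[[ids[s]]], width, step, ids[s])
        feats[[s]] <- t(wf$features)
        cd[[s]] <- data.frame(
            subject_id = ids[s],
            group = grp[s],
            window_index = seq_along(wf$starts),
            window_start = wf$starts)
    }
    a <- do.call(cbind, feats)
    cdat <- do.call(rbind, cd)
    C <- ncol(x@subjects[[1]])
    pairs <- upperPairs(C)
    rd <- S4Vectors::DataFrame(pairs)
    rownames(a) <- paste0("c", pairs$i, "_", pairs$j)
    colnames(a) <- paste0(cdat$subject_id, ".w", cdat$window_index)
    se <- SummarizedExperiment(
        assays = list(fc = a),
        rowData = rd,
        colData = S4Vectors::DataFrame(cdat),
        metadata = list(width = width, step = step,
                        n_components = C,
                        n_timepoints = nrow(x@subjects[[1]])))
    new("FCWindows", se)
})

#' Write per-subject window features to TSV
#'
#' One TSV per subject with a leading \code{window_start} column followed by
#' the E connection features, plus a cohort-level stacked file
#' (\code{subject_id}, \code{window_index}, features).
#'
#' @param fcw an [FCWindows-class].
#' @param directory output directory.
#' @return invisible character vector of files written.
#' @export
writeDynamicFC <- function(fcw, directory) {
    stopifnot(is(fcw, "FCWindows"))
    if (!dir.exists(directory))
        dir.create(directory, recursive = TRUE)
    paths <- character(0)
    cd <- colData(fcw)
    for (id in subjectIDs(fcw)) {
        sel <- cd$subject_id == id
        df <- data.frame(window_start = cd$window_start[sel],
                         t(assay(fcw, "fc")[, sel, drop = FALSE]))
        p <- file.path(directory, paste0(id, "_dfc.tsv"))
        utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
        paths[id] <- p
    }
    stacked <- data.frame(subject_id = cd$subject_id,
                          window_index = cd$window_index,
                          t(assay(fcw, "fc")))
    p <- file.path(directory, "dfc_stacked.tsv")
    utils::write.table(stacked, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths["stacked"] <- p
    invisible(paths)
}
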