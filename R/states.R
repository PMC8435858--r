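# Squared Euclidean distances from each row of x to each row of centers.
.sqDist <- function(x, centers) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
    pmax(d2, 0)
}

# k-means++ seeding (Arthur & Vassilvitskii). Falls back to uniform draws
# when all candidate distances are zero (degenerate data).
.kmeansppInit <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1L), ]
    if (k > 1L) {
        d2 <- .sqDist(x, centers[1, , drop = FALSE])[, 1]
        for (j in 2:k) {
            tot <- sum(d2)
            pick <- if (tot > 0) sample.int(n, 1L, prob = d2 / tot)
                    else sample.int(n, 1L)
            centers[j, ] <- x[pick, ]
            d2 <- pmin(d2, .sqDist(x, centers[j, , drop = FALSE])[, 1])
        }
    }
    centers
}

# Plain Lloyd iterations with farthest-point re-seeding of empty clusters.
# Used when stats::kmeans rejects an initialization (duplicate centers /
# degenerate data); stats::kmeans does the heavy lifting otherwise.
.lloyd <- function(x, centers, maxIter) {
    k <- nrow(centers)
    labels <- integer(nrow(x))
    for (it in seq_len(maxIter)) {
        d2 <- .sqDist(x, centers)
        newLabels <- max.col(-d2, ties.method = "first")
        mind2 <- d2[cbind(seq_len(nrow(x)), newLabels)]
        for (j in seq_len(k)) {
            if (!any(newLabels == j)) {
                far <- which.max(mind2)
                centers[j, ] <- x[far, ]
                newLabels[far] <- j
                mind2[far] <- 0
            }
        }
        if (identical(newLabels, labels)) break
        labels <- newLabels
        for (j in seq_len(k))
            if (any(labels == j))
                centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    list(centers = centers, labels = labels)
}

.kmeansOnce <- function(x, k, maxIter) {
    init <- .kmeansppInit(x, k)
    if (anyDuplicated(init)) {
        fit <- .lloyd(x, init, maxIter)
        centers <- fit$centers
    } else {
        km <- tryCatch(
            suppressWarnings(stats::kmeans(x, centers = init,
                iter.max = maxIter, algorithm = "Lloyd")),
            error = function(e) NULL)
        centers <- if (is.null(km)) .lloyd(x, init, maxIter)$centers
                   else km$centers
    }
    # post-hoc consistency: labels are argmin distance to the final
    # centroids, ties to the lowest state index
    d2 <- .sqDist(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k))
        if (any(labels == j))
            centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    d2 <- .sqDist(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    sse <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    list(centers = centers, labels = labels, sse = sse)
}

.fitKMeansMatrix <- function(x, k, seed, nInit, maxIter) {
    if (!is.matrix(x)) x <- as.matrix(x)
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k > nrow(x))
        stop("k (", k, ") exceeds the number of windows (", nrow(x), ")")
    set.seed(as.integer(seed))
    best <- NULL
    for (r in seq_len(nInit)) {
        fit <- .kmeansOnce(x, k, maxIter)
        if (is.null(best) || fit$sse < best$sse)
            best <- fit
    }
    new("StateModel",
        k = k,
        centroids = best$centers,
        sse = best$sse,
        sseCurve = stats::setNames(numeric(0), character(0)),
        trainingLabels = as.integer(best$labels),
        seed = as.integer(seed),
        nInit = as.integer(nInit))
}

#' Fit a k-means connectivity-state model
#'
#' Clusters pooled window features into k states with Lloyd's algorithm,
#' k-means++ seeding and best-of-\code{nInit} restarts by within-cluster sum
#' of squares (SSE). Final labels are the argmin-distance centroid for every
#' window, ties broken towards the lowest state index; an empty cluster
#' arising during iteration is re-seeded at the point farthest from its
#' centroid. Deterministic under a fixed seed.
#'
#' @param x pooled N x E window matrix (windows as rows) or an
#'   [FCWindows-class] (its pooled features are used and the training labels
#'   stay aligned with its columns).
#' @param k number of states (1 <= k <= N).
#' @param seed RNG seed.
#' @param nInit number of restarts.
#' @param maxIter maximum Lloyd iterations per restart.
#' @return a [StateModel-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
#' fitStateModel(x, k = 2, seed = 1, nInit = 5)
#' @export
#' @rdname fitStateModel
setMethod("fitStateModel", "matrix",
    function(x, k, seed = 1L, nInit = 20L, maxIter = 300L)
        .fitKMeansMatrix(x, k, seed, nInit, maxIter))

#' @rdname fitStateModel
#' @export
setMethod("fitStateModel", "FCWindows",
    function(x, k, seed = 1L, nInit = 20L, maxIter = 300L)
        .fitKMeansMatrix(pooledFeatures(x), k, seed, nInit, maxIter))

.elbowFromCurve <- function(ks, sse) {
    # knee: max perpendicular distance to the chord joining the curve's
    # endpoints, computed in axis-normalized coordinates; near-flat curves
    # (no cluster structure) fall back to the smallest k
    drop <- sse[1] - sse[length(sse)]
    if (drop <= 1e-8 * max(sse[1], .Machine$double.xmin))
        return(ks[1])
    kn <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
    sn <- (sse - sse[length(sse)]) / drop
    # distance from (kn, sn) to the line through (0,1) and (1,0)
    d <- (1 - kn - sn) / sqrt(2)
    ks[which.max(d)]
}

#' Select the number of states by the elbow criterion
#'
#' Fits k-means for each candidate k in \code{[kMin, kMax]} and picks the k
#' whose point on the SSE-versus-k curve lies farthest from the chord
#' joining the curve's endpoints (a "kneedle"-style rule, computed after
#' normalizing both axes to \eqn{[0,1]}). Ties and structureless (flat)
#' curves resolve to the smallest candidate k. A non-monotone SSE curve
#' triggers a warning but the rule is still applied.
#'
#' @param x pooled N x E window matrix or an [FCWindows-class].
#' @param kMin,kMax candidate range (\code{kMax >= kMin + 2}).
#' @param seed RNG seed; each candidate k uses a seed derived from it.
#' @param nInit restarts per candidate.
#' @param maxIter maximum Lloyd iterations.
#' @return a [StateModel-class] fit at the selected k, with the full
#'   SSE-versus-k curve in [sseCurve()].
#' @examples
#' set.seed(2)
#' x <- do.call(rbind, lapply(c(0, 8, 16), function(m)
#'     matrix(rnorm(60, m, 0.3), 30)))
#' nStates(selectStatesElbow(x, 1, 6, seed = 1, nInit = 5))  # 3
#' @export
#' @rdname selectStatesElbow
setMethod("selectStatesElbow", "matrix",
    function(x, kMin = 2L, kMax = 9L, seed = 1L, nInit = 20L, maxIter = 300L) {
        kMin <- as.integer(kMin); kMax <- as.integer(kMax)
        if (kMin < 1L) stop("kMin must be >= 1")
        if (kMax < kMin + 2L) stop("kMax must be >= kMin + 2")
        if (nrow(x) < kMax)
            stop("need at least kMax windows (kMax = ", kMax, ")")
        ks <- kMin:kMax
        fits <- lapply(ks, function(k)
            .fitKMeansMatrix(x, k, seed = as.integer(seed) + 97L * k,
                             nInit = nInit, maxIter = maxIter))
        sse <- vapply(fits, function(f) f@sse, numeric(1))
        if (any(diff(sse) > 1e-8 * abs(sse[1])))
            warning("SSE curve is not non-increasing in k; ",
                    "elbow rule applied regardless")
        kOpt <- .elbowFromCurve(ks, sse)
        model <- fits[[match(kOpt, ks)]]
        model@sseCurve <- stats::setNames(sse, ks)
        model
    })

#' @rdname selectStatesElbow
#' @export
setMethod("selectStatesElbow", "FCWindows",
    function(x, kMin = 2L, kMax = 9L, seed = 1L, nInit = 20L, maxIter = 300L)
        selectStatesElbow(pooledFeatures(x), kMin, kMax, seed, nInit, maxIter))

#' Assign windows to the nearest state centroid
#'
#' Labels each feature row with the nearest centroid of a fitted
#' [StateModel-class] (Euclidean distance, ties to the lowest state index).
#'
#' @param model a [StateModel-class].
#' @param features W x E matrix, an E-vector, or an [FCWindows-class].
#' @return integer state labels in \code{1..k}.
#' @export
#' @rdname assignStates
setMethod("assignStates", signature("StateModel", "matrix"),
    function(model, features) {
        if (ncol(features) != ncol(model@centroids))
            stop("feature dimension (", ncol(features),
                 ") does not match centroids (", ncol(model@centroids), ")")
        d2 <- .sqDist(features, model@centroids)
        as.integer(max.col(-d2, ties.method = "first"))
    })

#' @rdname assignStates
#' @export
setMethod("assignStates", signature("StateModel", "numeric"),
    function(model, features)
        assignStates(model, matrix(features, nrow = 1L)))

#' @rdname assignStates
#' @export
setMethod("assignStates", signature("StateModel", "FCWindows"),
    function(model, features)
        assignStates(model, pooledFeatures(features)))

#' Per-subject state-occupancy counts
#'
#' Counts, for each subject, the number of windows assigned to each state —
#' the 1 x k occupancy feature vector used for classification. Counts sum to
#' each subject's window count.
#'
#' @param fcw an [FCWindows-class] whose columns the labels refer to.
#' @param labels integer state labels in \code{1..k}, aligned with
#'   \code{colnames(fcw)} (e.g. [trainingLabels()] of a model fit on
#'   \code{fcw}, or [assignStates()] output).
#' @param k number of states (default \code{max(labels)}).
#' @return a [StateOccupancy-class].
#' @export
occupancyCounts <- function(fcw, labels, k = max(labels)) {
    stopifnot(is(fcw, "FCWindows"))
    labels <- as.integer(labels)
    if (length(labels) != ncol(fcw))
        stop("need one label per window column")
    if (any(labels < 1L) || any(labels > k))
        stop("labels must lie in 1..k")
    cd <- colData(fcw)
    ids <- subjectIDs(fcw)
    counts <- t(vapply(ids, function(id)
        tabulate(labels[cd$subject_id == id], nbins = k),
        integer(k)))
    rownames(counts) <- ids
    colnames(counts) <- paste0("state", seq_len(k))
    grp <- cd$group[match(ids, cd$subject_id)]
    new("StateOccupancy", counts = counts, group = grp)
}

#' Per-subject matrix of window state labels
#'
#' Rearranges pooled window labels into a subjects x windows matrix (rows in
#' cohort order, columns by window index), the layout used by
#' [windowDifferenceSelection()].
#'
#' @inheritParams occupancyCounts
#' @return integer matrix, subjects x W, with subject ids as rownames.
#' @export
stateAssignmentMatrix <- function(fcw, labels) {
    stopifnot(is(fcw, "FCWindows"))
    labels <- as.integer(labels)
    if (length(labels) != ncol(fcw))
        stop("need one label per window column")
    cd <- colData(fcw)
    ids <- subjectIDs(fcw)
    W <- max(cd$window_index)
    m <- matrix(NA_integer_, length(ids), W,
                dimnames = list(ids, NULL))
    for (s in seq_along(ids)) {
        sel <- cd$subject_id == ids[s]
        m[s, cd$window_index[sel]] <- labels[sel]
    }
    m
}
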