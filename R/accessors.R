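#' @describeIn FCCohort-class subject identifiers in cohort order.
#' @export
setMethod("subjectIDs", "FCCohort", function(x)
    as.character(x@subjectData$subject_id))

#' @describeIn FCCohort-class group factor, one entry per subject.
#' @export
setMethod("groups", "FCCohort", function(x) x@subjectData$group)

#' @describeIn FCCohort-class a subject's T x C time-course matrix.
#' @export
setMethod("timeCourses", "FCCohort", function(x, id) {
    if (!id %in% names(x@subjects))
        stop("unknown subject id: ", id)
    x@subjects[[id]]
})

#' @describeIn FCCohort-class named list of ground-truth state sequences
#'   (empty for real data).
#' @export
setMethod("trueStates", "FCCohort", function(x) x@trueStates)

setMethod("show", "FCCohort", function(object) {
    d <- if (length(object@subjects)) dim(object@subjects[[1]]) else c(0L, 0L)
    cat("FCCohort with", length(object@subjects), "subjects (",
        paste(table(groups(object)), collapse = " + "), "by group )\n")
    cat("  time courses:", d[1], "time points x", d[2], "components\n")
    cat("  ground-truth states:",
        if (length(object@trueStates)) "available" else "none", "\n")
})

#' @describeIn FCWindows-class subject identifiers (unique, cohort order).
#' @export
setMethod("subjectIDs", "FCWindows", function(x)
    unique(as.character(colData(x)$subject_id)))

#' @describeIn FCWindows-class group factor, one entry per window column.
#' @export
setMethod("groups", "FCWindows", function(x) colData(x)$group)

setMethod("show", "FCWindows", function(object) {
    md <- metadata(object)
    cat("FCWindows:", nrow(object), "connections x", ncol(object),
        "windows pooled over", length(subjectIDs(object)), "subjects\n")
    cat("  window width", md$width, "TR, step", md$step, "TR;",
        md$n_components, "components,", md$n_timepoints, "time points\n")
})

#' Pooled window-feature matrix
#'
#' Returns the N x E matrix of pooled window features (windows as rows), the
#' orientation used by the clustering stage.
#'
#' @param x an [FCWindows-class] object.
#' @return numeric matrix with one row per window and one column per
#'   component pair.
#' @export
pooledFeatures <- function(x) {
    stopifnot(is(x, "FCWindows"))
    t(assay(x, "fc"))
}

#' Per-subject window-feature matrix
#'
#' @param x an [FCWindows-class] object.
#' @param id subject identifier.
#' @return W x E numeric matrix of that subject's window features, rows
#'   ordered by window index.
#' @export
subjectFeatures <- function(x, id) {
    stopifnot(is(x, "FCWindows"))
    sel <- colData(x)$subject_id == id
    if (!any(sel))
        stop("unknown subject id: ", id)
    m <- t(assay(x, "fc")[, sel, drop = FALSE])
    rownames(m) <- colData(x)$window_index[sel]
    m[order(colData(x)$window_index[sel]), , drop = FALSE]
}

#' @describeIn StateModel-class number of states k.
#' @export
setMethod("nStates", "StateModel", function(x) x@k)

#' @describeIn StateModel-class k x E centroid matrix.
#' @export
setMethod("stateCentroids", "StateModel", function(x) x@centroids)

#' @describeIn StateModel-class named SSE-versus-k curve (empty if fit at
#'   fixed k).
#' @export
setMethod("sseCurve", "StateModel", function(x) x@sseCurve)

#' @describeIn StateModel-class state labels of the pooled training windows.
#' @export
setMethod("trainingLabels", "StateModel", function(x) x@trainingLabels)

setMethod("show", "StateModel", function(object) {
    cat("StateModel:", object@k, "connectivity states over",
        ncol(object@centroids), "connections\n")
    cat("  total within-cluster SSE:", format(object@sse), "\n")
    if (length(object@sseCurve))
        cat("  elbow curve over k =", paste(names(object@sseCurve),
            collapse = ", "), "\n")
})

#' @describeIn StateOccupancy-class n_subjects x k count matrix.
#' @export
setMethod("occupancyMatrix", "StateOccupancy", function(x) x@counts)

#' @describeIn StateOccupancy-class group factor, one entry per subject.
#' @export
setMethod("groups", "StateOccupancy", function(x) x@group)

#' @describeIn StateOccupancy-class subject identifiers.
#' @export
setMethod("subjectIDs", "StateOccupancy", function(x) rownames(x@counts))

setMethod("show", "StateOccupancy", function(object) {
    cat("StateOccupancy:", nrow(object@counts), "subjects x",
        ncol(object@counts), "states\n")
    cat("  groups:", paste(levels(object@group), table(object@group),
        sep = ":", collapse = "  "), "\n")
})

#' @describeIn NetworkAtlas-class ordered network names.
#' @export
setMethod("networkNames", "NetworkAtlas", function(x) names(x@masks))

#' @describeIn NetworkAtlas-class named list of binary mask arrays.
#' @export
setMethod("networkMasks", "NetworkAtlas", function(x) x@masks)

setMethod("show", "NetworkAtlas", function(object) {
    cat("NetworkAtlas:", length(object@masks), "networks on grid",
        paste(dim(object@masks[[1]]), collapse = " x "), "\n")
    cat(" ", paste(names(object@masks), collapse = ", "), "\n")
})
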