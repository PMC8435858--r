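#' Construct a network atlas from binary masks
#'
#' @param masks named list of 3-D arrays (0/1 or logical) on a common grid.
#'   List order defines the tie-breaking order of [assignComponents()]. The
#'   conventional resting-state set has 11 networks (ASN, AN, DDMN, HVN, LN,
#'   PSN, PN, RECN, SN, VDMN, VN), but any non-empty named set is accepted.
#' @return a [NetworkAtlas-class].
#' @export
NetworkAtlas <- function(masks) {
    masks <- lapply(masks, function(m) {
        storage.mode(m) <- "double"
        m
    })
    new("NetworkAtlas", masks = masks)
}

#' Read NIfTI volumes on a consistent grid
#'
#' Reads one or more NIfTI-1 files (plain or gzipped) and verifies that all
#' share the same voxel grid and affine orientation.
#'
#' @param paths character vector of \file{.nii}/\file{.nii.gz} paths.
#' @return list with \code{volumes} (named list of 3-D arrays),
#'   \code{dim}, and \code{affine} (the shared 4 x 4 voxel-to-world
#'   matrix).
#' @export
readVolumes <- function(paths) {
    vols <- lapply(paths, function(p) {
        if (!file.exists(p)) stop("cannot read volume: ", p)
        RNifti::readNifti(p)
    })
    names(vols) <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
        names(paths) else basename(paths)
    dims <- lapply(vols, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
        stop("grid mismatch: volumes have dimensions ",
             paste(unique(vapply(dims, paste, "", collapse = "x")),
                   collapse = " vs "))
    affs <- lapply(vols, function(v) unclass(RNifti::xform(v)))
    for (i in seq_along(affs)[-1])
        if (max(abs(affs[[i]] - affs[[1]])) > 1e-4)
            stop("grid mismatch: volume '", names(vols)[i],
                 "' has a different affine than '", names(vols)[1], "'")
    list(volumes = lapply(vols, function(v) {
            a <- as.array(v)
            attributes(a)[setdiff(names(attributes(a)), "dim")] <- NULL
            a
         }),
         dim = dims[[1]],
         affine = affs[[1]])
}

#' Assign IC spatial maps to networks by maximal spatial correlation
#'
#' Each IC map is z-scored and correlated (Pearson) with every binary
#' network mask over the support voxels — by default the union of all mask
#' voxels, since correlating over empty background inflates coefficients —
#' and allocated to the network with the highest coefficient. Ties break by
#' atlas order. The full coefficient table is retained.
#'
#' @param icMaps named list of 3-D arrays on the atlas grid.
#' @param atlas a [NetworkAtlas-class].
#' @param support \code{"union"} (voxels inside any mask) or \code{"all"}
#'   (whole volume).
#' @return data.frame with one row per IC: \code{ic}, \code{network}, and
#'   one \code{coeff_<name>} column per network.
#' @export
assignComponents <- function(icMaps, atlas, support = c("union", "all")) {
    stopifnot(is(atlas, "NetworkAtlas"))
    support <- match.arg(support)
    masks <- networkMasks(atlas)
    gdim <- dim(masks[[1]])
    if (is.null(names(icMaps)))
        names(icMaps) <- paste0("IC", seq_along(icMaps))
    for (nm in names(icMaps))
        if (!identical(dim(icMaps[[nm]]), gdim))
            stop("grid mismatch: IC '", nm, "' is ",
                 paste(dim(icMaps[[nm]]), collapse = "x"),
                 " but atlas grid is ", paste(gdim, collapse = "x"))
    vox <- if (support == "union")
        which(Reduce("+", masks) > 0) else seq_len(prod(gdim))
    maskVecs <- vapply(masks, function(m) as.numeric(m[vox]),
                       numeric(length(vox)))
    if (any(apply(maskVecs, 2, stats::sd) == 0))
        stop("a mask is constant over the correlation support; ",
             "use support = 'all' or check the atlas")
    coeffs <- t(vapply(names(icMaps), function(nm) {
        v <- as.numeric(icMaps[[nm]][vox])
        if (stats::sd(v) == 0)
            stop("IC '", nm, "' is constant over the correlation support; ",
                 "correlation undefined")
        v <- (v - mean(v)) / stats::sd(v)
        as.numeric(stats::cor(v, maskVecs))
    }, numeric(length(masks))))
    colnames(coeffs) <- names(masks)
    best <- max.col(coeffs, ties.method = "first")
    out <- data.frame(ic = names(icMaps),
                      network = names(masks)[best],
                      stringsAsFactors = FALSE)
    co <- as.data.frame(coeffs)
    names(co) <- paste0("coeff_", names(masks))
    rownames(out) <- NULL
    cbind(out, co)
}

#' Per-network mean map intensity for each subject
#'
#' Subject-level spatial summary used by [networkSpatialGroupTest()]: the
#' mean intensity of each subject's map within each network mask.
#'
#' @param subjectMaps named list of per-subject 3-D arrays on the atlas
#'   grid.
#' @param atlas a [NetworkAtlas-class].
#' @return numeric matrix, subjects x networks.
#' @export
maskMeanSummaries <- function(subjectMaps, atlas) {
    stopifnot(is(atlas, "NetworkAtlas"))
    masks <- networkMasks(atlas)
    gdim <- dim(masks[[1]])
    out <- t(vapply(subjectMaps, function(v) {
        if (!identical(dim(v), gdim))
            stop("grid mismatch between subject map and atlas")
        vapply(masks, function(m) mean(v[m > 0]), numeric(1))
    }, numeric(length(masks))))
    colnames(out) <- names(masks)
    out
}

#' Per-network spatial-domain group tests
#'
#' For each network, a two-sample t-test across groups on a subject-level
#' scalar spatial summary (one value per subject per network, e.g. from
#' [maskMeanSummaries()]). Networks with constant summaries are skipped
#' with a warning.
#'
#' @param summaries subjects x networks numeric matrix.
#' @param group group factor aligned with the rows.
#' @param equalVar pooled-variance t-test (default) or Welch.
#' @return data.frame with one row per network: \code{network}, \code{t},
#'   \code{p}.
#' @export
networkSpatialGroupTest <- function(summaries, group, equalVar = TRUE) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2L) stop("both groups must be represented")
    if (nrow(summaries) != length(group))
        stop("one group label per subject row required")
    lv <- levels(group)
    res <- lapply(colnames(summaries), function(nw) {
        x <- summaries[group == lv[1], nw]
        y <- summaries[group == lv[2], nw]
        if (stats::var(c(x, y)) == 0) {
            warning("network ", nw, ": constant summaries; test skipped")
            return(data.frame(network = nw, t = NA_real_, p = NA_real_))
        }
        tt <- twoSampleT(x, y, equalVar = equalVar)
        data.frame(network = nw, t = tt$t, p = tt$p)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
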