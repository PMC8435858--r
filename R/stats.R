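#' Two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] returning the statistic, two-sided
#' p-value and degrees of freedom; pooled-variance (Student) by default,
#' Welch when \code{equalVar = FALSE}. Errors when both samples are
#' essentially constant (zero pooled variance).
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param equalVar assume equal variances (classical two-sample t-test).
#' @return named list with \code{t}, \code{p}, \code{df}.
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleT <- function(x, y, equalVar = TRUE) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 values")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("values must be finite")
    if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (mean(x) == mean(y))
            return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
        stop("zero pooled variance with unequal means; t undefined")
    }
    ht <- stats::t.test(x, y, var.equal = equalVar)
    list(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter))
}

#' Per-state group tests of occupancy counts
#'
#' One two-sample t-test per state on subjects' window counts, comparing the
#' two groups. The state with the smallest p-value is flagged as the
#' discriminative state. States whose counts are constant in both groups are
#' skipped with a warning (NA statistics).
#'
#' @param occupancy a [StateOccupancy-class].
#' @param equalVar pooled-variance t-test (default) or Welch.
#' @return data.frame with one row per state: \code{state}, \code{t},
#'   \code{p}, per-group mean counts, and logical \code{discriminative}.
#' @export
stateOccupancyTests <- function(occupancy, equalVar = TRUE) {
    stopifnot(is(occupancy, "StateOccupancy"))
    grp <- groups(occupancy)
    if (nlevels(droplevels(grp)) != 2L)
        stop("both groups must be present")
    counts <- occupancyMatrix(occupancy)
    lv <- levels(droplevels(grp))
    res <- lapply(seq_len(ncol(counts)), function(k) {
        x <- counts[grp == lv[1], k]
        y <- counts[grp == lv[2], k]
        if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) != mean(y))
            return(data.frame(state = k, t = NA_real_, p = NA_real_,
                              mean_a = mean(x), mean_b = mean(y)))
        if (stats::var(c(x, y)) == 0) {
            warning("state ", k, ": counts constant in both groups; ",
                    "test skipped")
            return(data.frame(state = k, t = NA_real_, p = NA_real_,
                              mean_a = mean(x), mean_b = mean(y)))
        }
        tt <- twoSampleT(x, y, equalVar = equalVar)
        data.frame(state = k, t = tt$t, p = tt$p,
                   mean_a = mean(x), mean_b = mean(y))
    })
    res <- do.call(rbind, res)
    names(res)[names(res) == "mean_a"] <- paste0("mean_", lv[1])
    names(res)[names(res) == "mean_b"] <- paste0("mean_", lv[2])
    res$discriminative <- FALSE
    if (any(!is.na(res$p)))
        res$discriminative[which.min(res$p)] <- TRUE
    res
}

#' Window-index difference profile and selection
#'
#' For the target (discriminative) state, counts at each window index w how
#' many subjects of each group occupy that state at window w, takes the
#' absolute group difference d_w, and selects the windows whose difference
#' strictly exceeds the mean difference over all windows.
#'
#' @param assignment subjects x W integer matrix of window state labels
#'   (from [stateAssignmentMatrix()]).
#' @param group group factor aligned with the matrix rows.
#' @param targetState the state whose occupancy is profiled.
#' @return data.frame with one row per window index: \code{window}
#'   (1-based), per-group counts, \code{difference}, logical
#'   \code{selected}.
#' @export
windowDifferenceSelection <- function(assignment, group, targetState) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2L) stop("exactly two groups required")
    if (nrow(assignment) != length(group))
        stop("one group label per assignment row required")
    if (!targetState %in% assignment)
        warning("target state ", targetState,
                " never occupied by any window")
    lv <- levels(group)
    inState <- assignment == targetState
    nA <- colSums(inState[group == lv[1], , drop = FALSE])
    nB <- colSums(inState[group == lv[2], , drop = FALSE])
    d <- abs(nA - nB)
    out <- data.frame(window = seq_len(ncol(assignment)), nA = nA, nB = nB,
                      difference = d, selected = d > mean(d))
    names(out)[2:3] <- paste0("n_", lv)
    rownames(out) <- NULL
    out
}

# Vectorized pooled/Welch two-sample t across the columns of a and b
# (groups as rows); returns t and two-sided p per column.
.columnTTests <- function(a, b, equalVar = TRUE) {
    na <- nrow(a); nb <- nrow(b)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
    if (equalVar) {
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
        se <- sqrt(sp2 * (1 / na + 1 / nb))
        df <- rep(na + nb - 2, length(ma))
    } else {
        se <- sqrt(va / na + vb / nb)
        df <- (va / na + vb / nb)^2 /
            ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    t <- (ma - mb) / se
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, p = p, df = df)
}

#' Connection-wise group tests over selected windows
#'
#' Averages, per subject, each connection's correlation over the selected
#' window indices, then compares the two groups connection-by-connection
#' with two-sample t-tests and Benjamini-Hochberg FDR adjustment across all
#' E connections. By default a connection is significant when its
#' BH-adjusted p-value falls below \code{threshold} (default 1e-4);
#' \code{mode = "raw"} thresholds the raw p-values instead.
#'
#' @param fcw an [FCWindows-class].
#' @param selectedWindows non-empty vector of 1-based window indices (e.g.
#'   from [windowDifferenceSelection()]).
#' @param threshold significance threshold on the (adjusted) p-value.
#' @param mode \code{"adjusted"} (threshold BH-adjusted p) or \code{"raw"}.
#' @param equalVar pooled-variance t-tests (default) or Welch.
#' @param icNetworks optional named character vector mapping component index
#'   (as character) or \code{IC<i>} to a network name, used to annotate
#'   each connection with its network pair.
#' @return data.frame with one row per connection: \code{i}, \code{j},
#'   \code{t}, \code{p}, \code{p_adj}, \code{significant},
#'   \code{higher_group}, and (when \code{icNetworks} is given)
#'   \code{network_i}, \code{network_j}, \code{network_pair}.
#' @export
connectionGroupTests <- function(fcw, selectedWindows, threshold = 1e-4,
                                 mode = c("adjusted", "raw"),
                                 equalVar = TRUE, icNetworks = NULL) {
    stopifnot(is(fcw, "FCWindows"))
    mode <- match.arg(mode)
    selectedWindows <- unique(as.integer(selectedWindows))
    if (!length(selectedWindows))
        stop("no windows selected; inspect the window difference profile")
    cd <- colData(fcw)
    if (any(!selectedWindows %in% cd$window_index))
        stop("selected window indices outside the available range")
    ids <- subjectIDs(fcw)
    a <- assay(fcw, "fc")
    subjMeans <- t(vapply(ids, function(id) {
        sel <- cd$subject_id == id & cd$window_index %in% selectedWindows
        rowMeans(a[, sel, drop = FALSE])
    }, numeric(nrow(fcw))))
    grp <- droplevels(cd$group[match(ids, cd$subject_id)])
    if (nlevels(grp) != 2L) stop("both groups must be present")
    lv <- levels(grp)
    tt <- .columnTTests(subjMeans[grp == lv[1], , drop = FALSE],
                        subjMeans[grp == lv[2], , drop = FALSE],
                        equalVar = equalVar)
    pAdj <- stats::p.adjust(tt$p, method = "BH")
    sig <- if (mode == "adjusted") pAdj < threshold else tt$p < threshold
    higher <- ifelse(colMeans(subjMeans[grp == lv[1], , drop = FALSE]) >
                     colMeans(subjMeans[grp == lv[2], , drop = FALSE]),
                     lv[1], lv[2])
    rd <- rowData(fcw)
    out <- data.frame(i = rd$i, j = rd$j, t = tt$t, p = tt$p, p_adj = pAdj,
                      significant = sig, higher_group = higher)
    if (!is.null(icNetworks)) {
        lookup <- function(ic) {
            key <- as.character(ic)
            net <- icNetworks[key]
            if (is.na(net)) net <- icNetworks[paste0("IC", key)]
            if (is.na(net))
                stop("component ", key, " has no network assignment")
            unname(net)
        }
        out$network_i <- vapply(out$i, lookup, "")
        out$network_j <- vapply(out$j, lookup, "")
        out$network_pair <- paste(pmin(out$network_i, out$network_j),
                                  pmax(out$network_i, out$network_j),
                                  sep = "-")
    }
    rownames(out) <- NULL
    out
}

#' Summarize significant connections by network and network pair
#'
#' Tallies the significant connections of a connection test table per
#' network (connections touching the network) and per unordered network
#' pair, split by which group's mean connectivity is higher, and identifies
#' the network carrying the most significant connections.
#'
#' @param table output of [connectionGroupTests()]; must carry network
#'   annotation (pass \code{icNetworks} there, or supply it here).
#' @param icNetworks optional IC-to-network map used when \code{table}
#'   lacks network columns.
#' @return list with \code{perNetwork} (data.frame: network, counts split
#'   by higher group, total), \code{perPair} (data.frame keyed by network
#'   pair), and \code{topNetwork}.
#' @export
summarizeNetworkPairs <- function(table, icNetworks = NULL) {
    if (!all(c("network_i", "network_j") %in% names(table))) {
        if (is.null(icNetworks))
            stop("table lacks network annotation and no icNetworks given")
        lookup <- function(ic) {
            key <- as.character(ic)
            net <- icNetworks[key]
            if (is.na(net)) net <- icNetworks[paste0("IC", key)]
            if (is.na(net)) stop("component ", key, " unmapped")
            unname(net)
        }
        table$network_i <- vapply(table$i, lookup, "")
        table$network_j <- vapply(table$j, lookup, "")
        table$network_pair <- paste(pmin(table$network_i, table$network_j),
                                    pmax(table$network_i, table$network_j),
                                    sep = "-")
    }
    sig <- table[table$significant, , drop = FALSE]
    nets <- sort(unique(c(table$network_i, table$network_j)))
    lv <- sort(unique(table$higher_group))
    perNetwork <- do.call(rbind, lapply(nets, function(nw) {
        touch <- sig$network_i == nw | sig$network_j == nw
        row <- data.frame(network = nw, total = sum(touch))
        for (g in lv)
            row[[paste0("higher_", g)]] <- sum(touch & sig$higher_group == g)
        row
    }))
    pairs <- sort(unique(sig$network_pair))
    perPair <- do.call(rbind, c(list(data.frame(network_pair = character(0),
                                                total = integer(0))),
        lapply(pairs, function(pp) {
            sel <- sig$network_pair == pp
            row <- data.frame(network_pair = pp, total = sum(sel))
            for (g in lv)
                row[[paste0("higher_", g)]] <- sum(sel & sig$higher_group == g)
            row
        })))
    top <- if (nrow(perNetwork) && any(perNetwork$total > 0))
        perNetwork$network[which.max(perNetwork$total)] else NA_character_
    list(perNetwork = perNetwork, perPair = perPair, topNetwork = top)
}

#' Export the significant-connection graph in Pajek format
#'
#' Writes the significant connections as an undirected Pajek \file{.net}
#' graph (via \pkg{igraph}), vertices named \code{IC<i>}, with an edge
#' weight of +1 when the first group's mean connectivity is higher and -1
#' otherwise.
#'
#' @param table output of [connectionGroupTests()].
#' @param file output path.
#' @param higherGroup group name mapped to weight +1 (default: first
#'   alphabetically present).
#' @return invisible path of the file written.
#' @export
writePajek <- function(table, file, higherGroup = NULL) {
    sig <- table[table$significant, , drop = FALSE]
    if (is.null(higherGroup))
        higherGroup <- sort(unique(table$higher_group))[1]
    ics <- sort(unique(c(table$i, table$j)))
    g <- igraph::make_empty_graph(n = length(ics), directed = FALSE)
    igraph::V(g)$id <- paste0("IC", ics)
    igraph::V(g)$name <- paste0("IC", ics)
    if (nrow(sig)) {
        ei <- rbind(match(sig$i, ics), match(sig$j, ics))
        g <- igraph::add_edges(g, as.vector(ei))
        igraph::E(g)$weight <- ifelse(sig$higher_group == higherGroup, 1, -1)
    }
    igraph::write_graph(g, file, format = "pajek")
    invisible(file)
}
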