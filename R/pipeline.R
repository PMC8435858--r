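#' Motion quality control from realignment parameters
#'
#' Excludes a subject when any absolute translation exceeds
#' \code{transThreshold} millimetres or any absolute rotation exceeds
#' \code{rotThreshold} degrees (strict inequalities: a subject exactly at a
#' threshold is kept). Realignment series have six columns: three
#' translations (mm) then three rotations (degrees).
#'
#' @param params named list of T x 6 numeric matrices, or a character vector
#'   of whitespace-delimited parameter files (one per subject).
#' @param transThreshold translation threshold in mm (default 2).
#' @param rotThreshold rotation threshold in degrees (default 2).
#' @return list with \code{kept}, \code{excluded} (subject id vectors) and
#'   \code{report} (data.frame: subject, max absolute translation/rotation,
#'   excluded flag, reason).
#' @examples
#' ok <- matrix(0, 10, 6)
#' bad <- ok; bad[4, 2] <- 2.5
#' motionQC(list(a = ok, b = bad))$excluded
#' @export
motionQC <- function(params, transThreshold = 2, rotThreshold = 2) {
    stopifnot(transThreshold > 0, rotThreshold > 0)
    if (is.character(params)) {
        paths <- params
        ids <- if (!is.null(names(paths))) names(paths)
               else sub("\\.[^.]*$", "", basename(paths))
        params <- lapply(paths, function(p)
            as.matrix(utils::read.table(p, header = FALSE)))
        names(params) <- ids
    }
    if (is.null(names(params)))
        names(params) <- paste0("sub", seq_along(params))
    rows <- lapply(names(params), function(id) {
        m <- params[[id]]
        if (!is.numeric(m) || ncol(m) != 6L || !all(is.finite(m)))
            stop("malformed realignment parameters for subject '", id,
                 "': need a finite T x 6 matrix")
        mt <- max(abs(m[, 1:3]))
        mr <- max(abs(m[, 4:6]))
        reason <- c(if (mt > transThreshold)
                        sprintf("translation %.3f mm > %g mm", mt,
                                transThreshold),
                    if (mr > rotThreshold)
                        sprintf("rotation %.3f deg > %g deg", mr,
                                rotThreshold))
        data.frame(subject = id, max_translation = mt, max_rotation = mr,
                   excluded = length(reason) > 0L,
                   reason = if (length(reason))
                       paste(reason, collapse = "; ") else "")
    })
    report <- do.call(rbind, rows)
    list(kept = report$subject[!report$excluded],
         excluded = report$subject[report$excluded],
         report = report)
}

# Leakage-free cross-validation: states are learned on training-fold
# windows only, test-fold windows are assigned to the nearest learned
# centroid. Returns a dfcMetricReport like crossvalDecisionTree().
.cleanCrossval <- function(fcw, k, nFolds, seed, nInit, positive = "normal") {
    cd <- colData(fcw)
    ids <- subjectIDs(fcw)
    grp <- droplevels(cd$group[match(ids, cd$subject_id)])
    set.seed(as.integer(seed))
    folds <- .stratifiedFolds(grp, nFolds)
    ctrl <- rpart::rpart.control(maxdepth = 30L, minbucket = 1L,
                                 minsplit = 2L, cp = 0, xval = 0L)
    perFold <- vector("list", nFolds)
    scores <- numeric(length(ids))
    for (f in seq_len(nFolds)) {
        testIds <- ids[folds == f]
        trainCols <- cd$subject_id %in% ids[folds != f]
        model <- fitStateModel(t(assay(fcw, "fc")[, trainCols, drop = FALSE]),
                               k = k, seed = as.integer(seed) + f,
                               nInit = nInit)
        labels <- integer(ncol(fcw))
        labels[trainCols] <- trainingLabels(model)
        labels[!trainCols] <- assignStates(model,
            t(assay(fcw, "fc")[, !trainCols, drop = FALSE]))
        occ <- occupancyCounts(fcw, labels, k = k)
        df <- data.frame(group = groups(occ), occupancyMatrix(occ))
        test <- rownames(occupancyMatrix(occ)) %in% testIds
        tree <- rpart::rpart(group ~ ., data = df[!test, , drop = FALSE],
                             method = "class",
                             parms = list(split = "gini"), control = ctrl)
        cls <- predict(tree, df[test, , drop = FALSE], type = "class")
        prob <- predict(tree, df[test, , drop = FALSE], type = "prob")
        scores[match(rownames(df)[test], ids)] <- prob[, positive]
        perFold[[f]] <- .confusion(df$group[test], cls, positive)
    }
    pooled <- Reduce("+", perFold)
    metricsPerFold <- do.call(rbind, lapply(perFold, function(cc)
        suppressWarnings(computeMetrics(cc))))
    out <- list(perFold = perFold, pooled = pooled,
                metricsPerFold = as.data.frame(metricsPerFold),
                metricsAveraged = colMeans(metricsPerFold, na.rm = TRUE),
                metricsPooled = suppressWarnings(computeMetrics(pooled)),
                scores = scores, truth = grp, folds = folds,
                positive = positive)
    class(out) <- "dfcMetricReport"
    out
}

#' Run the full dynamic-connectivity state pipeline
#'
#' Orchestrates the end-to-end analysis on a cohort: optional motion QC,
#' sliding-window connectivity, elbow-based state discovery (or a fixed k),
#' occupancy features, cross-validated decision-tree classification with
#' ROC, per-state occupancy tests, window-difference selection for the
#' discriminative state, and connection-wise group tests with BH-FDR. All
#' tabular artifacts are written to \code{outputDir} together with a JSON
#' run manifest; results are fully reproducible under the seed (stage seeds
#' are derived from it by fixed offsets).
#'
#' @param cohort an [FCCohort-class]; if \code{NULL}, a cohort is simulated
#'   from \code{synthetic}.
#' @param outputDir output directory (created if needed).
#' @param synthetic a \code{SyntheticConfig} (or argument list for
#'   [syntheticConfig()]) used when \code{cohort} is \code{NULL}.
#' @param width,step sliding-window geometry in TR.
#' @param kRange candidate k range for the elbow rule (length-2 vector).
#' @param k fixed number of states; overrides \code{kRange} when given.
#' @param seed global seed.
#' @param nFolds cross-validation folds.
#' @param nInit k-means restarts.
#' @param stateAlpha significance level noted for the per-state tests
#'   (default 0.05).
#' @param connThreshold threshold on BH-adjusted connection p-values
#'   (default 1e-4).
#' @param cleanCV additionally run leakage-free cross-validation in which
#'   states are re-learned on each fold's training windows (the default
#'   pipeline clusters all windows before classification, so occupancy
#'   features see test subjects' windows; see the vignette).
#' @param motionParams optional input to [motionQC()]; excluded subjects are
#'   dropped before analysis.
#' @param icNetworks optional IC-to-network map for connection annotation
#'   and network-pair summaries.
#' @return invisibly, the run manifest (list), which also echoes the key
#'   results (\code{k}, metrics, discriminative state, significant
#'   connection count).
#' @export
runPipeline <- function(cohort = NULL, outputDir, synthetic = NULL,
                        width = 25L, step = 2L, kRange = c(2L, 9L), k = NULL,
                        seed = 1L, nFolds = 5L, nInit = 20L,
                        stateAlpha = 0.05, connThreshold = 1e-4,
                        cleanCV = FALSE, motionParams = NULL,
                        icNetworks = NULL) {
    stopifnot(stateAlpha > 0, connThreshold > 0)
    seed <- as.integer(seed)
    if (!dir.exists(outputDir))
        dir.create(outputDir, recursive = TRUE)
    log <- function(...) message("[dfcStates] ", ...)
    files <- character(0)
    put <- function(name, writer) {
        p <- file.path(outputDir, name)
        writer(p)
        files[[name]] <<- p
        p
    }

    if (is.null(cohort)) {
        if (is.null(synthetic))
            stop("either a cohort or a synthetic configuration is required")
        if (!inherits(synthetic, "SyntheticConfig"))
            synthetic <- do.call(syntheticConfig,
                                 c(synthetic, list(seed = seed)))
        log("simulating cohort: ", 2L * synthetic$nPerGroup, " subjects, C=",
            synthetic$nComponents, ", T=", synthetic$nTimepoints)
        cohort <- simulateCohort(synthetic)
    }
    qc <- NULL
    if (!is.null(motionParams)) {
        qc <- motionQC(motionParams)
        log("motion QC: ", length(qc$kept), " kept, ",
            length(qc$excluded), " excluded")
        put("motion_qc.csv", function(p)
            utils::write.csv(qc$report, p, row.names = FALSE))
        keep <- subjectIDs(cohort) %in% qc$kept
        if (!all(keep)) {
            kept <- subjectIDs(cohort)[keep]
            cohort <- new("FCCohort",
                subjects = cohort@subjects[kept],
                subjectData = cohort@subjectData[keep, ],
                trueStates = if (length(cohort@trueStates))
                    cohort@trueStates[kept] else list(),
                config = cohort@config)
        }
    }

    log("sliding-window connectivity (width ", width, ", step ", step, ")")
    fcw <- slidingWindowFC(cohort, width = width, step = step)
    log("pooled windows: ", ncol(fcw), " x ", nrow(fcw), " connections")

    if (is.null(k)) {
        log("elbow model selection over k in [", kRange[1], ", ",
            kRange[2], "]")
        model <- selectStatesElbow(fcw, kMin = kRange[1], kMax = kRange[2],
                                   seed = seed + 101L, nInit = nInit)
        put("sse_curve.csv", function(p)
            utils::write.csv(data.frame(k = as.integer(names(sseCurve(model))),
                                        sse = unname(sseCurve(model))),
                             p, row.names = FALSE))
    } else {
        model <- fitStateModel(fcw, k = as.integer(k), seed = seed + 101L,
                               nInit = nInit)
    }
    kOpt <- nStates(model)
    log("states: k = ", kOpt)
    put("centroids.tsv", function(p)
        utils::write.table(stateCentroids(model), p, sep = "\t",
                           row.names = FALSE, col.names = FALSE))
    labels <- trainingLabels(model)
    put("state_labels.csv", function(p)
        utils::write.csv(data.frame(
            subject_id = colData(fcw)$subject_id,
            window_index = colData(fcw)$window_index,
            state = labels), p, row.names = FALSE))

    occ <- occupancyCounts(fcw, labels, k = kOpt)
    put("occupancy.csv", function(p)
        utils::write.csv(data.frame(subject_id = subjectIDs(occ),
                                    group = as.character(groups(occ)),
                                    occupancyMatrix(occ)),
                         p, row.names = FALSE))

    log("decision-tree cross-validation (", nFolds, " folds)")
    report <- crossvalDecisionTree(occ, nFolds = nFolds, seed = seed + 202L)
    roc <- computeROC(report$scores, as.character(report$truth),
                      positive = report$positive)
    put("metrics.json", function(p)
        jsonlite::write_json(list(
            per_fold = report$metricsPerFold,
            averaged = as.list(report$metricsAveraged),
            pooled = as.list(report$metricsPooled),
            auc = roc$auc), p, auto_unbox = TRUE, digits = NA))
    put("confusion.csv", function(p)
        utils::write.csv(data.frame(fold = seq_along(report$perFold),
                                    do.call(rbind, report$perFold)),
                         p, row.names = FALSE))
    put("roc.csv", function(p)
        utils::write.csv(roc$points, p, row.names = FALSE))

    cleanReport <- NULL
    if (cleanCV) {
        log("leakage-free cross-validation (states re-learned per fold)")
        cleanReport <- .cleanCrossval(fcw, k = kOpt, nFolds = nFolds,
                                      seed = seed + 303L, nInit = nInit)
        put("metrics_clean_cv.json", function(p)
            jsonlite::write_json(list(
                averaged = as.list(cleanReport$metricsAveraged),
                pooled = as.list(cleanReport$metricsPooled)),
                p, auto_unbox = TRUE, digits = NA))
    }

    stateTests <- stateOccupancyTests(occ)
    put("state_tests.csv", function(p)
        utils::write.csv(stateTests, p, row.names = FALSE))
    targetState <- stateTests$state[stateTests$discriminative][1]
    log("discriminative state: ", targetState, " (p = ",
        format(min(stateTests$p, na.rm = TRUE), digits = 3), ")")

    am <- stateAssignmentMatrix(fcw, labels)
    grp <- groups(occ)
    profile <- windowDifferenceSelection(am, grp, targetState)
    put("window_profile.csv", function(p)
        utils::write.csv(profile, p, row.names = FALSE))
    selected <- profile$window[profile$selected]
    log(length(selected), " of ", nrow(profile), " windows selected")

    connTests <- NULL
    if (length(selected)) {
        connTests <- connectionGroupTests(fcw, selected,
                                          threshold = connThreshold,
                                          icNetworks = icNetworks)
        put("connection_tests.csv", function(p)
            utils::write.csv(connTests, p, row.names = FALSE))
        log(sum(connTests$significant), " significant connections at ",
            "BH-adjusted p < ", connThreshold)
        if (!is.null(icNetworks)) {
            np <- summarizeNetworkPairs(connTests)
            put("network_counts.csv", function(p)
                utils::write.csv(np$perNetwork, p, row.names = FALSE))
            put("network_pair_counts.csv", function(p)
                utils::write.csv(np$perPair, p, row.names = FALSE))
        }
        if (any(connTests$significant))
            put("significant_connections.net", function(p)
                writePajek(connTests, p))
    } else {
        log("no windows selected; connection tests skipped")
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("dfcStates")),
        seed = seed,
        parameters = list(width = width, step = step,
                          kRange = kRange, k = kOpt, nFolds = nFolds,
                          nInit = nInit, stateAlpha = stateAlpha,
                          connThreshold = connThreshold, cleanCV = cleanCV),
        n_subjects = length(subjectIDs(cohort)),
        n_windows_per_subject = max(colData(fcw)$window_index),
        n_connections = nrow(fcw),
        k = kOpt,
        metrics_averaged = as.list(report$metricsAveraged),
        metrics_pooled = as.list(report$metricsPooled),
        auc = roc$auc,
        clean_cv_metrics = if (!is.null(cleanReport))
            as.list(cleanReport$metricsAveraged) else NULL,
        discriminative_state = targetState,
        n_selected_windows = length(selected),
        n_significant_connections = if (!is.null(connTests))
            sum(connTests$significant) else 0L,
        motion_excluded = if (!is.null(qc)) as.character(qc$excluded)
            else character(0),
        outputs = as.list(files))
    p <- file.path(outputDir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
    missing <- !vapply(unlist(manifest$outputs), file.exists, logical(1))
    if (any(missing))
        stop("manifest lists missing outputs: ",
             paste(names(files)[missing], collapse = ", "))
    log("done; manifest at ", p)
    invisible(manifest)
}
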