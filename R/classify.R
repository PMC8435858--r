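#' Confusion-matrix performance metrics
#'
#' Computes the five standard two-class metrics from confusion counts. The
#' positive class is, by this package's convention, the \emph{normal} group:
#' TP = normal subjects correctly identified, TN = case subjects correctly
#' identified, FP = case subjects called normal, FN = normal subjects called
#' case.
#'
#' \deqn{sensitivity = TP/(TP+FN)}
#' \deqn{specificity = TN/(TN+FP)}
#' \deqn{precision  = TP/(TP+FP)}
#' \deqn{accuracy   = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{F1 = 2 \cdot precision \cdot sensitivity /
#'            (precision + sensitivity)}
#'
#' Ratios with zero denominator are returned as \code{NaN} with a warning.
#'
#' @param counts named list or vector with elements \code{TP}, \code{TN},
#'   \code{FP}, \code{FN} (non-negative integers, not all zero).
#' @return named numeric vector with elements \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{accuracy}, \code{f1}.
#' @examples
#' computeMetrics(c(TP = 3, TN = 2, FP = 2, FN = 1))
#' @export
computeMetrics <- function(counts) {
    counts <- as.list(counts)
    need <- c("TP", "TN", "FP", "FN")
    if (!all(need %in% names(counts)))
        stop("counts must contain TP, TN, FP, FN")
    v <- vapply(counts[need], as.numeric, numeric(1))
    if (any(v < 0)) stop("counts must be non-negative")
    if (sum(v) == 0) stop("at least one evaluated subject required")
    ratio <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined (zero denominator); returning NaN")
            return(NaN)
        }
        num / den
    }
    sens <- ratio(v["TP"], v["TP"] + v["FN"], "sensitivity")
    spec <- ratio(v["TN"], v["TN"] + v["FP"], "specificity")
    prec <- ratio(v["TP"], v["TP"] + v["FP"], "precision")
    acc <- (v["TP"] + v["TN"]) / sum(v)
    f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) {
        warning("F1 undefined; returning NaN")
        NaN
    } else 2 * prec * sens / (prec + sens)
    c(sensitivity = unname(sens), specificity = unname(spec),
      precision = unname(prec), accuracy = unname(acc), f1 = unname(f1))
}

.confusion <- function(truth, predicted, positive) {
    c(TP = sum(truth == positive & predicted == positive),
      TN = sum(truth != positive & predicted != positive),
      FP = sum(truth != positive & predicted == positive),
      FN = sum(truth == positive & predicted != positive))
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so fold sizes differ by at most one per class.
.stratifiedFolds <- function(group, nFolds) {
    folds <- integer(length(group))
    for (g in levels(group)) {
        idx <- sample(which(group == g))
        folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    folds
}

#' Cross-validated decision-tree classification of occupancy features
#'
#' Classifies subjects from their 1 x k state-occupancy count vectors with a
#' CART decision tree (Gini impurity, via \pkg{rpart}) under stratified
#' k-fold cross-validation. Reports per-fold confusion counts, per-fold
#' metrics and their average, pooled-count metrics, and each subject's
#' held-out probability of the positive class (for ROC analysis).
#'
#' @param occupancy a [StateOccupancy-class], or a data.frame/matrix of
#'   features accompanied by \code{group}.
#' @param group group factor (ignored when \code{occupancy} is a
#'   [StateOccupancy-class]).
#' @param nFolds number of folds (default 5; must not exceed the smaller
#'   class size).
#' @param seed RNG seed for the fold split.
#' @param positive positive-class label (default \code{"normal"}: TP counts
#'   correctly identified normal subjects).
#' @param maxDepth,minLeaf,cp tree hyperparameters passed to
#'   [rpart::rpart.control()] (defaults: unlimited depth via 30, minimum
#'   leaf size 1, no complexity pruning).
#' @return list of class \code{"dfcMetricReport"} with elements
#'   \code{perFold} (list of confusion-count vectors), \code{pooled}
#'   (summed counts), \code{metricsPerFold} (data.frame),
#'   \code{metricsAveraged}, \code{metricsPooled} (named vectors),
#'   \code{scores} (held-out positive-class probabilities), \code{truth},
#'   \code{folds}.
#' @examples
#' set.seed(1)
#' grp <- factor(rep(c("normal", "case"), each = 10),
#'               levels = c("normal", "case"))
#' feat <- cbind(s1 = rnorm(20), s2 = c(rnorm(10, 3), rnorm(10, -3)))
#' rep5 <- crossvalDecisionTree(feat, grp, nFolds = 5, seed = 1)
#' rep5$metricsAveraged
#' @export
crossvalDecisionTree <- function(occupancy, group = NULL, nFolds = 5L,
                                 seed = 1L, positive = "normal",
                                 maxDepth = 30L, minLeaf = 1L, cp = 0) {
    if (is(occupancy, "StateOccupancy")) {
        group <- groups(occupancy)
        feat <- occupancyMatrix(occupancy)
    } else {
        feat <- as.matrix(occupancy)
    }
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2L)
        stop("exactly two groups required")
    if (!positive %in% levels(group))
        stop("positive class '", positive, "' not a group level")
    if (min(table(group)) < 2L)
        stop("need at least 2 subjects per class")
    nFolds <- as.integer(nFolds)
    if (nFolds < 2L || nFolds > min(table(group)))
        stop("nFolds must be between 2 and the smaller class size (",
             min(table(group)), ")")
    df <- data.frame(group = group, feat)
    set.seed(as.integer(seed))
    folds <- .stratifiedFolds(group, nFolds)
    ctrl <- rpart::rpart.control(maxdepth = maxDepth, minbucket = minLeaf,
                                 minsplit = 2L, cp = cp, xval = 0L)
    perFold <- vector("list", nFolds)
    scores <- numeric(length(group))
    pred <- factor(rep(levels(group)[1], length(group)),
                   levels = levels(group))
    for (f in seq_len(nFolds)) {
        test <- folds == f
        if (nlevels(droplevels(df$group[!test])) < 2L)
            stop("fold ", f, " training set has a single class; ",
                 "use stratified folds or a different seed")
        tree <- rpart::rpart(group ~ ., data = df[!test, , drop = FALSE],
                             method = "class",
                             parms = list(split = "gini"), control = ctrl)
        prob <- predict(tree, df[test, , drop = FALSE], type = "prob")
        cls <- predict(tree, df[test, , drop = FALSE], type = "class")
        scores[test] <- prob[, positive]
        pred[test] <- cls
        perFold[[f]] <- .confusion(group[test], cls, positive)
    }
    pooled <- Reduce("+", perFold)
    metricsPerFold <- do.call(rbind, lapply(perFold, function(cc)
        suppressWarnings(computeMetrics(cc))))
    out <- list(
        perFold = perFold,
        pooled = pooled,
        metricsPerFold = as.data.frame(metricsPerFold),
        metricsAveraged = colMeans(metricsPerFold, na.rm = TRUE),
        metricsPooled = suppressWarnings(computeMetrics(pooled)),
        scores = scores,
        truth = group,
        folds = folds,
        positive = positive)
    class(out) <- "dfcMetricReport"
    out
}

#' @export
print.dfcMetricReport <- function(x, ...) {
    cat("Decision-tree cross-validation (", length(x$perFold),
        " folds, positive class = '", x$positive, "')\n", sep = "")
    cat("fold-averaged metrics:\n")
    print(round(x$metricsAveraged, 4))
    cat("pooled-count metrics:\n")
    print(round(x$metricsPooled, 4))
    invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold across the unique scores (descending),
#' computing the true- and false-positive rates of the rule
#' \code{score >= threshold}, and integrates the curve by the trapezoidal
#' rule. Equivalent to the Mann-Whitney concordance probability.
#'
#' @param scores numeric vector, higher = more positive-class-like.
#' @param labels group labels aligned with \code{scores}; both classes must
#'   be present.
#' @param positive positive-class label.
#' @return list with \code{points} (data.frame: \code{threshold},
#'   \code{fpr}, \code{tpr}) and \code{auc}.
#' @examples
#' computeROC(c(0.9, 0.8, 0.4, 0.2), c("a", "a", "b", "b"), positive = "a")$auc
#' @export
computeROC <- function(scores, labels, positive = "normal") {
    if (length(scores) != length(labels))
        stop("scores and labels must be aligned")
    isPos <- labels == positive
    nPos <- sum(isPos)
    nNeg <- sum(!isPos)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present")
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(scores >= t & isPos) / nPos, 0)
    fpr <- vapply(thr, function(t) sum(scores >= t & !isPos) / nNeg, 0)
    fpr <- c(0, fpr)
    tpr <- c(0, tpr)
    if (utils::tail(fpr, 1) != 1 || utils::tail(tpr, 1) != 1) {
        fpr <- c(fpr, 1)
        tpr <- c(tpr, 1)
        thr <- c(thr, -Inf)
    }
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
         auc = auc)
}
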