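# Multi-feature fusion classification of lameness severity: z-scoring on
# the training split, RF / KNN / SVM back-ends, confusion-matrix metrics
# (accuracy, per-class sensitivity / specificity, macro F1) and the fusion
# experiment grid over feature subsets.

#' Standardize features using training-set statistics
#'
#' Columns are centred and scaled to zero mean and unit variance with
#' statistics estimated on the training table only, then applied to both
#' tables (no information leaks from the evaluation split).
#'
#' @param trainX data.frame/matrix of training features (>= 2 rows).
#' @param applyX optional second table transformed with the same statistics.
#' @return list(train, apply, center, scale); \code{apply} is NULL when
#'   \code{applyX} is.
#' @export
standardizeFeatures <- function(trainX, applyX = NULL) {
    trainX <- as.data.frame(trainX)
    if (nrow(trainX) < 2) stop("training table needs at least 2 rows")
    mu <- vapply(trainX, mean, numeric(1))
    sd <- vapply(trainX, stats::sd, numeric(1))
    if (any(sd == 0))
        stop("zero-variance feature: ",
             paste(names(sd)[sd == 0], collapse = ", "))
    z <- function(tab) {
        tab <- as.data.frame(tab)[names(mu)]
        as.data.frame(Map(function(col, m, s) (col - m) / s, tab, mu, sd))
    }
    list(train = z(trainX), apply = if (is.null(applyX)) NULL else z(applyX),
         center = mu, scale = sd)
}

#' Stratified train/validation split
#'
#' Splits samples by class into training and held-out sets in the given
#' ratio (default 8:2), preserving class proportions; assignment is seeded.
#'
#' @param y class labels.
#' @param trainFrac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list(train, test): integer index vectors.
#' @export
stratifiedSplit <- function(y, trainFrac = 0.8, seed = 1L) {
    y <- factor(y)
    withSeed(seed, {
        tr <- unlist(lapply(levels(y), function(cl) {
            idx <- which(y == cl)
            sample(idx, round(trainFrac * length(idx)))
        }))
        list(train = sort(tr), test = sort(setdiff(seq_along(y), tr)))
    })
}

#' Train a classifier and predict held-out labels
#'
#' Back-ends: "RF" (random forest, 500 trees), "KNN" (k = 5, Euclidean
#' distance on the z-scored features) and "SVM" (RBF kernel, C = 1,
#' gamma = 1/d). Features should already be standardized (see
#' \code{\link{standardizeFeatures}}). Deterministic per seed.
#'
#' @param trainX,trainY training features and labels.
#' @param testX features to predict.
#' @param algo "RF", "KNN" or "SVM".
#' @param seed integer seed.
#' @param nTrees RF tree count.
#' @param k KNN neighbour count.
#' @param cost,gamma SVM parameters; gamma defaults to 1/d.
#' @return Factor of predicted labels with the levels of \code{trainY}.
#' @export
trainAndPredict <- function(trainX, trainY, testX, algo = c("RF", "KNN", "SVM"),
                            seed = 1L, nTrees = 500, k = 5,
                            cost = 1, gamma = NULL) {
    algo <- match.arg(algo)
    trainX <- as.data.frame(trainX); testX <- as.data.frame(testX)
    trainY <- factor(trainY)
    if (algo == "RF") {
        fit <- ranger::ranger(x = trainX, y = trainY, num.trees = nTrees,
                              seed = as.integer(seed), num.threads = 1L)
        stats::predict(fit, data = testX, num.threads = 1L)$predictions
    } else if (algo == "KNN") {
        withSeed(seed,
            class::knn(train = as.matrix(trainX), test = as.matrix(testX),
                       cl = trainY, k = k))
    } else {
        if (is.null(gamma)) gamma <- 1 / ncol(trainX)
        fit <- withSeed(seed,
            e1071::svm(x = as.matrix(trainX), y = trainY, kernel = "radial",
                       cost = cost, gamma = gamma))
        stats::predict(fit, as.matrix(testX))
    }
}

#' Evaluate predictions against true labels
#'
#' Builds the 3-class confusion matrix (rows true, columns predicted) and
#' the derived metrics: accuracy (fraction of correct predictions),
#' per-class sensitivity \eqn{TP_c/(TP_c+FN_c)}, per-class specificity
#' \eqn{TN_c/(TN_c+FP_c)}, per-class F1 and their arithmetic mean
#' (macro F1). Degenerate conventions: F1 is 0 when precision + recall is
#' 0; a specificity or sensitivity with zero denominator is 0; both are
#' flagged with a warning.
#'
#' @param trueLabels,predictions equal-length label vectors over the three
#'   severity classes.
#' @param algorithm,features tags recorded in the report.
#' @return A \linkS4class{ClassificationReport}.
#' @export
#' @examples
#' evaluateClassification(rep(lamenessClasses(), each = 4),
#'                        rep(lamenessClasses(), times = 4))
evaluateClassification <- function(trueLabels, predictions,
                                   algorithm = "NA", features = character()) {
    lv <- lamenessClasses()
    trueLabels <- factor(trueLabels, levels = lv)
    predictions <- factor(predictions, levels = lv)
    if (length(trueLabels) != length(predictions))
        stop("label vectors must have equal length")
    conf <- table(true = trueLabels, predicted = predictions)
    conf <- matrix(as.integer(conf), 3, 3, dimnames = dimnames(conf))
    reportFromConfusion(conf, algorithm, features)
}

# Metrics from a 3x3 confusion matrix (rows true, cols predicted).
reportFromConfusion <- function(conf, algorithm = "NA",
                                features = character()) {
    n <- sum(conf)
    tp <- diag(conf)
    fn <- rowSums(conf) - tp
    fp <- colSums(conf) - tp
    tn <- n - tp - fn - fp
    safeDiv <- function(num, den, what) {
        out <- ifelse(den == 0, 0, num / den)
        if (any(den == 0))
            warning("zero denominator in ", what, " for class(es) ",
                    paste(rownames(conf)[den == 0], collapse = ", "),
                    "; reported as 0")
        out
    }
    sens <- safeDiv(tp, tp + fn, "sensitivity")
    spec <- safeDiv(tn, tn + fp, "specificity")
    prec <- safeDiv(tp, tp + fp, "precision")
    pr <- prec + sens
    f1 <- ifelse(pr == 0, 0, 2 * prec * sens / pr)
    lv <- rownames(conf)
    names(sens) <- names(spec) <- names(f1) <- lv
    new("ClassificationReport", confusion = conf,
        accuracy = sum(tp) / n, sensitivity = sens, specificity = spec,
        f1 = f1, macroF1 = mean(f1), algorithm = algorithm,
        features = features)
}

#' The named feature subsets of the fusion experiment
#'
#' The six single features plus the fused combinations examined in the
#' fusion grid: BC+MAI+VOB, BC+MAI+VOB+VOH, that plus TI, and all six.
#'
#' @return Named list of character vectors.
#' @export
fusionSubsets <- function() {
    singles <- as.list(featureNames())
    names(singles) <- featureNames()
    c(singles,
      list("BC+MAI+VOB" = c("BC", "MAI", "VOB"),
           "BC+MAI+VOB+VOH" = c("BC", "MAI", "VOB", "VOH"),
           "BC+MAI+VOB+VOH+TI" = c("BC", "MAI", "VOB", "VOH", "TI"),
           "All" = featureNames()))
}

#' Run the multi-feature fusion experiment grid
#'
#' For each feature subset and algorithm: stratified 8:2 split,
#' training-set z-scoring, train, predict the held-out set, evaluate. One
#' \linkS4class{ClassificationReport} per (subset, algorithm) cell.
#'
#' @param features data.frame with a \code{label} column and the six
#'   feature columns.
#' @param subsets named list of feature-name vectors (default
#'   \code{\link{fusionSubsets}}).
#' @param algos algorithms to run (default RF, KNN, SVM).
#' @param trainFrac training fraction of the stratified split.
#' @param seed integer seed (drives the split and the learners).
#' @return Named list of \linkS4class{ClassificationReport}s
#'   ("subset|algo"), with a \code{data.frame} summary in attribute
#'   \code{"summary"}.
#' @export
runFusionGrid <- function(features, subsets = fusionSubsets(),
                          algos = c("RF", "KNN", "SVM"), trainFrac = 0.8,
                          seed = 1L) {
    stopifnot("label" %in% names(features))
    known <- setdiff(names(features), c("label", "sequence_id"))
    bad <- setdiff(unique(unlist(subsets)), known)
    if (length(bad))
        stop("unknown feature name(s): ", paste(bad, collapse = ", "))
    sp <- stratifiedSplit(features$label, trainFrac, seed)
    out <- list()
    summ <- NULL
    for (sn in names(subsets)) {
        cols <- subsets[[sn]]
        zs <- standardizeFeatures(features[sp$train, cols, drop = FALSE],
                                  features[sp$test, cols, drop = FALSE])
        for (al in algos) {
            pred <- trainAndPredict(zs$train, features$label[sp$train],
                                    zs$apply, algo = al, seed = seed)
            rep <- evaluateClassification(features$label[sp$test], pred,
                                          algorithm = al, features = cols)
            out[[paste(sn, al, sep = "|")]] <- rep
            summ <- rbind(summ, data.frame(
                subset = sn, algorithm = al, acc = accuracy(rep),
                macro_f1 = macroF1(rep), stringsAsFactors = FALSE))
        }
    }
    attr(out, "summary") <- summ
    out
}
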