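# Keypoint evaluation metrics: PCK at a normalized-distance threshold, and
# AP / AR averaged over a ladder of thresholds. The pose task is fixed-set
# (every annotated keypoint has exactly one prediction), so per threshold
# FP = FN and AP = AR unless a visibility mask excludes some ground-truth
# points.

kpDistances <- function(predicted, groundTruth) {
    predicted <- as.matrix(predicted); groundTruth <- as.matrix(groundTruth)
    if (!identical(dim(predicted), dim(groundTruth)) || ncol(predicted) != 2L)
        stop("predicted and ground truth must be matching N x 2 matrices")
    if (nrow(predicted) == 0L) stop("empty keypoint set")
    sqrt(rowSums((predicted - groundTruth)^2))
}

#' Percentage of correct keypoints (PCK)
#'
#' A keypoint is correctly located when the Euclidean distance between
#' prediction and ground truth is at most \code{t * max(H, W)} (the
#' normalization scale of the heatmap). PCK is the fraction of correct
#' keypoints; it is nondecreasing in \code{t}.
#'
#' @param predicted,groundTruth N x 2 matrices of (x, y) coordinates.
#' @param H,W heatmap extent.
#' @param t normalized distance threshold (> 0), e.g. 0.05 or 0.02.
#' @param visible optional logical(N); invisible points are excluded.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
#' @examples
#' g <- cbind(c(10, 20, 30, 40), 10)
#' p <- g + cbind(c(1, 2, 5, 10), 0)
#' pck(p, g, H = 64, W = 48, t = 0.05)  # threshold 3.2 px -> 0.5
pck <- function(predicted, groundTruth, H, W, t = 0.05, visible = NULL) {
    if (t <= 0) stop("t must be positive")
    d <- kpDistances(predicted, groundTruth)
    if (!is.null(visible)) d <- d[visible]
    if (!length(d)) stop("no visible keypoints")
    mean(d <= t * max(H, W))
}

#' Average precision and recall over a threshold ladder
#'
#' At each normalized-distance threshold, TP is the number of correctly
#' located keypoints, FP the predicted-but-incorrect ones, and FN the
#' ground-truth points without a correct prediction. Precision and recall
#' are averaged across thresholds to give AP and AR. The default ladder
#' scales 0.50--0.95 (step 0.05) into normalized-distance thresholds by the
#' base PCK threshold 0.05. With a full visibility mask the task is
#' fixed-set, so FP = FN and AP = AR.
#'
#' @inheritParams pck
#' @param thresholds numeric vector of normalized-distance thresholds.
#' @param visible optional logical(N); invisible ground-truth points are
#'   excluded from recall, their predictions from precision.
#' @return list(AP, AR, perThreshold): the averages and the per-threshold
#'   precision/recall table.
#' @export
apAr <- function(predicted, groundTruth, H, W,
                 thresholds = seq(0.50, 0.95, by = 0.05) * 0.05,
                 visible = NULL) {
    if (!length(thresholds)) stop("threshold list must be nonempty")
    d <- kpDistances(predicted, groundTruth)
    if (is.null(visible)) visible <- rep(TRUE, length(d))
    d <- d[visible]
    scale <- max(H, W)
    per <- t(vapply(thresholds, function(tt) {
        correct <- sum(d <= tt * scale)
        tp <- correct
        fp <- length(d) - correct
        fn <- length(d) - correct
        c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
          recall = if (tp + fn == 0) 0 else tp / (tp + fn))
    }, numeric(2)))
    list(AP = mean(per[, "precision"]), AR = mean(per[, "recall"]),
         perThreshold = data.frame(threshold = thresholds,
                                   precision = per[, "precision"],
                                   recall = per[, "recall"]))
}
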