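#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' The eight back keypoints
#'
#' Names of the eight anatomical landmarks tracked on the cow's back, in
#' head-to-tail order: poll, withers, left/right scapula, lumbar region,
#' left/right tuber coxae and sacral tuber.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' keypointNames()
keypointNames <- function() {
    c("poll", "withers", "left_scapula", "right_scapula", "lumbar",
      "left_tuber_coxae", "right_tuber_coxae", "sacral_tuber")
}

#' The six gait feature names
#'
#' @return Character vector: BC (back curvature, 1/cm), MAI (movement
#'   asymmetry index, unitless), VOB / VOH (vertical oscillation of back /
#'   head, cm), TI (trunk inclination, cm), LSAS (lateral sway amplitude of
#'   the spine, cm).
#' @export
featureNames <- function() c("BC", "MAI", "VOB", "VOH", "TI", "LSAS")

#' The three lameness severity classes
#'
#' @return Character vector \code{c("sound", "mild", "severe")}, the fixed
#'   level order used throughout.
#' @export
lamenessClasses <- function() c("sound", "mild", "severe")

#' WalkingSequence: one overhead walking pass of one cow
#'
#' The unit of analysis: a time-ordered stack of depth frames (mm, 0 = void),
#' per-frame pixel coordinates of the eight back keypoints, optional
#' grayscale textured frames for optical flow, and the camera geometry
#' needed to convert pixels and depths to centimetres.
#'
#' @slot depth numeric array H x W x T, depth in mm; 0 marks a void pixel.
#' @slot tracks numeric array T x 8 x 2 with dimnames
#'   \code{list(NULL, keypointNames(), c("x","y"))}; x is the column
#'   coordinate, y the row coordinate, both 1-based pixel positions.
#' @slot frames optional numeric array H x W x T of 8-bit-range grayscale
#'   images (values in [0, 255]) used for optical-flow computation, or NULL.
#' @slot scaleCmPerPx numeric(1), ground-plane scale in cm per pixel.
#' @slot cameraHeightMm numeric(1), camera mount height above the floor, mm.
#' @slot fps numeric(1), frame rate.
#' @slot label character(1), one of \code{lamenessClasses()} or NA.
#'
#' @exportClass WalkingSequence
setClass("WalkingSequence",
    representation(depth = "array", tracks = "array", frames = "arrayOrNULL",
                   scaleCmPerPx = "numeric", cameraHeightMm = "numeric",
                   fps = "numeric", label = "character"))

setValidity("WalkingSequence", function(object) {
    msg <- character()
    d <- dim(object@depth)
    if (length(d) != 3L)
        msg <- c(msg, "depth must be an H x W x T array")
    else {
        if (d[3] < 3L) msg <- c(msg, "sequence must have at least 3 frames")
        td <- dim(object@tracks)
        if (length(td) != 3L || td[2] != 8L || td[3] != 2L)
            msg <- c(msg, "tracks must be a T x 8 x 2 array")
        else {
            if (td[1] != d[3])
                msg <- c(msg, "tracks and depth disagree on frame count")
            if (!identical(dimnames(object@tracks)[[2]], keypointNames()))
                msg <- c(msg, "tracks must be named by keypointNames()")
            x <- object@tracks[, , 1]; y <- object@tracks[, , 2]
            if (any(!is.finite(x)) || any(!is.finite(y)) ||
                any(x < 1) || any(x > d[2]) || any(y < 1) || any(y > d[1]))
                msg <- c(msg, "keypoints must lie inside image bounds")
        }
        if (!is.null(object@frames) && !identical(dim(object@frames), d))
            msg <- c(msg, "frames must match depth dimensions")
    }
    if (length(object@scaleCmPerPx) != 1L || object@scaleCmPerPx <= 0)
        msg <- c(msg, "scaleCmPerPx must be a positive scalar")
    if (length(object@cameraHeightMm) != 1L || object@cameraHeightMm <= 0)
        msg <- c(msg, "cameraHeightMm must be a positive scalar")
    if (length(object@fps) != 1L || object@fps <= 0)
        msg <- c(msg, "fps must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Construct a WalkingSequence
#'
#' @param depth numeric array H x W x T, depth in mm (0 = void).
#' @param tracks numeric array T x 8 x 2 (keypoints x (x, y)); dimnames are
#'   filled in if missing.
#' @param frames optional H x W x T grayscale array or NULL.
#' @param scaleCmPerPx cm per pixel.
#' @param cameraHeightMm camera mount height, mm.
#' @param fps frames per second.
#' @param label class label ("sound", "mild", "severe") or NA.
#' @return A \linkS4class{WalkingSequence}.
#' @export
WalkingSequence <- function(depth, tracks, frames = NULL, scaleCmPerPx,
                            cameraHeightMm, fps = 30, label = NA_character_) {
    if (is.null(dimnames(tracks)))
        dimnames(tracks) <- list(NULL, keypointNames(), c("x", "y"))
    new("WalkingSequence", depth = depth, tracks = tracks, frames = frames,
        scaleCmPerPx = scaleCmPerPx, cameraHeightMm = cameraHeightMm,
        fps = fps, label = label)
}

#' @describeIn WalkingSequence-class depth stack accessor (H x W x T, mm).
#' @param object,x a WalkingSequence.
#' @aliases depthStack
#' @export
setGeneric("depthStack", function(x) standardGeneric("depthStack"))
#' @export
setMethod("depthStack", "WalkingSequence", function(x) x@depth)

#' @describeIn WalkingSequence-class keypoint track accessor (T x 8 x 2).
#' @aliases keypointTracks
#' @export
setGeneric("keypointTracks", function(x) standardGeneric("keypointTracks"))
#' @export
setMethod("keypointTracks", "WalkingSequence", function(x) x@tracks)

#' @describeIn WalkingSequence-class textured frame accessor (or NULL).
#' @aliases textureFrames
#' @export
setGeneric("textureFrames", function(x) standardGeneric("textureFrames"))
#' @export
setMethod("textureFrames", "WalkingSequence", function(x) x@frames)

#' @describeIn WalkingSequence-class number of frames.
#' @aliases nFrames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "WalkingSequence", function(x) dim(x@depth)[3])

#' @describeIn WalkingSequence-class severity label accessor.
#' @aliases seqLabel
#' @export
setGeneric("seqLabel", function(x) standardGeneric("seqLabel"))
#' @export
setMethod("seqLabel", "WalkingSequence", function(x) x@label)

setMethod("show", "WalkingSequence", function(object) {
    d <- dim(object@depth)
    cat("WalkingSequence:", d[3], "frames of", d[1], "x", d[2], "px\n")
    cat("  label:", object@label,
        "| scale:", object@scaleCmPerPx, "cm/px",
        "| camera:", object@cameraHeightMm, "mm",
        "| fps:", object@fps, "\n")
    cat("  textured frames:", if (is.null(object@frames)) "absent" else "present", "\n")
})

#' ScreeningResult: PIMP-corrected feature screening report
#'
#' Per-feature random-forest Gini importance, the permutation null
#' distribution, raw right-tail permutation p-values, Benjamini-Hochberg
#' adjusted p-values and the retention decision at FDR level alpha.
#'
#' @slot table data.frame with columns feature, gini, p_kw (Kruskal-Wallis
#'   inter-group p, reported only), p_raw, p_adj, retained.
#' @slot nullImportances B x d matrix of Gini importances under label
#'   permutation (one row per permutation).
#' @slot B integer, number of label permutations.
#' @slot alpha numeric, FDR level.
#' @slot seed integer, master seed.
#' @exportClass ScreeningResult
setClass("ScreeningResult",
    representation(table = "data.frame", nullImportances = "matrix",
                   B = "integer", alpha = "numeric", seed = "integer"))

setValidity("ScreeningResult", function(object) {
    msg <- character()
    need <- c("feature", "gini", "p_kw", "p_raw", "p_adj", "retained")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, "table must have feature/gini/p_kw/p_raw/p_adj/retained")
    else {
        if (abs(sum(object@table$gini) - 1) > 1e-6)
            msg <- c(msg, "gini importances must sum to 1")
        if (any(object@table$p_adj < object@table$p_raw - 1e-12))
            msg <- c(msg, "p_adj must be >= p_raw")
        if (!identical(object@table$retained,
                       object@table$p_adj < object@alpha))
            msg <- c(msg, "retained must equal p_adj < alpha")
    }
    if (nrow(object@nullImportances) != object@B)
        msg <- c(msg, "nullImportances must have B rows")
    if (length(msg)) msg else TRUE
})

#' @describeIn ScreeningResult-class the per-feature report table.
#' @param x a ScreeningResult.
#' @aliases screeningTable
#' @export
setGeneric("screeningTable", function(x) standardGeneric("screeningTable"))
#' @export
setMethod("screeningTable", "ScreeningResult", function(x) x@table)

#' @describeIn ScreeningResult-class names of retained features.
#' @aliases retainedFeatures
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))
#' @export
setMethod("retainedFeatures", "ScreeningResult",
          function(x) x@table$feature[x@table$retained])

setMethod("show", "ScreeningResult", function(object) {
    cat("ScreeningResult: B =", object@B, "permutations, alpha =",
        object@alpha, "\n")
    tab <- object@table
    tab$gini <- round(tab$gini, 3)
    tab$p_kw <- signif(tab$p_kw, 3)
    tab$p_raw <- round(tab$p_raw, 4)
    tab$p_adj <- round(tab$p_adj, 4)
    print(tab, row.names = FALSE)
})

#' ClassificationReport: confusion matrix and derived metrics
#'
#' Three-class confusion matrix (rows = true sound/mild/severe, columns =
#' predicted) with overall accuracy, per-class sensitivity and specificity,
#' and the macro-averaged F1 score. All metrics are recomputable from the
#' confusion matrix alone via \code{\link{evaluateClassification}}.
#'
#' @slot confusion 3 x 3 integer matrix, rows true, columns predicted.
#' @slot accuracy numeric(1).
#' @slot sensitivity named numeric(3), per-class recall.
#' @slot specificity named numeric(3).
#' @slot f1 named numeric(3), per-class F1.
#' @slot macroF1 numeric(1).
#' @slot algorithm character(1) tag (e.g. "RF").
#' @slot features character, feature subset used.
#' @exportClass ClassificationReport
setClass("ClassificationReport",
    representation(confusion = "matrix", accuracy = "numeric",
                   sensitivity = "numeric", specificity = "numeric",
                   f1 = "numeric", macroF1 = "numeric",
                   algorithm = "character", features = "character"))

setValidity("ClassificationReport", function(object) {
    msg <- character()
    if (!identical(dim(object@confusion), c(3L, 3L)))
        msg <- c(msg, "confusion must be 3 x 3")
    if (any(object@confusion < 0))
        msg <- c(msg, "confusion entries must be nonnegative")
    if (object@accuracy < 0 || object@accuracy > 1)
        msg <- c(msg, "accuracy must lie in [0, 1]")
    if (object@macroF1 < 0 || object@macroF1 > 1)
        msg <- c(msg, "macro F1 must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn ClassificationReport-class confusion matrix accessor.
#' @param x a ClassificationReport.
#' @aliases confusionMatrix
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @export
setMethod("confusionMatrix", "ClassificationReport", function(x) x@confusion)

#' @describeIn ClassificationReport-class overall accuracy.
#' @aliases accuracy
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @export
setMethod("accuracy", "ClassificationReport", function(x) x@accuracy)

#' @describeIn ClassificationReport-class macro-averaged F1 score.
#' @aliases macroF1
#' @export
setGeneric("macroF1", function(x) standardGeneric("macroF1"))
#' @export
setMethod("macroF1", "ClassificationReport", function(x) x@macroF1)

#' @describeIn ClassificationReport-class per-class sensitivity (recall).
#' @aliases sensitivity
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @export
setMethod("sensitivity", "ClassificationReport", function(x) x@sensitivity)

#' @describeIn ClassificationReport-class per-class specificity.
#' @aliases specificity
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @export
setMethod("specificity", "ClassificationReport", function(x) x@specificity)

setMethod("show", "ClassificationReport", function(object) {
    cat("ClassificationReport [", object@algorithm, "] features:",
        paste(object@features, collapse = "+"), "\n")
    cat("  ACC:", round(object@accuracy, 4),
        " Macro F1:", round(object@macroF1, 4), "\n")
    cat("  SENS:", paste(names(object@sensitivity),
                         round(object@sensitivity, 3), collapse = "  "), "\n")
    cat("  SPEC:", paste(names(object@specificity),
                         round(object@specificity, 3), collapse = "  "), "\n")
    print(object@confusion)
})
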