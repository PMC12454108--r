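# The six gait / posture features computed from a preprocessed
# WalkingSequence: back curvature (BC), movement asymmetry index (MAI),
# vertical oscillation of back (VOB) and head (VOH), trunk inclination (TI)
# and lateral sway amplitude of the spine (LSAS).

# Depth (mm) at a keypoint: median of the valid values in the 3x3
# neighbourhood around the rounded pixel, tolerating single-pixel noise.
# NA when the whole patch is void.
keypointDepth <- function(frame, x, y) {
    H <- nrow(frame); W <- ncol(frame)
    rr <- pmin(pmax((round(y) - 1):(round(y) + 1), 1), H)
    cc <- pmin(pmax((round(x) - 1):(round(x) + 1), 1), W)
    v <- frame[rr, cc]
    v <- v[v > 0]
    if (!length(v)) return(NA_real_)
    stats::median(v)
}

#' Curvature of the circle through three points
#'
#' Curvature \eqn{k = 1/R} of the unique circle through three planar points
#' (coordinates in cm), computed as \eqn{k = 4\,\mathrm{Area}/(|a||b||c|)}
#' with \eqn{a, b, c} the triangle side lengths. Collinear points (triangle
#' area below 1e-9) give 0; coincident points are a degenerate-input error.
#'
#' @param p1,p2,p3 numeric(2) points, cm.
#' @return Curvature in 1/cm.
#' @export
#' @examples
#' circumcircleCurvature(c(0, 0), c(50, 50), c(100, 0))  # R = 50 -> 0.02
circumcircleCurvature <- function(p1, p2, p3) {
    a <- sqrt(sum((p2 - p1)^2))
    b <- sqrt(sum((p3 - p2)^2))
    cc <- sqrt(sum((p3 - p1)^2))
    if (min(a, b, cc) < 1e-12)
        stop("degenerate input: coincident points")
    area <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
    if (area < 1e-9) return(0)
    4 * area / (a * b * cc)
}

# Sagittal-plane spine points for one frame: (cumulative along-spine
# horizontal distance, height above floor plane), both cm.
sagittalSpinePoints <- function(seq, t) {
    tr <- seq@tracks[t, , ]
    fr <- seq@depth[, , t]
    kp <- c("withers", "lumbar", "sacral_tuber")
    d <- vapply(kp, function(k) keypointDepth(fr, tr[k, "x"], tr[k, "y"]),
                numeric(1))
    if (any(is.na(d))) return(NULL)
    h <- (seq@cameraHeightMm - d) / 10
    seg1 <- sqrt(sum((tr["lumbar", ] - tr["withers", ])^2)) * seq@scaleCmPerPx
    seg2 <- sqrt(sum((tr["sacral_tuber", ] - tr["lumbar", ])^2)) *
        seq@scaleCmPerPx
    cbind(s = c(0, seg1, seg1 + seg2), h = h)
}

#' Back curvature (BC)
#'
#' Per frame, the withers, lumbar and sacral-tuber keypoints are expressed
#' in the sagittal plane as (cumulative along-spine horizontal distance,
#' height above floor), both in cm, with height derived from depth as
#' (camera height - depth)/10. The curvature of the circle through the
#' three points is computed frame by frame and the maximum is the feature
#' (kyphosis is a peak posture, not an average).
#'
#' @param seq a \linkS4class{WalkingSequence} with filled depth.
#' @return BC in 1/cm.
#' @export
backCurvature <- function(seq) {
    ks <- rep(NA_real_, nFrames(seq))
    for (t in seq_len(nFrames(seq))) {
        pts <- sagittalSpinePoints(seq, t)
        if (is.null(pts)) next
        ks[t] <- circumcircleCurvature(pts[1, ], pts[2, ], pts[3, ])
    }
    if (all(is.na(ks)))
        stop("invalid depth at a spine keypoint in every frame")
    max(ks, na.rm = TRUE)
}

#' Split a body mask into left and right halves
#'
#' Partitions mask pixels by the sign of the 2-D cross product of the
#' withers-to-lumbar axis with the pixel offset: pixels with positive cross
#' product (and the zero-cross boundary) are labelled left of the travel
#' direction, the rest right.
#'
#' @param mask logical matrix, the body region.
#' @param withers,lumbar numeric(2) keypoints as (x, y) pixel coordinates.
#' @return list(left, right): logical matrices partitioning \code{mask}.
#' @export
splitLeftRight <- function(mask, withers, lumbar) {
    dxy <- lumbar - withers
    if (sqrt(sum(dxy^2)) < 1e-9)
        stop("degenerate axis: withers and lumbar coincide")
    H <- nrow(mask); W <- ncol(mask)
    qx <- matrix(seq_len(W), H, W, byrow = TRUE)
    qy <- matrix(seq_len(H), H, W)
    cross <- dxy[1] * (qy - withers[2]) - dxy[2] * (qx - withers[1])
    list(left = mask & cross >= 0, right = mask & cross < 0)
}

#' Movement asymmetry index from flow fields (Eq. form |muL-muR|/(muL+muR))
#'
#' Mean dense-flow magnitudes are accumulated over all frame pairs within
#' the left and right body regions; the index is
#' \eqn{|\mu_L - \mu_R| / (\mu_L + \mu_R)}, 0 when both means are 0.
#'
#' @param flows list of flow fields (each \code{list(u, v)}).
#' @param leftMasks,rightMasks logical matrices (one per flow field, or a
#'   single matrix recycled) delimiting the two regions.
#' @return MAI in \eqn{[0, 1]}.
#' @export
movementAsymmetryIndex <- function(flows, leftMasks, rightMasks) {
    if (!length(flows)) stop("at least one flow field is required")
    if (is.matrix(leftMasks)) leftMasks <- rep(list(leftMasks), length(flows))
    if (is.matrix(rightMasks)) rightMasks <- rep(list(rightMasks), length(flows))
    sL <- sR <- nL <- nR <- 0
    for (i in seq_along(flows)) {
        M <- flowMagnitude(flows[[i]])
        if (!any(leftMasks[[i]]) || !any(rightMasks[[i]]))
            stop("empty left or right region")
        sL <- sL + sum(M[leftMasks[[i]]]); nL <- nL + sum(leftMasks[[i]])
        sR <- sR + sum(M[rightMasks[[i]]]); nR <- nR + sum(rightMasks[[i]])
    }
    muL <- sL / nL; muR <- sR / nR
    if (muL + muR == 0) return(0)
    abs(muL - muR) / (muL + muR)
}

# MAI for a WalkingSequence: foreground from depth, split along the
# withers-lumbar axis, dense flow between consecutive textured frames.
sequenceMAI <- function(seq, floorDepthMm = 2500, minHeightMm = 300, ...) {
    if (is.null(seq@frames)) return(NA_real_)
    T <- nFrames(seq)
    flows <- vector("list", T - 1)
    lm <- vector("list", T - 1); rm_ <- vector("list", T - 1)
    for (t in seq_len(T - 1)) {
        flows[[t]] <- farnebackFlow(seq@frames[, , t], seq@frames[, , t + 1],
                                    ...)
        fg <- foregroundMask(seq@depth[, , t], floorDepthMm, minHeightMm)
        halves <- splitLeftRight(fg, seq@tracks[t, "withers", ],
                                 seq@tracks[t, "lumbar", ])
        lm[[t]] <- halves$left; rm_[[t]] <- halves$right
    }
    movementAsymmetryIndex(flows, lm, rm_)
}

# Per-keypoint depth series in cm over time (NA where patch is void).
depthSeriesCm <- function(seq, kp) {
    vapply(seq_len(nFrames(seq)), function(t)
        keypointDepth(seq@depth[, , t], seq@tracks[t, kp, "x"],
                      seq@tracks[t, kp, "y"]), numeric(1)) / 10
}

rangeNoNA <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    diff(range(x))
}

#' Vertical oscillation of the back (VOB)
#'
#' Temporal range (max - min, cm) of the depth at the withers, lumbar and
#' sacral-tuber keypoints; the feature is the maximum of the three ranges.
#'
#' @inheritParams backCurvature
#' @return VOB in cm.
#' @export
verticalOscillationBack <- function(seq) {
    r <- vapply(c("withers", "lumbar", "sacral_tuber"),
                function(kp) rangeNoNA(depthSeriesCm(seq, kp)), numeric(1))
    if (all(is.na(r))) stop("no valid spine depth in any frame")
    max(r, na.rm = TRUE)
}

#' Vertical oscillation of the head (VOH)
#'
#' Temporal range (cm) of the poll keypoint depth.
#'
#' @inheritParams backCurvature
#' @return VOH in cm.
#' @export
verticalOscillationHead <- function(seq) {
    r <- rangeNoNA(depthSeriesCm(seq, "poll"))
    if (is.na(r)) stop("no valid poll depth in any frame")
    r
}

#' Trunk inclination (TI)
#'
#' Per frame, the absolute depth difference (cm) between the left and right
#' scapulae and between the left and right tuber coxae; the feature is the
#' maximum over frames and both pairs.
#'
#' @inheritParams backCurvature
#' @return TI in cm.
#' @export
trunkInclination <- function(seq) {
    dScap <- abs(depthSeriesCm(seq, "left_scapula") -
                 depthSeriesCm(seq, "right_scapula"))
    dCox <- abs(depthSeriesCm(seq, "left_tuber_coxae") -
                depthSeriesCm(seq, "right_tuber_coxae"))
    v <- c(dScap, dCox)
    if (all(is.na(v))) stop("no valid paired depths in any frame")
    max(v, na.rm = TRUE)
}

#' Lateral sway amplitude of the spine (LSAS)
#'
#' Peak-to-valley range (cm) of the horizontal image coordinate of three
#' tracked abscissae - the midpoint of the two scapulae, the lumbar region
#' and the sacral tuber - with the maximum of the three as the feature.
#' Raw image x is used without drift detrending (set \code{detrend = TRUE}
#' to remove a linear drift first).
#'
#' @inheritParams backCurvature
#' @param detrend remove a least-squares linear trend from each abscissa
#'   track before taking the range (default FALSE).
#' @return LSAS in cm.
#' @export
lateralSwayAmplitude <- function(seq, detrend = FALSE) {
    xs <- cbind(
        mid_scapula = (seq@tracks[, "left_scapula", "x"] +
                       seq@tracks[, "right_scapula", "x"]) / 2,
        lumbar = seq@tracks[, "lumbar", "x"],
        sacral_tuber = seq@tracks[, "sacral_tuber", "x"]) * seq@scaleCmPerPx
    if (detrend) {
        t <- seq_len(nrow(xs))
        xs <- apply(xs, 2, function(col) stats::lm.fit(cbind(1, t), col)$residuals)
    }
    max(apply(xs, 2, function(col) diff(range(col))))
}

#' Extract the six-feature gait vector from a sequence
#'
#' Computes BC, MAI, VOB, VOH, TI and LSAS. MAI needs textured frames; when
#' they are absent it is reported as NA with a warning and the other five
#' features are still computed. Per-feature failures are rethrown with the
#' feature name attached.
#'
#' @inheritParams backCurvature
#' @param withMAI compute the flow-based MAI (TRUE); set FALSE to skip the
#'   (comparatively expensive) optical-flow stage.
#' @param floorDepthMm,minHeightMm foreground extraction parameters used by
#'   the MAI stage.
#' @return Named numeric(6) in \code{featureNames()} order.
#' @export
extractFeatures <- function(seq, withMAI = TRUE, floorDepthMm = 2500,
                            minHeightMm = 300) {
    runFeat <- function(name, fn) {
        tryCatch(fn(), error = function(e)
            stop("feature ", name, ": ", conditionMessage(e), call. = FALSE))
    }
    out <- c(BC = runFeat("BC", function() backCurvature(seq)),
             MAI = NA_real_,
             VOB = runFeat("VOB", function() verticalOscillationBack(seq)),
             VOH = runFeat("VOH", function() verticalOscillationHead(seq)),
             TI = runFeat("TI", function() trunkInclination(seq)),
             LSAS = runFeat("LSAS", function() lateralSwayAmplitude(seq)))
    if (withMAI) {
        if (is.null(seq@frames))
            warning("textured frames missing: MAI reported as NA")
        else
            out["MAI"] <- runFeat("MAI", function()
                sequenceMAI(seq, floorDepthMm, minHeightMm))
    }
    out
}

#' Extract a labelled feature table from a list of sequences
#'
#' @param seqs list of \linkS4class{WalkingSequence} objects.
#' @param ... passed to \code{\link{extractFeatures}}.
#' @return data.frame with columns sequence_id, label and the six features.
#' @export
extractFeatureTable <- function(seqs, ...) {
    rows <- lapply(seq_along(seqs), function(i) {
        f <- extractFeatures(seqs[[i]], ...)
        cbind(data.frame(sequence_id = i, label = seqLabel(seqs[[i]]),
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(f)))
    })
    do.call(rbind, rows)
}
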