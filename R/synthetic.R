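# Class-conditional synthetic walking sequences. The simulator lays an
# 8-keypoint cow template on a depth image walking along the vertical image
# axis, and shapes analytic depth / coordinate signals so that each gait
# feature extractor recovers a prescribed target exactly (for zero
# coefficient of variation) or a truncated-normal draw around the class
# mean. Textured frames translate the left and right body halves at
# different speeds so that dense-flow asymmetry approximates the target
# movement asymmetry index.

#' Published class means of the six gait features
#'
#' Estimated mean values of the six lameness indicators per severity class:
#' BC (1/cm), MAI (unitless), VOB, VOH, TI, LSAS (cm). These are the
#' simulator's default calibration targets.
#'
#' @return 3 x 6 numeric matrix, rows \code{lamenessClasses()}, columns
#'   \code{featureNames()}.
#' @export
#' @examples
#' classFeatureMeans()["severe", "VOH"]
classFeatureMeans <- function() {
    m <- rbind(
        sound  = c(0.00021, 0.012, 4.72,  7.92,  3.63, 5.33),
        mild   = c(0.00054, 0.027, 8.23, 10.36,  5.18, 6.67),
        severe = c(0.00093, 0.064, 12.90, 17.28, 6.76, 9.18))
    colnames(m) <- featureNames()
    m
}

#' GaitClassParams: generator settings for one severity class
#'
#' @slot label character(1), one of \code{lamenessClasses()}.
#' @slot targetMeans named numeric(6), per-feature target means (BC 1/cm,
#'   MAI unitless, others cm).
#' @slot targetCv named numeric(6), per-feature coefficient of variation of
#'   the truncated-at-zero normal noise model.
#' @slot nFrames integer(1), frames per sequence (>= 3).
#' @slot fps numeric(1), frame rate.
#' @slot strideFreqHz numeric(1), gait oscillation frequency, Hz.
#' @slot chordCm numeric(1), withers-to-sacral-tuber chord length, cm.
#' @exportClass GaitClassParams
setClass("GaitClassParams",
    representation(label = "character", targetMeans = "numeric",
                   targetCv = "numeric", nFrames = "integer",
                   fps = "numeric", strideFreqHz = "numeric",
                   chordCm = "numeric"))

setValidity("GaitClassParams", function(object) {
    msg <- character()
    if (!object@label %in% lamenessClasses())
        msg <- c(msg, "label must be one of sound/mild/severe")
    if (!identical(names(object@targetMeans), featureNames()))
        msg <- c(msg, "targetMeans must be named by featureNames()")
    else {
        if (any(object@targetMeans < 0))
            msg <- c(msg, "target means must be nonnegative")
        if (object@targetMeans["MAI"] >= 1)
            msg <- c(msg, "MAI mean must lie in [0, 1)")
    }
    if (any(object@targetCv < 0))
        msg <- c(msg, "coefficient of variation must be nonnegative")
    if (object@nFrames < 3L)
        msg <- c(msg, "nFrames must be at least 3")
    if (object@chordCm <= 0)
        msg <- c(msg, "chordCm must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GaitClassParams", function(object) {
    cat("GaitClassParams [", object@label, "] ",
        object@nFrames, " frames @ ", object@fps, " fps, stride ",
        object@strideFreqHz, " Hz, chord ", object@chordCm, " cm\n", sep = "")
    print(rbind(mean = object@targetMeans,
                cv = rep(object@targetCv, length.out = 6)))
})

#' Construct generator settings for a severity class
#'
#' Target means default to the published per-class estimates
#' (\code{\link{classFeatureMeans}}); the within-class spread is a
#' truncated-at-zero normal with coefficient of variation \code{targetCv}
#' (default 0.15, chosen to produce class overlap comparable to real
#' feature box plots; the source data report only class means).
#'
#' @param label "sound", "mild" or "severe".
#' @param targetMeans named numeric(6) of feature targets; defaults to the
#'   class row of \code{\link{classFeatureMeans}}.
#' @param targetCv scalar or per-feature coefficient of variation.
#' @param nFrames frames per sequence.
#' @param fps frame rate (default 30, the recording rate).
#' @param strideFreqHz gait oscillation frequency.
#' @param chordCm withers-to-sacral chord length, cm.
#' @return A \linkS4class{GaitClassParams}.
#' @export
#' @examples
#' gaitClassParams("severe")
gaitClassParams <- function(label, targetMeans = classFeatureMeans()[label, ],
                            targetCv = 0.15, nFrames = 60L, fps = 30,
                            strideFreqHz = 1.0, chordCm = 120) {
    cv <- rep(targetCv, length.out = 6)
    names(cv) <- featureNames()
    tm <- targetMeans[featureNames()]
    new("GaitClassParams", label = label, targetMeans = tm, targetCv = cv,
        nFrames = as.integer(nFrames), fps = fps,
        strideFreqHz = strideFreqHz, chordCm = chordCm)
}

#' Draw labelled feature vectors directly from the class model
#'
#' Feature-level shortcut past the image pipeline: n rows of the six
#' features drawn independently from truncated-at-zero normal distributions
#' with the class's target means and coefficients of variation. With
#' \code{cv = 0} every row equals the target means exactly.
#'
#' @param params a \linkS4class{GaitClassParams}.
#' @param n number of rows (>= 1).
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with columns label, BC, MAI, VOB, VOH, TI, LSAS.
#' @export
#' @examples
#' sampleFeatureVectors(gaitClassParams("sound", targetCv = 0), n = 1, seed = 1)
sampleFeatureVectors <- function(params, n, seed = 1L) {
    stopifnot(is(params, "GaitClassParams"))
    if (n < 1) stop("n must be at least 1")
    withSeed(seed, {
        cols <- lapply(featureNames(), function(f)
            rtruncnormZero(n, params@targetMeans[[f]], params@targetCv[[f]]))
        names(cols) <- featureNames()
        cbind(data.frame(label = rep(params@label, n),
                         stringsAsFactors = FALSE),
              as.data.frame(cols))
    })
}

#' Midpoint sag producing a prescribed back curvature
#'
#' Inverts the circumcircle geometry of the back-curvature feature: returns
#' the sag delta (cm) by which the chord midpoint must be raised so that
#' the circle through the two endpoints (chord L apart, height 0) and the
#' raised midpoint has curvature \code{kTarget}. Solves
#' \eqn{R = L^2/(8\delta) + \delta/2} with \eqn{R = 1/k}, taking the
#' smaller quadratic root; \code{kTarget = 0} gives 0.
#'
#' @param kTarget curvature, 1/cm (>= 0).
#' @param chordCm chord length L, cm (> 0).
#' @return Sag in cm.
#' @export
#' @examples
#' archSagForCurvature(0.01, 120)
archSagForCurvature <- function(kTarget, chordCm) {
    stopifnotScalar(kTarget, "kTarget"); stopifnotScalar(chordCm, "chordCm")
    if (kTarget < 0) stop("kTarget must be nonnegative")
    if (chordCm <= 0) stop("chordCm must be positive")
    if (kTarget == 0) return(0)
    R <- 1 / kTarget
    disc <- R^2 - chordCm^2 / 4
    if (disc < 0)
        stop("curvature too large for this chord: no real sag exists")
    R - sqrt(disc)
}

# Unit-amplitude oscillation over T frames whose realised extrema are
# exactly +/- 1 (constant 0 when amp is 0).
unitOsc <- function(T, fps, freqHz, phase) {
    s <- sin(2 * pi * freqHz * (seq_len(T) - 1) / fps + phase)
    rescaleToRange(s, -1, 1)
}

#' Simulate one synthetic walking sequence
#'
#' Lays the 8-keypoint template on a cow walking along the vertical image
#' axis and constructs analytic signals hitting per-sequence feature
#' targets: a static spine arch (via \code{\link{archSagForCurvature}})
#' for BC, shared sinusoidal depth oscillation of the three spine keypoints
#' (peak-to-peak = VOB), poll depth oscillation (VOH), mirrored left/right
#' depth offsets at the scapulae and tuber coxae (max |difference| = TI)
#' and rigid lateral sway of the template (peak-to-peak = LSAS). Textured
#' frames translate the left body half faster than the right so dense-flow
#' asymmetry approximates MAI. Targets are drawn per sequence from the
#' class noise model (exactly the class means when cv = 0).
#'
#' @param params a \linkS4class{GaitClassParams}.
#' @param seed integer seed; identical seeds give identical sequences.
#' @param imageH,imageW frame size in px (default 160 x 96, desk scale).
#' @param scaleCmPerPx ground-plane scale (default 1.25 cm/px).
#' @param cameraHeightMm camera mount height (default 3200 mm).
#' @param baseDepthMm resting depth of the back (default 1900 mm).
#' @param floorDepthMm floor plane depth (default 2500 mm).
#' @param walkSpeedPxPerFrame mean travel speed of the template.
#' @param withFrames generate textured frames for optical flow (TRUE).
#' @param noiseSdMm optional iid sensor noise added to the depth surface
#'   outside the exact keypoint patches (default 0, analytic signals).
#' @return A \linkS4class{WalkingSequence} with attribute
#'   \code{"targets"}: the per-sequence feature targets actually encoded.
#' @export
simulateSequence <- function(params, seed = 1L, imageH = 160L, imageW = 96L,
                             scaleCmPerPx = 1.25, cameraHeightMm = 3200,
                             baseDepthMm = 1900, floorDepthMm = 2500,
                             walkSpeedPxPerFrame = 0.55, withFrames = TRUE,
                             noiseSdMm = 0) {
    stopifnot(is(params, "GaitClassParams"))
    tg <- sampleFeatureVectors(params, 1L, seed)
    targets <- unlist(tg[featureNames()])
    s <- scaleCmPerPx
    T <- params@nFrames
    aPx <- params@chordCm / (2 * s)        # withers-lumbar = lumbar-sacral, px
    pollOffPx <- 30 / s                    # poll ahead of withers, px
    scapOffPx <- 25 / s                    # scapula lateral offset, px
    coxOffPx <- 22.5 / s
    coxAheadPx <- 12 / s                   # tuber coxae ahead of sacral tuber
    spineX0 <- imageW / 2
    y0 <- 4                                # sacral tuber row at t = 1
    travel <- walkSpeedPxPerFrame * (T - 1)
    if (y0 + 2 * aPx + pollOffPx + travel > imageH - 2 ||
        spineX0 + scapOffPx + targets["LSAS"] / (2 * s) > imageW - 2)
        stop("template does not fit image bounds; enlarge the frame or ",
             "reduce chordCm / nFrames")

    withSeed(seed + 1L, {
        ph <- stats::runif(4, 0, 2 * pi)
        oscVOB <- unitOsc(T, params@fps, params@strideFreqHz, ph[1])
        oscVOH <- unitOsc(T, params@fps, params@strideFreqHz, ph[2])
        sigTI <- unitOsc(T, params@fps, params@strideFreqHz / 2, ph[3])
        sway <- unitOsc(T, params@fps, params@strideFreqHz / 2, ph[4])
        noise <- if (noiseSdMm > 0)
            array(stats::rnorm(imageH * imageW * T, 0, noiseSdMm),
                  c(imageH, imageW, T)) else NULL
        bigTex <- matrix(stats::runif((imageH + ceiling(travel) + 40) *
                                      imageW), imageH + ceiling(travel) + 40,
                         imageW)
    })
    k <- exp(-(-4:4)^2 / (2 * 2^2)); k <- k / sum(k)
    bigTex <- sepFilter2(bigTex, k, k)
    bigTex <- 255 * (bigTex - min(bigTex)) / diff(range(bigTex))

    sag <- archSagForCurvature(targets[["BC"]], 2 * aPx * s)

    # depth signals, mm (smaller = closer to camera = higher point)
    dSpine <- baseDepthMm + 5 * targets[["VOB"]] * oscVOB
    dPoll <- baseDepthMm + 80 + 5 * targets[["VOH"]] * oscVOH
    dLumbar <- dSpine - 10 * sag
    dLscap <- dSpine - 5 * targets[["TI"]] * sigTI
    dRscap <- dSpine + 5 * targets[["TI"]] * sigTI
    dLcox <- dSpine - 4 * targets[["TI"]] * sigTI
    dRcox <- dSpine + 4 * targets[["TI"]] * sigTI

    swayPx <- targets[["LSAS"]] / (2 * s) * sway          # +/- LSAS/2 in cm
    yS <- y0 + walkSpeedPxPerFrame * (seq_len(T) - 1)     # sacral row
    yCx <- yS + coxAheadPx
    yL <- yS + aPx
    yW <- yS + 2 * aPx
    yP <- yW + pollOffPx
    xSpine <- spineX0 + swayPx

    tracks <- array(NA_real_, c(T, 8, 2),
                    dimnames = list(NULL, keypointNames(), c("x", "y")))
    tracks[, "poll", ] <- cbind(xSpine, yP)
    tracks[, "withers", ] <- cbind(xSpine, yW)
    tracks[, "left_scapula", ] <- cbind(xSpine - scapOffPx, yW)
    tracks[, "right_scapula", ] <- cbind(xSpine + scapOffPx, yW)
    tracks[, "lumbar", ] <- cbind(xSpine, yL)
    tracks[, "left_tuber_coxae", ] <- cbind(xSpine - coxOffPx, yCx)
    tracks[, "right_tuber_coxae", ] <- cbind(xSpine + coxOffPx, yCx)
    tracks[, "sacral_tuber", ] <- cbind(xSpine, yS)

    kpDepth <- cbind(poll = dPoll, withers = dSpine, left_scapula = dLscap,
                     right_scapula = dRscap, lumbar = dLumbar,
                     left_tuber_coxae = dLcox, right_tuber_coxae = dRcox,
                     sacral_tuber = dSpine)

    depth <- array(floorDepthMm, c(imageH, imageW, T))
    frames <- if (withFrames) array(0, c(imageH, imageW, T)) else NULL
    bodyHalfW <- scapOffPx + 6
    rows <- seq_len(imageH); cols <- seq_len(imageW)
    for (t in seq_len(T)) {
        fr <- matrix(floorDepthMm, imageH, imageW)
        # smooth body surface: spine profile along y, lateral tilt along x
        yk <- c(yS[t], yCx[t], yL[t], yW[t], yP[t])
        dk <- c(dSpine[t], dSpine[t], dLumbar[t], dSpine[t], dPoll[t])
        inBody <- rows >= yS[t] - 6 & rows <= yP[t] + 4
        prof <- stats::approx(yk, dk, xout = pmin(pmax(rows, yk[1]), yk[5]),
                              rule = 2)$y
        slopeScap <- (dRscap[t] - dSpine[t]) / scapOffPx
        slopeCox <- (dRcox[t] - dSpine[t]) / coxOffPx
        slope <- stats::approx(c(yCx[t], yW[t]), c(slopeCox, slopeScap),
                               xout = pmin(pmax(rows, yCx[t]), yW[t]),
                               rule = 2)$y
        dx <- matrix(cols, imageH, imageW, byrow = TRUE) - xSpine[t]
        surf <- matrix(prof, imageH, imageW) + matrix(slope, imageH, imageW) * dx
        body <- inBody & TRUE
        bmask <- matrix(body, imageH, imageW) & abs(dx) <= bodyHalfW
        fr[bmask] <- surf[bmask]
        if (!is.null(noise)) fr[bmask] <- fr[bmask] + noise[, , t][bmask]
        # exact 3x3 patches at the keypoint pixels
        for (kp in keypointNames()) {
            cx <- round(tracks[t, kp, "x"]); cy <- round(tracks[t, kp, "y"])
            rr <- pmin(pmax((cy - 1):(cy + 1), 1), imageH)
            cc <- pmin(pmax((cx - 1):(cx + 1), 1), imageW)
            fr[rr, cc] <- kpDepth[t, kp]
        }
        depth[, , t] <- fr
        if (withFrames) {
            m <- targets[["MAI"]]
            vL <- walkSpeedPxPerFrame * (1 + m)
            vR <- walkSpeedPxPerFrame * (1 - m)
            texRow <- function(v) rows - v * (t - 1) + 20
            left <- matrix(bilinearAt(bigTex,
                       rep(texRow(vL), imageW), rep(cols, each = imageH)),
                       imageH, imageW)
            right <- matrix(bilinearAt(bigTex,
                       rep(texRow(vR), imageW), rep(cols, each = imageH)),
                       imageH, imageW)
            xs <- matrix(cols, imageH, imageW, byrow = TRUE)
            frames[, , t] <- ifelse(xs < xSpine[t], left, right)
        }
    }
    seq <- WalkingSequence(depth = depth, tracks = tracks, frames = frames,
                           scaleCmPerPx = s, cameraHeightMm = cameraHeightMm,
                           fps = params@fps, label = params@label)
    attr(seq, "targets") <- targets
    seq
}

#' Simulate a labelled cohort of walking sequences
#'
#' @param counts named integer vector, sequences per class, e.g.
#'   \code{c(sound = 10, mild = 10, severe = 10)}.
#' @param targetCv,nFrames passed to \code{\link{gaitClassParams}}.
#' @param seed master seed; per-sequence seeds are derived from it.
#' @param ... further arguments to \code{\link{simulateSequence}}.
#' @return List of \linkS4class{WalkingSequence} objects.
#' @export
simulateCohort <- function(counts = c(sound = 5, mild = 5, severe = 5),
                           targetCv = 0.15, nFrames = 60L, seed = 1L, ...) {
    seeds <- deriveSeeds(seed, sum(counts))
    out <- vector("list", sum(counts))
    i <- 0L
    for (cl in names(counts)) {
        prm <- gaitClassParams(cl, targetCv = targetCv, nFrames = nFrames)
        for (j in seq_len(counts[[cl]])) {
            i <- i + 1L
            out[[i]] <- simulateSequence(prm, seed = seeds[i], ...)
        }
    }
    out
}
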