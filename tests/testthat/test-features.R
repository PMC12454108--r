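# Gait feature extractors against brute-force oracles and constructed
# sequences with known answers.

test_that("circumcircle curvature matches the perpendicular-bisector oracle", {
    expect_equal(circumcircleCurvature(c(0, 0), c(50, 50), c(100, 0)), 0.02)
    expect_equal(circumcircleCurvature(c(0, 0), c(60, 0), c(120, 0)), 0)
    expect_error(circumcircleCurvature(c(1, 1), c(1, 1), c(2, 2)),
                 "degenerate")
    set.seed(13)
    for (i in 1:200) {
        p <- matrix(runif(6, -50, 50), 3, 2)
        area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
        if (area < 1e-6) next
        expect_lt(abs(circumcircleCurvature(p[1, ], p[2, ], p[3, ]) -
                      circumcurvOracle(p[1, ], p[2, ], p[3, ])), 1e-9)
    }
})

test_that("back curvature is zero for a flat back and takes the per-frame maximum", {
    flat <- makeTestSequence(constantKpDepths(5))
    expect_equal(backCurvature(flat), 0)
    # arch only in frame 3: lumbar raised by 4 cm (40 mm closer)
    kd <- constantKpDepths(5)
    kd[3, "lumbar"] <- 1900 - 40
    arched <- makeTestSequence(kd)
    # oracle: chord withers->lumbar->sacral is 8 + 8 px at 1 cm/px
    expected <- circumcircleCurvature(c(0, 130), c(8, 134), c(16, 130))
    expect_equal(backCurvature(arched), expected, tolerance = 1e-12)
    expect_gt(backCurvature(arched), 0)
})

test_that("left/right split matches a per-pixel signed-cross-product oracle", {
    mask <- matrix(FALSE, 21, 21)
    for (i in 1:21) for (j in 1:21)
        mask[i, j] <- (i - 11)^2 + (j - 11)^2 <= 81
    sp <- splitLeftRight(mask, withers = c(11, 2), lumbar = c(11, 20))
    expect_lte(abs(sum(sp$left) - sum(sp$right)), 21)  # symmetric +/- axis row
    expect_equal(sum(sp$left) + sum(sp$right), sum(mask))
    # reversing the axis swaps the halves (zero-cross pixels stay left)
    spRev <- splitLeftRight(mask, withers = c(11, 20), lumbar = c(11, 2))
    boundary <- mask & col(mask) == 11
    expect_identical(spRev$left, sp$right | boundary)
    expect_identical(spRev$right, sp$left & !boundary)
    expect_error(splitLeftRight(mask, c(5, 5), c(5, 5)), "degenerate")

    set.seed(21)
    rmask <- matrix(runif(15 * 15) < 0.5, 15, 15)
    p1 <- c(3, 4); p2 <- c(12, 11)
    sp3 <- splitLeftRight(rmask, p1, p2)
    for (i in 1:15) for (j in 1:15) {
        if (!rmask[i, j]) next
        cr <- (p2[1] - p1[1]) * (i - p1[2]) - (p2[2] - p1[2]) * (j - p1[1])
        expect_equal(sp3$left[i, j], cr >= 0)
    }
})

test_that("movement asymmetry index follows its defining ratio", {
    L <- matrix(FALSE, 6, 6); L[, 1:3] <- TRUE
    R <- !L
    mkflow <- function(u) list(u = matrix(u, 6, 6), v = matrix(0, 6, 6))
    # identical motion in both halves
    expect_equal(movementAsymmetryIndex(list(mkflow(2)), L, R), 0)
    # muL = 3, muR = 1 -> 0.5
    fl <- list(u = cbind(matrix(3, 6, 3), matrix(1, 6, 3)),
               v = matrix(0, 6, 6))
    expect_equal(movementAsymmetryIndex(list(fl), L, R), 0.5)
    # zero motion everywhere -> 0 by convention
    expect_equal(movementAsymmetryIndex(list(mkflow(0)), L, R), 0)
    expect_error(movementAsymmetryIndex(list(mkflow(1)), matrix(FALSE, 6, 6), R),
                 "empty")
    set.seed(17)
    for (i in 1:50) {
        fl <- list(u = matrix(rnorm(36), 6), v = matrix(rnorm(36), 6))
        m <- movementAsymmetryIndex(list(fl), L, R)
        expect_gte(m, 0); expect_lte(m, 1)
    }
})

test_that("vertical oscillations and trunk inclination equal brute-force ranges", {
    T <- 20
    kd <- constantKpDepths(T)
    expect_equal(verticalOscillationBack(makeTestSequence(kd)), 0)
    expect_equal(verticalOscillationHead(makeTestSequence(kd)), 0)
    expect_equal(trunkInclination(makeTestSequence(kd)), 0)

    # withers sinusoid of 4 cm peak-to-peak, others flat
    kd2 <- constantKpDepths(T)
    kd2[, "withers"] <- 1900 + 20 * cos(pi * (0:(T - 1)) / (T - 1))
    expect_equal(verticalOscillationBack(makeTestSequence(kd2)), 4)

    # scapula offset of 5 cm in one frame only
    kd3 <- constantKpDepths(T)
    kd3[7, "left_scapula"] <- 1900 - 50
    expect_equal(trunkInclination(makeTestSequence(kd3)), 5)

    # random tracks vs direct scan
    set.seed(23)
    kd4 <- constantKpDepths(T) + matrix(runif(T * 8, -80, 80), T, 8)
    sq <- makeTestSequence(kd4)
    rng <- function(x) diff(range(x)) / 10
    expect_equal(verticalOscillationBack(sq),
                 max(rng(kd4[, "withers"]), rng(kd4[, "lumbar"]),
                     rng(kd4[, "sacral_tuber"])))
    expect_equal(verticalOscillationHead(sq), rng(kd4[, "poll"]))
    expect_equal(trunkInclination(sq),
                 max(abs(kd4[, "left_scapula"] - kd4[, "right_scapula"]) / 10,
                     abs(kd4[, "left_tuber_coxae"] -
                         kd4[, "right_tuber_coxae"]) / 10))
})

test_that("lateral sway is the maximum peak-to-valley of the three abscissae", {
    T <- 16
    tr <- testTemplate(T)
    expect_equal(lateralSwayAmplitude(
        makeTestSequence(constantKpDepths(T), tr)), 0)
    sw <- 4.59 * sin(seq(0, 2 * pi, length.out = T))  # 9.18 cm peak-to-peak?
    sw <- sw - min(sw); sw <- sw * 9.18 / max(sw) - 9.18 / 2
    tr2 <- tr
    tr2[, "lumbar", "x"] <- tr[, "lumbar", "x"] + sw
    sq <- makeTestSequence(constantKpDepths(T), tr2)
    expect_equal(lateralSwayAmplitude(sq), 9.18, tolerance = 1e-9)
    # random tracks vs brute force
    set.seed(29)
    tr3 <- tr
    for (kp in keypointNames())
        tr3[, kp, "x"] <- tr[, kp, "x"] + runif(T, -2, 2)
    sq3 <- makeTestSequence(constantKpDepths(T), tr3)
    mids <- (tr3[, "left_scapula", "x"] + tr3[, "right_scapula", "x"]) / 2
    expect_equal(lateralSwayAmplitude(sq3),
                 max(diff(range(mids)), diff(range(tr3[, "lumbar", "x"])),
                     diff(range(tr3[, "sacral_tuber", "x"]))))
})

test_that("features are invariant to rigid translation and scale as dimensioned quantities", {
    T <- 8
    set.seed(37)
    kd <- constantKpDepths(T) + matrix(runif(T * 8, -60, 60), T, 8)
    tr <- testTemplate(T)
    sq1 <- makeTestSequence(kd, tr, H = 60, W = 44)
    tr2 <- tr; tr2[, , "x"] <- tr[, , "x"] + 7; tr2[, , "y"] <- tr[, , "y"] + 11
    sq2 <- makeTestSequence(kd, tr2, H = 60, W = 44)
    for (fn in list(backCurvature, verticalOscillationBack,
                    verticalOscillationHead, trunkInclination))
        expect_equal(fn(sq1), fn(sq2), tolerance = 1e-12)
    # translation along the travel axis leaves LSAS unchanged
    tr3 <- tr; tr3[, , "y"] <- tr[, , "y"] + 5
    expect_equal(lateralSwayAmplitude(makeTestSequence(kd, tr3, H = 60)),
                 lateralSwayAmplitude(sq1))
    # doubling the scale doubles LSAS and halves BC when heights scale too
    camH <- 3200
    kdScaled <- camH - 2 * (camH - kd)   # heights double
    sqBig <- makeTestSequence(kdScaled, tr, H = 60, W = 44, scale = 2,
                              camH = camH)
    expect_equal(lateralSwayAmplitude(sqBig), 2 * lateralSwayAmplitude(sq1))
    expect_equal(backCurvature(sqBig), backCurvature(sq1) / 2,
                 tolerance = 1e-12)
})

test_that("extractFeatures flags a missing MAI and attaches feature names to errors", {
    sq <- makeTestSequence(constantKpDepths(6))
    expect_warning(f <- extractFeatures(sq), "MAI")
    expect_true(is.na(f["MAI"]))
    expect_false(anyNA(f[c("BC", "VOB", "VOH", "TI", "LSAS")]))
    f2 <- extractFeatures(sq, withMAI = FALSE)
    expect_true(is.na(f2["MAI"]))
    # all-void depth at spine keypoints in every frame -> named error
    sqBad <- sq
    sqBad@depth[] <- 0
    sqBad@depth[1, 1, ] <- 1500  # keep at least one valid pixel
    expect_error(extractFeatures(sqBad, withMAI = FALSE), "BC")
})
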