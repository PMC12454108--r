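# Shared fixtures: hand-built walking sequences with prescribed keypoint
# depth series, independent geometry oracles, and feature-table generators
# for the screening simulations.

# Template keypoint layout for a small test frame (H = 40 rows, W = 30
# cols): spine on column 15, head toward larger y.
testTemplate <- function(T) {
    tr <- array(NA_real_, c(T, 8, 2),
                dimnames = list(NULL, keypointNames(), c("x", "y")))
    xy <- rbind(poll = c(15, 30), withers = c(15, 22),
                left_scapula = c(9, 22), right_scapula = c(21, 22),
                lumbar = c(15, 14), left_tuber_coxae = c(9, 8),
                right_tuber_coxae = c(21, 8), sacral_tuber = c(15, 6))
    for (kp in keypointNames()) tr[, kp, ] <- rep(xy[kp, ], each = T)
    tr
}

# Build a WalkingSequence by stamping per-keypoint depth series (T x 8,
# mm) onto a constant floor; tracks default to the static template.
makeTestSequence <- function(kpDepths, tracks = NULL, H = 40, W = 30,
                             floor = 2500, scale = 1, camH = 3200, fps = 30) {
    T <- nrow(kpDepths)
    if (is.null(tracks)) tracks <- testTemplate(T)
    depth <- array(floor, c(H, W, T))
    for (t in seq_len(T)) {
        fr <- depth[, , t]
        for (k in seq_len(8)) {
            cx <- round(tracks[t, k, "x"]); cy <- round(tracks[t, k, "y"])
            rr <- pmin(pmax((cy - 1):(cy + 1), 1), H)
            cc <- pmin(pmax((cx - 1):(cx + 1), 1), W)
            fr[rr, cc] <- kpDepths[t, k]
        }
        depth[, , t] <- fr
    }
    WalkingSequence(depth = depth, tracks = tracks, scaleCmPerPx = scale,
                    cameraHeightMm = camH, fps = fps)
}

# Constant depth series at the template: every keypoint at `mm`.
constantKpDepths <- function(T, mm = 1900) {
    matrix(mm, T, 8, dimnames = list(NULL, keypointNames()))
}

# Independent circumcircle oracle: perpendicular-bisector intersection.
circumcurvOracle <- function(p1, p2, p3) {
    A <- 2 * rbind(p2 - p1, p3 - p1)
    b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
    det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    if (abs(det) < 1e-12) return(0)     # collinear
    ctr <- solve(A, b)
    1 / sqrt(sum((ctr - p1)^2))
}

# Class-conditional feature table with 3 strong (BC, MAI, VOB), 1 weak
# (VOH, class separation shrunk to a quarter) and 2 null (TI, LSAS, same
# distribution in every class) features; n split as evenly as possible.
mixedSignalTable <- function(n, seed, cv = 0.15) {
    counts <- rep(n %/% 3, 3) + (seq_len(3) <= n %% 3)
    names(counts) <- lamenessClasses()
    means <- classFeatureMeans()
    grand <- colMeans(means)
    rows <- lapply(lamenessClasses(), function(cl) {
        tm <- means[cl, ]
        tm["VOH"] <- grand["VOH"] + 0.25 * (means[cl, "VOH"] - grand["VOH"])
        tm["TI"] <- means["sound", "TI"]
        tm["LSAS"] <- means["sound", "LSAS"]
        prm <- gaitClassParams(cl, targetMeans = tm, targetCv = cv)
        sampleFeatureVectors(prm, counts[[cl]],
                             seed = seed + match(cl, lamenessClasses()))
    })
    do.call(rbind, rows)
}

# Pure-noise table: six iid standard-normal-ish features, labels balanced.
pureNoiseTable <- function(n, seed) {
    withr::with_seed(seed, {
        X <- as.data.frame(matrix(stats::rnorm(n * 6), n, 6))
        names(X) <- featureNames()
        X$label <- sample(rep(lamenessClasses(), length.out = n))
        X
    })
}

# Table calibrated to the published class means with the published cohort
# sizes (260 sound / 237 mild / 244 severe).
cohortFeatureTable <- function(seed, cv = 0.15,
                               counts = c(sound = 260, mild = 237,
                                          severe = 244)) {
    do.call(rbind, lapply(names(counts), function(cl)
        sampleFeatureVectors(gaitClassParams(cl, targetCv = cv),
                             counts[[cl]],
                             seed = seed + match(cl, names(counts)))))
}
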