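# Internal helpers shared across modules.

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Derive reproducible child seeds from a master seed (kept below 2^31).
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Rescale a numeric vector so its realised min/max hit lo/hi exactly.
# A constant vector maps to the midpoint; used by the simulator to make
# sampled sinusoids attain their nominal peak-to-peak amplitude.
rescaleToRange <- function(s, lo, hi) {
    rng <- range(s)
    if (hi == lo) return(rep(lo, length(s)))
    if (rng[2] == rng[1]) return(rep((lo + hi) / 2, length(s)))
    lo + (hi - lo) * (s - rng[1]) / (rng[2] - rng[1])
}

# Round half away from zero (half-up for nonnegative input).
roundHalfUp <- function(x) floor(x + 0.5)

# Separable 2-D correlation with border replication. kx runs along columns
# (x), ky along rows (y); kernels are centred, odd length.
sepFilter2 <- function(img, kx, ky) {
    filt1 <- function(m, k, along) {
        r <- (length(k) - 1L) %/% 2L
        n <- if (along == "row") nrow(m) else ncol(m)
        acc <- 0
        for (j in seq_along(k)) {
            off <- j - 1L - r
            idx <- pmin(pmax(seq_len(n) + off, 1L), n)
            acc <- acc + k[j] * (if (along == "row") m[idx, , drop = FALSE]
                                 else m[, idx, drop = FALSE])
        }
        acc
    }
    filt1(filt1(img, ky, "row"), kx, "col")
}

# Box (mean) blur with odd window, border replication; separable.
boxBlur <- function(img, win) {
    k <- rep(1 / win, win)
    sepFilter2(img, k, k)
}

# Bilinear interpolation of matrix m at (row, col) positions; coordinates
# clamped to the image domain.
bilinearAt <- function(m, row, col) {
    H <- nrow(m); W <- ncol(m)
    row <- pmin(pmax(row, 1), H)
    col <- pmin(pmax(col, 1), W)
    r0 <- pmin(floor(row), H - 1L); c0 <- pmin(floor(col), W - 1L)
    fr <- row - r0; fc <- col - c0
    i00 <- (c0 - 1) * H + r0
    m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
        m[i00 + H] * (1 - fr) * fc + m[i00 + H + 1] * fr * fc
}

# Truncated-at-zero normal sampler via inverse CDF; sd = cv * mean.
# cv = 0 returns the mean exactly.
rtruncnormZero <- function(n, mean, cv) {
    if (cv < 0) stop("coefficient of variation must be nonnegative")
    if (cv == 0 || mean == 0) return(rep(mean, n))
    sd <- cv * mean
    p0 <- stats::pnorm(0, mean, sd)
    stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

stopifnotScalar <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(name, " must be a finite numeric scalar")
    invisible(x)
}
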