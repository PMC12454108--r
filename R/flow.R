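# Dense optical flow by polynomial expansion (Farneback). Each image patch
# is approximated by a local quadratic f(x) ~ x'Ax + b'x + c under a
# Gaussian applicability; the displacement between two expansions solves
# A d = -(b2 - b1)/2, accumulated over a smoothing window and refined
# iteratively over an image pyramid.
#
# Convention: flow (u, v) maps frame 1 into frame 2 as
# img2(y + v, x + u) ~ img1(y, x), i.e. content moving down-right has
# positive (u, v).

# Quadratic expansion coefficients of one image. Returns per-pixel matrices
# A11, A12, A22 (A is symmetric) and b1, b2.
polyExpand <- function(img, polyN = 7, polySigma = 1.5) {
    x <- -polyN:polyN
    w <- exp(-x^2 / (2 * polySigma^2))
    w <- w / sum(w)
    g <- w; gx <- w * x; gxx <- w * x^2
    s00 <- sepFilter2(img, g, g)
    s10 <- sepFilter2(img, gx, g)    # x moment (columns)
    s01 <- sepFilter2(img, g, gx)    # y moment (rows)
    s20 <- sepFilter2(img, gxx, g)
    s02 <- sepFilter2(img, g, gxx)
    s11 <- sepFilter2(img, gx, gx)
    # Normal matrix of the basis (1, x, y, x^2, y^2, xy) under the same
    # weights; constant across pixels (full certainty).
    offs <- expand.grid(dx = x, dy = x)
    w2 <- w[match(offs$dx, x)] * w[match(offs$dy, x)]
    B <- rbind(1, offs$dx, offs$dy, offs$dx^2, offs$dy^2, offs$dx * offs$dy)
    M <- (B * rep(w2, each = 6)) %*% t(B)
    Minv <- solve(M)
    S <- cbind(as.vector(s00), as.vector(s10), as.vector(s01),
               as.vector(s20), as.vector(s02), as.vector(s11))
    P <- S %*% t(Minv)
    dims <- dim(img)
    list(A11 = matrix(P[, 4], dims[1], dims[2]),
         A22 = matrix(P[, 5], dims[1], dims[2]),
         A12 = matrix(P[, 6] / 2, dims[1], dims[2]),
         b1  = matrix(P[, 2], dims[1], dims[2]),
         b2  = matrix(P[, 3], dims[1], dims[2]))
}

# Bilinear resize to (H, W).
resizeBilinear <- function(m, H, W) {
    sy <- nrow(m) / H; sx <- ncol(m) / W
    rows <- (seq_len(H) - 0.5) * sy + 0.5
    cols <- (seq_len(W) - 0.5) * sx + 0.5
    rr <- matrix(rows, H, W)
    cc <- matrix(cols, H, W, byrow = TRUE)
    matrix(bilinearAt(m, as.vector(rr), as.vector(cc)), H, W)
}

gaussBlur <- function(img, sigma) {
    r <- ceiling(2 * sigma)
    k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
    sepFilter2(img, k, k)
}

# One-level displacement refinement given both expansions and a prior flow.
flowRefine <- function(e1, e2, u, v, winsize, iterations) {
    H <- nrow(e1$A11); W <- ncol(e1$A11)
    base_r <- matrix(seq_len(H), H, W)
    base_c <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (it in seq_len(iterations)) {
        rr <- as.vector(base_r + v); cc <- as.vector(base_c + u)
        A11 <- 0.5 * (e1$A11 + matrix(bilinearAt(e2$A11, rr, cc), H, W))
        A12 <- 0.5 * (e1$A12 + matrix(bilinearAt(e2$A12, rr, cc), H, W))
        A22 <- 0.5 * (e1$A22 + matrix(bilinearAt(e2$A22, rr, cc), H, W))
        db1 <- -0.5 * (matrix(bilinearAt(e2$b1, rr, cc), H, W) - e1$b1) +
            A11 * u + A12 * v
        db2 <- -0.5 * (matrix(bilinearAt(e2$b2, rr, cc), H, W) - e1$b2) +
            A12 * u + A22 * v
        G11 <- boxBlur(A11 * A11 + A12 * A12, winsize)
        G12 <- boxBlur(A11 * A12 + A12 * A22, winsize)
        G22 <- boxBlur(A12 * A12 + A22 * A22, winsize)
        h1 <- boxBlur(A11 * db1 + A12 * db2, winsize)
        h2 <- boxBlur(A12 * db1 + A22 * db2, winsize)
        det <- G11 * G22 - G12 * G12
        det[abs(det) < 1e-12] <- Inf
        u <- (G22 * h1 - G12 * h2) / det
        v <- (G11 * h2 - G12 * h1) / det
    }
    list(u = u, v = v)
}

#' Dense optical flow between two grayscale frames
#'
#' Polynomial-expansion (Farneback) dense flow with an image pyramid.
#' Defaults follow common practice for this algorithm: pyramid scale 0.5
#' over 3 levels, 15 px averaging window, 3 iterations per level, 7 px
#' expansion neighbourhood with Gaussian sigma 1.5.
#'
#' @param img1,img2 numeric matrices of equal size (grayscale intensities).
#' @param pyrScale pyramid downscale factor per level (0.5 halves).
#' @param levels number of pyramid levels.
#' @param winsize odd averaging window for the displacement solve, px.
#' @param iterations refinement iterations per level.
#' @param polyN expansion neighbourhood radius, px.
#' @param polySigma Gaussian sigma of the expansion applicability.
#' @return list(u, v): per-pixel displacement fields (px/frame) such that
#'   \code{img2[y + v, x + u] ~ img1[y, x]}.
#' @export
farnebackFlow <- function(img1, img2, pyrScale = 0.5, levels = 3,
                          winsize = 15, iterations = 3,
                          polyN = 7, polySigma = 1.5) {
    if (!identical(dim(img1), dim(img2)))
        stop("frames must have identical dimensions")
    H <- nrow(img1); W <- ncol(img1)
    # pyramid sizes, coarsest first
    sizes <- list(c(H, W))
    for (l in seq_len(levels - 1)) {
        p <- sizes[[1]]
        np <- round(p * pyrScale)
        if (min(np) < 4 * polyN) break
        sizes <- c(list(np), sizes)
    }
    u <- v <- NULL
    for (s in sizes) {
        i1 <- if (all(s == c(H, W))) img1 else
            resizeBilinear(gaussBlur(img1, 1 / pyrScale * 0.5), s[1], s[2])
        i2 <- if (all(s == c(H, W))) img2 else
            resizeBilinear(gaussBlur(img2, 1 / pyrScale * 0.5), s[1], s[2])
        if (is.null(u)) {
            u <- matrix(0, s[1], s[2]); v <- matrix(0, s[1], s[2])
        } else {
            u <- resizeBilinear(u, s[1], s[2]) / pyrScale
            v <- resizeBilinear(v, s[1], s[2]) / pyrScale
        }
        e1 <- polyExpand(i1, polyN, polySigma)
        e2 <- polyExpand(i2, polyN, polySigma)
        fl <- flowRefine(e1, e2, u, v, winsize, iterations)
        u <- fl$u; v <- fl$v
    }
    list(u = u, v = v)
}

#' Flow magnitude field
#'
#' @param flow list(u, v) as returned by \code{\link{farnebackFlow}}.
#' @return Matrix of Euclidean flow magnitudes (px/frame), nonnegative.
#' @export
flowMagnitude <- function(flow) sqrt(flow$u^2 + flow$v^2)
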