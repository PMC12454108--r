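# Depth-frame preprocessing: range clipping, void-aware denoising,
# nearest-neighbour hole filling, void-rate screening, foreground masking
# and grayscale conversion.
#
# A depth frame is a numeric H x W matrix in millimetres with 0 marking a
# void (invalid) pixel; all functions preserve that convention.

# out[r, c] = m[r + dy, c + dx], NA outside the image.
shiftMat <- function(m, dy, dx) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(NA_real_, H, W)
    rs <- max(1, 1 - dy):min(H, H - dy)
    cs <- max(1, 1 - dx):min(W, W - dx)
    if (length(rs) && length(cs))
        out[rs, cs] <- m[rs + dy, cs + dx, drop = FALSE]
    out
}

#' Clip a depth frame to the working range
#'
#' Pixels outside \code{[clipMin, clipMax]} (boundaries inclusive) are
#' marked void (set to 0); in-range pixels are unchanged. The default range
#' 1200--2600 mm brackets the cow's back and the floor under an overhead
#' mount.
#'
#' @param frame numeric matrix, depth in mm (0 = void).
#' @param clipMin,clipMax clip range in mm, \code{clipMin < clipMax}.
#' @return Clipped depth matrix.
#' @export
#' @examples
#' clipDepth(matrix(c(1000, 1200, 2600, 3000), 2))
clipDepth <- function(frame, clipMin = 1200, clipMax = 2600) {
    if (clipMin >= clipMax) stop("clipMin must be less than clipMax")
    frame[frame < clipMin | frame > clipMax] <- 0
    frame
}

# Void-aware bilateral filter (compiled kernel). Spatial Gaussian sigma in
# px, truncated at radius ceiling(2*sigma); range Gaussian sigma on depth
# normalised to [0, 1] over the clip span. Void pixels are excluded from
# every kernel and remain void in the output.
bilateralDepth <- function(frame, spatialSigma = 5, rangeSigma = 0.1,
                           clipMin = 1200, clipMax = 2600) {
    if (!any(frame > 0)) return(frame)
    bilateral_depth_cpp(frame, spatialSigma, rangeSigma, clipMin, clipMax)
}

# Void-aware median filter with odd square window; voids excluded from the
# kernel and preserved in the output.
medianDepth <- function(frame, win = 3) {
    median_depth_cpp(frame, as.integer(win))
}

#' Denoise a clipped depth frame
#'
#' Bilateral filtering (spatial sigma 5 px; range sigma 0.1 on depth
#' normalised to \eqn{[0,1]} over the clip span) to suppress random noise,
#' followed by a 3 x 3 median to remove isolated outliers. Void pixels are
#' excluded from both kernels and stay void.
#'
#' @inheritParams clipDepth
#' @param spatialSigma bilateral spatial-domain sigma, px.
#' @param rangeSigma bilateral range-domain sigma on normalised depth.
#' @param medianWin odd median window size.
#' @return Denoised depth matrix.
#' @export
denoiseDepth <- function(frame, spatialSigma = 5, rangeSigma = 0.1,
                         medianWin = 3, clipMin = 1200, clipMax = 2600) {
    medianDepth(bilateralDepth(frame, spatialSigma, rangeSigma,
                               clipMin, clipMax), medianWin)
}

#' Fill depth voids by nearest-neighbour interpolation
#'
#' Every void pixel takes the value of its nearest valid pixel by Euclidean
#' distance; equidistant candidates are resolved by smaller row, then
#' smaller column, so the result is reproducible.
#'
#' @inheritParams clipDepth
#' @return Depth matrix with no voids.
#' @export
fillHolesNearest <- function(frame) {
    valid <- frame > 0
    if (!any(valid)) stop("cannot fill an all-void frame")
    if (all(valid)) return(frame)
    H <- nrow(frame); W <- ncol(frame)
    rmax <- max(H, W) - 1L
    offs <- expand.grid(dy = -rmax:rmax, dx = -rmax:rmax)
    offs$d2 <- offs$dy^2 + offs$dx^2
    offs <- offs[offs$d2 > 0, ]
    # Within one distance shell, (dy, dx) order equals candidate (row, col)
    # order for a fixed void pixel, giving the documented tie-break.
    offs <- offs[order(offs$d2, offs$dy, offs$dx), ]
    todo <- which(!valid)
    tr <- ((todo - 1L) %% H) + 1L
    tc <- ((todo - 1L) %/% H) + 1L
    out <- frame
    for (i in seq_len(nrow(offs))) {
        if (!length(todo)) break
        rr <- tr + offs$dy[i]; cc <- tc + offs$dx[i]
        ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        if (any(ok)) {
            src <- (cc[ok] - 1L) * H + rr[ok]
            hit <- valid[src]
            if (any(hit)) {
                sel <- which(ok)[hit]
                out[todo[sel]] <- frame[src[hit]]
                keep <- setdiff(seq_along(todo), sel)
                todo <- todo[keep]; tr <- tr[keep]; tc <- tc[keep]
            }
        }
    }
    out
}

#' Void rate within a body region
#'
#' Fraction of void pixels inside a body mask. A walking sequence is
#' rejected when any frame's body void rate is greater than or equal to the
#' screening threshold (0.10 by default, boundary inclusive).
#'
#' @inheritParams clipDepth
#' @param bodyMask logical matrix, the cow body region (nonempty).
#' @return Fraction in \eqn{[0, 1]}.
#' @seealso \code{\link{screenByVoidRate}}
#' @export
voidRate <- function(frame, bodyMask) {
    if (!any(bodyMask)) stop("body mask is empty")
    sum(frame[bodyMask] == 0) / sum(bodyMask)
}

#' Screen a depth sequence by body void rate
#'
#' @param stack H x W x T depth array.
#' @param bodyMasks logical H x W x T array of per-frame body regions (or a
#'   single H x W matrix reused for all frames).
#' @param threshold rejection threshold; a sequence is rejected when any
#'   frame's void rate is >= threshold.
#' @return list(keep = logical(1), rates = per-frame void rates).
#' @export
screenByVoidRate <- function(stack, bodyMasks, threshold = 0.10) {
    T <- dim(stack)[3]
    getMask <- if (length(dim(bodyMasks)) == 3L)
        function(t) bodyMasks[, , t] else function(t) bodyMasks
    rates <- vapply(seq_len(T), function(t) voidRate(stack[, , t], getMask(t)),
                    numeric(1))
    list(keep = all(rates < threshold), rates = rates)
}

#' Extract the cow foreground from a depth frame
#'
#' Pixels standing at least \code{minHeightMm} above the floor plane
#' (\code{depth < floorDepthMm - minHeightMm}, voids excluded) form the
#' candidate foreground; only the largest 4-connected component is kept.
#'
#' @inheritParams clipDepth
#' @param floorDepthMm depth of the floor plane, mm.
#' @param minHeightMm minimum height above the floor for body pixels, mm.
#' @return Logical H x W matrix.
#' @export
foregroundMask <- function(frame, floorDepthMm = 2500, minHeightMm = 300) {
    cand <- frame > 0 & frame < (floorDepthMm - minHeightMm)
    if (!any(cand)) stop("no animal present: foreground mask is empty")
    H <- nrow(frame)
    idx <- which(cand)
    pos <- match(idx, idx)
    r <- ((idx - 1L) %% H) + 1L
    # 4-connectivity edges between adjacent candidate pixels
    edges <- integer(0)
    down <- idx + 1L
    ok <- r < H & (down %in% idx)
    if (any(ok)) edges <- c(edges, rbind(pos[ok], match(down[ok], idx)))
    right <- idx + H
    ok <- (right %in% idx)
    if (any(ok)) edges <- c(edges, rbind(pos[ok], match(right[ok], idx)))
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)
    keep <- idx[comp$membership == which.max(comp$csize)]
    out <- matrix(FALSE, H, ncol(frame))
    out[keep] <- TRUE
    out
}

#' Convert a filled depth frame to 8-bit grayscale
#'
#' Linear map of \code{[clipMin, clipMax]} to \code{[0, 255]}, rounded half
#' up; values are clamped to the range first. Deeper pixels never map to a
#' smaller gray value.
#'
#' @inheritParams clipDepth
#' @return Integer matrix with values 0..255.
#' @export
depthToGray <- function(frame, clipMin = 1200, clipMax = 2600) {
    v <- pmin(pmax(frame, clipMin), clipMax)
    g <- roundHalfUp(255 * (v - clipMin) / (clipMax - clipMin))
    matrix(as.integer(g), nrow(frame), ncol(frame))
}

#' Run the full depth-preprocessing chain on a stack
#'
#' Fixed stage order clip -> bilateral -> median -> nearest-neighbour hole
#' filling, applied per frame.
#'
#' @param stack H x W x T depth array, mm.
#' @param clipMin,clipMax clip range, mm.
#' @param spatialSigma,rangeSigma,medianWin denoising parameters, see
#'   \code{\link{denoiseDepth}}.
#' @param denoise set FALSE to skip the smoothing stages (clean synthetic
#'   input).
#' @return Preprocessed H x W x T array with no voids.
#' @export
preprocessDepthStack <- function(stack, clipMin = 1200, clipMax = 2600,
                                 spatialSigma = 5, rangeSigma = 0.1,
                                 medianWin = 3, denoise = TRUE) {
    out <- stack
    for (t in seq_len(dim(stack)[3])) {
        f <- clipDepth(stack[, , t], clipMin, clipMax)
        if (denoise)
            f <- denoiseDepth(f, spatialSigma, rangeSigma, medianWin,
                              clipMin, clipMax)
        out[, , t] <- fillHolesNearest(f)
    }
    out
}
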