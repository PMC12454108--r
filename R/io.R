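# File-format adapters: 16-bit PNG depth stacks, JSON keypoint tracks,
# CSV feature tables and manifests.
#
# Depth frames are written as true 16-bit grayscale PNGs. The png package
# reads those but only writes 8-bit, so the writer below emits the fixed
# subformat itself (bit depth 16, colour type 0, filter 0 scanlines,
# zlib-compressed via memCompress); png::readPNG is used for reading.

pngCrcTable <- local({
    tab <- NULL
    function() {
        if (is.null(tab)) {
            t0 <- integer(256)
            for (n in 0:255) {
                cc <- n
                for (k in 1:8)
                    cc <- if (bitwAnd(cc, 1L))
                        bitwXor(bitwShiftR(cc, 1L), -306674912L)
                    else bitwShiftR(cc, 1L)
                t0[n + 1] <- cc
            }
            tab <<- t0
        }
        tab
    }
})

pngCrc32 <- function(bytes) {
    tab <- pngCrcTable()
    cc <- -1L
    for (b in as.integer(bytes))
        cc <- bitwXor(bitwShiftR(cc, 8L),
                      tab[bitwAnd(bitwXor(cc, b), 255L) + 1L])
    bitwXor(cc, -1L)
}

pngBe32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "big")

pngChunk <- function(type, data) {
    td <- c(charToRaw(type), data)
    c(pngBe32(length(data)), td, pngBe32(pngCrc32(td)))
}

# Write one integer matrix (0..65535) as a 16-bit grayscale PNG.
writePNG16 <- function(mat, path) {
    H <- nrow(mat); W <- ncol(mat)
    V <- t(mat)
    inter <- matrix(0L, 2L * W, H)
    inter[seq(1L, 2L * W, 2L), ] <- V %/% 256L
    inter[seq(2L, 2L * W, 2L), ] <- V %% 256L
    scan <- rbind(0L, inter)                 # filter byte 0 per scanline
    ihdr <- c(pngBe32(W), pngBe32(H), as.raw(c(16, 0, 0, 0, 0)))
    idat <- memCompress(as.raw(scan), "gzip")
    out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
             pngChunk("IHDR", ihdr), pngChunk("IDAT", idat),
             pngChunk("IEND", raw(0)))
    writeBin(out, path)
    invisible(path)
}

#' Write a depth stack as 16-bit PNG frames
#'
#' One PNG per frame (\code{frame_0001.png}, ...), values stored in
#' millimetres as 16-bit integers.
#'
#' @param stack H x W x T depth array, mm (0 = void); values must fit in
#'   0..65535.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeDepthStack <- function(stack, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    T <- dim(stack)[3]
    paths <- file.path(dir, sprintf("frame_%04d.png", seq_len(T)))
    for (t in seq_len(T)) {
        v <- roundHalfUp(stack[, , t])
        if (any(v < 0 | v > 65535)) stop("depth out of 16-bit range")
        writePNG16(matrix(as.integer(v), dim(stack)[1]), paths[t])
    }
    invisible(paths)
}

#' Read a 16-bit PNG depth stack
#'
#' @param dir directory of \code{frame_*.png} files written by
#'   \code{\link{writeDepthStack}}.
#' @return H x W x T depth array in mm.
#' @export
readDepthStack <- function(dir) {
    paths <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                             full.names = TRUE))
    if (!length(paths)) stop("no depth frames found in ", dir)
    frames <- lapply(paths, function(p) roundHalfUp(png::readPNG(p) * 65535))
    array(unlist(frames), c(dim(frames[[1]]), length(frames)))
}

#' Write keypoint tracks as JSON
#'
#' Per-frame maps keypoint-name -> [x, y] (pixel coordinates).
#'
#' @param tracks T x 8 x 2 array as in \linkS4class{WalkingSequence}.
#' @param path output .json path.
#' @return Invisibly, \code{path}.
#' @export
writeKeypointTracks <- function(tracks, path) {
    frames <- lapply(seq_len(dim(tracks)[1]), function(t) {
        kp <- lapply(keypointNames(), function(k) unname(tracks[t, k, ]))
        names(kp) <- keypointNames()
        kp
    })
    jsonlite::write_json(frames, path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' Read keypoint tracks from JSON
#'
#' @param path .json file written by \code{\link{writeKeypointTracks}}.
#' @return T x 8 x 2 array with standard dimnames.
#' @export
readKeypointTracks <- function(path) {
    frames <- jsonlite::read_json(path, simplifyVector = FALSE)
    T <- length(frames)
    out <- array(NA_real_, c(T, 8, 2),
                 dimnames = list(NULL, keypointNames(), c("x", "y")))
    for (t in seq_len(T))
        for (k in keypointNames())
            out[t, k, ] <- as.numeric(unlist(frames[[t]][[k]]))
    out
}

#' Write / read a labelled feature table as CSV
#'
#' Columns: sequence_id, label, BC, MAI, VOB, VOH, TI, LSAS.
#'
#' @param features data.frame as from \code{\link{extractFeatureTable}}.
#' @param path .csv path.
#' @return Invisibly \code{path} (write) or the data.frame (read).
#' @export
writeFeatureTable <- function(features, path) {
    utils::write.csv(features, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
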