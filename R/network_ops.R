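# Desk-testable forward passes of the bespoke network modules: adaptive
# sparse self-attention (window DSA/SSA fusion), the feature-refinement
# feedforward network, and adaptive graph convolution over the 8-keypoint
# cow skeleton. No training: parameters are plain matrices supplied by the
# caller (or randomly initialised by the *Params constructors) and the
# functions are pure.

rowSoftmax <- function(S) {
    e <- exp(S - apply(S, 1, max))
    e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)

#' Adaptive sparse self-attention forward pass
#'
#' One attention window of M^2 tokens. Scores are
#' \eqn{S = QK^T/\sqrt{d} + B}. Dense self-attention applies a row softmax
#' to S; sparse self-attention squares the positive part
#' (\eqn{ReLU(S)^2}) and row-normalises (row sum + 1e-6, so an all-negative
#' score row contributes exactly zero). The two attended outputs are fused
#' with softmax weights over two learnable scalars.
#'
#' @param X M^2 x C token matrix (one flattened window).
#' @param Wq,Wk,Wv C x d projection matrices.
#' @param B M^2 x M^2 position bias.
#' @param fusionLogits numeric(2); fusion weights are softmax of these
#'   (default c(0, 0): equal weights).
#' @return list(out, dsa, ssa, weights): fused output (M^2 x d) and the two
#'   branch outputs.
#' @export
assaForward <- function(X, Wq, Wk, Wv, B = NULL, fusionLogits = c(0, 0)) {
    X <- as.matrix(X)
    if (ncol(X) != nrow(Wq) || ncol(X) != nrow(Wk) || ncol(X) != nrow(Wv))
        stop("projection dimensions do not match token channels")
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    d <- ncol(Q)
    S <- Q %*% t(K) / sqrt(d)
    if (!is.null(B)) {
        if (!identical(dim(B), dim(S))) stop("position bias has wrong shape")
        S <- S + B
    }
    dsaAtt <- rowSoftmax(S)
    relu2 <- pmax(S, 0)^2
    ssaAtt <- relu2 / (rowSums(relu2) + 1e-6)
    w <- exp(fusionLogits - max(fusionLogits))
    w <- w / sum(w)
    dsa <- dsaAtt %*% V
    ssa <- ssaAtt %*% V
    list(out = w[1] * dsa + w[2] * ssa, dsa = dsa, ssa = ssa, weights = w)
}

#' Random parameters for the feature-refinement feedforward network
#'
#' @param C channel count of the input feature map (even).
#' @param seed integer seed.
#' @return Parameter list for \code{\link{frfnForward}}: a 3x3 partial
#'   convolution kernel acting on the first ceiling(C/4) channels, the
#'   expansion map W1 (C -> 2C), a 3x3 depthwise kernel per split channel
#'   and the reduction map W2 (C -> C). Biases are zero.
#' @export
frfnParams <- function(C, seed = 1L) {
    if (C %% 2L != 0L) stop("channel count must be even")
    withSeed(seed, {
        cp <- ceiling(C / 4)
        list(C = C,
             pconvKernel = array(stats::rnorm(3 * 3 * cp, sd = 0.2),
                                 c(3, 3, cp)),
             W1 = matrix(stats::rnorm(C * 2 * C, sd = 0.2), C, 2 * C),
             dwKernel = array(stats::rnorm(3 * 3 * C, sd = 0.2), c(3, 3, C)),
             W2 = matrix(stats::rnorm(C * C, sd = 0.2), C, C))
    })
}

# 3x3 single-channel convolution with zero padding (correlation form).
conv3x3 <- function(m, k) {
    out <- matrix(0, nrow(m), ncol(m))
    for (dy in -1:1) for (dx in -1:1) {
        s <- shiftMat(m, dy, dx)
        s[is.na(s)] <- 0
        out <- out + k[dy + 2, dx + 2] * s
    }
    out
}

#' Feature-refinement feedforward network forward pass
#'
#' Enhancement-simplification chain: partial convolution (3x3 on the first
#' quarter of the channels, identity elsewhere), linear expansion W1
#' followed by GELU, split into two channel halves, depthwise 3x3
#' convolution of the second half reshaped to its 2-D spatial layout,
#' elementwise (channelwise) gating of the first half by the result, then
#' linear reduction W2 with GELU. Spatial shape is preserved; zero input
#' with zero biases maps to zero.
#'
#' @param X H x W x C numeric array.
#' @param params parameter list from \code{\link{frfnParams}}.
#' @return H x W x C array.
#' @export
frfnForward <- function(X, params) {
    dm <- dim(X)
    H <- dm[1]; W <- dm[2]; C <- dm[3]
    if (C != params$C) stop("channel count does not match parameters")
    # partial convolution: first ceiling(C/4) channels convolved
    cp <- dim(params$pconvKernel)[3]
    Xp <- X
    for (c in seq_len(cp))
        Xp[, , c] <- conv3x3(X[, , c], params$pconvKernel[, , c])
    # tokens (H*W) x C -> expand -> GELU
    tok <- matrix(Xp, H * W, C)
    Xhat <- gelu(tok %*% params$W1)                  # (H*W) x 2C
    if (ncol(Xhat) %% 2L != 0L) stop("odd channel count at split")
    X1 <- Xhat[, seq_len(C), drop = FALSE]
    X2 <- Xhat[, C + seq_len(C), drop = FALSE]
    # reshape second half to 2-D, depthwise convolve, flatten, gate
    gate <- matrix(0, H * W, C)
    for (c in seq_len(C))
        gate[, c] <- as.vector(conv3x3(matrix(X2[, c], H, W),
                                       params$dwKernel[, , c]))
    Xr <- X1 * gate
    out <- gelu(Xr %*% params$W2)                    # (H*W) x C
    array(out, c(H, W, C))
}

#' Symmetric normalization of a binary adjacency matrix
#'
#' \eqn{A = \Lambda^{-1/2} \bar A \Lambda^{-1/2}} with \eqn{\Lambda} the
#' degree diagonal of \eqn{\bar A} (a small epsilon guards isolated
#' nodes). Symmetric input gives symmetric output with spectral radius at
#' most 1.
#'
#' @param Abar binary N x N adjacency matrix.
#' @param eps guard added to zero degrees.
#' @return Normalized N x N matrix.
#' @export
#' @examples
#' normalizeAdjacency(rbind(c(0, 1), c(1, 0)))
normalizeAdjacency <- function(Abar, eps = 1e-6) {
    if (!all(Abar %in% c(0, 1))) stop("adjacency must be binary")
    deg <- rowSums(Abar)
    dinv <- 1 / sqrt(pmax(deg, eps))
    Abar * outer(dinv, dinv)
}

#' Data-driven graph from embedded Gaussian similarity
#'
#' Embeds the per-node feature vectors (channels x time) with two 1x1
#' maps theta and phi and forms the N x N similarity
#' \eqn{S_{ij} = \sum_{e,t} \theta(v_i)_{et}\,\phi(v_j)_{et}}, normalised
#' by a row softmax so every row sums to 1. Identical node features give
#' the uniform graph (all entries 1/N).
#'
#' @param X Cin x T x N array (channels x time x keypoints).
#' @param Wtheta,Wphi Ce x Cin embedding matrices.
#' @return N x N row-stochastic matrix.
#' @export
dataDrivenGraph <- function(X, Wtheta, Wphi) {
    dm <- dim(X)
    if (ncol(Wtheta) != dm[1] || ncol(Wphi) != dm[1])
        stop("embedding maps must have Cin columns")
    N <- dm[3]
    # theta/phi: Ce x T x N; similarity contracts channels and time
    flat <- matrix(X, dm[1], dm[2] * dm[3])
    th <- array(Wtheta %*% flat, c(nrow(Wtheta), dm[2], N))
    ph <- array(Wphi %*% flat, c(nrow(Wphi), dm[2], N))
    thm <- matrix(th, ncol = N); phm <- matrix(ph, ncol = N)
    rowSoftmax(t(thm) %*% phm)
}

#' Skeleton adjacency subsets for the 8-keypoint cow graph
#'
#' Builds the cow back skeleton (spine chain poll--withers--lumbar--sacral
#' tuber; scapulae attached to the withers; tuber coxae attached to the
#' sacral tuber) and partitions neighbourhoods into the three spatial
#' subsets of the root/centripetal/centrifugal convention around the
#' skeleton centre (the lumbar region): subset 1 holds self-connections,
#' subset 2 neighbours closer to the centre, subset 3 neighbours farther
#' from it.
#'
#' @return list of three binary 8 x 8 matrices named root, centripetal,
#'   centrifugal, with dimnames \code{keypointNames()}.
#' @export
cowSkeletonAdjacency <- function() {
    kp <- keypointNames()
    edges <- rbind(c("poll", "withers"), c("withers", "lumbar"),
                   c("lumbar", "sacral_tuber"),
                   c("left_scapula", "withers"), c("right_scapula", "withers"),
                   c("left_tuber_coxae", "sacral_tuber"),
                   c("right_tuber_coxae", "sacral_tuber"))
    # hop distance to the centre node (lumbar)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    dist <- igraph::distances(g, v = kp, to = "lumbar")[, 1]
    mk <- function() matrix(0, 8, 8, dimnames = list(kp, kp))
    root <- mk(); centripetal <- mk(); centrifugal <- mk()
    diag(root) <- 1
    for (i in seq_len(nrow(edges))) {
        a <- edges[i, 1]; b <- edges[i, 2]
        # from a's viewpoint, b is centripetal if closer to the centre
        if (dist[b] < dist[a]) centripetal[a, b] <- 1 else centrifugal[a, b] <- 1
        if (dist[a] < dist[b]) centripetal[b, a] <- 1 else centrifugal[b, a] <- 1
    }
    list(root = root, centripetal = centripetal, centrifugal = centrifugal)
}

#' Parameters for the adaptive graph convolution
#'
#' @param Cin,Cout channel counts.
#' @param N node count (8 for the cow skeleton).
#' @param Abar list of Kv binary adjacency matrices (default the cow
#'   skeleton subsets, Kv = 3).
#' @param Ce embedding dimension of the data-driven graph; 0 disables the
#'   data-driven term (Ck = 0).
#' @param seed integer seed for the random weights.
#' @return Parameter list: per-subset 1x1 convolution weights Wk
#'   (Cout x Cin), normalized adjacencies Ak, learnable offsets Bk
#'   (initialised to zero), optional embeddings, and the residual map
#'   (identity when Cin = Cout, else a 1x1 channel-aligning matrix).
#' @export
agcParams <- function(Cin, Cout, N = 8, Abar = NULL, Ce = 0, seed = 1L) {
    if (is.null(Abar)) {
        if (N != 8L) stop("default skeleton subsets require N = 8")
        Abar <- cowSkeletonAdjacency()
    }
    Kv <- length(Abar)
    withSeed(seed, {
        Wk <- lapply(seq_len(Kv), function(k)
            matrix(stats::rnorm(Cout * Cin, sd = 1 / sqrt(Cin)), Cout, Cin))
        emb <- if (Ce > 0) lapply(seq_len(Kv), function(k) list(
            Wtheta = matrix(stats::rnorm(Ce * Cin, sd = 0.2), Ce, Cin),
            Wphi = matrix(stats::rnorm(Ce * Cin, sd = 0.2), Ce, Cin)))
            else NULL
        Wres <- if (Cin == Cout) NULL else
            matrix(stats::rnorm(Cout * Cin, sd = 1 / sqrt(Cin)), Cout, Cin)
    })
    list(Kv = Kv, Cin = Cin, Cout = Cout,
         Ak = lapply(Abar, normalizeAdjacency),
         Bk = replicate(Kv, matrix(0, N, N), simplify = FALSE),
         Wk = Wk, embeddings = emb, Wres = Wres)
}

#' Adaptive graph convolution forward pass
#'
#' \eqn{Y' = \sum_{k=1}^{K_v} W_k X (A_k + B_k + C_k)} over the node
#' dimension, followed by the residual connection
#' \eqn{Y = Y' + R(X)} (identity when Cin = Cout, else a 1x1
#' channel-aligning map). \eqn{A_k} is the normalized predefined
#' adjacency, \eqn{B_k} a learnable offset (zero at initialisation) and
#' \eqn{C_k} the data-driven graph (zero when no embeddings are
#' configured).
#'
#' @param X Cin x T x N array.
#' @param params from \code{\link{agcParams}}.
#' @return Cout x T x N array.
#' @export
agcForward <- function(X, params) {
    dm <- dim(X)
    if (dm[1] != params$Cin) stop("input channels do not match params")
    N <- dm[3]; T <- dm[2]
    if (length(params$Ak) != params$Kv) stop("Kv mismatch with params")
    flat <- matrix(X, dm[1], T * N)
    Yp <- matrix(0, params$Cout, T * N)
    for (k in seq_len(params$Kv)) {
        G <- params$Ak[[k]] + params$Bk[[k]]
        if (!is.null(params$embeddings))
            G <- G + dataDrivenGraph(X, params$embeddings[[k]]$Wtheta,
                                     params$embeddings[[k]]$Wphi)
        # X (C x T x N) times G on the node dimension
        XG <- array(0, dm)
        for (t in seq_len(T))
            XG[, t, ] <- matrix(X[, t, ], dm[1], N) %*% G
        Yp <- Yp + params$Wk[[k]] %*% matrix(XG, dm[1], T * N)
    }
    res <- if (is.null(params$Wres)) flat else params$Wres %*% flat
    array(Yp + res, c(params$Cout, T, N))
}
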