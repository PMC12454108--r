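# Forward passes of the attention, feedforward and graph-convolution
# modules against straight-line scripted oracles.

test_that("attention rows are stochastic and the sparse branch kills negative scores", {
    withr::with_seed(91, {
        X <- matrix(rnorm(9 * 6), 9, 6)
        Wq <- matrix(rnorm(6 * 3), 6, 3)
        Wk <- matrix(rnorm(6 * 3), 6, 3)
        Wv <- matrix(rnorm(6 * 3), 6, 3)
        B <- matrix(rnorm(81, sd = 0.1), 9, 9)
    })
    att <- assaForward(X, Wq, Wk, Wv, B)
    # straight-line oracle of the printed equations
    S <- (X %*% Wq) %*% t(X %*% Wk) / sqrt(3) + B
    dsaA <- exp(S - apply(S, 1, max)); dsaA <- dsaA / rowSums(dsaA)
    expect_equal(unname(rowSums(dsaA)), rep(1, 9), tolerance = 1e-6)
    r2 <- pmax(S, 0)^2
    ssaA <- r2 / (rowSums(r2) + 1e-6)
    expect_equal(att$dsa, dsaA %*% (X %*% Wv), tolerance = 1e-9)
    expect_equal(att$ssa, ssaA %*% (X %*% Wv), tolerance = 1e-9)
    expect_equal(att$out, 0.5 * att$dsa + 0.5 * att$ssa)
    expect_equal(sum(att$weights), 1)
    # all-negative scores: SSA contribution exactly zero
    attNeg <- assaForward(X, Wq, Wk, Wv, B = matrix(-100, 9, 9) - abs(S))
    expect_true(all(attNeg$ssa == 0))
    # single token, nonnegative score: output equals the projected V row
    x1 <- X[1, , drop = FALSE]
    att1 <- assaForward(x1, Wq, Wk, Wv,
                        B = matrix(10 + abs(sum((x1 %*% Wq) * (x1 %*% Wk))), 1, 1))
    expect_equal(att1$out, x1 %*% Wv, tolerance = 1e-6)
    expect_error(assaForward(X, Wq[1:3, ], Wk, Wv), "dimensions")
})

test_that("the feedforward refinement matches its scripted oracle and contracts", {
    prm <- frfnParams(4, seed = 17)
    withr::with_seed(19, X <- array(rnorm(6 * 5 * 4), c(6, 5, 4)))
    Y <- frfnForward(X, prm)
    expect_equal(dim(Y), dim(X))                     # spatial shape preserved
    expect_equal(frfnForward(array(0, dim(X)), prm), array(0, dim(X)))
    # independent step-by-step evaluation
    gelu <- function(x) x * pnorm(x)
    conv3 <- function(m, k) {
        out <- matrix(0, nrow(m), ncol(m))
        for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
            acc <- 0
            for (dy in -1:1) for (dx in -1:1) {
                y <- i + dy; x <- j + dx
                if (y >= 1 && y <= nrow(m) && x >= 1 && x <= ncol(m))
                    acc <- acc + k[dy + 2, dx + 2] * m[y, x]
            }
            out[i, j] <- acc
        }
        out
    }
    Xp <- X
    Xp[, , 1] <- conv3(X[, , 1], prm$pconvKernel[, , 1])
    tok <- matrix(Xp, 30, 4)
    Xhat <- gelu(tok %*% prm$W1)
    X1 <- Xhat[, 1:4]; X2 <- Xhat[, 5:8]
    gate <- sapply(1:4, function(c)
        as.vector(conv3(matrix(X2[, c], 6, 5), prm$dwKernel[, , c])))
    ref <- array(gelu((X1 * gate) %*% prm$W2), c(6, 5, 4))
    expect_equal(Y, ref, tolerance = 1e-6)
    expect_error(frfnParams(5), "even")
})

test_that("adjacency normalization matches hand values and bounds the spectrum", {
    expect_equal(normalizeAdjacency(rbind(c(0, 1), c(1, 0))),
                 rbind(c(0, 1), c(1, 0)))
    path <- matrix(0, 3, 3)
    path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
    An <- normalizeAdjacency(path)
    expect_equal(An[1, 2], 1 / sqrt(2))
    expect_equal(An[2, 3], 1 / sqrt(2))
    expect_error(normalizeAdjacency(matrix(2, 2, 2)), "binary")
    withr::with_seed(23, {
        for (i in 1:5) {
            A <- matrix(rbinom(36, 1, 0.4), 6, 6)
            A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
            ev <- eigen(normalizeAdjacency(A), only.values = TRUE)$values
            expect_lte(max(abs(ev)), 1 + 1e-9)
        }
    })
})

test_that("the data-driven graph is row-stochastic and uniform for identical nodes", {
    withr::with_seed(29, {
        X <- array(rnorm(3 * 4 * 8), c(3, 4, 8))
        Wt <- matrix(rnorm(2 * 3), 2, 3)
        Wp <- matrix(rnorm(2 * 3), 2, 3)
    })
    Ck <- dataDrivenGraph(X, Wt, Wp)
    expect_equal(unname(rowSums(Ck)), rep(1, 8), tolerance = 1e-6)
    # explicit elementwise oracle
    S <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8)
        S[i, j] <- sum((Wt %*% X[, , i]) * (Wp %*% X[, , j]))
    ref <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    expect_equal(Ck, ref, tolerance = 1e-6)
    # identical features across nodes -> uniform 1/N
    Xc <- array(rep(rnorm(3 * 4), 8), c(3, 4, 8))
    expect_equal(dataDrivenGraph(Xc, Wt, Wp), matrix(1 / 8, 8, 8))
})

test_that("graph convolution matches a hand-multiplied 2-node example and is linear", {
    # N = 2, T = 1, Cin = Cout = 1: Y = w * x %*% G + x
    prm <- list(Kv = 1L, Cin = 1L, Cout = 1L,
                Ak = list(rbind(c(0, 1), c(1, 0))),
                Bk = list(matrix(c(0.5, 0, 0, -0.25), 2, 2)),
                Wk = list(matrix(2)), embeddings = NULL, Wres = NULL)
    X <- array(c(3, 5), c(1, 1, 2))
    G <- prm$Ak[[1]] + prm$Bk[[1]]
    ref <- 2 * matrix(c(3, 5), 1, 2) %*% G + c(3, 5)
    expect_equal(as.vector(agcForward(X, prm)), as.vector(ref))

    # pure residual: all graph terms zero
    prm0 <- agcParams(4, 4, Ce = 0, seed = 3)
    prm0$Ak <- replicate(3, matrix(0, 8, 8), simplify = FALSE)
    withr::with_seed(31, Xg <- array(rnorm(4 * 5 * 8), c(4, 5, 8)))
    expect_equal(agcForward(Xg, prm0), Xg)

    # linearity in X for frozen graphs (no data-driven term)
    prm1 <- agcParams(4, 6, Ce = 0, seed = 5)
    withr::with_seed(37, {
        X1 <- array(rnorm(4 * 5 * 8), c(4, 5, 8))
        X2 <- array(rnorm(4 * 5 * 8), c(4, 5, 8))
    })
    lhs <- agcForward(2 * X1 - 3 * X2, prm1)
    rhs <- 2 * agcForward(X1, prm1) - 3 * agcForward(X2, prm1)
    # residual is linear too, so the whole map is linear
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_equal(dim(agcForward(X1, prm1)), c(6L, 5L, 8L))
    expect_error(agcForward(array(0, c(3, 5, 8)), prm1), "channels")
})

test_that("the cow skeleton subsets partition the edge set around the lumbar centre", {
    ad <- cowSkeletonAdjacency()
    expect_named(ad, c("root", "centripetal", "centrifugal"))
    expect_equal(unname(diag(ad$root)), rep(1, 8))
    # every skeleton edge appears once in each direction across the subsets
    un <- ad$centripetal + ad$centrifugal
    expect_true(all(un %in% c(0, 1)))
    expect_equal(sum(un), 14)                        # 7 undirected edges
    # withers -> lumbar is centripetal; lumbar -> withers centrifugal
    expect_equal(ad$centripetal["withers", "lumbar"], 1)
    expect_equal(ad$centrifugal["lumbar", "withers"], 1)
    expect_true(all(networkSelfCheck(4)))
})
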