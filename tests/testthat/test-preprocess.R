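# Depth preprocessing: clipping, void-aware denoising, hole filling,
# void-rate screening, foreground extraction and grayscale conversion.

test_that("clipping marks out-of-range pixels void and keeps boundaries", {
    fr <- matrix(c(1000, 1200, 2600, 3000), 2)
    expect_equal(clipDepth(fr), matrix(c(0, 1200, 2600, 0), 2))
    const <- matrix(2000, 8, 8)
    expect_identical(clipDepth(const), const)
    expect_error(clipDepth(fr, 2600, 1200), "clipMin")
    # elementwise oracle on a random frame
    set.seed(11)
    fr <- matrix(runif(400, 800, 3000), 20)
    expect_equal(sum(clipDepth(fr) == 0), sum(fr < 1200 | fr > 2600))
})

test_that("denoising preserves constants, removes impulses, matches a brute-force masked oracle", {
    const <- matrix(1800, 16, 16)
    expect_equal(denoiseDepth(const), const, tolerance = 1e-9)
    # single impulse amid constant background dies in the median stage
    imp <- matrix(1800, 16, 16); imp[8, 8] <- 2400
    expect_equal(denoiseDepth(imp)[8, 8], 1800, tolerance = 1e-6)

    # independent direct implementation (double loop, voids excluded)
    bruteDenoise <- function(fr, ss = 5, sr = 0.1, lo = 1200, hi = 2600) {
        H <- nrow(fr); W <- ncol(fr); r <- ceiling(2 * ss)
        nrm <- (fr - lo) / (hi - lo)
        bil <- fr
        for (i in seq_len(H)) for (j in seq_len(W)) {
            if (fr[i, j] == 0) next
            num <- den <- 0
            for (di in -r:r) for (dj in -r:r) {
                y <- i + di; x <- j + dj
                if (y < 1 || y > H || x < 1 || x > W || fr[y, x] == 0) next
                w <- exp(-(di^2 + dj^2) / (2 * ss^2)) *
                     exp(-(nrm[y, x] - nrm[i, j])^2 / (2 * sr^2))
                num <- num + w * fr[y, x]; den <- den + w
            }
            bil[i, j] <- num / den
        }
        med <- bil
        for (i in seq_len(H)) for (j in seq_len(W)) {
            if (bil[i, j] == 0) next
            y <- max(1, i - 1):min(H, i + 1)
            x <- max(1, j - 1):min(W, j + 1)
            v <- bil[y, x]; v <- v[v > 0]
            med[i, j] <- median(v)
        }
        med
    }
    set.seed(7)
    fr <- matrix(runif(24 * 24, 1300, 2500), 24)
    fr[sample(576, 40)] <- 0
    expect_lt(max(abs(denoiseDepth(fr) - bruteDenoise(fr))), 1)
})

test_that("hole filling uses the nearest valid pixel with a lexicographic tie-break", {
    fr <- matrix(1500, 9, 9)
    expect_identical(fillHolesNearest(fr), fr)      # identity without voids
    fr[5, 5] <- 0
    expect_equal(fillHolesNearest(fr)[5, 5], 1500)
    expect_error(fillHolesNearest(matrix(0, 4, 4)), "all-void")

    bruteFill <- function(fr) {
        H <- nrow(fr); W <- ncol(fr)
        valid <- which(fr > 0, arr.ind = TRUE)
        out <- fr
        for (idx in which(fr == 0)) {
            r <- ((idx - 1) %% H) + 1; c <- ((idx - 1) %/% H) + 1
            d2 <- (valid[, 1] - r)^2 + (valid[, 2] - c)^2
            cand <- valid[d2 == min(d2), , drop = FALSE]
            cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
            out[idx] <- fr[cand[1, 1], cand[1, 2]]
        }
        out
    }
    for (rep in 1:5) {
        set.seed(rep)
        fr <- matrix(sample(1300:2500, 15 * 12, TRUE), 15, 12)
        fr[sample(180, 60)] <- 0
        got <- fillHolesNearest(fr)
        expect_identical(got, bruteFill(fr))
        expect_true(all(got > 0))                  # no voids remain
        expect_true(all(got %in% fr[fr > 0]))      # values come from input
    }
})

test_that("void rate counts exactly and the 10% screening boundary is inclusive", {
    fr <- matrix(1800, 10, 10)
    mask <- matrix(TRUE, 10, 10)
    expect_equal(voidRate(fr, mask), 0)
    fr[sample(100, 10)] <- 0
    expect_equal(voidRate(fr, mask), 0.10)
    stack <- array(fr, c(10, 10, 3))
    expect_false(screenByVoidRate(stack, mask)$keep)   # 0.10 rejects
    fr2 <- matrix(1800, 10, 10); fr2[1] <- 0
    expect_true(screenByVoidRate(array(fr2, c(10, 10, 3)), mask)$keep)
    expect_error(voidRate(fr, matrix(FALSE, 10, 10)), "empty")
    set.seed(3)
    fr3 <- matrix(sample(c(0, 1800), 100, TRUE, c(0.3, 0.7)), 10)
    fr3[1, 1] <- 1800
    expect_equal(voidRate(fr3, mask), sum(fr3 == 0) / 100)
})

test_that("foreground mask keeps the largest component of above-floor pixels", {
    fr <- matrix(2500, 30, 30)
    fr[10:20, 10:20] <- 1800
    expect_identical(foregroundMask(fr), fr < 2200)
    expect_error(foregroundMask(matrix(2500, 10, 10)), "no animal")
    fr[25:26, 25:26] <- 1800                     # much smaller second blob
    fg <- foregroundMask(fr)
    expect_true(all(fg[10:20, 10:20]))
    expect_false(any(fg[25:26, 25:26]))
    expect_equal(sum(fg), 121)
})

test_that("grayscale conversion is a linear half-up rounded map", {
    expect_equal(depthToGray(matrix(1200))[1], 0L)
    expect_equal(depthToGray(matrix(2600))[1], 255L)
    expect_equal(depthToGray(matrix(1900))[1], 128L)  # 127.5 rounds up
    set.seed(5)
    d <- sort(runif(100, 1200, 2600))
    g <- depthToGray(matrix(d, 1))
    expect_true(all(diff(as.vector(g)) >= 0))         # monotone
})

test_that("the full chain leaves no voids and is idempotent in the fill stage", {
    set.seed(9)
    stack <- array(runif(20 * 20 * 3, 1300, 2500), c(20, 20, 3))
    stack[sample(length(stack), 60)] <- 0
    pp <- preprocessDepthStack(stack)
    expect_true(all(pp > 0))
    expect_true(all(pp >= 1200 & pp <= 2600))
    one <- pp[, , 1]
    expect_identical(fillHolesNearest(one), one)
})
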