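# PIMP-corrected feature screening: importance ranking, permutation
# p-values, BH retention, and reproducibility.

test_that("Gini importance normalises, ranks true signal first, and is seeded", {
    # one perfectly separating feature among pure noise
    withr::with_seed(101, {
        y <- rep(lamenessClasses(), each = 100)
        X <- as.data.frame(matrix(rnorm(300 * 6), 300, 6))
        names(X) <- featureNames()
        X$BC <- match(y, lamenessClasses()) + rnorm(300, sd = 0.01)
    })
    imp <- giniImportance(X, y, nTrees = 100, seed = 5)
    expect_equal(sum(imp), 1)
    expect_equal(names(which.max(imp)), "BC")
    expect_identical(imp, giniImportance(X, y, nTrees = 100, seed = 5))
    expect_error(giniImportance(X, rep("sound", 300)), "two classes")
    # d = 1 -> importance 1 by normalization
    expect_equal(unname(giniImportance(X["BC"], y, nTrees = 50, seed = 1)), 1)
})

test_that("independent forest implementation agrees on the importance ranking", {
    withr::with_seed(77, {
        y <- factor(rep(lamenessClasses(), each = 60))
        X <- as.data.frame(matrix(rnorm(180 * 4), 180, 4))
        names(X) <- c("strong", "n1", "n2", "n3")
        X$strong <- as.numeric(y) + rnorm(180, sd = 0.3)
    })
    imp <- giniImportance(X, y, nTrees = 200, seed = 3)
    rf <- randomForest::randomForest(X, y, ntree = 200)
    ref <- rf$importance[, "MeanDecreaseGini"]
    expect_equal(names(which.max(imp)), names(which.max(ref)))
    # the planted signal dominates every noise feature under both engines
    expect_true(all(imp["strong"] > imp[c("n1", "n2", "n3")]))
    expect_true(all(ref["strong"] > ref[c("n1", "n2", "n3")]))
})

test_that("permutation p-values are exact at the boundaries", {
    expect_equal(pimpPvalue(0.9, rep(0.1, 50)), 1 / 51)
    expect_equal(pimpPvalue(0.01, seq(0.1, 0.5, length.out = 50)), 1)
    expect_equal(pimpPvalue(0.2, rep(0.2, 50)), 1)   # ties count as >=
    # monotonicity: larger observed importance never raises p
    null <- runif(50)
    p <- vapply(seq(0, 1, 0.05), pimpPvalue, numeric(1), null = null)
    expect_true(all(diff(p) <= 0))
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
    p <- c(0.005, 0.01, 0.02, 0.3, 0.5, 0.9)
    adj <- bhAdjust(p, alpha = 0.05)
    expect_identical(adj$retained, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_equal(adj$pAdj[1:3], c(0.03, 0.03, 0.04))
    expect_false(any(bhAdjust(rep(1, 6))$retained))
    expect_equal(bhAdjust(0.03)$pAdj, 0.03)          # d = 1: unchanged
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("the null matrix is reproducible and B is validated", {
    X <- pureNoiseTable(60, seed = 7)
    null1 <- pimpNull(X[featureNames()], X$label, B = 3, nTrees = 30, seed = 9)
    null2 <- pimpNull(X[featureNames()], X$label, B = 3, nTrees = 30, seed = 9)
    expect_identical(null1, null2)
    expect_equal(dim(null1), c(3L, 6L))
    expect_error(pimpNull(X[featureNames()], X$label, B = 0), "at least 1")
})

test_that("screening composes the stages and retains a perfectly separating feature", {
    # a perfectly separating feature beside one noise feature: the signal
    # feature sits above every permutation null, the noise feature does not
    withr::with_seed(55, {
        y <- rep(lamenessClasses(), each = 40)
        X <- data.frame(BC = match(y, lamenessClasses()) + rnorm(120, sd = 0.05),
                        LSAS = rnorm(120))
    })
    res <- screenFeatures(X, y, B = 50, nTrees = 50, seed = 2)
    tab <- screeningTable(res)
    expect_equal(tab$p_raw[tab$feature == "BC"], 1 / 51)
    expect_identical(retainedFeatures(res), "BC")
    expect_gt(tab$gini[tab$feature == "BC"], tab$gini[tab$feature == "LSAS"])
    expect_s4_class(res, "ScreeningResult")
    # full result is a pure function of (X, y, B, alpha, seed)
    res2 <- screenFeatures(X, y, B = 50, nTrees = 50, seed = 2)
    expect_identical(screeningTable(res), screeningTable(res2))
})

test_that("strong features are retained and nulls dropped in the mixed-signal table", {
    X <- mixedSignalTable(400, seed = 1234)
    res <- screenFeatures(X[featureNames()], X$label, B = 50, nTrees = 50,
                          seed = 99)
    tab <- screeningTable(res)
    strong <- tab$retained[match(c("BC", "MAI", "VOB"), tab$feature)]
    nulls <- tab$retained[match(c("TI", "LSAS"), tab$feature)]
    expect_true(all(strong))
    expect_false(any(nulls))
    # Kruskal-Wallis context column: strong features highly significant
    expect_true(all(tab$p_kw[match(c("BC", "MAI", "VOB"), tab$feature)] < 1e-6))
})
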