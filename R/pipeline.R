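# End-to-end demonstration pipeline: simulate -> preprocess -> extract ->
# screen -> classify, driven by one declarative configuration and one
# master seed (stage seeds are derived substreams, so each stage is
# independently reproducible).

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one list. Values with a
#' published counterpart keep it (clip range 1200--2600 mm, bilateral
#' spatial sigma 5 px / range sigma 0.1, median window 3, void-rate
#' threshold 0.10, B = 50 permutations, FDR alpha 0.05, 8:2 split); the
#' rest are the package's documented defaults.
#'
#' @return Named list of configuration values.
#' @export
defaultConfig <- function() {
    list(
        # simulation
        nPerClass = c(sound = 20, mild = 20, severe = 20),
        targetCv = 0.15, nFrames = 60L, withFrames = FALSE,
        # preprocessing
        clipMin = 1200, clipMax = 2600, bilateralS = 5, bilateralR = 0.1,
        medianWin = 3, voidThreshold = 0.10,
        floorDepthMm = 2500, minHeightMm = 300, denoise = TRUE,
        # flow
        flow = list(pyrScale = 0.5, levels = 3, winsize = 15, iterations = 3,
                    polyN = 7, polySigma = 1.5),
        # screening
        B = 50, alpha = 0.05, nTrees = 500,
        # classification
        algos = c("RF", "KNN", "SVM"), trainFrac = 0.8,
        subsets = NULL)  # NULL -> fusionSubsets()
}

validateConfig <- function(config) {
    def <- defaultConfig()
    unknown <- setdiff(names(config), names(def))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    config <- utils::modifyList(def, config)
    if (!is.null(config$subsets)) {
        bad <- setdiff(unlist(config$subsets), featureNames())
        if (length(bad))
            stop("invalid feature name in subsets: ",
                 paste(bad, collapse = ", "))
    }
    if (config$clipMin >= config$clipMax) stop("clipMin must be < clipMax")
    config
}

#' Write / read a run configuration as JSON
#'
#' The configuration (defaults merged in, see \code{\link{defaultConfig}})
#' round-trips through the file: reading gives back an equivalent validated
#' configuration.
#'
#' @param config configuration list.
#' @param path .json file path.
#' @return \code{writeRunConfig}: invisibly \code{path};
#'   \code{readRunConfig}: the validated configuration list.
#' @export
writeRunConfig <- function(config, path) {
    config <- validateConfig(config)
    config$nPerClass <- as.list(config$nPerClass)   # keep class names
    jsonlite::write_json(config[!vapply(config, is.null, logical(1))], path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    raw$nPerClass <- unlist(raw$nPerClass)
    raw$nFrames <- as.integer(raw$nFrames)
    if (!is.null(raw$subsets)) raw$subsets <- lapply(raw$subsets, unlist)
    raw$flow <- as.list(raw$flow)
    validateConfig(raw)
}

#' Run the full pipeline end to end on synthetic data
#'
#' Simulates a labelled cohort, preprocesses the depth stacks, extracts the
#' six-feature table, screens features by PIMP-corrected importance, and
#' runs the fusion classification grid on the retained features. All
#' outputs are a pure function of (config, seed). When \code{outDir} is
#' given, the feature table (CSV), screening report (JSON + CSV) and
#' classification grid (CSV) are written there along with a run log.
#'
#' @param config configuration list; missing entries take
#'   \code{\link{defaultConfig}} values. Invalid entries fail before any
#'   computation.
#' @param seed master seed.
#' @param outDir optional output directory.
#' @return list(features, screening, grid, config, seed).
#' @export
runDemo <- function(config = list(), seed = 1L, outDir = NULL) {
    config <- validateConfig(config)
    seeds <- deriveSeeds(seed, 3L)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    seqs <- stage("simulate",
        simulateCohort(config$nPerClass, targetCv = config$targetCv,
                       nFrames = config$nFrames, seed = seeds[1],
                       withFrames = config$withFrames))
    seqs <- stage("preprocess", lapply(seqs, function(sq) {
        pp <- preprocessDepthStack(depthStack(sq), config$clipMin,
                                   config$clipMax, config$bilateralS,
                                   config$bilateralR, config$medianWin,
                                   denoise = config$denoise)
        initialize(sq, depth = pp)
    }))
    features <- stage("extract",
        extractFeatureTable(seqs, withMAI = config$withFrames,
                            floorDepthMm = config$floorDepthMm,
                            minHeightMm = config$minHeightMm))
    featCols <- featureNames()[!vapply(featureNames(), function(f)
        anyNA(features[[f]]), logical(1))]
    screening <- stage("screen",
        screenFeatures(features[featCols], features$label, B = config$B,
                       alpha = config$alpha, nTrees = config$nTrees,
                       seed = seeds[2]))
    keep <- retainedFeatures(screening)
    if (!length(keep)) keep <- featCols  # degenerate run: keep everything
    subsets <- config$subsets
    if (is.null(subsets)) {
        subsets <- lapply(fusionSubsets(), intersect, featCols)
        subsets <- subsets[lengths(subsets) > 0 & !duplicated(subsets)]
        names(subsets) <- ifelse(lengths(subsets) == length(featCols), "All",
                                 vapply(subsets, paste, "", collapse = "+"))
        subsets <- subsets[!duplicated(names(subsets))]
        subsets$Retained <- keep
    }
    grid <- stage("classify",
        runFusionGrid(features, subsets = subsets, algos = config$algos,
                      trainFrac = config$trainFrac, seed = seeds[3]))
    out <- list(features = features, screening = screening, grid = grid,
                config = config, seed = seed)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeFeatureTable(features, file.path(outDir, "features.csv"))
        tab <- screeningTable(screening)
        utils::write.csv(tab, file.path(outDir, "screening.csv"),
                         row.names = FALSE)
        jsonlite::write_json(tab, file.path(outDir, "screening.json"),
                             digits = NA)
        utils::write.csv(attr(grid, "summary"),
                         file.path(outDir, "classification_grid.csv"),
                         row.names = FALSE)
        log <- c(paste("bovigait", as.character(utils::packageVersion("bovigait"))),
                 paste("seed:", seed),
                 paste("stage seeds:", paste(seeds, collapse = " ")),
                 paste("config:", jsonlite::toJSON(config[
                     vapply(config, function(x) !is.null(x), logical(1))],
                     auto_unbox = TRUE)))
        writeLines(log, file.path(outDir, "run_log.txt"))
    }
    out
}

#' Quick self-check of the network forward passes
#'
#' Runs the row-stochasticity, sparsity, normalization and residual
#' identities of the attention and graph-convolution modules on random
#' tensors and reports pass/fail per property.
#'
#' @param seed integer seed.
#' @return Named logical vector (all TRUE on a healthy installation).
#' @export
networkSelfCheck <- function(seed = 1L) {
    res <- withSeed(seed, {
        X <- matrix(stats::rnorm(16 * 8), 16, 8)
        Wq <- matrix(stats::rnorm(8 * 4), 8, 4)
        Wk <- matrix(stats::rnorm(8 * 4), 8, 4)
        Wv <- matrix(stats::rnorm(8 * 4), 8, 4)
        att <- assaForward(X, Wq, Wk, Wv)
        Q <- X %*% Wq; K <- X %*% Wk
        S <- Q %*% t(K) / 2
        dsaRows <- max(abs(rowSums(rowSoftmax(S)) - 1)) < 1e-6
        attNeg <- assaForward(X, Wq, Wk, Wv,
                              B = matrix(-1e6, 16, 16))
        ssaZero <- max(abs(attNeg$ssa)) == 0
        path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
        path[2, 3] <- path[3, 2] <- 1
        An <- normalizeAdjacency(path)
        pathOk <- abs(An[1, 2] - 1 / sqrt(2)) < 1e-12
        Xg <- array(stats::rnorm(4 * 5 * 8), c(4, 5, 8))
        Ck <- dataDrivenGraph(Xg, matrix(stats::rnorm(8), 2, 4),
                              matrix(stats::rnorm(8), 2, 4))
        ckRows <- max(abs(rowSums(Ck) - 1)) < 1e-6
        prm <- agcParams(4, 4, Ce = 0)
        prm$Ak <- replicate(3, matrix(0, 8, 8), simplify = FALSE)
        resid <- max(abs(agcForward(Xg, prm) - Xg)) == 0
        c(dsa_rows_sum_1 = dsaRows, ssa_kills_negative = ssaZero,
          path_normalization = pathOk, ck_rows_sum_1 = ckRows,
          pure_residual_identity = resid)
    })
    res
}
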