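# Cross-validation protocol (random 90/10 splits with parent filtering),
# prediction-accuracy metrics, and the benchmark harness comparing
# combining-ability BLUP, GBLUP, tuned base learners and the stacked
# ensemble under identical splits.

#' Random 90/10 cross-validation splits with parent filtering
#'
#' Each split draws `testFraction` of the realized hybrids uniformly at
#' random as the test set; hybrids for which only one or neither parent
#' is represented in the remaining training crosses are moved to
#' `removed` (combining-ability prediction needs both parents trained).
#' A split whose filtered test set comes out empty is regenerated with a
#' perturbed sub-seed (up to 10 attempts).
#'
#' @param factorial a [Factorial-class] with at least 10 crosses.
#' @param nSplits number of random splits (default 100).
#' @param testFraction fraction of hybrids per test set (default 0.10).
#' @param seed integer seed; the split sequence is reproducible.
#' @return list of splits, each a list with `splitId`, `train`, `test`,
#'   `removed` (data.frames of crosses with yields).
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 10, n2 = 4, n_crosses = 30,
#'                                           n_markers = 0, seed = 1))
#' sp <- makeCvSplits(sim$factorial, nSplits = 3, seed = 1)
#' sapply(sp, function(s) nrow(s$test))
#' @export
makeCvSplits <- function(factorial, nSplits = 100, testFraction = 0.10,
                         seed = 1L) {
  stopifnot(is(factorial, "Factorial"))
  cr <- crosses(factorial)
  n <- nrow(cr)
  if (n < 10) stop("need at least 10 crosses for cross-validation")
  nTest <- round(testFraction * n)
  if (nTest < 1) stop("testFraction leaves an empty test set")
  splits <- vector("list", nSplits)
  for (s in seq_len(nSplits)) {
    done <- FALSE
    for (attempt in 0:9) {
      set.seed(as.integer(seed) + 131L * s + attempt)
      testIdx <- sample.int(n, nTest)
      train <- cr[-testIdx, , drop = FALSE]
      test <- cr[testIdx, , drop = FALSE]
      okParents <- test$parent1 %in% train$parent1 &
        test$parent2 %in% train$parent2
      if (any(okParents)) {
        if (attempt > 0)
          message(sprintf("split %d regenerated (attempt %d)", s, attempt))
        splits[[s]] <- list(splitId = s,
                            train = train,
                            test = test[okParents, , drop = FALSE],
                            removed = test[!okParents, , drop = FALSE])
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("split %d: filtered test set empty after 10 attempts", s))
  }
  splits
}

#' Prediction accuracy (Pearson correlation)
#'
#' The Pearson correlation between observed and predicted test-set
#' yields — the standard accuracy measure for genomic and
#' combining-ability prediction. Constant predictions score 0 with a
#' warning (the convention also used when scoring stacked ensembles).
#'
#' @param yObs observed yields (non-constant, length >= 3).
#' @param yPred predicted yields, same length.
#' @return the correlation in \[-1, 1\].
#' @examples
#' predictionAccuracy(c(1, 2, 3, 4), c(2, 2, 4, 4))  # 0.8944
#' @export
predictionAccuracy <- function(yObs, yPred) {
  if (length(yObs) != length(yPred)) stop("lengths differ")
  if (length(yObs) < 3) stop("need at least 3 observations")
  if (stats::sd(yObs) < 1e-12) stop("observed yields are constant")
  safePearson(yObs, yPred)
}

#' Percentage overlap of the top-k predicted and observed hybrids
#'
#' Compares the k best hybrids by predicted yield with the k best by
#' observed yield and returns the percentage overlap — breeders mostly
#' care about ranking the best hybrids correctly. Ties are broken by
#' stable input order; k is truncated to the number of hybrids.
#'
#' @param yObs,yPred equal-length yield vectors.
#' @param k size of the top set (default 20).
#' @return overlap percentage in \[0, 100\].
#' @examples
#' topKOverlap(1:10, 10:1, k = 3)  # reversed ranking: 0
#' @export
topKOverlap <- function(yObs, yPred, k = 20) {
  if (length(yObs) != length(yPred)) stop("lengths differ")
  if (k < 1) stop("k must be >= 1")
  kEff <- min(k, length(yObs))
  topObs <- order(yObs, decreasing = TRUE)[seq_len(kEff)]
  topPred <- order(yPred, decreasing = TRUE)[seq_len(kEff)]
  100 * length(intersect(topObs, topPred)) / kEff
}

#' Benchmark configuration
#'
#' @param nSplits number of cross-validation splits (100 matches the
#'   full protocol; 20 is a desk-scale default).
#' @param testFraction test fraction per split.
#' @param seed integer master seed; per-split seeds are derived from it.
#' @param gridSize number of models in each random grid search.
#' @param folds grid-search CV folds.
#' @param ks candidate stacked-ensemble sizes.
#' @param encodings named list overriding the per-algorithm default
#'   predictor encoding (`parentage`, `yield-features`, or `markers`).
#' @return classed list (`BenchmarkConfig`).
#' @export
benchmarkConfig <- function(nSplits = 20, testFraction = 0.10, seed = 1L,
                            gridSize = 50, folds = 10, ks = seq(5, 50, 5),
                            encodings = list()) {
  structure(list(nSplits = nSplits, testFraction = testFraction,
                 seed = as.integer(seed), gridSize = gridSize,
                 folds = folds, ks = ks, encodings = encodings),
            class = "BenchmarkConfig")
}

defaultEncoding <- function(algorithm) {
  switch(algorithm,
         "gb" = , "rf" = , "svm" = , "mf" = , "gb-se" = "parentage",
         "gb-marker" = , "rkhs" = "markers",
         "none")
}

# build train/test feature tables with a consistent schema; training
# yields only, so test yields can never leak into the features
encodeForSplit <- function(encoding, trainFact, trainPairs, testPairs,
                           panel1, panel2) {
  allPairs <- rbind(trainPairs[, c("parent1", "parent2")],
                    testPairs[, c("parent1", "parent2")])
  ft <- switch(encoding,
    "parentage" = encodeParentage(trainFact, allPairs),
    "yield-features" = suppressMessages(
      encodeYieldFeatures(trainFact, allPairs)),
    "markers" = encodeHybridGenotypes(panel1, panel2, allPairs),
    stop(sprintf("unknown encoding '%s'", encoding)))
  nTr <- nrow(trainPairs)
  list(train = subsetFeatureTable(ft, seq_len(nTr)),
       test = subsetFeatureTable(ft, nTr + seq_len(nrow(testPairs))))
}

#' Benchmark prediction algorithms under a shared CV protocol
#'
#' Runs the full protocol: random 90/10 splits with parent filtering,
#' per-split model fitting (REML refits for the combining-ability and
#' GBLUP models; a fresh random grid search, and stacking for `gb-se`,
#' within every training set), prediction of the filtered test hybrids,
#' and both metrics (prediction accuracy, top-20 overlap) per split and
#' algorithm. Feature encodings are rebuilt per split from training
#' yields only, so no function of a test yield ever enters a training
#' input. Per-split failures are recorded and skipped; an algorithm
#' failing more than half its splits is flagged.
#'
#' @param factorial a [Factorial-class].
#' @param markers optional list with `panel1`, `panel2` (imputed
#'   [MarkerPanel-class]) — required for `gblup`, `gb-marker`, `rkhs`.
#' @param algorithms character vector from `gca`, `gblup`, `gb`, `rf`,
#'   `svm`, `mf`, `gb-se`, `gb-marker`, `rkhs`, `oracle` (the oracle
#'   returns the observed test yields; a harness-integrity check).
#' @param config a [benchmarkConfig()].
#' @return A `BenchmarkResult`: list with `results` (one row per split x
#'   algorithm), `medians`, and `flagged` (algorithms failing > 50% of
#'   splits).
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 12, n2 = 5, n_crosses = 40,
#'                                           n_markers = 0, seed = 2))
#' bench <- runBenchmark(sim$factorial, algorithms = c("gca", "oracle"),
#'                       config = benchmarkConfig(nSplits = 3, seed = 1))
#' bench$medians
#' @export
runBenchmark <- function(factorial, markers = NULL, algorithms,
                         config = benchmarkConfig()) {
  stopifnot(is(factorial, "Factorial"), inherits(config, "BenchmarkConfig"))
  markerAlgos <- c("gblup", "gb-marker", "rkhs")
  if (any(algorithms %in% markerAlgos) &&
      (is.null(markers$panel1) || is.null(markers$panel2)))
    stop(sprintf("algorithms %s need marker panels",
                 paste(intersect(algorithms, markerAlgos), collapse = ", ")))
  G1 <- G2 <- NULL
  if ("gblup" %in% algorithms) {
    G1 <- vanRadenG(imputeMarkers(markers$panel1))$G
    G2 <- vanRadenG(imputeMarkers(markers$panel2))$G
  }
  splits <- makeCvSplits(factorial, config$nSplits, config$testFraction,
                         seed = config$seed)
  rows <- list()
  for (sp in splits) {
    splitSeed <- config$seed + 7919L * sp$splitId
    trainFact <- Factorial(sp$train)
    yTest <- sp$test$yield
    for (algo in algorithms) {
      enc <- config$encodings[[algo]] %||% defaultEncoding(algo)
      preds <- tryCatch({
        if (algo == "oracle") {
          yTest
        } else if (algo == "gca") {
          sol <- fitGcaBlup(trainFact)
          as.numeric(predictGca(sol, sp$test))
        } else if (algo == "gblup") {
          mod <- fitGblup(trainFact, G1, G2)
          as.numeric(predictGblup(mod, sp$test))
        } else {
          fts <- encodeForSplit(enc, trainFact, sp$train, sp$test,
                                markers$panel1, markers$panel2)
          yTr <- sp$train$yield
          if (algo == "rkhs") {
            fitPredict(ModelSpec("rkhs", seed = splitSeed),
                       fts$train, yTr, fts$test)
          } else if (algo == "gb-se") {
            specs <- sampleHyperparameters(defaultHyperparameterSpace("gb"),
                                           config$gridSize, seed = splitSeed)
            grid <- runGridSearch(specs, fts$train, yTr,
                                  folds = config$folds, seed = splitSeed)
            se <- buildStackedEnsemble(grid, fts$train, yTr, ks = config$ks)
            predictEnsemble(se, fts$test)
          } else {
            specs <- sampleHyperparameters(defaultHyperparameterSpace(algo),
                                           config$gridSize, seed = splitSeed)
            grid <- runGridSearch(specs, fts$train, yTr,
                                  folds = config$folds, seed = splitSeed)
            fitPredict(grid@specs[[grid@bestIndex]], fts$train, yTr,
                       fts$test)
          }
        }
      }, error = function(e) e)
      if (inherits(preds, "error")) {
        message(sprintf("split %d, %s failed: %s", sp$splitId, algo,
                        conditionMessage(preds)))
        rows[[length(rows) + 1L]] <- data.frame(
          split_id = sp$splitId, algorithm = algo, encoding = enc,
          accuracy = NA_real_, top20_overlap = NA_real_)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        split_id = sp$splitId, algorithm = algo, encoding = enc,
        accuracy = predictionAccuracy(yTest, preds),
        top20_overlap = topKOverlap(yTest, preds, k = 20))
    }
  }
  results <- do.call(rbind, rows)
  medians <- do.call(rbind, lapply(split(results, results$algorithm),
    function(d) data.frame(
      algorithm = d$algorithm[1],
      median_accuracy = stats::median(d$accuracy, na.rm = TRUE),
      median_top20_overlap = stats::median(d$top20_overlap, na.rm = TRUE),
      n_failed = sum(is.na(d$accuracy)))))
  rownames(medians) <- NULL
  flagged <- medians$algorithm[medians$n_failed > config$nSplits / 2]
  structure(list(results = results, medians = medians, flagged = flagged),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat("Benchmark medians across splits:\n")
  print(x$medians, row.names = FALSE)
  if (length(x$flagged))
    cat("flagged (failed > 50% of splits):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
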