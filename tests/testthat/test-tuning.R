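smallSpace <- function() {
  list(algorithm = "gb",
       grid = list(n_trees = c(10, 20, 30), max_depth = c(2, 3, 4, 5)),
       fixed = list(learn_rate = 0.1))
}

test_that("small spaces are exhausted and sampling is deterministic", {
  specs <- sampleHyperparameters(smallSpace(), n = 50, seed = 1)
  expect_length(specs, 12)
  combos <- sapply(specs, function(s)
    paste(s@params$n_trees, s@params$max_depth))
  expect_equal(anyDuplicated(combos), 0L)
  a <- sampleHyperparameters(defaultHyperparameterSpace("gb"), 50, seed = 4)
  b <- sampleHyperparameters(defaultHyperparameterSpace("gb"), 50, seed = 4)
  expect_identical(lapply(a, function(s) s@params),
                   lapply(b, function(s) s@params))
})

test_that("draws from a large space are pairwise distinct across seeds", {
  space <- defaultHyperparameterSpace("gb")
  for (seed in 1:100) {
    specs <- sampleHyperparameters(space, 50, seed = seed)
    combos <- sapply(specs, function(s)
      paste(unlist(s@params), collapse = "|"))
    expect_equal(anyDuplicated(combos), 0L)
  }
})

test_that("grid search ranks specs like a hand-rolled CV loop", {
  sim <- simulateFactorial(simulationConfig(n1 = 5, n2 = 4, n_crosses = 20,
                                            n_markers = 0, seed = 12))
  ft <- encodeParentage(sim$factorial)
  y <- crosses(sim$factorial)$yield
  specs <- list(
    ModelSpec("gb", list(n_trees = 100, max_depth = 3, min_rows = 1,
                         sample_rate = 1, nbins_cats = 16), seed = 21),
    ModelSpec("gb", list(n_trees = 5, max_depth = 1, min_rows = 10,
                         sample_rate = 1, nbins_cats = 8), seed = 22))
  g <- runGridSearch(specs, ft, y, folds = 10, seed = 3)
  # independent re-computation with the stored fold partition
  manual <- sapply(specs, function(sp) {
    oof <- rep(NA_real_, length(y))
    for (f in 1:10) {
      inF <- g@foldAssignment == f
      oof[inF] <- fitPredict(sp, hybfact:::subsetFeatureTable(ft, !inF),
                             y[!inF], hybfact:::subsetFeatureTable(ft, inF))
    }
    mean((y - oof)^2)
  })
  expect_equal(g@cvMse, manual, tolerance = 1e-12)
  expect_equal(g@bestIndex, as.integer(which.min(manual)))
  # the definitional identity between stored OOF and MSE
  expect_equal(g@cvMse[1], mean((y - g@oof[, 1])^2))
  # reproducibility of the whole search
  g2 <- runGridSearch(specs, ft, y, folds = 10, seed = 3)
  expect_equal(g@cvMse, g2@cvMse)
  expect_identical(g@foldAssignment, g2@foldAssignment)
})

test_that("an ensemble containing a perfect base model scores near 1", {
  set.seed(13)
  n <- 60
  y <- rnorm(n)
  oof <- cbind(y,
               y + rnorm(n, 0, 2),
               rnorm(n), rnorm(n))
  specs <- lapply(1:4, function(i)
    ModelSpec("gb", list(n_trees = 10 * i, max_depth = 2, min_rows = 1,
                         sample_rate = 1, nbins_cats = 8), seed = i))
  grid <- new("GridSearchResult", specs = specs,
              cvMse = colMeans((y - oof)^2), oof = oof,
              foldAssignment = rep(1:10, length.out = n),
              failed = rep(FALSE, 4), bestIndex = 1L)
  ft <- mkFt(data.frame(x = rnorm(n)))
  se <- buildStackedEnsemble(grid, ft, y, ks = c(2, 4))
  expect_gte(max(se@cvRByK), 0.999)
  expect_equal(se@k, 2L)  # smallest k on (near-)ties
  # the returned k maximizes the reported correlation curve
  expect_equal(se@cvRByK[[as.character(se@k)]], max(se@cvRByK))
})

test_that("a pure-noise ensemble cannot reach a high CV correlation", {
  set.seed(14)
  n <- 200
  y <- rnorm(n)
  oof <- matrix(rnorm(n * 6), n, 6)
  specs <- lapply(1:6, function(i)
    ModelSpec("gb", list(n_trees = 10, max_depth = 2, min_rows = 1,
                         sample_rate = 1, nbins_cats = 8), seed = i))
  mses <- colMeans((y - oof)^2)
  grid <- new("GridSearchResult", specs = specs,
              cvMse = mses, oof = oof,
              foldAssignment = rep(1:10, length.out = n),
              failed = rep(FALSE, 6), bestIndex = which.min(mses))
  ft <- mkFt(data.frame(x = rnorm(n)))
  se <- buildStackedEnsemble(grid, ft, y, ks = c(2, 4, 6))
  expect_lte(max(se@cvRByK), 0.3)
})

test_that("ensemble prediction is the ridge combination of its bases", {
  constModel <- function(v) list(spec = ModelSpec("gb", seed = 1),
                                 schema = "x", kind = "constant", value = v)
  se <- new("StackedEnsemble",
            baseSpecs = list(ModelSpec("gb", seed = 1)),
            baseModels = list(constModel(2), constModel(5)),
            k = 2L, superIntercept = 1, superCoefs = c(0.5, 2),
            ridgeLambda = 1, cvRByK = c("2" = 0.5))
  ft <- mkFt(data.frame(x = c(0, 1, 2)))
  expect_equal(predictEnsemble(se, ft), rep(1 + 0.5 * 2 + 2 * 5, 3))
  # k = 1 with unit coefficient reduces to the base model
  se1 <- new("StackedEnsemble", baseSpecs = list(ModelSpec("gb", seed = 1)),
             baseModels = list(constModel(7)), k = 1L,
             superIntercept = 0, superCoefs = 1, ridgeLambda = 1,
             cvRByK = c("1" = 0.2))
  expect_equal(predictEnsemble(se1, ft), rep(7, 3))
  # all-zero coefficients give the intercept
  se0 <- new("StackedEnsemble", baseSpecs = list(ModelSpec("gb", seed = 1)),
             baseModels = list(constModel(7)), k = 1L,
             superIntercept = 4, superCoefs = 0, ridgeLambda = 1,
             cvRByK = c("1" = 0))
  expect_equal(predictEnsemble(se0, ft), rep(4, 3))
})

test_that("extreme ridge penalties shrink the super learner to the mean", {
  set.seed(15)
  Z <- matrix(rnorm(80), 40, 2)
  y <- Z %*% c(1, -1) + rnorm(40, 0, 0.1)
  pLow <- with(hybfact:::ridgeAt(Z, y, 1e2),
               intercept + Z %*% coefs)
  pHigh <- with(hybfact:::ridgeAt(Z, y, 1e6),
                intercept + Z %*% coefs)
  expect_lt(max(abs(pHigh - mean(y))), max(abs(pLow - mean(y))))
  expect_lt(max(abs(pHigh - mean(y))), 1e-2 * sd(y))
})

test_that("hyperparameter-MSE correlations match direct Pearson computation", {
  vals <- c(1, 2, 3, 4, 5)
  mses <- c(0.9, 1.4, 1.1, 2.2, 2.0)
  specs <- lapply(seq_along(vals), function(i)
    ModelSpec("gb", list(n_trees = vals[i], kernel = "linear"), seed = i))
  grid <- new("GridSearchResult", specs = specs, cvMse = mses,
              oof = matrix(0, 1, 5), foldAssignment = 1L,
              failed = rep(FALSE, 5), bestIndex = 1L)
  r <- hyperparameterMseCorrelations(grid)
  expect_equal(r[["n_trees"]], cor(vals, mses))
  expect_false("kernel" %in% names(r))  # non-numeric parameter skipped
  # a monotone rigged fixture reaches r ~ 1; constant columns are NA
  specs2 <- lapply(1:4, function(i)
    ModelSpec("gb", list(n_trees = i, max_depth = 3), seed = i))
  grid2 <- new("GridSearchResult", specs = specs2, cvMse = 1:4 * 1.0,
               oof = matrix(0, 1, 4), foldAssignment = 1L,
               failed = rep(FALSE, 4), bestIndex = 1L)
  r2 <- hyperparameterMseCorrelations(grid2)
  expect_gte(r2[["n_trees"]], 0.99)
  expect_true(is.na(r2[["max_depth"]]))
})

test_that("failed specs are excluded from ranking without aborting", {
  sim <- simulateFactorial(simulationConfig(n1 = 5, n2 = 4, n_crosses = 20,
                                            n_markers = 0, seed = 16))
  ft <- encodeParentage(sim$factorial)
  y <- crosses(sim$factorial)$yield
  specs <- list(
    ModelSpec("mf", list(dim = 0), seed = 1),  # invalid: always fails
    ModelSpec("gb", list(n_trees = 20, max_depth = 2, min_rows = 1,
                         sample_rate = 1, nbins_cats = 8), seed = 2))
  g <- suppressMessages(runGridSearch(specs, ft, y, folds = 5, seed = 2))
  expect_true(g@failed[1])
  expect_false(g@failed[2])
  expect_equal(g@bestIndex, 2L)
})
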