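# Random grid search (50 models, shared 10-fold CV, MSE selection) and
# the stacked ensemble of gradient boosting machines with a ridge
# regression super learner trained on out-of-fold base predictions.

#' Sample hyperparameter combinations uniformly without replacement
#'
#' Draws `n` distinct combinations from the Cartesian product of a
#' hyperparameter space; if the space holds at most `n` combinations,
#' all of them are returned. Each sampled spec receives a deterministic
#' seed derived from `seed` and its sampling position.
#'
#' @param space a [defaultHyperparameterSpace()] (or a list with the same
#'   structure).
#' @param n maximum number of models (default 50, the grid-search
#'   stopping criterion).
#' @param seed integer seed.
#' @return list of [ModelSpec-class].
#' @examples
#' specs <- sampleHyperparameters(defaultHyperparameterSpace("gb"), 5, seed = 1)
#' specs[[1]]
#' @export
sampleHyperparameters <- function(space, n = 50, seed = 1L) {
  stopifnot(is.list(space), !is.null(space$grid))
  set.seed(as.integer(seed))
  sizes <- lengths(space$grid)
  total <- if (length(sizes)) prod(sizes) else 1L
  take <- if (total <= n) seq_len(total) else sort(sample.int(total, n))
  specs <- lapply(seq_along(take), function(pos) {
    idx <- take[pos] - 1L
    params <- space$fixed
    for (pn in names(space$grid)) {
      params[[pn]] <- space$grid[[pn]][idx %% sizes[[pn]] + 1L]
      idx <- idx %/% sizes[[pn]]
    }
    ModelSpec(space$algorithm, params, seed = as.integer(seed) + pos)
  })
  specs
}

#' Evaluate hyperparameter combinations by shared k-fold cross-validation
#'
#' All specs are evaluated with one shared random fold partition; each
#' spec's out-of-fold predictions over the full training set give its CV
#' mean squared error, and the spec with the lowest MSE is marked best
#' (ties: first in sampling order). A spec whose learner fails on any
#' fold is flagged failed and excluded from ranking rather than aborting
#' the search.
#'
#' @param specs list of [ModelSpec-class].
#' @param xTrain a [FeatureTable-class].
#' @param yTrain numeric response.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold partition.
#' @return A [GridSearchResult-class].
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 6, n2 = 4, n_crosses = 24,
#'                                           n_markers = 0, seed = 1))
#' ft <- encodeParentage(sim$factorial)
#' specs <- sampleHyperparameters(defaultHyperparameterSpace("gb"), 2, seed = 1)
#' runGridSearch(specs, ft, crosses(sim$factorial)$yield, folds = 4, seed = 1)
#' @export
runGridSearch <- function(specs, xTrain, yTrain, folds = 10, seed = 1L) {
  stopifnot(is(xTrain, "FeatureTable"))
  n <- length(yTrain)
  if (n < folds) stop("need at least as many training rows as folds")
  set.seed(as.integer(seed))
  foldAssignment <- sample(rep(seq_len(folds), length.out = n))
  oof <- matrix(NA_real_, n, length(specs))
  failed <- logical(length(specs))
  for (m in seq_along(specs)) {
    for (f in seq_len(folds)) {
      inFold <- foldAssignment == f
      pred <- tryCatch(
        fitPredict(specs[[m]], subsetFeatureTable(xTrain, !inFold),
                   yTrain[!inFold], subsetFeatureTable(xTrain, inFold)),
        error = function(e) e)
      if (inherits(pred, "error")) {
        failed[m] <- TRUE
        message(sprintf("spec %d failed on fold %d: %s", m, f,
                        conditionMessage(pred)))
        break
      }
      oof[inFold, m] <- pred
    }
  }
  cvMse <- ifelse(failed, NA_real_, colMeans((yTrain - oof)^2))
  ok <- which(!failed)
  if (!length(ok)) stop("every spec failed during the grid search")
  best <- ok[which.min(cvMse[ok])]
  new("GridSearchResult", specs = specs, cvMse = cvMse, oof = oof,
      foldAssignment = as.integer(foldAssignment), failed = failed,
      bestIndex = as.integer(best))
}

# ridge fit on the out-of-fold matrix; lambda on glmnet's scale
ridgeAt <- function(Z, y, lambda, nonneg = FALSE) {
  fit <- glmnet::glmnet(Z, y, alpha = 0, lambda = lambda,
                        standardize = TRUE,
                        lower.limits = if (nonneg) 0 else -Inf)
  cf <- as.numeric(stats::coef(fit, s = lambda))
  list(intercept = cf[1], coefs = cf[-1])
}

#' Build a stacked ensemble from a grid search
#'
#' Base models are ranked by grid-search CV MSE. For each candidate
#' ensemble size k (default 5, 10, ..., 50) a ridge super learner
#' (penalty chosen by internal 5-fold CV over a geometric grid 1e-4 to
#' 1e2) is trained on the out-of-fold predictions of the top k models —
#' never on in-fold predictions, so the super learner never sees a base
#' model's fit to its own training rows. Each k is scored by the Pearson
#' correlation between the response and the super learner's own
#' out-of-fold predictions (reusing the grid-search folds); the k with
#' the highest correlation wins, ties going to the smallest k. The top
#' k base models are then refit on the full training data for
#' prediction.
#'
#' @param grid a [GridSearchResult-class].
#' @param xTrain,yTrain the training data the grid search used.
#' @param ks candidate ensemble sizes.
#' @param nonneg constrain super-learner coefficients to be
#'   non-negative (default FALSE).
#' @return A [StackedEnsemble-class].
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 6, n2 = 4, n_crosses = 24,
#'                                           n_markers = 0, seed = 1))
#' ft <- encodeParentage(sim$factorial)
#' specs <- sampleHyperparameters(defaultHyperparameterSpace("gb"), 4, seed = 1)
#' g <- runGridSearch(specs, ft, crosses(sim$factorial)$yield,
#'                    folds = 4, seed = 1)
#' buildStackedEnsemble(g, ft, crosses(sim$factorial)$yield, ks = c(2, 4))
#' @export
buildStackedEnsemble <- function(grid, xTrain, yTrain, ks = seq(5, 50, 5),
                                 nonneg = FALSE) {
  stopifnot(is(grid, "GridSearchResult"))
  ok <- which(!grid@failed)
  ranked <- ok[order(grid@cvMse[ok])]
  ks <- sort(unique(as.integer(ks)))
  ks <- ks[ks >= 2 & ks <= length(ranked)]
  if (!length(ks))
    stop("no feasible ensemble size: too few non-failed base models")
  lambdaGrid <- 10^seq(2, -4, length.out = 25)
  innerFolds <- ((grid@foldAssignment - 1L) %% 5L) + 1L
  cvR <- stats::setNames(numeric(length(ks)), ks)
  lambdaByK <- stats::setNames(numeric(length(ks)), ks)
  for (iK in seq_along(ks)) {
    k <- ks[iK]
    Z <- grid@oof[, ranked[seq_len(k)], drop = FALSE]
    cvfit <- glmnet::cv.glmnet(Z, yTrain, alpha = 0, lambda = lambdaGrid,
                               foldid = innerFolds, standardize = TRUE,
                               lower.limits = if (nonneg) 0 else -Inf)
    lam <- cvfit$lambda.min
    lambdaByK[iK] <- lam
    oofSuper <- rep(NA_real_, length(yTrain))
    for (f in sort(unique(grid@foldAssignment))) {
      inF <- grid@foldAssignment == f
      rf <- ridgeAt(Z[!inF, , drop = FALSE], yTrain[!inF], lam, nonneg)
      oofSuper[inF] <- rf$intercept +
        as.numeric(Z[inF, , drop = FALSE] %*% rf$coefs)
    }
    cvR[iK] <- safePearson(yTrain, oofSuper)
  }
  kStar <- ks[which.max(cvR)]  # which.max takes the first (smallest) k on ties
  Zstar <- grid@oof[, ranked[seq_len(kStar)], drop = FALSE]
  lamStar <- lambdaByK[as.character(kStar)]
  final <- ridgeAt(Zstar, yTrain, lamStar, nonneg)
  topSpecs <- grid@specs[ranked[seq_len(kStar)]]
  baseModels <- lapply(topSpecs, fitLearner, xTrain = xTrain,
                       yTrain = yTrain)
  new("StackedEnsemble", baseSpecs = grid@specs[ranked],
      baseModels = baseModels, k = as.integer(kStar),
      superIntercept = final$intercept, superCoefs = final$coefs,
      ridgeLambda = lamStar, cvRByK = cvR)
}

#' Predict with a stacked ensemble
#'
#' Prediction is the ridge combination super_intercept + sum_m coef_m *
#' base_m(X) over the selected base models (refit on the full training
#' data during ensemble construction).
#'
#' @param se a [StackedEnsemble-class].
#' @param xTest a [FeatureTable-class].
#' @return numeric predictions.
#' @export
predictEnsemble <- function(se, xTest) {
  stopifnot(is(se, "StackedEnsemble"))
  if (length(se@baseModels) < se@k)
    stop("refit base models are missing from the ensemble")
  B <- vapply(se@baseModels[seq_len(se@k)], predictLearner,
              numeric(length(rowKeys(xTest))), xTest = xTest)
  if (length(rowKeys(xTest)) == 1L) B <- matrix(B, nrow = 1L)
  se@superIntercept + as.numeric(B %*% se@superCoefs)
}

#' Correlations between hyperparameter levels and grid-search MSE
#'
#' For every numeric hyperparameter, the Pearson correlation between its
#' sampled values and the CV MSE across the non-failed grid-search
#' entries; a positive value means larger settings hurt on this data.
#' Constant columns are reported as NA.
#'
#' @param grid a [GridSearchResult-class] with at least 3 non-failed
#'   entries.
#' @return named numeric vector of correlations.
#' @export
hyperparameterMseCorrelations <- function(grid) {
  stopifnot(is(grid, "GridSearchResult"))
  ok <- which(!grid@failed)
  if (length(ok) < 3) stop("need at least 3 non-failed grid entries")
  pnames <- unique(unlist(lapply(grid@specs[ok],
                                 function(s) names(s@params))))
  out <- c()
  for (pn in pnames) {
    vals <- sapply(grid@specs[ok], function(s) {
      v <- s@params[[pn]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1) NA_real_ else v
    })
    if (all(is.na(vals))) next  # non-numeric hyperparameter
    r <- if (stats::sd(vals) < 1e-12) NA_real_ else
      stats::cor(vals, grid@cvMse[ok])
    out[pn] <- r
  }
  out
}
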