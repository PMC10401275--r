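# Uniform fit/predict layer over the base regression algorithms:
# gradient boosting (gb; gb-marker for high-dimensional marker inputs),
# random forest, support vector regression, Gaussian multi-kernel ridge
# (rkhs), and a from-scratch matrix factorization (mf).

#' Default hyperparameter space for an algorithm
#'
#' Finite per-parameter value lists spanning the named tunables of each
#' algorithm; random grid search samples combinations uniformly from the
#' Cartesian product. Gradient boosting keeps the learning rate fixed at
#' 0.1 and tunes tree count, depth, minimum rows per leaf, row sampling
#' and the number of bins for categorical levels; the marker-mode
#' gradient booster fixes the tree count at 1000 with early stopping
#' (patience 10) and instead tunes the learning rate, pruning gamma and
#' per-tree column subsampling. The ranges are deliberately wide: optimal
#' values are known to sit at both ends in some factorials.
#'
#' @param algorithm one of `gb`, `gb-marker`, `rf`, `svm`, `mf`, `rkhs`.
#' @return A classed list (`HyperparameterSpace`) with elements
#'   `algorithm`, `grid` (named list of value vectors) and `fixed`
#'   (named list of non-tuned settings).
#' @examples
#' sp <- defaultHyperparameterSpace("gb")
#' prod(lengths(sp$grid))  # size of the Cartesian space
#' @export
defaultHyperparameterSpace <- function(algorithm = c("gb", "gb-marker", "rf",
                                                     "svm", "mf", "rkhs")) {
  algorithm <- match.arg(algorithm)
  grid <- switch(algorithm,
    "gb" = list(
      n_trees = c(50, 100, 200, 400, 800),
      max_depth = 2:12,
      min_rows = c(1, 2, 5, 10, 20),
      sample_rate = c(0.5, 0.632, 0.8, 1.0),
      nbins_cats = c(8, 16, 32, 64, 128, 256, 512, 1024)),
    "gb-marker" = list(
      learn_rate = c(0.01, 0.05, 0.1, 0.3),
      gamma = c(0, 0.1, 1, 10),
      colsample = c(0.3, 0.5, 0.8, 1.0)),
    "rf" = list(
      n_trees = c(50, 100, 200, 400, 800),
      max_depth = 2:12,
      min_rows = c(1, 2, 5, 10, 20),
      sample_rate = c(0.5, 0.632, 0.8, 1.0),
      nbins_cats = c(8, 16, 32, 64, 128, 256, 512, 1024)),
    "svm" = list(
      C = c(0.1, 1, 10, 100),
      epsilon = c(0.01, 0.1, 0.5),
      kernel = c("linear", "radial", "polynomial2", "polynomial3",
                 "polynomial4")),
    "mf" = list(
      dim = c(2, 4, 8, 16, 32, 64),
      costp_l1 = c(0, 0.01, 0.1),
      costq_l1 = c(0, 0.01, 0.1)),
    "rkhs" = list())
  fixed <- switch(algorithm,
    "gb" = list(learn_rate = 0.1),
    "gb-marker" = list(n_trees = 1000, patience = 10),
    "mf" = list(lrate = 0.05, niters = 500),
    "rkhs" = list(bandwidths = c(0.1, 0.5, 2.5)),
    list())
  structure(list(algorithm = algorithm, grid = grid, fixed = fixed),
            class = "HyperparameterSpace")
}

#' @export
print.HyperparameterSpace <- function(x, ...) {
  cat(sprintf("HyperparameterSpace[%s]: %d tunables, Cartesian size %d\n",
              x$algorithm, length(x$grid),
              if (length(x$grid)) prod(lengths(x$grid)) else 1L))
  invisible(x)
}

# ---- design-matrix preparation ----------------------------------------

# encode factor levels by their smoothed training-target statistic
# (empirical-Bayes m-estimate, pulling sparse levels toward the grand
# mean); the histogram binning of the tree learners then groups levels
# with similar target statistics, the standard treatment of
# high-cardinality nominal predictors such as parent lines with very few
# crosses each
targetStatMap <- function(col, y, m = 5) {
  mns <- tapply(y, col, mean)
  cnt <- tapply(rep(1, length(y)), col, sum)
  gm <- mean(y)
  enc <- (cnt * mns + m * gm) / (cnt + m)
  enc[is.na(enc)] <- gm  # unseen levels fall back to the grand mean
  enc
}

prepDesign <- function(ft, y = NULL, info = NULL) {
  vals <- featureValues(ft)
  isFac <- vapply(vals, function(v) is.factor(v) || is.character(v), logical(1))
  if (is.null(info)) {
    stopifnot(!is.null(y))
    maps <- lapply(vals[isFac], function(v) targetStatMap(as.factor(v), y))
    info <- list(columns = names(vals), isFac = isFac, maps = maps)
  } else {
    if (!identical(names(vals), info$columns))
      stop("feature schema differs between training and prediction data")
  }
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(NULL, names(vals)))
  for (cn in names(vals)) {
    if (info$isFac[[cn]]) {
      out[, cn] <- unname(info$maps[[cn]][as.character(vals[[cn]])])
    } else {
      out[, cn] <- as.numeric(vals[[cn]])
    }
  }
  list(X = out, info = info)
}

# collapse encoded level statistics into at most nbins equal-frequency
# bins (for backends without a histogram bin control)
binCodes <- function(X, info, nbins) {
  for (cn in names(which(unlist(info$isFac)))) {
    lvVals <- sort(unname(info$maps[[cn]]))
    L <- length(lvVals)
    if (L > nbins) {
      brk <- unique(lvVals[ceiling(seq_len(nbins - 1) * L / nbins)])
      X[, cn] <- findInterval(X[, cn], brk)
    }
  }
  X
}

imputeByTrainMeans <- function(X, means = NULL) {
  if (is.null(means)) {
    means <- colMeans(X, na.rm = TRUE)
    means[!is.finite(means)] <- 0
  }
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- means[idx[, 2]]
  list(X = X, means = means)
}

# ---- fit / predict -----------------------------------------------------

#' Fit a base learner and predict new hybrids
#'
#' Uniform interface over all base algorithms: fits the learner described
#' by a [ModelSpec-class] on a training [FeatureTable-class] and response
#' vector, then predicts the test table. Deterministic given the spec's
#' seed. Nominal parent factors are target-mean-ordered and (for the tree
#' learners) grouped into at most `nbins_cats` bins before split search;
#' missing predictor values are passed natively to gradient boosting and
#' mean-imputed (training means) for the other algorithms.
#'
#' @param spec a [ModelSpec-class].
#' @param xTrain,xTest [FeatureTable-class] objects with identical column
#'   schemas.
#' @param yTrain finite numeric response, aligned with `xTrain` rows.
#' @return numeric predictions for the rows of `xTest`.
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 6, n2 = 4, n_crosses = 24,
#'                                           n_markers = 0, seed = 1))
#' ft <- encodeParentage(sim$factorial)
#' spec <- ModelSpec("gb", list(n_trees = 50, max_depth = 3, min_rows = 2,
#'                              sample_rate = 1, nbins_cats = 16), seed = 1)
#' head(fitPredict(spec, ft, crosses(sim$factorial)$yield, ft))
#' @export
fitPredict <- function(spec, xTrain, yTrain, xTest) {
  model <- fitLearner(spec, xTrain, yTrain)
  predictLearner(model, xTest)
}

# fit one learner; returns a list carrying everything predictLearner needs
fitLearner <- function(spec, xTrain, yTrain) {
  stopifnot(is(spec, "ModelSpec"), is(xTrain, "FeatureTable"))
  if (!all(is.finite(yTrain))) stop("response must be finite")
  if (length(yTrain) != length(rowKeys(xTrain)))
    stop("response length must match the training rows")
  set.seed(spec@seed)
  p <- spec@params
  base <- list(spec = spec, schema = names(featureValues(xTrain)))
  if (stats::sd(yTrain) < 1e-12 && spec@algorithm != "mf") {
    return(c(base, list(kind = "constant", value = mean(yTrain))))
  }
  switch(spec@algorithm,
    "gb" = {
      nTrees <- p$n_trees %||% 100
      if (nTrees == 0)  # null ensemble: prior mean only
        return(c(base, list(kind = "constant", value = mean(yTrain))))
      prep <- prepDesign(xTrain, yTrain)
      dtr <- xgboost::xgb.DMatrix(prep$X, label = yTrain, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(eta = 0.1, max_depth = p$max_depth %||% 6,
                      min_child_weight = p$min_rows %||% 5,
                      subsample = p$sample_rate %||% 1,
                      tree_method = "hist",
                      max_bin = max(2, p$nbins_cats %||% 256),
                      base_score = mean(yTrain), nthread = 1),
        data = dtr, nrounds = nTrees, verbose = 0)
      c(base, list(kind = "xgb", fit = fit, prep = prep$info))
    },
    "gb-marker" = {
      prep <- prepDesign(xTrain, yTrain)
      n <- nrow(prep$X)
      hold <- sample.int(n, max(2L, round(0.1 * n)))
      dtr <- xgboost::xgb.DMatrix(prep$X[-hold, , drop = FALSE],
                                  label = yTrain[-hold], nthread = 1)
      dva <- xgboost::xgb.DMatrix(prep$X[hold, , drop = FALSE],
                                  label = yTrain[hold], nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(eta = p$learn_rate %||% 0.1,
                      gamma = p$gamma %||% 0,
                      colsample_bytree = p$colsample %||% 1,
                      max_depth = p$max_depth %||% 6,
                      tree_method = "hist",
                      base_score = mean(yTrain), nthread = 1),
        data = dtr, nrounds = 1000,
        evals = list(val = dva), early_stopping_rounds = 10, verbose = 0)
      c(base, list(kind = "xgb", fit = fit, prep = prep$info))
    },
    "rf" = {
      prep <- prepDesign(xTrain, yTrain)
      X <- binCodes(prep$X, prep$info, p$nbins_cats %||% 1024)
      imp <- imputeByTrainMeans(X)
      df <- as.data.frame(imp$X)
      df$.y <- yTrain
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = p$n_trees %||% 200,
        max.depth = p$max_depth %||% 0,
        min.node.size = p$min_rows %||% 5,
        sample.fraction = p$sample_rate %||% 0.632,
        replace = FALSE, num.threads = 1, seed = spec@seed)
      c(base, list(kind = "rf", fit = fit, prep = prep$info,
                   nbins = p$nbins_cats %||% 1024, means = imp$means))
    },
    "svm" = {
      prep <- prepDesign(xTrain, yTrain)
      imp <- imputeByTrainMeans(prep$X)
      keep <- apply(imp$X, 2, function(v) max(v) - min(v) > 1e-12)
      if (!any(keep))
        return(c(base, list(kind = "constant", value = mean(yTrain))))
      kern <- p$kernel %||% "radial"
      degree <- 3
      if (grepl("^polynomial", kern)) {
        degree <- as.integer(sub("polynomial", "", kern))
        kern <- "polynomial"
      }
      fit <- e1071::svm(imp$X[, keep, drop = FALSE], yTrain,
                        type = "eps-regression", kernel = kern,
                        degree = degree, cost = p$C %||% 1,
                        epsilon = p$epsilon %||% 0.1)
      c(base, list(kind = "svm", fit = fit, prep = prep$info,
                   means = imp$means, keep = keep))
    },
    "rkhs" = {
      prep <- prepDesign(xTrain, yTrain)
      imp <- imputeByTrainMeans(prep$X)
      c(base, list(kind = "rkhs", Xtrain = imp$X, y = yTrain,
                   prep = prep$info, means = imp$means,
                   bandwidths = p$bandwidths %||% c(0.1, 0.5, 2.5)))
    },
    "mf" = {
      vals <- featureValues(xTrain)
      if (!all(c("parent1", "parent2") %in% names(vals)))
        stop("matrix factorization needs the parentage encoding")
      p1 <- as.character(vals$parent1)
      p2 <- as.character(vals$parent2)
      lv1 <- unique(p1); lv2 <- unique(p2)
      Y <- matrix(NA_real_, length(lv1), length(lv2),
                  dimnames = list(lv1, lv2))
      center <- mean(yTrain)
      Y[cbind(match(p1, lv1), match(p2, lv2))] <- yTrain - center
      mf <- fitMF(Y, dim = p$dim %||% 8,
                  costp_l1 = p$costp_l1 %||% 0,
                  costq_l1 = p$costq_l1 %||% 0,
                  lrate = p$lrate %||% 0.05,
                  niters = p$niters %||% 500, seed = spec@seed)
      c(base, list(kind = "mf", fit = mf, center = center,
                   lv1 = lv1, lv2 = lv2))
    },
    stop(sprintf("unknown algorithm '%s'", spec@algorithm)))
}

predictLearner <- function(model, xTest) {
  stopifnot(is(xTest, "FeatureTable"))
  if (!identical(names(featureValues(xTest)), model$schema))
    stop("feature schema differs between training and prediction data")
  n <- length(rowKeys(xTest))
  switch(model$kind,
    "constant" = rep(model$value, n),
    "xgb" = {
      X <- prepDesign(xTest, info = model$prep)$X
      as.numeric(stats::predict(model$fit,
                                xgboost::xgb.DMatrix(X, nthread = 1)))
    },
    "rf" = {
      X <- binCodes(prepDesign(xTest, info = model$prep)$X,
                    model$prep, model$nbins)
      X <- imputeByTrainMeans(X, model$means)$X
      stats::predict(model$fit, data = as.data.frame(X),
                     num.threads = 1)$predictions
    },
    "svm" = {
      X <- imputeByTrainMeans(prepDesign(xTest, info = model$prep)$X,
                              model$means)$X
      as.numeric(stats::predict(model$fit, X[, model$keep, drop = FALSE]))
    },
    "rkhs" = {
      X <- imputeByTrainMeans(prepDesign(xTest, info = model$prep)$X,
                              model$means)$X
      ks <- gaussianKernels(model$Xtrain, X, model$bandwidths)
      as.numeric(rkhsFitPredict(ks$Ktrain, ks$Kcross, model$y)$predictions)
    },
    "mf" = {
      pr <- splitPairKey(rowKeys(xTest))
      i <- match(pr$parent1, model$lv1)
      j <- match(pr$parent2, model$lv2)
      if (anyNA(i) || anyNA(j))
        stop("matrix factorization cannot predict parents absent from training")
      model$center +
        rowSums(model$fit$P[i, , drop = FALSE] * model$fit$Q[j, , drop = FALSE])
    },
    stop("unknown fitted model kind"))
}

# ---- matrix factorization ---------------------------------------------

#' Matrix factorization of an incomplete factorial by SGD
#'
#' Factorizes the group-1 x group-2 yield matrix with missing cells into
#' latent factors P (n1 x dim) and Q (n2 x dim), minimizing squared error
#' over observed cells with L1 penalties by stochastic gradient descent.
#' No bias terms are used; the prediction for cell (i, j) is P_i . Q_j.
#' The learning rate defaults to the fixed value 0.05 and the iteration
#' count to 500.
#'
#' @param Y numeric matrix with NA for unobserved cells; every row and
#'   column needs at least one observation.
#' @param dim number of latent factors (>= 1).
#' @param costp_l1,costq_l1 L1 penalties on P and Q.
#' @param lrate SGD learning rate.
#' @param niters number of passes over the observed cells.
#' @param seed integer seed (initialization and cell order).
#' @return list with `P`, `Q`, and `trace` (observed-cell MSE per pass,
#'   monitored on the training cells).
#' @examples
#' a <- runif(4, 0.5, 1.5); b <- runif(3, 0.5, 1.5)
#' fit <- fitMF(outer(a, b), dim = 1, seed = 1)
#' max(abs(fit$P %*% t(fit$Q) - outer(a, b)))
#' @export
fitMF <- function(Y, dim, costp_l1 = 0, costq_l1 = 0,
                  lrate = 0.05, niters = 500, seed = 1L) {
  if (dim < 1) stop("dim must be >= 1")
  obs <- which(!is.na(Y), arr.ind = TRUE)
  if (!nrow(obs)) stop("no observed cells")
  if (any(tabulate(obs[, 1], nrow(Y)) == 0))
    stop("every row needs at least one observed cell")
  if (any(tabulate(obs[, 2], ncol(Y)) == 0))
    stop("every column needs at least one observed cell")
  set.seed(as.integer(seed))
  P <- matrix(stats::rnorm(nrow(Y) * dim, 0, 0.1), nrow(Y), dim)
  Q <- matrix(stats::rnorm(ncol(Y) * dim, 0, 0.1), ncol(Y), dim)
  vals <- Y[obs]
  trace <- numeric(niters)
  for (it in seq_len(niters)) {
    ord <- sample.int(nrow(obs))
    for (c_ in ord) {
      i <- obs[c_, 1]; j <- obs[c_, 2]
      pi <- P[i, ]; qj <- Q[j, ]
      e <- vals[c_] - sum(pi * qj)
      P[i, ] <- pi + lrate * (e * qj - costp_l1 * sign(pi))
      Q[j, ] <- qj + lrate * (e * pi - costq_l1 * sign(qj))
    }
    trace[it] <- mean((vals - rowSums(P[obs[, 1], , drop = FALSE] *
                                        Q[obs[, 2], , drop = FALSE]))^2)
  }
  list(P = P, Q = Q, trace = trace)
}

# ---- Gaussian multi-kernel (RKHS) regression --------------------------

# kernels exp(-h * D) with D the squared Euclidean distance divided by
# its mean over training pairs
gaussianKernels <- function(Xtrain, Xtest, bandwidths) {
  sq <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  }
  D <- pmax(sq(Xtrain, Xtrain), 0)
  scale <- mean(D)
  if (scale <= 0) scale <- 1  # identical genotypes: all-ones kernels
  Dc <- pmax(sq(Xtest, Xtrain), 0) / scale
  D <- D / scale
  list(Ktrain = lapply(bandwidths, function(h) exp(-h * D)),
       Kcross = lapply(bandwidths, function(h) exp(-h * Dc)))
}

#' Multi-kernel Gaussian ridge regression with REML weights
#'
#' Fits y = 1 b0 + sum_k u_k + e with u_k ~ N(0, sigma2_k K_k) for a list
#' of Gaussian kernels (bandwidths 0.1, 0.5 and 2.5 by default elsewhere)
#' and estimates the per-kernel variances by REML; predictions are the
#' BLUPs b0 + sum_k sigma2_k Kcross_k V^-1 (y - b0), linear in y.
#'
#' @param kTrainList list of PSD train x train kernel matrices.
#' @param kCrossList list of test x train kernel matrices (same order).
#' @param yTrain numeric response.
#' @return list with `predictions`, `sigma2` (per-kernel variances
#'   followed by the residual), and `beta0`.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' ks <- hybfact:::gaussianKernels(X[1:15, ], X[16:20, ], c(0.1, 0.5, 2.5))
#' rkhsFitPredict(ks$Ktrain, ks$Kcross, rnorm(15))$sigma2
#' @export
rkhsFitPredict <- function(kTrainList, kCrossList, yTrain) {
  stopifnot(length(kTrainList) == length(kCrossList))
  n <- length(yTrain)
  for (K in kTrainList) {
    ev <- min(eigen(K + diag(1e-8, n), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < -1e-6) stop("kernel not positive semi-definite after jitter")
  }
  X <- matrix(1, n, 1)
  fit <- remlFitKernels(yTrain, X, kTrainList)
  pred <- rep(fit$beta[1], nrow(kCrossList[[1]]))
  for (m in seq_along(kCrossList))
    pred <- pred + fit$sigma2[m] * as.numeric(kCrossList[[m]] %*% fit$Vir)
  list(predictions = pred, sigma2 = fit$sigma2, beta0 = fit$beta[1])
}
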