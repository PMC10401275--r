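#' @import methods
NULL

#' Two-group testcross factorial
#'
#' Central design object: two ordered lists of inbred parent identifiers
#' (group 1, group 2) and the realized crosses between them with one
#' adjusted entry mean (yield) per hybrid.
#'
#' @slot parents1 character vector of group-1 parent IDs.
#' @slot parents2 character vector of group-2 parent IDs.
#' @slot crosses data.frame with columns `parent1`, `parent2`, `yield`;
#'   one row per realized hybrid, no duplicate parent pairs.
#'
#' @seealso [Factorial()], [describeFactorial()], [fitGcaBlup()]
#' @exportClass Factorial
setClass("Factorial",
  representation(
    parents1 = "character",
    parents2 = "character",
    crosses  = "data.frame"
  )
)

setValidity("Factorial", function(object) {
  cr <- object@crosses
  msgs <- character()
  need <- c("parent1", "parent2", "yield")
  if (!all(need %in% names(cr)))
    return(sprintf("crosses must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@parents1)) msgs <- c(msgs, "duplicate IDs in parents1")
  if (anyDuplicated(object@parents2)) msgs <- c(msgs, "duplicate IDs in parents2")
  if (nrow(cr)) {
    if (!all(cr$parent1 %in% object@parents1))
      msgs <- c(msgs, "crosses reference unknown group-1 parents")
    if (!all(cr$parent2 %in% object@parents2))
      msgs <- c(msgs, "crosses reference unknown group-2 parents")
    if (anyDuplicated(paste(cr$parent1, cr$parent2, sep = "\r")))
      msgs <- c(msgs, "duplicate (parent1, parent2) pairs")
    if (!all(is.finite(cr$yield)))
      msgs <- c(msgs, "yields must be finite")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Inbred-parent SNP panel
#'
#' Parents x markers genotype matrix for one parent group. Inbred parents
#' are fully homozygous, so raw entries are -1 or 1 (NA allowed); after
#' mean imputation entries are reals in \[-1, 1\]. The slot `freqs` holds
#' the frequency of the 1 allele per marker, estimated within this parent
#' group from the non-missing entries at construction (or filtering) time
#' and deliberately kept through imputation.
#'
#' @slot genotypes numeric matrix, rows = parents, columns = markers.
#' @slot freqs named numeric vector, one frequency per marker.
#'
#' @seealso [MarkerPanel()], [filterMarkers()], [imputeMarkers()], [vanRadenG()]
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  representation(
    genotypes = "matrix",
    freqs     = "numeric"
  )
)

setValidity("MarkerPanel", function(object) {
  g <- object@genotypes
  msgs <- character()
  if (is.null(rownames(g))) msgs <- c(msgs, "genotypes must have parent IDs as rownames")
  if (is.null(colnames(g))) msgs <- c(msgs, "genotypes must have marker IDs as colnames")
  if (length(object@freqs) != ncol(g))
    msgs <- c(msgs, "freqs length must equal the number of markers")
  vals <- g[!is.na(g)]
  if (length(vals) && (min(vals) < -1 - 1e-9 || max(vals) > 1 + 1e-9))
    msgs <- c(msgs, "genotype entries must lie in [-1, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Variance components of the combining-ability model
#'
#' Holds the GCA variances of the two parent groups, the SCA variance, the
#' residual variance, and the derived proportion tau = sigma2_SCA /
#' (sigma2_GCA1 + sigma2_GCA2 + sigma2_SCA). With one entry mean per hybrid
#' the SCA term is inseparable from the residual; in that case `sigma2E` is
#' NA and `eConfounded` is TRUE, meaning `sigma2Sca` is the residual
#' variance absorbing both.
#'
#' @slot sigma2Gca1,sigma2Gca2,sigma2Sca,sigma2E numeric variances
#'   (yield^2 units); `sigma2E` may be NA when confounded with SCA.
#' @slot eConfounded logical flag, TRUE when sigma2_e is confounded with SCA.
#' @slot tau numeric in \[0, 1\] (NA when all genetic variances are zero).
#'
#' @seealso [VarianceComponents()], [computeTau()]
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(
    sigma2Gca1  = "numeric",
    sigma2Gca2  = "numeric",
    sigma2Sca   = "numeric",
    sigma2E     = "numeric",
    eConfounded = "logical",
    tau         = "numeric"
  )
)

setValidity("VarianceComponents", function(object) {
  v <- c(object@sigma2Gca1, object@sigma2Gca2, object@sigma2Sca)
  msgs <- character()
  if (any(!is.finite(v)) || any(v < 0))
    msgs <- c(msgs, "GCA/SCA variances must be finite and >= 0")
  if (!is.na(object@sigma2E) && object@sigma2E < 0)
    msgs <- c(msgs, "sigma2E must be >= 0")
  if (!is.na(object@tau) && (object@tau < -1e-12 || object@tau > 1 + 1e-12))
    msgs <- c(msgs, "tau must lie in [0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Fitted combining-ability solution
#'
#' REML fit of the crossed random-intercepts model
#' y_ij = mu + GCA1_i + GCA2_j + SCA_ij on the entry means of a factorial.
#' GCA effects are BLUPs; SCA_ij is the raw residual
#' y_ij - mu - GCA1_i - GCA2_j, defined exactly on the realized crosses.
#'
#' @slot mu numeric intercept (yield units).
#' @slot gca1,gca2 named numeric vectors of parent BLUPs.
#' @slot sca named numeric vector of residual SCA, names are
#'   `parent1:parent2` keys of the realized crosses.
#' @slot vc [VarianceComponents-class] at the REML estimates.
#' @slot singular logical; TRUE when a parent group has a single level
#'   or the fit sits on the variance boundary.
#'
#' @seealso [fitGcaBlup()], [predictGca()], [gcaScaYieldCorrelations()]
#' @exportClass GcaSolution
setClass("GcaSolution",
  representation(
    mu       = "numeric",
    gca1     = "numeric",
    gca2     = "numeric",
    sca      = "numeric",
    vc       = "VarianceComponents",
    singular = "logical"
  )
)

#' Fitted GBLUP model with GCA and SCA kernels
#'
#' REML fit of y = 1 b0 + Z1 g1 + Z2 g2 + Z_S s + e with
#' var(g1) = sigma2_1 G1, var(g2) = sigma2_2 G2 and
#' var(s) = sigma2_s S, where S is the Kronecker product G1 (x) G2
#' restricted to realized hybrids (assembled entry-wise).
#'
#' @slot beta0 numeric fixed intercept.
#' @slot g1,g2 named numeric BLUPs for every parent present in G1 / G2
#'   (including parents without training crosses).
#' @slot s named numeric SCA BLUPs for the training hybrids.
#' @slot vc4 named numeric vector (sigma2_1, sigma2_2, sigma2_s, sigma2_e).
#' @slot G1,G2 genomic relationship matrices used for the fit (jittered).
#' @slot trainPairs data.frame of the training crosses (parent1, parent2, yield).
#' @slot viResid numeric V^{-1}(y - beta0) on the training observations,
#'   cached for kernel-regression prediction.
#' @slot logLik numeric REML log-likelihood at the optimum.
#'
#' @seealso [fitGblup()], [predictGblup()], [vanRadenG()]
#' @exportClass GblupModel
setClass("GblupModel",
  representation(
    beta0      = "numeric",
    g1         = "numeric",
    g2         = "numeric",
    s          = "numeric",
    vc4        = "numeric",
    G1         = "matrix",
    G2         = "matrix",
    trainPairs = "data.frame",
    viResid    = "numeric",
    logLik     = "numeric"
  )
)

#' Predictor table for machine-learning regressors
#'
#' One row per hybrid (keyed `parent1:parent2`), columns are predictor
#' variables: nominal parent factors, one-hot parent indicators,
#' cross-yield features (sparse, NA for unrealized or excluded crosses),
#' virtual-hybrid marker dosages in \[-1, 1\], or a combination.
#'
#' @slot rowKeys character vector of `parent1:parent2` hybrid keys.
#' @slot values data.frame of predictors (factor or numeric columns).
#' @slot encodingKind one of `parentage`, `parentage-onehot`,
#'   `yield-features`, `markers`, `combined`.
#' @slot dropped character vector of column names removed because they
#'   were constant or all-missing after exclusion.
#'
#' @seealso [encodeParentage()], [encodeYieldFeatures()],
#'   [encodeHybridGenotypes()], [combineFeatures()]
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(
    rowKeys      = "character",
    values       = "data.frame",
    encodingKind = "character",
    dropped      = "character"
  )
)

setValidity("FeatureTable", function(object) {
  kinds <- c("parentage", "parentage-onehot", "yield-features", "markers", "combined")
  msgs <- character()
  if (!(object@encodingKind %in% kinds))
    msgs <- c(msgs, sprintf("encodingKind must be one of %s", paste(kinds, collapse = ", ")))
  if (nrow(object@values) != length(object@rowKeys))
    msgs <- c(msgs, "values must have one row per row key")
  if (object@encodingKind == "parentage-onehot" && ncol(object@values)) {
    rs <- rowSums(as.matrix(object@values))
    if (any(abs(rs - 2) > 1e-9))
      msgs <- c(msgs, "one-hot rows must have exactly two active indicators")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Hyperparameter combination for one base learner
#'
#' @slot algorithm one of `gb`, `gb-marker`, `rf`, `svm`, `rkhs`, `mf`.
#' @slot params named list of hyperparameter values, drawn from the
#'   algorithm's [defaultHyperparameterSpace()].
#' @slot seed integer seed making fits reproducible.
#'
#' @seealso [sampleHyperparameters()], [fitPredict()]
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    algorithm = "character",
    params    = "list",
    seed      = "integer"
  )
)

setValidity("ModelSpec", function(object) {
  algos <- c("gb", "gb-marker", "rf", "svm", "rkhs", "mf")
  if (!(object@algorithm %in% algos))
    return(sprintf("algorithm must be one of %s", paste(algos, collapse = ", ")))
  TRUE
})

#' Result of a random grid search
#'
#' Up to 50 hyperparameter combinations, each evaluated with the same
#' 10-fold cross-validation partition; stores per-model out-of-fold
#' predictions and CV mean squared error. Failed specs are flagged and
#' excluded from ranking.
#'
#' @slot specs list of [ModelSpec-class] in sampling order.
#' @slot cvMse numeric CV MSE per spec (NA for failed specs).
#' @slot oof numeric matrix (training rows x specs) of out-of-fold predictions.
#' @slot foldAssignment integer fold id (1..folds) per training row,
#'   shared by all specs.
#' @slot failed logical per spec.
#' @slot bestIndex index of the lowest-MSE non-failed spec (ties: first).
#'
#' @seealso [runGridSearch()], [buildStackedEnsemble()],
#'   [hyperparameterMseCorrelations()]
#' @exportClass GridSearchResult
setClass("GridSearchResult",
  representation(
    specs          = "list",
    cvMse          = "numeric",
    oof            = "matrix",
    foldAssignment = "integer",
    failed         = "logical",
    bestIndex      = "integer"
  )
)

setValidity("GridSearchResult", function(object) {
  msgs <- character()
  if (length(object@specs) > 50) msgs <- c(msgs, "at most 50 specs per grid search")
  if (length(object@cvMse) != length(object@specs))
    msgs <- c(msgs, "cvMse must align with specs")
  ok <- which(!object@failed)
  if (length(ok) && length(object@bestIndex) == 1) {
    if (abs(object@cvMse[object@bestIndex] - min(object@cvMse[ok])) > 1e-12)
      msgs <- c(msgs, "bestIndex must minimize cvMse among non-failed specs")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Stacked ensemble of ranked base models with a ridge super learner
#'
#' Base models are ranked by grid-search CV MSE; for each candidate size k
#' a ridge regression is trained on the out-of-fold predictions of the top
#' k models and scored by the Pearson correlation of its own out-of-fold
#' predictions with the response; the k with the highest correlation wins
#' (ties: smallest k).
#'
#' @slot baseSpecs list of [ModelSpec-class], ranked by CV MSE.
#' @slot baseModels list of fitted base learners (top k, refit on the full
#'   training data) used for prediction.
#' @slot k selected number of base models.
#' @slot superIntercept,superCoefs ridge super-learner parameters.
#' @slot ridgeLambda penalty selected by internal 5-fold CV.
#' @slot cvRByK named numeric, CV Pearson r per candidate k.
#'
#' @seealso [buildStackedEnsemble()], [predictEnsemble()]
#' @exportClass StackedEnsemble
setClass("StackedEnsemble",
  representation(
    baseSpecs      = "list",
    baseModels     = "list",
    k              = "integer",
    superIntercept = "numeric",
    superCoefs     = "numeric",
    ridgeLambda    = "numeric",
    cvRByK         = "numeric"
  )
)

setValidity("StackedEnsemble", function(object) {
  msgs <- character()
  if (length(object@superCoefs) != object@k)
    msgs <- c(msgs, "superCoefs must have length k")
  if (length(object@cvRByK)) {
    best <- max(object@cvRByK)
    kstar <- as.integer(names(object@cvRByK)[which(object@cvRByK >= best - 1e-12)])
    if (!(object@k %in% kstar))
      msgs <- c(msgs, "k must maximize cvRByK")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
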