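#' Construct a Factorial
#'
#' @param crosses data.frame with columns `parent1`, `parent2`, `yield`.
#' @param parents1,parents2 optional parent ID vectors; default to the
#'   parents observed in `crosses` (in order of first appearance).
#' @return A [Factorial-class] object.
#' @examples
#' f <- Factorial(data.frame(
#'   parent1 = c("A", "A", "B"), parent2 = c("X", "Y", "X"),
#'   yield = c(10, 12, 8)))
#' f
#' @export
Factorial <- function(crosses, parents1 = NULL, parents2 = NULL) {
  crosses <- as.data.frame(crosses)
  crosses$parent1 <- as.character(crosses$parent1)
  crosses$parent2 <- as.character(crosses$parent2)
  crosses$yield <- as.numeric(crosses$yield)
  if (is.null(parents1)) parents1 <- unique(crosses$parent1)
  if (is.null(parents2)) parents2 <- unique(crosses$parent2)
  new("Factorial", parents1 = as.character(parents1),
      parents2 = as.character(parents2),
      crosses = crosses[, c("parent1", "parent2", "yield")])
}

#' Construct a MarkerPanel
#'
#' Allele frequencies of the 1 allele are estimated per marker from the
#' non-missing entries, p_v = (mean(x_v) + 1) / 2, unless supplied.
#'
#' @param genotypes numeric matrix (parents x markers) with entries in
#'   \[-1, 1\] or NA; rownames = parent IDs, colnames = marker IDs.
#' @param freqs optional numeric vector of 1-allele frequencies.
#' @return A [MarkerPanel-class] object.
#' @examples
#' g <- matrix(c(1, -1, 1, 1), 2, 2,
#'   dimnames = list(c("A", "B"), c("m1", "m2")))
#' MarkerPanel(g)
#' @export
MarkerPanel <- function(genotypes, freqs = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(freqs)) {
    freqs <- (colMeans(genotypes, na.rm = TRUE) + 1) / 2
  }
  names(freqs) <- colnames(genotypes)
  new("MarkerPanel", genotypes = genotypes, freqs = freqs)
}

#' Construct a VarianceComponents object
#'
#' @param sigma2Gca1,sigma2Gca2,sigma2Sca GCA and SCA variances (>= 0).
#' @param sigma2E residual variance; NA (default) when it is confounded
#'   with SCA, as on entry-mean data with one observation per hybrid.
#' @param tau optional; computed via [computeTau()] when any genetic
#'   variance is positive, NA otherwise.
#' @return A [VarianceComponents-class] object.
#' @examples
#' VarianceComponents(0.516, 0.774, 2.663)
#' @export
VarianceComponents <- function(sigma2Gca1, sigma2Gca2, sigma2Sca,
                               sigma2E = NA_real_, tau = NULL) {
  if (is.null(tau)) {
    tot <- sigma2Gca1 + sigma2Gca2 + sigma2Sca
    tau <- if (is.finite(tot) && tot > 0) sigma2Sca / tot else NA_real_
  }
  new("VarianceComponents",
      sigma2Gca1 = as.numeric(sigma2Gca1), sigma2Gca2 = as.numeric(sigma2Gca2),
      sigma2Sca = as.numeric(sigma2Sca), sigma2E = as.numeric(sigma2E),
      eConfounded = is.na(sigma2E), tau = as.numeric(tau))
}

#' Construct a ModelSpec
#'
#' @param algorithm one of `gb`, `gb-marker`, `rf`, `svm`, `rkhs`, `mf`.
#' @param params named list of hyperparameter values.
#' @param seed integer seed.
#' @return A [ModelSpec-class] object.
#' @examples
#' ModelSpec("gb", list(n_trees = 100, max_depth = 4, min_rows = 5,
#'                      sample_rate = 0.8, nbins_cats = 64), seed = 1)
#' @export
ModelSpec <- function(algorithm, params = list(), seed = 1L) {
  new("ModelSpec", algorithm = algorithm, params = params,
      seed = as.integer(seed))
}

# ---- accessors ---------------------------------------------------------

#' Accessors for package classes
#'
#' `crosses()`, `parents1()`, `parents2()` read the design of a
#' [Factorial-class]; `genotypes()` and `markerFreqs()` read a
#' [MarkerPanel-class]; `varianceComponents()` reads the fitted variance
#' components of a [GcaSolution-class].
#'
#' @param object a package object.
#' @return The respective slot value.
#' @name accessors
#' @aliases crosses parents1 parents2 genotypes markerFreqs varianceComponents
#' @examples
#' f <- Factorial(data.frame(parent1 = "A", parent2 = "X", yield = 1))
#' crosses(f)
NULL

#' @rdname accessors
#' @export
setGeneric("crosses", function(object) standardGeneric("crosses"))
#' @rdname accessors
#' @export
setMethod("crosses", "Factorial", function(object) object@crosses)

#' @rdname accessors
#' @export
setGeneric("parents1", function(object) standardGeneric("parents1"))
#' @rdname accessors
#' @export
setMethod("parents1", "Factorial", function(object) object@parents1)

#' @rdname accessors
#' @export
setGeneric("parents2", function(object) standardGeneric("parents2"))
#' @rdname accessors
#' @export
setMethod("parents2", "Factorial", function(object) object@parents2)

#' @rdname accessors
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "MarkerPanel", function(object) object@genotypes)

#' @rdname accessors
#' @export
setGeneric("markerFreqs", function(object) standardGeneric("markerFreqs"))
#' @rdname accessors
#' @export
setMethod("markerFreqs", "MarkerPanel", function(object) object@freqs)

#' @rdname accessors
#' @export
setGeneric("varianceComponents",
           function(object) standardGeneric("varianceComponents"))
#' @rdname accessors
#' @export
setMethod("varianceComponents", "GcaSolution", function(object) object@vc)

# ---- show methods ------------------------------------------------------

setMethod("show", "Factorial", function(object) {
  cat(sprintf("Factorial: %d x %d parents, %d realized of %d possible hybrids\n",
              length(object@parents1), length(object@parents2),
              nrow(object@crosses),
              length(object@parents1) * length(object@parents2)))
})

setMethod("show", "MarkerPanel", function(object) {
  g <- object@genotypes
  cat(sprintf("MarkerPanel: %d parents x %d markers (%.2f%% missing)\n",
              nrow(g), ncol(g), 100 * mean(is.na(g))))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: sigma2_GCA1=%.4g sigma2_GCA2=%.4g sigma2_SCA=%.4g%s tau=%.2f\n",
    object@sigma2Gca1, object@sigma2Gca2, object@sigma2Sca,
    if (object@eConfounded) " (residual confounded with SCA)" else
      sprintf(" sigma2_e=%.4g", object@sigma2E),
    object@tau))
})

setMethod("show", "GcaSolution", function(object) {
  cat(sprintf("GcaSolution: mu=%.4g, %d + %d parent BLUPs, %d SCA residuals\n",
              object@mu, length(object@gca1), length(object@gca2),
              length(object@sca)))
  show(object@vc)
})

setMethod("show", "GblupModel", function(object) {
  cat(sprintf(
    "GblupModel: beta0=%.4g, %d + %d kernel parents, %d training hybrids\n",
    object@beta0, length(object@g1), length(object@g2), nrow(object@trainPairs)))
  cat(sprintf("  variances: g1=%.4g g2=%.4g sca=%.4g e=%.4g\n",
              object@vc4[1], object@vc4[2], object@vc4[3], object@vc4[4]))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable (%s): %d hybrids x %d predictors\n",
              object@encodingKind, length(object@rowKeys),
              ncol(object@values)))
  if (length(object@dropped))
    cat(sprintf("  dropped %d constant/all-missing columns\n",
                length(object@dropped)))
})

setMethod("show", "ModelSpec", function(object) {
  ps <- paste(names(object@params),
              vapply(object@params, function(x) paste(format(x), collapse = ","), ""),
              sep = "=", collapse = ", ")
  cat(sprintf("ModelSpec[%s] %s (seed %d)\n", object@algorithm, ps, object@seed))
})

setMethod("show", "GridSearchResult", function(object) {
  ok <- !object@failed
  cat(sprintf("GridSearchResult: %d specs (%d failed), best CV MSE %.4g\n",
              length(object@specs), sum(!ok),
              object@cvMse[object@bestIndex]))
})

setMethod("show", "StackedEnsemble", function(object) {
  cat(sprintf(
    "StackedEnsemble: k=%d of %d ranked base models, ridge lambda=%.3g, CV r=%.3f\n",
    object@k, length(object@baseSpecs), object@ridgeLambda,
    max(object@cvRByK)))
})
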