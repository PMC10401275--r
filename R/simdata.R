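#' Configuration for the synthetic factorial generator
#'
#' Bundles all parameters of the generator: group sizes, variance
#' components of the combining-ability model, design sparsity and skew,
#' and the linked marker panels. Defaults describe a mid-sized two-group
#' factorial with tau = sigma2_sca / (sigma2_gca1 + sigma2_gca2 +
#' sigma2_sca) = 0.5 and noiseless entry means, the reference condition
#' used for variance-component recovery checks.
#'
#' @param n1,n2 number of inbred parents in groups 1 and 2 (>= 2).
#' @param sigma2_gca1,sigma2_gca2,sigma2_sca,sigma2_e variance components
#'   in yield^2 units (all >= 0). `sigma2_e` is measurement noise added on
#'   top of the SCA deviation; the two are drawn separately so that tests
#'   know the truth even though an entry-mean analysis cannot split them.
#' @param mu grand mean (yield units).
#' @param n_crosses number of realized hybrids, in
#'   \[max(n1, n2), n1 * n2\] so every parent can be covered.
#' @param skew nonnegative real controlling per-parent cross-count
#'   imbalance; 0 gives uniform cell probabilities, larger values give
#'   long-tailed per-parent cross counts (weights proportional to
#'   rank^skew).
#' @param n_markers SNPs per parent group (0 = no marker panels).
#' @param maf_range interval in (0, 0.5\] from which per-marker minor
#'   allele frequencies are drawn uniformly, independently per group.
#' @param architecture `"effects-direct"` draws GCA/SCA effects i.i.d.
#'   Gaussian and markers independently of them (negative-control panel);
#'   `"marker-driven"` rebuilds the effects from per-marker additive and
#'   dominance effects so the panels are informative.
#' @param seed integer seed.
#' @return A classed list (`SimulationConfig`).
#' @examples
#' cfg <- simulationConfig(n1 = 10, n2 = 4, n_crosses = 25, seed = 7)
#' sim <- simulateFactorial(cfg)
#' sim$factorial
#' @export
simulationConfig <- function(n1 = 60, n2 = 20,
                             sigma2_gca1 = 1, sigma2_gca2 = 1,
                             sigma2_sca = 2, sigma2_e = 0,
                             mu = 100, n_crosses = 600, skew = 1,
                             n_markers = 200, maf_range = c(0.1, 0.5),
                             architecture = c("effects-direct", "marker-driven"),
                             seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(n1 >= 2, n2 >= 2)
  if (n_crosses <= 0 || n_crosses > n1 * n2)
    stop(sprintf("n_crosses must lie in (0, n1*n2] = (0, %d]", n1 * n2))
  vars <- c(sigma2_gca1, sigma2_gca2, sigma2_sca, sigma2_e)
  if (any(vars < 0)) stop("all variances must be >= 0")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (skew < 0) stop("skew must be >= 0")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 sigma2_gca1 = sigma2_gca1, sigma2_gca2 = sigma2_gca2,
                 sigma2_sca = sigma2_sca, sigma2_e = sigma2_e,
                 mu = mu, n_crosses = as.integer(n_crosses), skew = skew,
                 n_markers = as.integer(n_markers), maf_range = maf_range,
                 architecture = architecture, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "SimulationConfig: %d x %d parents, %d crosses (skew %.2g), mu=%.3g\n",
    "  variances GCA1=%.3g GCA2=%.3g SCA=%.3g e=%.3g; %d markers (%s), seed %d\n"),
    x$n1, x$n2, x$n_crosses, x$skew, x$mu,
    x$sigma2_gca1, x$sigma2_gca2, x$sigma2_sca, x$sigma2_e,
    x$n_markers, x$architecture, x$seed))
  invisible(x)
}

# parent IDs: lines (group 1) x testers (group 2)
parentIds <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))

# weighted cell sampling + coverage repair; assumes RNG state is set
.sampleDesign <- function(n1, n2, n_crosses, skew) {
  if (n_crosses < max(n1, n2))
    stop(sprintf(
      "n_crosses (%d) must be >= max(n1, n2) (%d) so every parent appears",
      n_crosses, max(n1, n2)))
  if (n_crosses > n1 * n2)
    stop(sprintf("n_crosses (%d) must be <= n1*n2 (%d)", n_crosses, n1 * n2))
  if (n_crosses == n1 * n2) {
    grid <- expand.grid(i = seq_len(n1), j = seq_len(n2))
    return(grid[order(grid$i, grid$j), ])
  }
  w1 <- seq_len(n1)^skew
  w2 <- seq_len(n2)^skew
  cellw <- as.vector(outer(w1, w2))
  sel <- sample.int(n1 * n2, n_crosses, prob = cellw)
  iOf <- function(cells) ((cells - 1L) %% n1) + 1L
  jOf <- function(cells) ((cells - 1L) %/% n1) + 1L
  for (rep in seq_len(200L)) {
    i <- iOf(sel); j <- jOf(sel)
    c1 <- tabulate(i, n1); c2 <- tabulate(j, n2)
    miss1 <- which(c1 == 0L); miss2 <- which(c2 == 0L)
    if (!length(miss1) && !length(miss2)) break
    # candidate cells fixing the first uncovered parent, in weighted
    # random order; take the first whose swap keeps everyone covered
    if (length(miss1)) {
      i0 <- miss1[1L]
      cand <- (sample.int(n2, prob = w2) - 1L) * n1 + i0
    } else {
      j0 <- miss2[1L]
      cand <- (j0 - 1L) * n1 + sample.int(n1, prob = w1)
    }
    done <- FALSE
    for (addCell in cand) {
      a1 <- c1; a2 <- c2
      a1[iOf(addCell)] <- a1[iOf(addCell)] + 1L
      a2[jOf(addCell)] <- a2[jOf(addCell)] + 1L
      removable <- which(a1[i] >= 2L & a2[j] >= 2L)
      if (length(removable)) {
        drop <- removable[sample.int(length(removable), 1L)]
        sel <- c(sel[-drop], addCell)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not repair design coverage; increase n_crosses")
  }
  i <- iOf(sel); j <- jOf(sel)
  if (any(tabulate(i, n1) == 0L) || any(tabulate(j, n2) == 0L))
    stop("could not repair design coverage; increase n_crosses")
  data.frame(i = i, j = j)
}

#' Sample an unbalanced incomplete crossing design
#'
#' Draws `n_crosses` distinct parent pairs from the `n1 x n2` grid by
#' weighted sampling without replacement with per-parent weights
#' proportional to rank^skew, then repairs the draw so that every parent
#' of both groups appears in at least one cross. `skew = 0` gives uniform
#' sampling; larger values reproduce the long-tailed per-parent cross
#' counts typical of early-stage breeding factorials.
#'
#' @param n1,n2 group sizes.
#' @param n_crosses number of pairs, in \[max(n1, n2), n1 * n2\].
#' @param skew nonnegative skew exponent.
#' @param seed integer seed; identical inputs give identical designs.
#' @return data.frame with character columns `parent1`, `parent2`.
#' @examples
#' d <- sampleCrossingDesign(5, 4, 20, skew = 0, seed = 1)  # complete design
#' nrow(d)
#' @export
sampleCrossingDesign <- function(n1, n2, n_crosses, skew = 0, seed = 1L) {
  set.seed(as.integer(seed))
  d <- .sampleDesign(n1, n2, n_crosses, skew)
  data.frame(parent1 = parentIds(n1, "L")[d$i],
             parent2 = parentIds(n2, "T")[d$j],
             stringsAsFactors = FALSE)
}

#' Simulate a factorial with known combining-ability effects
#'
#' Generates a crossing design via the weighted sampler, draws GCA, SCA
#' and noise effects i.i.d. Gaussian with the configured variances, and
#' builds the entry means y_ij = mu + GCA1_i + GCA2_j + SCA_ij + e_ij.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `factorial` ([Factorial-class]) and
#'   `effects` (list `mu`, `gca1`, `gca2`, `sca`, `e`; the effect maps are
#'   named vectors, SCA and noise keyed by `parent1:parent2`).
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 8, n2 = 4, n_crosses = 20,
#'                                           n_markers = 0, seed = 3))
#' head(crosses(sim$factorial))
#' @export
simulateFactorial <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  d <- .sampleDesign(config$n1, config$n2, config$n_crosses, config$skew)
  ids1 <- parentIds(config$n1, "L")
  ids2 <- parentIds(config$n2, "T")
  gca1 <- stats::rnorm(config$n1, 0, sqrt(config$sigma2_gca1))
  gca2 <- stats::rnorm(config$n2, 0, sqrt(config$sigma2_gca2))
  sca <- stats::rnorm(config$n_crosses, 0, sqrt(config$sigma2_sca))
  e <- stats::rnorm(config$n_crosses, 0, sqrt(config$sigma2_e))
  names(gca1) <- ids1
  names(gca2) <- ids2
  p1 <- ids1[d$i]; p2 <- ids2[d$j]
  keys <- pairKey(p1, p2)
  names(sca) <- keys
  names(e) <- keys
  yield <- config$mu + gca1[d$i] + gca2[d$j] + sca + e
  fact <- Factorial(data.frame(parent1 = p1, parent2 = p2,
                               yield = as.numeric(yield)),
                    parents1 = ids1, parents2 = ids2)
  effects <- structure(list(mu = config$mu, gca1 = gca1, gca2 = gca2,
                            sca = sca, e = e),
                       class = "TrueEffects")
  list(factorial = fact, effects = effects)
}

#' @export
print.TrueEffects <- function(x, ...) {
  cat(sprintf("TrueEffects: mu=%.3g, %d + %d GCA effects, %d SCA effects\n",
              x$mu, length(x$gca1), length(x$gca2), length(x$sca)))
  invisible(x)
}

# draw a homozygous {-1, 1} panel with per-marker 1-allele frequency p
.drawPanel <- function(nParents, p, ids, markerIds) {
  g <- vapply(p, function(pv) 2 * stats::rbinom(nParents, 1L, pv) - 1, numeric(nParents))
  g <- matrix(as.numeric(g), nrow = nParents,
              dimnames = list(ids, markerIds))
  g
}

#' Simulate linked inbred-parent marker panels
#'
#' Draws homozygous SNP panels (entries -1/1) for both parent groups with
#' per-marker allele frequencies uniform on `maf_range`. Under
#' `architecture = "effects-direct"` the panels carry no signal about the
#' simulated effects (a negative-control panel). Under `"marker-driven"`
#' the factorial's yields and effects are regenerated from the panels:
#' GCA_i = sum_v a_v x_iv centered within group, SCA_ij = sum_v d_v
#' \[x_iv != x_jv\] centered over realized crosses, with the Gaussian
#' additive effects a and dominance effects d rescaled so the realized
#' GCA/SCA variances equal the configured components; fresh N(0,
#' sigma2_e) noise is added.
#'
#' @param config a [simulationConfig()].
#' @param sim output of [simulateFactorial()] for the same config.
#' @return list with `panel1`, `panel2` ([MarkerPanel-class]),
#'   and (regenerated under marker-driven) `factorial` and `effects`.
#' @examples
#' cfg <- simulationConfig(n1 = 12, n2 = 6, n_crosses = 40, n_markers = 30,
#'                         architecture = "marker-driven", seed = 5)
#' sim <- simulateFactorial(cfg)
#' md <- simulateMarkers(cfg, sim)
#' md$panel1
#' @export
simulateMarkers <- function(config, sim) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$n_markers < 1) stop("n_markers must be >= 1")
  set.seed(config$seed + 101L)
  m <- config$n_markers
  markerIds <- sprintf("M%04d", seq_len(m))
  ids1 <- parentIds(config$n1, "L")
  ids2 <- parentIds(config$n2, "T")
  p1 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  p2 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  X1 <- .drawPanel(config$n1, p1, ids1, markerIds)
  X2 <- .drawPanel(config$n2, p2, ids2, markerIds)
  panel1 <- MarkerPanel(X1)
  panel2 <- MarkerPanel(X2)
  if (config$architecture == "effects-direct")
    return(list(panel1 = panel1, panel2 = panel2,
                factorial = sim$factorial, effects = sim$effects))

  if (m < 10)
    stop("marker-driven architecture needs at least 10 markers")
  cr <- crosses(sim$factorial)
  i <- match(cr$parent1, ids1)
  j <- match(cr$parent2, ids2)

  scaleTo <- function(x, target) {
    x <- x - mean(x)
    v <- stats::var(x)
    if (target == 0) return(x * 0)
    if (v < 1e-12)
      stop("marker panel too uninformative to reach the requested variance")
    x * sqrt(target / v)
  }
  g1 <- scaleTo(as.vector(X1 %*% stats::rnorm(m)), config$sigma2_gca1)
  g2 <- scaleTo(as.vector(X2 %*% stats::rnorm(m)), config$sigma2_gca2)
  names(g1) <- ids1
  names(g2) <- ids2
  # dominance acts on loci where the two parents carry different alleles
  H <- (X1[i, , drop = FALSE] * X2[j, , drop = FALSE]) < 0
  sca <- scaleTo(as.vector(H %*% stats::rnorm(m)), config$sigma2_sca)
  e <- stats::rnorm(nrow(cr), 0, sqrt(config$sigma2_e))
  keys <- pairKey(cr$parent1, cr$parent2)
  names(sca) <- keys
  names(e) <- keys
  yield <- config$mu + g1[i] + g2[j] + sca + e
  fact <- Factorial(data.frame(parent1 = cr$parent1, parent2 = cr$parent2,
                               yield = as.numeric(yield)),
                    parents1 = ids1, parents2 = ids2)
  effects <- structure(list(mu = config$mu, gca1 = g1, gca2 = g2,
                            sca = sca, e = e),
                       class = "TrueEffects")
  list(panel1 = panel1, panel2 = panel2, factorial = fact, effects = effects)
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper: [simulateFactorial()] plus, when `n_markers > 0`,
#' [simulateMarkers()]. Under the marker-driven architecture the returned
#' factorial and effects are the regenerated, marker-consistent ones.
#'
#' @param config a [simulationConfig()].
#' @return list with `factorial`, `effects`, and optionally `panel1`,
#'   `panel2`.
#' @examples
#' ds <- simulateDataset(simulationConfig(n1 = 10, n2 = 5, n_crosses = 30,
#'                                        n_markers = 20, seed = 2))
#' names(ds)
#' @export
simulateDataset <- function(config) {
  sim <- simulateFactorial(config)
  if (config$n_markers > 0) {
    md <- simulateMarkers(config, sim)
    list(factorial = md$factorial, effects = md$effects,
         panel1 = md$panel1, panel2 = md$panel2)
  } else {
    list(factorial = sim$factorial, effects = sim$effects)
  }
}
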