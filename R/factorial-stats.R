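#' Descriptive statistics of a testcross factorial
#'
#' Computes the standard descriptive summary of a two-group factorial:
#' group sizes, possible and realized hybrid counts, fraction of realized
#' hybrids, group-size ratio, and the per-parent cross-count distribution
#' (mean, median, range) within each group.
#'
#' @param factorial a [Factorial-class].
#' @return A classed list (`FactorialSummary`) with elements `n1`, `n2`,
#'   `nPossible`, `nRealized`, `fractionRealized` (a proportion),
#'   `ratioGroups` (n1/n2), and `group1`/`group2` (each a list with
#'   `counts`, `mean`, `median`, `range`).
#' @examples
#' f <- Factorial(data.frame(
#'   parent1 = c("A", "A", "B", "B"), parent2 = c("X", "Y", "X", "Y"),
#'   yield = c(1, 2, 3, 4)))
#' describeFactorial(f)
#' @export
describeFactorial <- function(factorial) {
  stopifnot(is(factorial, "Factorial"))
  cr <- crosses(factorial)
  if (!nrow(cr)) stop("factorial has no realized crosses")
  n1 <- length(parents1(factorial))
  n2 <- length(parents2(factorial))
  c1 <- table(factor(cr$parent1, levels = parents1(factorial)))
  c2 <- table(factor(cr$parent2, levels = parents2(factorial)))
  grp <- function(counts) {
    counts <- as.integer(counts)
    list(counts = counts, mean = mean(counts),
         median = stats::median(counts), range = range(counts))
  }
  structure(list(
    n1 = n1, n2 = n2,
    nPossible = n1 * n2, nRealized = nrow(cr),
    fractionRealized = nrow(cr) / (n1 * n2),
    ratioGroups = n1 / n2,
    group1 = grp(c1), group2 = grp(c2)),
    class = "FactorialSummary")
}

#' @export
print.FactorialSummary <- function(x, ...) {
  cat(sprintf("No. of parents in group 1      %d\n", x$n1))
  cat(sprintf("No. of parents in group 2      %d\n", x$n2))
  cat(sprintf("Ratio group 1/group 2          %.1f\n", x$ratioGroups))
  cat(sprintf("No. of possible hybrids        %d\n", x$nPossible))
  cat(sprintf("No. of realized hybrids        %d\n", x$nRealized))
  cat(sprintf("Fraction of realized hybrids   %.1f%%\n",
              100 * x$fractionRealized))
  for (g in 1:2) {
    s <- x[[paste0("group", g)]]
    cat(sprintf("Group %d crosses/parent         mean %.1f, median %.1f, range %d-%d\n",
                g, s$mean, s$median, s$range[1], s$range[2]))
  }
  invisible(x)
}

#' Proportion of SCA variance of the total genetic variance
#'
#' tau = sigma2_SCA / (sigma2_GCA1 + sigma2_GCA2 + sigma2_SCA). High tau
#' marks factorials in which hybrid performance deviates strongly from
#' the sum of parental general combining abilities, the regime where
#' GCA-based selection loses efficiency.
#'
#' @param sigma2Gca1 either a [VarianceComponents-class] or the group-1
#'   GCA variance.
#' @param sigma2Gca2,sigma2Sca GCA-2 and SCA variances (ignored when a
#'   VarianceComponents object is supplied).
#' @return tau, a proportion in \[0, 1\].
#' @examples
#' computeTau(0.516, 0.774, 2.663)  # 0.67 after rounding
#' @export
computeTau <- function(sigma2Gca1, sigma2Gca2 = NULL, sigma2Sca = NULL) {
  if (is(sigma2Gca1, "VarianceComponents")) {
    vc <- sigma2Gca1
    sigma2Gca1 <- vc@sigma2Gca1
    sigma2Gca2 <- vc@sigma2Gca2
    sigma2Sca <- vc@sigma2Sca
  }
  v <- c(sigma2Gca1, sigma2Gca2, sigma2Sca)
  if (any(!is.finite(v)) || any(v < 0))
    stop("variances must be finite and >= 0")
  tot <- sum(v)
  if (tot <= 0)
    stop("tau is undefined when all genetic variances are zero")
  sigma2Sca / tot
}

#' Correlations of GCA sums and SCA deviations with hybrid yield
#'
#' For every realized hybrid (i, j) of the factorial, forms the sum
#' GCA1_i + GCA2_j and the residual SCA_ij from a fitted
#' [GcaSolution-class], and returns their Pearson correlations with the
#' observed yields. These two correlations summarize whether a factorial
#' is GCA- or SCA-dominated.
#'
#' @param factorial the [Factorial-class] the solution was fitted on.
#' @param solution a [GcaSolution-class] from [fitGcaBlup()].
#' @return named numeric vector `c(r_gca = ..., r_sca = ...)`.
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 10, n2 = 4, n_crosses = 30,
#'                                           n_markers = 0, seed = 1))
#' sol <- fitGcaBlup(sim$factorial)
#' gcaScaYieldCorrelations(sim$factorial, sol)
#' @export
gcaScaYieldCorrelations <- function(factorial, solution) {
  stopifnot(is(factorial, "Factorial"), is(solution, "GcaSolution"))
  cr <- crosses(factorial)
  if (nrow(cr) < 3)
    stop("need at least 3 realized hybrids")
  keys <- pairKey(cr$parent1, cr$parent2)
  if (!all(keys %in% names(solution@sca)))
    stop("solution was not fitted on this factorial (missing SCA entries)")
  gsum <- solution@gca1[cr$parent1] + solution@gca2[cr$parent2]
  sca <- solution@sca[keys]
  y <- cr$yield
  if (stats::sd(y) == 0)
    stop("yields have zero variance; correlations undefined")
  # a component with no variation (e.g. SCA residuals in a purely
  # additive factorial) is undefined: reported NA with a warning
  corOrNA <- function(x, what) {
    if (stats::sd(x) == 0) {
      warning(sprintf("%s have zero variance; correlation undefined", what))
      return(NA_real_)
    }
    as.numeric(stats::cor(x, y))
  }
  c(r_gca = corOrNA(gsum, "GCA sums"),
    r_sca = corOrNA(sca, "SCA deviations"))
}
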