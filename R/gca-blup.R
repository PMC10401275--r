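#' Fit the combining-ability mixed model by REML
#'
#' Fits y_ij = mu + GCA1_i + GCA2_j + SCA_ij on the entry means of a
#' factorial with both GCA terms as crossed random intercepts, estimated
#' by REML. With a single adjusted entry mean per hybrid the SCA term is
#' not separable from the residual; the residual variance is therefore
#' reported as sigma2_SCA (with `sigma2E` flagged as confounded), and
#' SCA_ij is defined as the raw residual y_ij - mu - GCA1_i - GCA2_j.
#' This makes the decomposition y_ij = mu + GCA1_i + GCA2_j + SCA_ij
#' exact on every realized cross.
#'
#' @param train a [Factorial-class]; every listed parent must appear in at
#'   least one cross and at least 3 crosses are required.
#' @return A [GcaSolution-class]. The slot `singular` is TRUE when a
#'   parent group has a single level or the REML fit is singular.
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 10, n2 = 4, n_crosses = 30,
#'                                           n_markers = 0, seed = 1))
#' fitGcaBlup(sim$factorial)
#' @export
fitGcaBlup <- function(train) {
  stopifnot(is(train, "Factorial"))
  cr <- crosses(train)
  if (nrow(cr) < 3) stop("need at least 3 crosses to fit the GCA model")
  used1 <- unique(cr$parent1)
  used2 <- unique(cr$parent2)
  if (!all(parents1(train) %in% used1) || !all(parents2(train) %in% used2))
    stop("every listed parent must appear in at least one cross")
  singular <- length(used1) < 2 || length(used2) < 2
  keys <- pairKey(cr$parent1, cr$parent2)
  y <- cr$yield

  if (stats::sd(y) < 1e-12) {
    # degenerate data: flat response, all effects zero
    gca1 <- stats::setNames(rep(0, length(used1)), used1)
    gca2 <- stats::setNames(rep(0, length(used2)), used2)
    sca <- stats::setNames(rep(0, nrow(cr)), keys)
    vc <- VarianceComponents(0, 0, 0, tau = NA_real_)
    return(new("GcaSolution", mu = mean(y), gca1 = gca1, gca2 = gca2,
               sca = sca, vc = vc, singular = TRUE))
  }

  df <- data.frame(y = y,
                   p1 = factor(cr$parent1, levels = used1),
                   p2 = factor(cr$parent2, levels = used2))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    calc.derivs = FALSE)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(y ~ (1 | p1) + (1 | p2), data = df, REML = TRUE,
               control = ctrl))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    mu <- as.numeric(lme4::fixef(fit)[1])
    re <- lme4::ranef(fit)
    gca1 <- stats::setNames(re$p1[[1]], rownames(re$p1))[used1]
    gca2 <- stats::setNames(re$p2[[1]], rownames(re$p2))[used2]
    names(gca1) <- used1
    names(gca2) <- used2
    vcm <- as.data.frame(lme4::VarCorr(fit))
    s1 <- vcm$vcov[vcm$grp == "p1"]
    s2 <- vcm$vcov[vcm$grp == "p2"]
    se <- vcm$vcov[vcm$grp == "Residual"]
    singular <- singular || lme4::isSingular(fit, tol = 1e-6)
  } else {
    # tiny or degenerate designs that the sparse fitter rejects: dense
    # derivative-free REML over the same two crossed random intercepts
    Z1 <- outer(cr$parent1, used1, `==`) * 1
    Z2 <- outer(cr$parent2, used2, `==`) * 1
    dfit <- remlFitKernels(y, matrix(1, length(y), 1),
                           list(tcrossprod(Z1), tcrossprod(Z2)))
    mu <- dfit$beta[1]
    s1 <- dfit$sigma2[1]
    s2 <- dfit$sigma2[2]
    se <- dfit$sigma2[3]
    gca1 <- stats::setNames(as.numeric(s1 * crossprod(Z1, dfit$Vir)), used1)
    gca2 <- stats::setNames(as.numeric(s2 * crossprod(Z2, dfit$Vir)), used2)
    singular <- singular || dfit$boundary
  }
  tau <- if (s1 + s2 + se > 0) computeTau(s1, s2, se) else NA_real_
  vc <- VarianceComponents(s1, s2, se, tau = tau)
  sca <- y - mu - gca1[cr$parent1] - gca2[cr$parent2]
  names(sca) <- keys
  new("GcaSolution", mu = mu, gca1 = gca1, gca2 = gca2, sca = sca,
      vc = vc, singular = singular)
}

#' Predict hybrid yield from a combining-ability solution
#'
#' Prediction for a hybrid (i, j) is mu + GCA1_i + GCA2_j: the SCA
#' deviation of an untested cross is unpredictable from phenotypic data
#' alone and is set to its prior mean of zero.
#'
#' @param solution a [GcaSolution-class].
#' @param pairs hybrid pairs: a data.frame with columns `parent1`,
#'   `parent2`, a 2-column matrix, or a list of length-2 vectors. Both
#'   parents of every pair must be present in the solution.
#' @return named numeric vector of predicted yields, keyed
#'   `parent1:parent2`.
#' @examples
#' sim <- simulateFactorial(simulationConfig(n1 = 10, n2 = 4, n_crosses = 30,
#'                                           n_markers = 0, seed = 1))
#' sol <- fitGcaBlup(sim$factorial)
#' predictGca(sol, data.frame(parent1 = "L001", parent2 = "T002"))
#' @export
predictGca <- function(solution, pairs) {
  stopifnot(is(solution, "GcaSolution"))
  pairs <- asPairs(pairs)
  bad1 <- setdiff(unique(pairs$parent1), names(solution@gca1))
  bad2 <- setdiff(unique(pairs$parent2), names(solution@gca2))
  if (length(bad1) || length(bad2))
    stop(sprintf("unknown parent(s): %s",
                 paste(c(bad1, bad2), collapse = ", ")))
  pred <- solution@mu + solution@gca1[pairs$parent1] +
    solution@gca2[pairs$parent2]
  stats::setNames(as.numeric(pred), pairKey(pairs$parent1, pairs$parent2))
}
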