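# Dense REML core for variance-component models with arbitrary
# covariance kernels:
#
#   y = X beta + sum_k u_k + e,  u_k ~ N(0, sigma2_k V_k),  e ~ N(0, sigma2_e I)
#
# where the V_k are fixed n x n PSD structures already expanded to
# observation space (Z_k K_k Z_k'). The REML log-likelihood
#   -0.5 [ log|V| + log|X'V^-1 X| + r' V^-1 r ],  r = y - X betaGLS,
# is maximized over log-variances with Nelder-Mead (derivative-free, all
# components bounded away from zero on the log scale). Used by the
# GCA+SCA GBLUP model and the Gaussian multi-kernel regression.

remlLogLik <- function(sigma2, y, X, Vlist) {
  n <- length(y)
  k <- length(Vlist)
  V <- diag(sigma2[k + 1L], n)
  for (m in seq_len(k)) V <- V + sigma2[m] * Vlist[[m]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  logdetV <- 2 * sum(log(diag(R)))
  ViX <- backsolve(R, forwardsolve(t(R), X))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  XtViX <- crossprod(X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(list(ll = -Inf))
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Viy)))
  r <- y - X %*% beta
  Vir <- backsolve(R, forwardsolve(t(R), r))
  quad <- sum(r * Vir)
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(cX))) + quad)
  list(ll = as.numeric(ll), beta = as.numeric(beta), Vir = as.numeric(Vir))
}

# maximize REML over log variances; returns estimates, GLS beta and
# V^-1 (y - X beta) at the optimum
remlFitKernels <- function(y, X, Vlist, init = NULL,
                           reltol = 1e-8, maxit = 1000L,
                           lowerBound = 1e-12) {
  n <- length(y)
  X <- as.matrix(X)
  k <- length(Vlist)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-24) {
    # flat response: all components at the lower bound, beta = lsq fit
    sigma2 <- rep(lowerBound, k + 1L)
    beta <- qr.coef(qr(X), y)
    return(list(sigma2 = sigma2, beta = as.numeric(beta),
                Vir = rep(0, n), logLik = NA_real_, converged = TRUE,
                boundary = TRUE))
  }
  if (is.null(init)) init <- rep(vy / (k + 1L), k + 1L)
  obj <- function(theta) {
    s2 <- pmax(exp(theta), lowerBound)
    -remlLogLik(s2, y, X, Vlist)$ll
  }
  opt <- stats::optim(log(pmax(init, lowerBound)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  sigma2 <- pmax(exp(opt$par), lowerBound)
  fin <- remlLogLik(sigma2, y, X, Vlist)
  if (!is.finite(fin$ll))
    stop(sprintf("REML did not converge (last log-likelihood %.6g)", -opt$value))
  list(sigma2 = sigma2, beta = fin$beta, Vir = fin$Vir,
       logLik = fin$ll, converged = opt$convergence == 0,
       boundary = any(sigma2 <= lowerBound * 10))
}
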