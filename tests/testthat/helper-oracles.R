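# Independent dense-linear-algebra oracles used across the tests. These
# never call the package's fitting routines; they spell out GLS / BLUP /
# conditioning formulas on small problems.

# GLS + BLUP for y = 1 mu + Z1 u1 + Z2 u2 + e at fixed variances
mmeOracle <- function(fact, s1, s2, se) {
  cr <- crosses(fact)
  p1 <- unique(cr$parent1)
  p2 <- unique(cr$parent2)
  Z1 <- outer(cr$parent1, p1, `==`) * 1
  Z2 <- outer(cr$parent2, p2, `==`) * 1
  n <- nrow(cr)
  V <- s1 * tcrossprod(Z1) + s2 * tcrossprod(Z2) + se * diag(n)
  Vi <- solve(V)
  one <- matrix(1, n, 1)
  mu <- solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% cr$yield)[1]
  r <- cr$yield - mu
  list(mu = mu,
       gca1 = stats::setNames(as.numeric(s1 * t(Z1) %*% Vi %*% r), p1),
       gca2 = stats::setNames(as.numeric(s2 * t(Z2) %*% Vi %*% r), p2))
}

# multivariate-normal conditioning oracle for the GCA+SCA GBLUP model at
# fixed variance components: predictions for target pairs given training
# pairs, via the explicit joint covariance
gblupCondOracle <- function(trainPairs, y, G1, G2, s2, targetPairs) {
  covBlock <- function(pa, pb) {
    s2[1] * G1[pa$parent1, pb$parent1, drop = FALSE] +
      s2[2] * G2[pa$parent2, pb$parent2, drop = FALSE] +
      s2[3] * (G1[pa$parent1, pb$parent1, drop = FALSE] *
                 G2[pa$parent2, pb$parent2, drop = FALSE])
  }
  n <- nrow(trainPairs)
  Vtr <- covBlock(trainPairs, trainPairs) + s2[4] * diag(n)
  Vi <- solve(Vtr)
  one <- matrix(1, n, 1)
  beta0 <- solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% y)[1]
  Ct <- covBlock(targetPairs, trainPairs)
  as.numeric(beta0 + Ct %*% Vi %*% (y - beta0))
}

# profiled REML log-likelihood over variance ratios (r1, r2) = (s1/se,
# s2/se) for the crossed random-intercepts model; residual variance
# profiled out analytically
profileRemlOracle <- function(fact, logR1Grid, logR2Grid) {
  cr <- crosses(fact)
  p1 <- unique(cr$parent1)
  p2 <- unique(cr$parent2)
  Z1 <- outer(cr$parent1, p1, `==`) * 1
  Z2 <- outer(cr$parent2, p2, `==`) * 1
  n <- nrow(cr)
  y <- cr$yield
  one <- matrix(1, n, 1)
  ll <- matrix(NA_real_, length(logR1Grid), length(logR2Grid))
  for (a in seq_along(logR1Grid)) for (b in seq_along(logR2Grid)) {
    V0 <- exp(logR1Grid[a]) * tcrossprod(Z1) +
      exp(logR2Grid[b]) * tcrossprod(Z2) + diag(n)
    Vi <- solve(V0)
    XtViX <- t(one) %*% Vi %*% one
    mu <- solve(XtViX, t(one) %*% Vi %*% y)[1]
    r <- y - mu
    quad <- as.numeric(t(r) %*% Vi %*% r)
    seHat <- quad / (n - 1)
    ll[a, b] <- -0.5 * ((n - 1) * log(seHat) +
                          determinant(V0)$modulus +
                          log(det(XtViX)) + (n - 1))
  }
  ll
}

pairKey_ <- function(a, b) paste(a, b, sep = ":")

# wrap a plain data.frame of predictors as a FeatureTable
mkFt <- function(df, kind = "markers") {
  new("FeatureTable", rowKeys = sprintf("L%03d:T%03d", seq_len(nrow(df)),
                                        seq_len(nrow(df))),
      values = df, encodingKind = kind, dropped = character())
}

# a small deterministic factorial fixture with hand-set yields
handFactorial22 <- function(yields = c(1, 2, 3, 4)) {
  Factorial(data.frame(
    parent1 = c("A", "A", "B", "B"),
    parent2 = c("X", "Y", "X", "Y"),
    yield = yields))
}

randomSmallFactorial <- function(seed, n1max = 6, n2max = 6) {
  set.seed(seed)
  n1 <- sample(2:n1max, 1)
  n2 <- sample(2:n2max, 1)
  nc <- sample(max(n1, n2):(n1 * n2), 1)
  d <- sampleCrossingDesign(n1, n2, nc, skew = runif(1, 0, 1.5), seed = seed)
  d$yield <- rnorm(nrow(d), 100, 3)
  Factorial(d)
}
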