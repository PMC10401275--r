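#' Filter markers on expected heterozygosity and missingness
#'
#' Removes markers whose expected heterozygosity He = 2 p (1 - p) falls
#' below `minHe`, or whose fraction of missing entries exceeds
#' `maxMissing`. Allele frequencies are (re-)estimated within the parent
#' group from the non-missing entries of this panel, and the retained
#' frequencies are carried along for downstream centering.
#'
#' @param panel a [MarkerPanel-class].
#' @param minHe minimum expected heterozygosity (default 0.10).
#' @param maxMissing maximum fraction of missing entries (default 0.01).
#' @return the filtered [MarkerPanel-class], column order preserved.
#' @examples
#' g <- matrix(c(1, -1, 1, 1, -1, 1), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("m1", "m2")))
#' filterMarkers(MarkerPanel(g))
#' @export
filterMarkers <- function(panel, minHe = 0.10, maxMissing = 0.01) {
  stopifnot(is(panel, "MarkerPanel"))
  g <- genotypes(panel)
  if (!ncol(g)) stop("empty marker panel")
  p <- (colMeans(g, na.rm = TRUE) + 1) / 2
  he <- 2 * p * (1 - p)
  missFrac <- colMeans(is.na(g))
  keep <- he >= minHe & missFrac <= maxMissing
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("all markers removed by filtering")
  MarkerPanel(g[, keep, drop = FALSE], freqs = p[keep])
}

#' Mean-impute missing marker entries
#'
#' Replaces each missing genotype with the mean of the non-missing
#' entries of the same marker. Idempotent; allele frequencies estimated
#' before imputation are preserved.
#'
#' @param panel a [MarkerPanel-class]; every marker needs at least one
#'   non-missing entry.
#' @return the imputed [MarkerPanel-class] (no missing entries).
#' @examples
#' g <- matrix(c(1, 1, NA, -1), 4, 1, dimnames = list(letters[1:4], "m1"))
#' genotypes(imputeMarkers(MarkerPanel(g)))  # NA -> 1/3
#' @export
imputeMarkers <- function(panel) {
  stopifnot(is(panel, "MarkerPanel"))
  g <- genotypes(panel)
  if (any(colSums(!is.na(g)) == 0))
    stop("markers with all entries missing cannot be imputed")
  if (anyNA(g)) {
    mns <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mns[idx[, 2]]
  }
  MarkerPanel(g, freqs = markerFreqs(panel))
}

#' VanRaden genomic relationship matrix
#'
#' G = W W' / c with w_uv = x_uv + 1 - 2 p_v and c = 2 sum_v p_v (1 -
#' p_v), where x_uv is the -1/1 genotype of parent u at marker v and p_v
#' the frequency of the 1 allele in this parent group. When the
#' frequencies are estimated from the panel itself, each column of W sums
#' to zero, so every row of G sums to (numerically) zero.
#'
#' @param panel an imputed [MarkerPanel-class] with at least one
#'   polymorphic marker.
#' @return list with `G` (parents x parents matrix) and the scaling
#'   constant `c`.
#' @examples
#' g <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "B"), "m1"))
#' vanRadenG(MarkerPanel(g))$G  # [[2, -2], [-2, 2]]
#' @export
vanRadenG <- function(panel) {
  stopifnot(is(panel, "MarkerPanel"))
  g <- genotypes(panel)
  if (anyNA(g)) stop("panel must be imputed before computing G")
  p <- markerFreqs(panel)
  cc <- 2 * sum(p * (1 - p))
  if (cc <= 0)
    stop("all markers monomorphic: scaling constant c = 0")
  W <- sweep(g + 1, 2L, 2 * p, `-`)
  G <- tcrossprod(W) / cc
  dimnames(G) <- list(rownames(g), rownames(g))
  list(G = G, c = cc)
}

#' Entry of the Kronecker-product SCA kernel
#'
#' The SCA covariance between hybrids (i, j) and (k, l) is
#' G1\[i, k\] * G2\[j, l\], i.e. an entry of G1 (x) G2. The kernel over
#' realized hybrids is assembled entry-wise from this rule; the full
#' n1 * n2 Kronecker product is never materialized.
#'
#' @param G1,G2 group-1 and group-2 relationship matrices with parent IDs
#'   as dimnames.
#' @param pair1,pair2 length-2 vectors (parent1, parent2) naming the two
#'   hybrids.
#' @return the scalar kernel entry.
#' @examples
#' G <- diag(2); dimnames(G) <- list(c("A", "B"), c("A", "B"))
#' scaKernelEntry(G, G, c("A", "A"), c("A", "A"))
#' @export
scaKernelEntry <- function(G1, G2, pair1, pair2) {
  G1[pair1[[1]], pair2[[1]]] * G2[pair1[[2]], pair2[[2]]]
}

# SCA kernel over two sets of hybrids, assembled entry-wise
assembleScaKernel <- function(G1, G2, pairsA, pairsB = pairsA) {
  G1[pairsA$parent1, pairsB$parent1, drop = FALSE] *
    G2[pairsA$parent2, pairsB$parent2, drop = FALSE]
}

#' Fit the GCA + SCA GBLUP model by REML
#'
#' Fits y = 1 b0 + Z1 g1 + Z2 g2 + Z_S s + e with var(g1) = sigma2_1 G1,
#' var(g2) = sigma2_2 G2 and var(s) = sigma2_s S, where S restricted to
#' the realized hybrids is assembled entry-wise from the Kronecker rule
#' S\[(i,j),(k,l)\] = G1\[i,k\] G2\[j,l\]. The four variance components
#' are estimated by derivative-free REML over log-variances; GCA BLUPs
#' are produced for every parent present in the kernels, including
#' parents without training crosses.
#'
#' A jitter of 1e-6 is added to the diagonals of G1 and G2 before
#' factorization, since VanRaden matrices built from few markers are
#' often rank-deficient.
#'
#' @param train a [Factorial-class] with at least 10 crosses; all
#'   training parents must be rows of G1 / G2.
#' @param G1,G2 relationship matrices with parent IDs as dimnames.
#' @return A [GblupModel-class].
#' @examples
#' ds <- simulateDataset(simulationConfig(n1 = 12, n2 = 6, n_crosses = 40,
#'   n_markers = 50, architecture = "marker-driven", seed = 4))
#' G1 <- vanRadenG(imputeMarkers(ds$panel1))$G
#' G2 <- vanRadenG(imputeMarkers(ds$panel2))$G
#' fitGblup(ds$factorial, G1, G2)
#' @export
fitGblup <- function(train, G1, G2) {
  stopifnot(is(train, "Factorial"))
  cr <- crosses(train)
  if (nrow(cr) < 10) stop("need at least 10 crosses to fit GBLUP")
  if (is.null(rownames(G1)) || is.null(rownames(G2)))
    stop("G1 and G2 need parent IDs as dimnames")
  bad1 <- setdiff(unique(cr$parent1), rownames(G1))
  bad2 <- setdiff(unique(cr$parent2), rownames(G2))
  if (length(bad1) || length(bad2))
    stop(sprintf("training parent(s) absent from the kernels: %s",
                 paste(c(bad1, bad2), collapse = ", ")))
  # kernel jitter guards against rank-deficient VanRaden matrices
  G1 <- G1 + diag(1e-6, nrow(G1))
  G2 <- G2 + diag(1e-6, nrow(G2))
  y <- cr$yield
  n <- length(y)
  i1 <- match(cr$parent1, rownames(G1))
  i2 <- match(cr$parent2, rownames(G2))
  V1 <- G1[i1, i1, drop = FALSE]
  V2 <- G2[i2, i2, drop = FALSE]
  Vs <- V1 * V2  # Kronecker restricted to realized hybrids
  ev <- min(eigen(Vs, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-6 * max(1, max(abs(Vs))))
    stop("SCA kernel not positive semi-definite after jitter")
  X <- matrix(1, n, 1)
  fit <- remlFitKernels(y, X, list(V1, V2, Vs))
  sigma2 <- fit$sigma2
  keys <- pairKey(cr$parent1, cr$parent2)
  beta0 <- fit$beta[1]  # equals mean(y) in the flat-response convention
  Vir <- fit$Vir
  g1 <- as.numeric(sigma2[1] * G1[, i1, drop = FALSE] %*% Vir)
  g2 <- as.numeric(sigma2[2] * G2[, i2, drop = FALSE] %*% Vir)
  names(g1) <- rownames(G1)
  names(g2) <- rownames(G2)
  s <- as.numeric(sigma2[3] * Vs %*% Vir)
  names(s) <- keys
  new("GblupModel", beta0 = beta0, g1 = g1, g2 = g2, s = s,
      vc4 = c(sigma2_1 = sigma2[1], sigma2_2 = sigma2[2],
              sigma2_s = sigma2[3], sigma2_e = sigma2[4]),
      G1 = G1, G2 = G2,
      trainPairs = cr, viResid = Vir,
      logLik = if (is.finite(fit$logLik)) fit$logLik else NA_real_)
}

#' Predict hybrid yield from a fitted GBLUP model
#'
#' Prediction is beta0 + g1_i + g2_j + s_ij, where effects of parents or
#' hybrids outside the training crosses are obtained by kernel
#' regression: cov(target, training) V^-1 (y - beta0), with the
#' covariance assembled from G1, G2 and the Kronecker SCA rule. Both
#' parents of each pair must be rows of the kernels, but need not appear
#' in the training crosses (marker-based prediction of untested parents).
#'
#' @param model a [GblupModel-class].
#' @param pairs hybrid pairs (data.frame / matrix / list, see
#'   [predictGca()]).
#' @return named numeric vector of predicted yields.
#' @examples
#' ds <- simulateDataset(simulationConfig(n1 = 12, n2 = 6, n_crosses = 40,
#'   n_markers = 50, architecture = "marker-driven", seed = 4))
#' G1 <- vanRadenG(imputeMarkers(ds$panel1))$G
#' G2 <- vanRadenG(imputeMarkers(ds$panel2))$G
#' m <- fitGblup(ds$factorial, G1, G2)
#' predictGblup(m, crosses(ds$factorial)[1:3, ])
#' @export
predictGblup <- function(model, pairs) {
  stopifnot(is(model, "GblupModel"))
  pairs <- asPairs(pairs)
  bad1 <- setdiff(unique(pairs$parent1), rownames(model@G1))
  bad2 <- setdiff(unique(pairs$parent2), rownames(model@G2))
  if (length(bad1) || length(bad2))
    stop(sprintf("parent(s) absent from the kernels: %s",
                 paste(c(bad1, bad2), collapse = ", ")))
  tr <- model@trainPairs
  s2 <- model@vc4
  C1 <- model@G1[pairs$parent1, tr$parent1, drop = FALSE]
  C2 <- model@G2[pairs$parent2, tr$parent2, drop = FALSE]
  cov <- s2[1] * C1 + s2[2] * C2 + s2[3] * (C1 * C2)
  pred <- model@beta0 + as.numeric(cov %*% model@viResid)
  stats::setNames(pred, pairKey(pairs$parent1, pairs$parent2))
}
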