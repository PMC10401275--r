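mkPanel <- function(g, parents, markers) {
  MarkerPanel(matrix(g, length(parents), length(markers),
                     dimnames = list(parents, markers)))
}

test_that("marker filtering applies the heterozygosity and missingness rules", {
  # m1: p = 0.5 (He = 0.5, keep); m2: p = 0.02 (He = 0.0392 < 0.10, drop);
  # m3: 2 of 100 entries missing (0.02 > 0.01, drop)
  n <- 100
  g <- cbind(m1 = rep(c(1, -1), 50),
             m2 = c(rep(1, 2), rep(-1, 98)),
             m3 = c(NA, NA, rep(c(1, -1), 49)))
  rownames(g) <- sprintf("P%03d", 1:n)
  filt <- filterMarkers(MarkerPanel(g))
  expect_equal(colnames(genotypes(filt)), "m1")
  expect_error(filterMarkers(MarkerPanel(g[, "m2", drop = FALSE])),
               "all markers removed")
})

test_that("mean imputation fills gaps with column means and is idempotent", {
  g <- matrix(c(1, 1, NA, -1), 4, 1, dimnames = list(letters[1:4], "m1"))
  imp <- imputeMarkers(MarkerPanel(g))
  expect_equal(genotypes(imp)[3, 1], 1 / 3)
  expect_identical(genotypes(imputeMarkers(imp)), genotypes(imp))
  g2 <- matrix(c(1, NA), 2, 1, dimnames = list(c("a", "b"), "m1"))
  expect_equal(genotypes(imputeMarkers(MarkerPanel(g2)))[2, 1], 1)
  g3 <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "m1"))
  expect_error(imputeMarkers(MarkerPanel(g3)), "all entries missing")
})

test_that("the VanRaden matrix matches hand evaluation and centering", {
  vr <- vanRadenG(mkPanel(c(1, -1), c("A", "B"), "m1"))
  expect_equal(vr$c, 0.5)
  expect_equal(unname(vr$G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # duplicate parents share identical relationship entries
  vr2 <- vanRadenG(mkPanel(c(1, 1, -1, 1, 1, -1), c("A", "Adup", "B"),
                           c("m1", "m2")))
  expect_equal(vr2$G["A", "A"], vr2$G["A", "Adup"])
  expect_equal(vr2$G["A", "A"], vr2$G["Adup", "Adup"])
  # panel-estimated frequencies center every row sum to zero
  set.seed(1)
  g <- matrix(sample(c(-1, 1), 20 * 50, TRUE), 20, 50,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("m%02d", 1:50)))
  expect_lt(max(abs(rowSums(vanRadenG(MarkerPanel(g))$G))), 1e-6)
  mono <- mkPanel(c(1, 1), c("A", "B"), "m1")
  expect_error(vanRadenG(mono), "monomorphic")
})

test_that("the SCA kernel entry rule matches the materialized Kronecker product", {
  set.seed(7)
  G1 <- crossprod(matrix(rnorm(16), 4)); dimnames(G1) <- rep(list(paste0("L", 1:4)), 2)
  G2 <- crossprod(matrix(rnorm(9), 3)); dimnames(G2) <- rep(list(paste0("T", 1:3)), 2)
  expect_equal(scaKernelEntry(G1, G2, c("L1", "T2"), c("L1", "T2")),
               G1["L1", "L1"] * G2["T2", "T2"])
  K <- kronecker(G1, G2)  # row (i-1)*3 + j  <->  hybrid (Li, Tj)
  hy <- expand.grid(j = 1:3, i = 1:4)
  pairs <- data.frame(parent1 = paste0("L", hy$i), parent2 = paste0("T", hy$j))
  S <- hybfact:::assembleScaKernel(G1, G2, pairs)
  expect_equal(unname(S), unname(K), tolerance = 1e-12)
  # incomplete designs up to n1*n2 = 64: entry-wise equals the submatrix
  set.seed(8)
  G1b <- crossprod(matrix(rnorm(64), 8)); dimnames(G1b) <- rep(list(paste0("L", 1:8)), 2)
  G2b <- crossprod(matrix(rnorm(64), 8)); dimnames(G2b) <- rep(list(paste0("T", 1:8)), 2)
  Kb <- kronecker(G1b, G2b)
  sel <- sort(sample(64, 30))
  ij <- cbind(i = (sel - 1) %/% 8 + 1, j = (sel - 1) %% 8 + 1)
  prs <- data.frame(parent1 = paste0("L", ij[, "i"]),
                    parent2 = paste0("T", ij[, "j"]))
  expect_equal(unname(hybfact:::assembleScaKernel(G1b, G2b, prs)),
               unname(Kb[sel, sel]), tolerance = 1e-12)
  idG <- diag(3); dimnames(idG) <- rep(list(paste0("L", 1:3)), 2)
  idH <- diag(3); dimnames(idH) <- rep(list(paste0("T", 1:3)), 2)
  allp <- data.frame(parent1 = rep(paste0("L", 1:3), each = 3),
                     parent2 = rep(paste0("T", 1:3), 3))
  expect_equal(unname(hybfact:::assembleScaKernel(idG, idH, allp)),
               diag(9))
})

test_that("GBLUP predictions match the dense conditioning oracle", {
  ds <- simulateDataset(simulationConfig(n1 = 4, n2 = 3, n_crosses = 11,
    n_markers = 40, architecture = "marker-driven", sigma2_e = 0.3,
    seed = 19))
  G1 <- vanRadenG(imputeMarkers(ds$panel1))$G
  G2 <- vanRadenG(imputeMarkers(ds$panel2))$G
  m <- fitGblup(ds$factorial, G1, G2)
  cr <- crosses(ds$factorial)
  allPairs <- expand.grid(parent1 = rownames(G1), parent2 = rownames(G2),
                          stringsAsFactors = FALSE)
  pred <- predictGblup(m, allPairs)
  orc <- gblupCondOracle(cr, cr$yield, m@G1, m@G2, m@vc4, allPairs)
  expect_equal(as.numeric(pred), orc, tolerance = 1e-8)
  # training pairs decompose as beta0 + g1 + g2 + s
  predTr <- predictGblup(m, cr)
  rec <- m@beta0 + m@g1[cr$parent1] + m@g2[cr$parent2] +
    m@s[pairKey_(cr$parent1, cr$parent2)]
  expect_equal(as.numeric(predTr), as.numeric(rec), tolerance = 1e-8)
})

test_that("predictions are linear in the response at fixed variances", {
  ds <- simulateDataset(simulationConfig(n1 = 6, n2 = 4, n_crosses = 20,
    n_markers = 40, architecture = "marker-driven", seed = 23))
  G1 <- vanRadenG(imputeMarkers(ds$panel1))$G + diag(1e-6, 6)
  G2 <- vanRadenG(imputeMarkers(ds$panel2))$G + diag(1e-6, 4)
  cr <- crosses(ds$factorial)
  s2 <- c(1, 0.8, 0.5, 0.4)
  target <- expand.grid(parent1 = rownames(G1), parent2 = rownames(G2),
                        stringsAsFactors = FALSE)
  set.seed(1)
  y1 <- rnorm(nrow(cr)); y2 <- rnorm(nrow(cr))
  # package model objects at fixed variance components
  mkModel <- function(y) {
    n <- nrow(cr)
    V <- s2[1] * G1[cr$parent1, cr$parent1] +
      s2[2] * G2[cr$parent2, cr$parent2] +
      s2[3] * G1[cr$parent1, cr$parent1] * G2[cr$parent2, cr$parent2] +
      s2[4] * diag(n)
    Vi <- solve(V)
    b0 <- sum(Vi %*% y) / sum(Vi)
    new("GblupModel", beta0 = b0,
        g1 = setNames(rep(0, nrow(G1)), rownames(G1)),
        g2 = setNames(rep(0, nrow(G2)), rownames(G2)),
        s = setNames(rep(0, n), pairKey_(cr$parent1, cr$parent2)),
        vc4 = s2, G1 = G1, G2 = G2,
        trainPairs = transform(cr, yield = y),
        viResid = as.numeric(Vi %*% (y - b0)), logLik = 0)
  }
  p1 <- predictGblup(mkModel(y1), target)
  p2 <- predictGblup(mkModel(y2), target)
  p12 <- predictGblup(mkModel(y1 + 2 * y2), target)
  expect_equal(as.numeric(p12), as.numeric(p1 + 2 * p2), tolerance = 1e-8)
  # and the package path agrees with the independent conditioning oracle
  expect_equal(as.numeric(p1), gblupCondOracle(cr, y1, G1, G2, s2, target),
               tolerance = 1e-8)
})

test_that("near-zero residual variance interpolates the training yields", {
  ds <- simulateDataset(simulationConfig(n1 = 5, n2 = 4, n_crosses = 12,
    n_markers = 40, architecture = "marker-driven", seed = 29))
  G1 <- vanRadenG(imputeMarkers(ds$panel1))$G + diag(1e-6, 5)
  G2 <- vanRadenG(imputeMarkers(ds$panel2))$G + diag(1e-6, 4)
  cr <- crosses(ds$factorial)
  n <- nrow(cr)
  s2 <- c(1, 1, 1, 1e-10)
  V <- s2[1] * G1[cr$parent1, cr$parent1] +
    s2[2] * G2[cr$parent2, cr$parent2] +
    s2[3] * G1[cr$parent1, cr$parent1] * G2[cr$parent2, cr$parent2] +
    s2[4] * diag(n)
  Vi <- solve(V)
  b0 <- sum(Vi %*% cr$yield) / sum(Vi)
  m <- new("GblupModel", beta0 = b0,
           g1 = setNames(rep(0, 5), rownames(G1)),
           g2 = setNames(rep(0, 4), rownames(G2)),
           s = setNames(rep(0, n), pairKey_(cr$parent1, cr$parent2)),
           vc4 = s2, G1 = G1, G2 = G2, trainPairs = cr,
           viResid = as.numeric(Vi %*% (cr$yield - b0)), logLik = 0)
  expect_equal(as.numeric(predictGblup(m, cr)), cr$yield, tolerance = 1e-5)
})

test_that("identical training yields collapse to the intercept", {
  ds <- simulateDataset(simulationConfig(n1 = 5, n2 = 4, n_crosses = 12,
    n_markers = 30, seed = 3))
  G1 <- vanRadenG(imputeMarkers(ds$panel1))$G
  G2 <- vanRadenG(imputeMarkers(ds$panel2))$G
  f <- Factorial(transform(crosses(ds$factorial), yield = 42))
  m <- fitGblup(f, G1, G2)
  expect_equal(m@beta0, 42)
  expect_true(all(m@vc4 <= 1e-10))
  expect_equal(as.numeric(predictGblup(m, crosses(f)[1:3, ])), rep(42, 3))
})

test_that("REML is translation invariant except through the intercept", {
  ds <- simulateDataset(simulationConfig(n1 = 10, n2 = 5, n_crosses = 40,
    n_markers = 60, architecture = "marker-driven", seed = 37))
  G1 <- vanRadenG(imputeMarkers(ds$panel1))$G
  G2 <- vanRadenG(imputeMarkers(ds$panel2))$G
  a <- fitGblup(ds$factorial, G1, G2)
  b <- fitGblup(Factorial(transform(crosses(ds$factorial), yield = yield + 17)),
                G1, G2)
  expect_equal(b@beta0, a@beta0 + 17, tolerance = 1e-4)
  expect_equal(b@vc4, a@vc4, tolerance = 1e-3)
})

test_that("parents missing from the kernels are rejected by name", {
  ds <- simulateDataset(simulationConfig(n1 = 5, n2 = 4, n_crosses = 12,
    n_markers = 30, seed = 3))
  G1 <- vanRadenG(imputeMarkers(ds$panel1))$G
  G2 <- vanRadenG(imputeMarkers(ds$panel2))$G
  m <- fitGblup(ds$factorial, G1, G2)
  expect_error(predictGblup(m, data.frame(parent1 = "L099", parent2 = "T001")),
               "L099")
})
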