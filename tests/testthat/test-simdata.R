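test_that("a full-size request returns the complete factorial", {
  d <- sampleCrossingDesign(5, 4, 20, skew = 0, seed = 1)
  expect_equal(nrow(d), 20)
  expect_equal(anyDuplicated(paste(d$parent1, d$parent2)), 0L)
  expect_equal(as.integer(table(d$parent1)), rep(4L, 5))
  expect_equal(as.integer(table(d$parent2)), rep(5L, 4))
})

test_that("minimal designs cover every parent with distinct pairs", {
  d <- sampleCrossingDesign(3, 2, 3, skew = 0, seed = 1)
  expect_equal(nrow(d), 3)
  expect_equal(anyDuplicated(paste(d$parent1, d$parent2)), 0L)
  expect_setequal(unique(d$parent1), c("L001", "L002", "L003"))
  expect_setequal(unique(d$parent2), c("T001", "T002"))
})

test_that("design sampling is deterministic under a fixed seed", {
  d1 <- sampleCrossingDesign(12, 5, 30, skew = 1.2, seed = 42)
  d2 <- sampleCrossingDesign(12, 5, 30, skew = 1.2, seed = 42)
  expect_identical(d1, d2)
})

test_that("infeasible cross counts are rejected with the violated bound", {
  expect_error(sampleCrossingDesign(5, 4, 3, seed = 1), ">= max")
  expect_error(simulationConfig(n1 = 3, n2 = 3, n_crosses = 10), "n1\\*n2")
})

test_that("design validity and skew behaviour hold across seeds", {
  cvs <- sapply(c(0, 2.5), function(sk) {
    median(sapply(1:8, function(s) {
      d <- sampleCrossingDesign(30, 10, 90, skew = sk, seed = s)
      expect_equal(nrow(d), 90)
      expect_equal(anyDuplicated(paste(d$parent1, d$parent2)), 0L)
      expect_length(unique(d$parent1), 30)
      expect_length(unique(d$parent2), 10)
      cnt <- table(d$parent1)
      sd(cnt) / mean(cnt)
    }))
  })
  # larger skew => larger coefficient of variation of per-parent counts
  expect_gt(cvs[2], cvs[1])
})

test_that("the additive-only limit reproduces yields exactly", {
  cfg <- simulationConfig(n1 = 8, n2 = 4, n_crosses = 20, sigma2_sca = 0,
                          sigma2_e = 0, n_markers = 0, seed = 9)
  sim <- simulateFactorial(cfg)
  cr <- crosses(sim$factorial)
  resid <- cr$yield - sim$effects$mu -
    sim$effects$gca1[cr$parent1] - sim$effects$gca2[cr$parent2]
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("drawn GCA effects have the configured variance (chi-square bounds)", {
  cfg <- simulationConfig(n1 = 60, n2 = 20, n_crosses = 600,
                          sigma2_gca1 = 1, sigma2_gca2 = 1, sigma2_sca = 1,
                          sigma2_e = 1, n_markers = 0, seed = 7)
  sim <- simulateFactorial(cfg)
  # sample variance of 60 iid N(0,1) draws lies in [0.6, 1.5] with ~99% cover
  expect_gt(var(sim$effects$gca1), 0.6)
  expect_lt(var(sim$effects$gca1), 1.5)
})

test_that("a complete configured factorial reports fraction realized 1", {
  cfg <- simulationConfig(n1 = 5, n2 = 4, n_crosses = 20, n_markers = 0,
                          seed = 2)
  sim <- simulateFactorial(cfg)
  expect_equal(describeFactorial(sim$factorial)$fractionRealized, 1.0)
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- simulationConfig(n1 = 10, n2 = 4, n_crosses = 30, n_markers = 25,
                          architecture = "marker-driven", seed = 31)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(a, b)
})

test_that("marker panels are homozygous codes with frequencies in range", {
  cfg <- simulationConfig(n1 = 15, n2 = 6, n_crosses = 45, n_markers = 40,
                          maf_range = c(0.2, 0.4), seed = 5)
  ds <- simulateDataset(cfg)
  g <- genotypes(ds$panel1)
  expect_true(all(g %in% c(-1, 1)))
  expect_equal(dim(g), c(15, 40))
})

test_that("marker-driven effects match the configured variances", {
  cfg <- simulationConfig(n1 = 60, n2 = 20, n_crosses = 600, n_markers = 200,
                          sigma2_gca1 = 1, sigma2_gca2 = 0.5, sigma2_sca = 2,
                          architecture = "marker-driven", seed = 13)
  ds <- simulateDataset(cfg)
  expect_lt(abs(var(ds$effects$gca1) - 1) / 1, 0.1)
  expect_lt(abs(var(ds$effects$gca2) - 0.5) / 0.5, 0.1)
  expect_lt(abs(var(ds$effects$sca) - 2) / 2, 0.1)
  # and the decomposition still holds exactly on the regenerated yields
  cr <- crosses(ds$factorial)
  resid <- cr$yield - ds$effects$mu - ds$effects$gca1[cr$parent1] -
    ds$effects$gca2[cr$parent2] -
    ds$effects$sca[pairKey_(cr$parent1, cr$parent2)] -
    ds$effects$e[pairKey_(cr$parent1, cr$parent2)]
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("zero SCA under marker-driven forces zero dominance deviations", {
  cfg <- simulationConfig(n1 = 20, n2 = 8, n_crosses = 80, n_markers = 50,
                          sigma2_sca = 0, architecture = "marker-driven",
                          seed = 3)
  ds <- simulateDataset(cfg)
  expect_true(all(ds$effects$sca == 0))
})

test_that("too few markers for the marker-driven architecture error out", {
  cfg <- simulationConfig(n1 = 10, n2 = 4, n_crosses = 30, n_markers = 5,
                          architecture = "marker-driven", seed = 1)
  sim <- simulateFactorial(cfg)
  expect_error(simulateMarkers(cfg, sim), "at least 10 markers")
})

test_that("effects-direct panels carry no signal about the true GCA", {
  # leave-one-out kernel regression of the true GCA on the VanRaden
  # kernel; informative only when effects derive from the markers
  looKernelCor <- function(ds) {
    G <- vanRadenG(imputeMarkers(ds$panel1))$G + diag(1e-6, 60)
    g <- ds$effects$gca1
    pred <- vapply(seq_along(g), function(i) {
      as.numeric(G[i, -i] %*% solve(G[-i, -i] + diag(0.5, 59), g[-i]))
    }, 0)
    cor(pred, g)
  }
  base <- list(n1 = 60, n2 = 20, n_crosses = 600, n_markers = 100, seed = 17)
  dsNull <- simulateDataset(do.call(simulationConfig,
    c(base, architecture = "effects-direct")))
  dsInf <- simulateDataset(do.call(simulationConfig,
    c(base, architecture = "marker-driven")))
  expect_lt(abs(looKernelCor(dsNull)), 0.5)
  expect_gt(looKernelCor(dsInf), 0.5)
})
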