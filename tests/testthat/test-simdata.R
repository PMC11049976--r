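test_that("marker generation respects the inbred limit and is deterministic", {
  cfg <- simConfig(nGenotypes = 30, nMarkers = 60, nSites = 2,
                   residualHetRate = 0, missingRate = 0, seed = 4)
  m1 <- simulateMarkers(cfg)
  expect_true(all(markerValues(m1) %in% c(-1, 1)))
  m2 <- simulateMarkers(cfg)
  expect_identical(markerValues(m1), markerValues(m2))

  cfgH <- simConfig(nGenotypes = 200, nMarkers = 50, nSites = 2,
                    residualHetRate = 0.3, missingRate = 0.2, seed = 4)
  mh <- markerValues(simulateMarkers(cfgH))
  expect_true(any(mh == 0, na.rm = TRUE))
  expect_true(anyNA(mh))
})

test_that("empirical minor-allele frequency matches the binomial draw", {
  ## p = 0.3 for every marker; SE of the empirical frequency is
  ## sqrt(0.3 * 0.7 / n) per marker
  n <- 2000
  cfg <- simConfig(nGenotypes = n, nMarkers = 40, nSites = 2,
                   mafLow = 0.3, mafHigh = 0.3, residualHetRate = 0,
                   missingRate = 0, seed = 12)
  x <- markerValues(simulateMarkers(cfg))
  pEmp <- colMeans(x == -1)
  se <- sqrt(0.3 * 0.7 / n)
  expect_true(all(abs(pEmp - 0.3) < 3 * se))
})

test_that("missingness mask does not perturb the drawn codes", {
  cfgA <- simConfig(nGenotypes = 25, nMarkers = 40, nSites = 2,
                    missingRate = 0, seed = 9)
  cfgB <- simConfig(nGenotypes = 25, nMarkers = 40, nSites = 2,
                    missingRate = 0.3, seed = 9)
  a <- markerValues(simulateMarkers(cfgA))
  b <- markerValues(simulateMarkers(cfgB))
  obs <- !is.na(b)
  expect_identical(a[obs], b[obs])
  ## ground-truth genetic values are also independent of the mask
  ta <- simulateGeneticValues(MarkerMatrix(a), cfgA)
  tb <- simulateDataset(cfgB)$truth
  expect_equal(ta@geneticValues, tb@geneticValues)
})

test_that("genetic-value decomposition and degenerate limits hold", {
  sim <- smallSim(seed = 3)
  tr <- sim$truth
  expect_equal(tr@geneticValues, tr@additiveValues + tr@epistaticValues)
  expect_true(all(tr@epistaticValues == 0))   # no epistatic pairs by default

  cfg0 <- simConfig(nGenotypes = 30, nMarkers = 50, nSites = 2,
                    loadings = matrix(0, 2, 1), psi = c(0, 0),
                    missingRate = 0, seed = 5)
  tr0 <- simulateDataset(cfg0)$truth
  expect_true(all(tr0@geneticValues == 0))

  cfgE <- simConfig(nGenotypes = 40, nMarkers = 100, nSites = 2,
                    nQtlPairsEpi = 10, missingRate = 0, seed = 6)
  trE <- simulateDataset(cfgE)$truth
  expect_gt(stats::sd(trE@epistaticValues), 0)
  expect_equal(trE@geneticValues, trE@additiveValues + trE@epistaticValues)
})

test_that("between-site correlation of true genetic values follows LL' + Psi", {
  ## q = 1, Lambda = (1, 0.8), Psi = diag(0.2): the implied correlation is
  ## (LL')[1,2] / sqrt((LL'+Psi)[1,1] (LL'+Psi)[2,2])
  L <- matrix(c(1, 0.8), 2, 1)
  psi <- c(0.2, 0.2)
  S <- tcrossprod(L) + diag(psi)
  rTheory <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  cfg <- simConfig(nGenotypes = 500, nMarkers = 300, nSites = 2,
                   loadings = L, psi = psi, missingRate = 0, seed = 8)
  g <- simulateDataset(cfg)$truth@geneticValues
  expect_lt(abs(stats::cor(g[, 1], g[, 2]) - rTheory), 0.08)
})

test_that("trial records have the stated structure and noiseless limit", {
  cfg <- simConfig(nGenotypes = 162, nMarkers = 100, nSites = 6,
                   missingRate = 0, seed = 2)
  sim <- simulateDataset(cfg)
  expect_equal(nrow(sim$phenotypes), 162 * 6 * 2)

  cfg0 <- simConfig(nGenotypes = 20, nMarkers = 50, nSites = 3,
                    repVar = 0, resVar = 0, missingRate = 0, seed = 2)
  sim0 <- simulateDataset(cfg0)
  ph <- sim0$phenotypes
  i <- match(ph$genotype, rownames(sim0$truth@geneticValues))
  j <- match(ph$site, colnames(sim0$truth@geneticValues))
  expect_equal(ph$yield,
               cfg0@siteMeans[j] + sim0$truth@geneticValues[cbind(i, j)])
})

test_that("per-site variance of genotype means matches the ANOVA expectation", {
  ## cell means average n_rep plot residuals; replicate effects are shared by
  ## every genotype within a site and so do not enter the across-genotype
  ## variance: E[var_i(ybar_ij)] = (LL'+Psi)_jj + resVar_j / nReps
  cfg <- simConfig(nGenotypes = 1500, nMarkers = 200, nSites = 3,
                   missingRate = 0, seed = 31)
  sim <- simulateDataset(cfg)
  ov <- observedValues(sim$phenotypes, center = FALSE)
  S <- sim$truth@siteCovariance
  for (j in 1:3) {
    expected <- S[j, j] + cfg@resVar[j] / cfg@nReps
    ## var of the sample variance of n normals ~ 2 sigma^4 / n
    se <- sqrt(2 / cfg@nGenotypes) * expected
    expect_lt(abs(stats::var(ov[, j]) - expected), 4 * se)
  }
})

test_that("simulation round-trips through the plain-text writer", {
  sim <- smallSim(seed = 13, missingRate = 0.1)
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  m2 <- readMarkersCSV(file.path(dir, "markers.csv"))
  expect_equal(markerValues(m2), markerValues(sim$markers))
  p2 <- readPhenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(p2$yield, sim$phenotypes$yield, tolerance = 1e-12)
})
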