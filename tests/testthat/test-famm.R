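oneSiteData <- function(seed = 11, n = 18, r = 2, s2g = 0.4, s2e = 0.5,
                        mu = 5) {
  set.seed(seed)
  g <- rnorm(n, 0, sqrt(s2g))
  data.frame(genotype = rep(paste0("g", seq_len(n)), each = r),
             site = "S1", rep = rep(seq_len(r), n),
             yield = mu + rep(g, each = r) + rnorm(n * r, 0, sqrt(s2e)))
}

test_that("restricted likelihood matches the balanced one-way closed form", {
  d <- oneSiteData()
  spec <- modelSpec(identityKernel(unique(d$genotype)), includeReps = FALSE)
  for (vals in list(c(0.4, 0.5), c(0.1, 1.2), c(2.0, 0.3))) {
    params <- list(fa = list(list(loadings = matrix(sqrt(vals[1] / 2)),
                                  specificVars = vals[1] / 2)),
                   repVars = 0, resVars = vals[2])
    expect_equal(-2 * remlLoglik(params, d, spec),
                 onewayREMLminus2ll(d$yield, d$genotype, vals[1], vals[2]),
                 tolerance = 1e-8)
  }
})

test_that("REML scale equivariance: scaling y by c and variances by c^2
           shifts -2 loglik by (N - rank X) log c^2", {
  sim <- smallSim(seed = 19, nGenotypes = 12, nSites = 2)
  d <- sim$phenotypes
  spec <- modelSpec(completeKernel(sim))
  params <- list(fa = list(list(loadings = matrix(c(0.3, 0.25), 2),
                                specificVars = c(0.05, 0.08))),
                 repVars = c(0.02, 0.04), resVars = c(0.2, 0.25))
  cc <- 2.5
  d2 <- d; d2$yield <- d$yield * cc
  params2 <- params
  params2$fa[[1]]$loadings <- params$fa[[1]]$loadings * cc
  params2$fa[[1]]$specificVars <- params$fa[[1]]$specificVars * cc^2
  params2$repVars <- params$repVars * cc^2
  params2$resVars <- params$resVars * cc^2
  N <- nrow(d); s <- 2
  expect_equal(-2 * remlLoglik(params2, d2, spec),
               -2 * remlLoglik(params, d, spec) + (N - s) * log(cc^2),
               tolerance = 1e-8)
})

test_that("zero genetic and replicate variance reduces to independent
           site-mean normals", {
  sim <- smallSim(seed = 23, nGenotypes = 10, nSites = 3)
  d <- sim$phenotypes
  spec <- modelSpec(completeKernel(sim))
  resv <- c(0.3, 0.4, 0.5)
  params <- list(fa = list(list(loadings = matrix(0, 3, 1),
                                specificVars = rep(0, 3))),
                 repVars = rep(0, 3), resVars = resv)
  sites <- sort(unique(d$site))
  ## direct REML of independent normals with per-site fixed means
  m2 <- 0
  for (j in seq_along(sites)) {
    yj <- d$yield[d$site == sites[j]]
    nj <- length(yj)
    m2 <- m2 + (nj - 1) * log(2 * pi) + nj * log(resv[j]) +
      log(nj / resv[j]) + sum((yj - mean(yj))^2) / resv[j]
  }
  expect_equal(-2 * remlLoglik(params, d, spec), m2, tolerance = 1e-8)
})

test_that("collapsed engine likelihood equals the record-level restricted
           likelihood at arbitrary parameter points", {
  sim <- smallSim(seed = 29, nGenotypes = 14, nSites = 3)
  GA <- completeKernel(sim)
  GG <- epistaticKernel(GA)
  spec <- modelSpec(list(GA, GG), faOrder = c(2, 1))
  prep <- metGP:::.prepCells(sim$phenotypes)
  str <- metGP:::.thetaStructure(spec, prep$sites, prep$nRep, TRUE)
  setup <- metGP:::.engineSetup(prep, spec)
  set.seed(1)
  for (i in 1:5) {
    th <- runif(str$nPar, -2, 0.5)
    pr <- metGP:::.unpackParams(th, str)
    eng <- metGP:::.engineEval(th, setup, str, "fn")
    rec <- metGP:::.minus2llRecords(pr, sim$phenotypes, spec,
                                    siteLevels = prep$sites)
    expect_equal(eng, rec, tolerance = 1e-10)
  }
})

test_that("fitted variance components agree with lme4 on a one-site
           identity-kernel design", {
  skip_if_not_installed("lme4")
  d <- oneSiteData(seed = 31, n = 40, r = 2)
  spec <- modelSpec(identityKernel(unique(d$genotype)), includeReps = FALSE)
  fit <- fitFAMM(d, spec, nRestarts = 2, seed = 1)
  lm4 <- lme4::lmer(yield ~ 1 + (1 | genotype), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  s2gHat <- sum(faLoadings(fit)^2) + specificVars(fit)
  expect_equal(unname(s2gHat), vc$vcov[1], tolerance = 1e-3)
  expect_equal(unname(fit@resVars), vc$vcov[2], tolerance = 1e-3)
  expect_equal(unname(fit@fixedEffects), lme4::fixef(lm4)[[1]],
               tolerance = 1e-4)
})

test_that("single-site FA+G BLUPs match Henderson-equation GBLUP at the
           fitted variances", {
  cfg <- simConfig(nGenotypes = 30, nMarkers = 150, nSites = 1,
                   loadings = matrix(0.5), psi = 0.05, repVar = 0,
                   missingRate = 0, seed = 37)
  sim <- simulateDataset(cfg)
  GA <- completeKernel(sim)
  spec <- modelSpec(GA, includeReps = FALSE)
  fit <- fitFAMM(sim$phenotypes, spec, nRestarts = 2, seed = 2)
  s2g <- unname(sum(faLoadings(fit)^2) + specificVars(fit))
  s2e <- unname(fit@resVars)
  d <- sim$phenotypes
  mme <- hendersonGBLUP(d$yield, match(d$genotype, genotypeIds(GA)),
                        kernelMatrix(GA), s2g, s2e)
  blup <- blupValues(fit)[genotypeIds(GA), 1]
  expect_equal(unname(blup), unname(mme$u), tolerance = 1e-6)
  expect_equal(unname(fit@fixedEffects), unname(mme$beta), tolerance = 1e-6)
})

test_that("BLUPs shrink cell means toward zero with an identity kernel", {
  d <- oneSiteData(seed = 41, n = 25, r = 2)
  spec <- modelSpec(identityKernel(unique(d$genotype)), includeReps = FALSE)
  fit <- fitFAMM(d, spec, nRestarts = 1, seed = 3)
  obs <- observedValues(d)[, 1]
  u <- blupValues(fit)[names(obs), 1]
  expect_true(all(abs(u) <= abs(obs) + 1e-8))
  expect_true(all(u * obs >= -1e-8))
})

test_that("permuting record order leaves the fit invariant", {
  sim <- smallSim(seed = 43, nGenotypes = 15, nSites = 2)
  spec <- modelSpec(completeKernel(sim))
  f1 <- fitFAMM(sim$phenotypes, spec, nRestarts = 1, seed = 4)
  set.seed(8)
  d2 <- sim$phenotypes[sample(nrow(sim$phenotypes)), ]
  f2 <- fitFAMM(d2, spec, nRestarts = 1, seed = 4)
  expect_equal(f1@remlLoglik, f2@remlLoglik, tolerance = 1e-6)
  expect_equal(blupValues(f1), blupValues(f2), tolerance = 1e-4)
})

test_that("kernel-based prediction flows zero information through zero
           covariance and equal information through equal rows", {
  sim <- smallSim(seed = 47, nGenotypes = 12, nSites = 2)
  GA <- kernelMatrix(completeKernel(sim))
  n <- nrow(GA)
  ids <- rownames(GA)
  ## append one genotype with zero covariance to everyone, and two unphenotyped
  ## copies of genotype 1
  big <- matrix(0, n + 3, n + 3)
  big[1:n, 1:n] <- GA
  big[n + 1, n + 1] <- mean(diag(GA))
  big[n + 2, ] <- c(GA[1, ], 0, GA[1, 1], GA[1, 1])
  big[, n + 2] <- big[n + 2, ]
  big[n + 3, ] <- c(GA[1, ], 0, GA[1, 1], GA[1, 1])
  big[, n + 3] <- big[n + 3, ]
  big[n + 2, n + 2] <- big[n + 3, n + 3] <- GA[1, 1]
  big[n + 2, n + 3] <- big[n + 3, n + 2] <- GA[1, 1]
  dimnames(big) <- list(c(ids, "zeroCov", "twinA", "twinB"),
                        c(ids, "zeroCov", "twinA", "twinB"))
  k <- stabilizeKernel(new("GenomicKernel", matrix = big, kind = "additive"))
  fit <- fitFAMM(sim$phenotypes, modelSpec(k), nRestarts = 1, seed = 5)
  pred <- predictGeneticValues(fit, c("zeroCov", "twinA", "twinB"))
  expect_equal(unname(pred["zeroCov", ]), c(0, 0), tolerance = 1e-10)
  expect_equal(pred["twinA", ], pred["twinB", ], tolerance = 1e-8)
  ## requesting fitted cells reproduces the stored BLUP matrix
  expect_identical(predictGeneticValues(fit, ids), blupValues(fit)[ids, ])
  expect_error(predictGeneticValues(fit, "nosuch"), "unknown genotype")
})

test_that("fittedSiteCovariance returns Delta Delta' + D and stays PSD", {
  fa <- list(list(loadings = matrix(c(1, 0.8), 2, 1),
                  specificVars = c(0.2, 0.2), kernel = "additive"))
  fit <- new("FAModelFit", modelName = "FA+G", sites = c("S1", "S2"),
             genotypeIds = "g1", fixedEffects = c(S1 = 0, S2 = 0), fa = fa,
             repVars = c(S1 = 0, S2 = 0), resVars = c(S1 = 1, S2 = 1),
             blup = list(), remlLoglik = 0, converged = TRUE, nIter = 0L,
             predictor = list())
  expect_equal(unname(fittedSiteCovariance(fit)),
               matrix(c(1.2, 0.8, 0.8, 0.84), 2, 2))

  sim <- smallSim(seed = 53, nGenotypes = 12, nSites = 3)
  f <- fitFAMM(sim$phenotypes, modelSpec(completeKernel(sim)),
               nRestarts = 1, seed = 6)
  S <- fittedSiteCovariance(f)
  expect_equal(S, t(S))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("model specification guards its preconditions", {
  sim <- smallSim(seed = 59, nGenotypes = 10, nSites = 2)
  GA <- completeKernel(sim)
  expect_error(fitFAMM(sim$phenotypes, modelSpec(GA, faOrder = 3)),
               "faOrder")
  expect_error(modelSpec(list(GA, GA, GA)), "kernel terms")
  d <- sim$phenotypes
  d$genotype[1] <- "intruder"
  expect_error(fitFAMM(d, modelSpec(GA)), "absent from the kernel")
})
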