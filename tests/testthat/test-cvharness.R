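gids <- function(n) sprintf("g%03d", seq_len(n))
sites6 <- paste0("S", 1:6)

test_that("CV1 fold plans split genotypes evenly and cover everyone once", {
  plan <- makeFolds("CV1", gids(162), sites6, nFolds = 5, seed = 1)
  sizes <- vapply(plan@testSets, function(d) length(unique(d$genotype)), 1L)
  expect_equal(sort(unname(sizes)), c(32L, 32L, 32L, 33L, 33L))
  expect_lte(max(sizes) - min(sizes), 1L)
  allTest <- unlist(lapply(plan@testSets, function(d) unique(d$genotype)))
  expect_false(anyDuplicated(allTest) > 0)
  expect_setequal(allTest, gids(162))
  ## every test genotype is masked at every site
  expect_true(all(vapply(plan@masks,
                         function(d) all(table(d$genotype) == 6L), TRUE)))

  tiny <- makeFolds("CV1", gids(5), sites6, nFolds = 5, seed = 1)
  expect_true(all(vapply(tiny@testSets,
                         function(d) length(unique(d$genotype)), 1L) == 1L))
})

test_that("CV2 masks a proper site subset and rejects degenerate choices", {
  plan <- makeFolds("CV2", gids(162), sites6, nFolds = 5, seed = 2,
                    maskedSites = c("S1", "S4", "S6"))
  for (f in 1:5) {
    expect_setequal(unique(plan@masks[[f]]$site), c("S1", "S4", "S6"))
  }
  expect_error(makeFolds("CV2", gids(10), sites6, maskedSites = sites6),
               "proper subset")
  expect_error(makeFolds("CV2", gids(10), sites6,
                         maskedSites = character(0)), "non-empty")
  ## default rotation masks ceiling(s/2) sites, differing across folds
  rot <- makeFolds("CV2", gids(60), sites6, nFolds = 5, seed = 3)
  maskSites <- lapply(rot@masks, function(d) sort(unique(d$site)))
  expect_true(all(lengths(maskSites) == 3L))
  expect_gt(length(unique(maskSites)), 1L)
})

test_that("CV3 keeps the stated focal-site training size in a single fold", {
  plan <- makeFolds("CV3", gids(162), sites6, seed = 4,
                    focalSite = "S1", nTrainFocal = 20)
  expect_equal(plan@nFolds, 1L)
  ts <- plan@testSets[[1]]
  expect_equal(length(unique(ts$genotype)), 142L)
  expect_equal(unique(ts$site), "S1")
  expect_error(makeFolds("CV3", gids(10), sites6, focalSite = "nope"),
               "focalSite")
})

test_that("masking removes exactly the planned records", {
  sim <- smallSim(seed = 61, nGenotypes = 162, nSites = 6, nMarkers = 50)
  d <- sim$phenotypes
  plan <- makeFolds("CV1", sort(unique(d$genotype)), sites6, seed = 5)
  f <- which(vapply(plan@testSets,
                    function(x) length(unique(x$genotype)), 1L) == 32L)[1]
  train <- maskRecords(d, plan, f)
  expect_equal(nrow(train), 130 * 6 * 2)

  plan2 <- makeFolds("CV2", sort(unique(d$genotype)), sites6, seed = 5,
                     maskedSites = c("S1", "S4", "S6"))
  f2 <- which(vapply(plan2@testSets,
                     function(x) length(unique(x$genotype)), 1L) == 32L)[1]
  train2 <- maskRecords(d, plan2, f2)
  expect_equal(nrow(d) - nrow(train2), 32 * 3 * 2)

  empty <- plan
  slot(empty, "masks", check = FALSE) <-
    rep(list(data.frame(genotype = character(0), site = character(0))), 5)
  expect_identical(maskRecords(d, empty, 1), d)
})

test_that("observed values are replicate means centred by site means", {
  d <- data.frame(genotype = c("a", "a", "b", "b"),
                  site = "S1", rep = c(1, 2, 1, 2),
                  yield = c(5, 6, 4, 5))
  ov <- observedValues(d)
  siteMean <- mean(c(5.5, 4.5))
  expect_equal(ov["a", "S1"], 5.5 - siteMean)
  expect_equal(ov["b", "S1"], 4.5 - siteMean)
  expect_equal(observedValues(d, center = FALSE)["a", "S1"], 5.5)
  ## record order does not matter
  expect_equal(observedValues(d[c(3, 1, 4, 2), ]), ov)

  ## noiseless simulation reproduces the truth up to a per-site constant
  cfg <- simConfig(nGenotypes = 15, nMarkers = 40, nSites = 2,
                   repVar = 0, resVar = 0, missingRate = 0, seed = 67)
  sim <- simulateDataset(cfg)
  ov2 <- observedValues(sim$phenotypes)
  tr <- sim$truth@geneticValues[rownames(ov2), colnames(ov2)]
  for (j in 1:2)
    expect_lt(max(abs((ov2[, j] - tr[, j]) - mean(ov2[, j] - tr[, j]))), 1e-10)
})

test_that("accuracy computes per-site Pearson correlations with guards", {
  pred <- cbind(S1 = c(1, 2, 3, 4))
  rownames(pred) <- gids(4)
  obs <- cbind(S1 = c(2, 1, 4, 3))
  rownames(obs) <- gids(4)
  cells <- data.frame(genotype = gids(4), site = "S1")
  expect_equal(cvAccuracy(pred, obs, cells)$pearson_r, 0.6)
  expect_equal(cvAccuracy(pred, pred, cells)$pearson_r, 1)
  neg <- -pred
  rownames(neg) <- gids(4)
  expect_equal(cvAccuracy(pred, neg, cells)$pearson_r, -1)
  expect_warning(r0 <- cvAccuracy(pred * 0, obs, cells), "zero variance")
  expect_true(is.na(r0$pearson_r))
  expect_warning(r1 <- cvAccuracy(pred, obs, cells[1:2, ]), "fewer than")
  expect_true(is.na(r1$pearson_r))
})

test_that("runCV is reproducible, leak-free and reports fold accuracies", {
  cfg <- simConfig(nGenotypes = 40, nMarkers = 200, nSites = 3,
                   missingRate = 0.05, seed = 71)
  sim <- simulateDataset(cfg)
  args <- list(data = sim$phenotypes, markers = sim$markers, scheme = "CV1",
               modelNames = "FA+G", nFolds = 4, seed = 9,
               fitArgs = list(nRestarts = 1, maxIter = 100, pgtol = 0.05))
  r1 <- suppressWarnings(do.call(runCV, args))
  r2 <- suppressWarnings(do.call(runCV, args))
  expect_identical(r1@accuracy, r2@accuracy)
  expect_identical(r1@summary, r2@summary)
  expect_equal(nrow(r1@accuracy), 4 * 3)   # folds x sites
  expect_true(all(r1@accuracy$n_test >= 3))
  expect_true(all(abs(r1@accuracy$pearson_r) <= 1, na.rm = TRUE))
})

test_that("CV2 via runCV rejects masking all sites", {
  sim <- smallSim(seed = 73, nGenotypes = 20, nSites = 2, nMarkers = 50)
  expect_error(
    runCV(sim$phenotypes, sim$markers, "CV2",
          maskedSites = c("S1", "S2"), seed = 1),
    "proper subset")
})
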