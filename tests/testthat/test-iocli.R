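test_that("phenotype CSV round-trips and rejects malformed input", {
  sim <- smallSim(seed = 81, nGenotypes = 8, nSites = 2, nMarkers = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  writePhenotypes(sim$phenotypes, path)
  back <- readPhenotypes(path)
  expect_equal(back$yield, sim$phenotypes$yield, tolerance = 1e-12)
  expect_equal(nrow(back), nrow(sim$phenotypes))

  dup <- rbind(sim$phenotypes, sim$phenotypes[1, ])
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup, p2, row.names = FALSE)
  expect_error(readPhenotypes(p2), "duplicate")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("genotype,site,yield\na,S1,5.0", p3)
  expect_error(readPhenotypes(p3), "lacks column")
})

test_that("VCF genotypes map to the numeric coding with multi-allelic
           records skipped", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL1\tL2\tL3",
    "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t./.",
    "1\t300\tsnpC\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2",
    "1\t400\tsnpD\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_message(mm <- readMarkersVCF(path), "multi-allelic")
  v <- markerValues(mm)
  expect_equal(dim(v), c(3L, 3L))
  expect_equal(unname(v[, "snpA"]), c(1, 0, -1))
  expect_equal(unname(v[, "snpB"]), c(-1, 1, NA))
  expect_equal(unname(v[, "snpD"]), c(1, 1, 0))
})

test_that("runConfig merges file and overrides, rejecting unknown fields", {
  cfg <- runConfig(seed = 9, minMaf = 0.1)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$minMaf, 0.1)
  expect_equal(cfg$maxMissing, 0.40)
  expect_equal(cfg$nFolds, 5)
  expect_error(runConfig(bogus = 1), "unknown config field")
  if (requireNamespace("yaml", quietly = TRUE)) {
    f <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("scheme: CV2", "nFolds: 4"), f)
    cfg2 <- runConfig(file = f, seed = 2)
    expect_equal(cfg2$scheme, "CV2")
    expect_equal(cfg2$nFolds, 4)
    expect_equal(cfg2$seed, 2)
  }
})

test_that("cli pipeline simulate -> qc -> kernel runs and logs QC counts", {
  dir <- withr::local_tempdir()
  simdir <- file.path(dir, "sim")
  expect_equal(cliMain(c("simulate", "--out", simdir, "--seed", "3",
                        "--n-genotypes", "40", "--n-markers", "120",
                        "--n-sites", "3")), 0L)
  expect_true(file.exists(file.path(simdir, "markers.csv")))
  expect_true(file.exists(file.path(simdir, "phenotypes.csv")))

  qcdir <- file.path(dir, "qc")
  code <- suppressWarnings(cliMain(c("qc", "--markers",
                                     file.path(simdir, "markers.csv"),
                                     "--out", qcdir)))
  expect_equal(code, 0L)
  log <- readLines(file.path(qcdir, "run_log.txt"))
  expect_true(any(grepl("qcFilter", log)))
  expect_true(any(grepl("imputeEM", log)))

  kdir <- file.path(dir, "kernel")
  expect_equal(cliMain(c("kernel", "--markers",
                         file.path(qcdir, "markers_qc.csv"),
                         "--out", kdir)), 0L)
  g <- readKernelCSV(file.path(kdir, "kernel_additive.csv"))
  gg <- readKernelCSV(file.path(kdir, "kernel_epistatic.csv"),
                      kind = "epistatic")
  expect_equal(kernelMatrix(gg), kernelMatrix(g)^2, tolerance = 1e-10)
})

test_that("cli surfaces usage errors with nonzero exit codes", {
  expect_gt(suppressMessages(cliMain(character(0))), 0L)
  expect_gt(suppressMessages(cliMain("frobnicate")), 0L)
  expect_gt(suppressMessages(cliMain(c("qc", "--nope"))), 0L)
  dir <- withr::local_tempdir()
  ## CV2 masking every site is a usage error surfaced through the CLI
  simdir <- file.path(dir, "sim")
  cliMain(c("simulate", "--out", simdir, "--seed", "5",
            "--n-genotypes", "25", "--n-markers", "80", "--n-sites", "3"))
  code <- suppressMessages(suppressWarnings(
    cliMain(c("cv", "--markers", file.path(simdir, "markers.csv"),
              "--phenotypes", file.path(simdir, "phenotypes.csv"),
              "--scheme", "CV2",
              "--masked-sites", paste(paste0("S", 1:6), collapse = ","),
              "--out", file.path(dir, "cv")))))
  expect_gt(code, 0L)
})

test_that("qc log counts a half-missing marker against the missingness rule", {
  set.seed(2)
  n <- 30
  good <- matrix(sample(c(-1, 1), n * 5, replace = TRUE), n, 5)
  bad <- sample(c(-1, 1), n, replace = TRUE)
  bad[sample(n, 15)] <- NA                   # exactly 50% missing
  m <- cbind(good, bad)
  dimnames(m) <- list(sprintf("g%02d", 1:n), paste0("m", 1:6))
  dir <- withr::local_tempdir()
  mpath <- file.path(dir, "markers.csv")
  writeMarkersCSV(MarkerMatrix(m), mpath)
  code <- suppressWarnings(cliMain(c("qc", "--markers", mpath,
                                     "--out", dir)))
  expect_equal(code, 0L)
  log <- readLines(file.path(dir, "run_log.txt"))
  qcline <- grep("qcFilter", log, value = TRUE)
  expect_true(grepl("1 removed by missingness", qcline))
})
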