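#' @include AllClasses.R kernels.R cv.R
NULL

#' Read and write the long phenotype table
#'
#' The phenotype CSV has header \code{genotype,site,rep,yield}; yields are
#' grain yield in t/ha. Duplicate (genotype, site, rep) keys, missing
#' columns and non-numeric yields are rejected with the offending rows
#' named.
#'
#' @param path CSV file.
#' @return \code{readPhenotypes}: validated data.frame;
#'   \code{writePhenotypes}: the path, invisibly.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "site", "rep", "yield")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(df$yield)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$yield))))
    stop("non-numeric yield at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  .assertPhenotypes(df[need])
}

#' @rdname readPhenotypes
#' @param data phenotype data.frame.
#' @export
writePhenotypes <- function(data, path) {
  utils::write.csv(data[c("genotype", "site", "rep", "yield")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write marker matrices as CSV
#'
#' Rows are genotypes (ids in the first column), columns are markers; cells
#' hold the \{1, 0, -1\} codes (fractional after imputation) with empty
#' cells for missing calls.
#'
#' @param path CSV file.
#' @param imputed mark the matrix as imputed on read.
#' @return \code{readMarkersCSV}: a \linkS4class{MarkerMatrix};
#'   \code{writeMarkersCSV}: the path, invisibly.
#' @export
readMarkersCSV <- function(path, imputed = FALSE) {
  m <- .readMatrixCSV(path)
  MarkerMatrix(m, imputed = imputed)
}

#' @rdname readMarkersCSV
#' @param markers a \linkS4class{MarkerMatrix}.
#' @export
writeMarkersCSV <- function(markers, path) {
  m <- markerValues(markers)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read biallelic SNPs from a VCF into marker codes
#'
#' Maps GT fields of biallelic SNP records to the numeric coding
#' (REF-hom 1, het 0, ALT-hom -1, missing NA); the minor-allele flip is
#' applied later by \code{\link{alleleFrequencies}}. Multi-allelic records
#' are skipped with a logged count. Requires the \pkg{vcfR} package.
#'
#' @param path VCF file (plain or gzipped).
#' @return a \linkS4class{MarkerMatrix} (genotypes x markers).
#' @export
readMarkersVCF <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readMarkersVCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"])
  nskip <- sum(!biallelic)
  if (nskip) message(nskip, " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- 1
    out[g %in% c("0/1", "1/0")] <- 0
    out[g %in% c("1/1")] <- -1
    out
  }
  m <- apply(gt, 2, code)
  rownames(m) <- rownames(gt)
  MarkerMatrix(t(m))
}

#' Assemble a run configuration
#'
#' Collects the pipeline settings (paths, QC thresholds, model list, CV
#' scheme and options, seeds) with the standard defaults: 40\% maximum
#' marker missingness, 5\% minimum MAF, 5 folds. A YAML file may supply any
#' subset of the fields; explicit arguments override it.
#'
#' @param file optional YAML configuration file.
#' @param ... named overrides of any configuration field.
#' @return a named list of settings with class \code{"metGPConfig"}.
#' @export
runConfig <- function(file = NULL, ...) {
  cfg <- list(markers = NULL, phenotypes = NULL, outDir = ".",
              maxMissing = 0.40, minMaf = 0.05,
              models = "FA+G", faOrder = 1, scheme = "CV1", nFolds = 5,
              maskedSites = NULL, focalSite = NULL, nTrainFocal = 20,
              seed = 1, imputeRank = NULL, imputeTol = 1e-4,
              stabilizeEps = 1e-6)
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    user <- yaml::read_yaml(file)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$maxMissing >= 0, cfg$maxMissing <= 1,
            cfg$minMaf >= 0, cfg$minMaf <= 1)
  structure(cfg, class = "metGPConfig")
}

.logLines <- function(dir, lines) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file.path(dir, "run_log.txt")
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), lines, "\n"),
      file = con, append = TRUE, sep = "")
}

.checksum <- function(path) unname(tools::md5sum(path))

#' Command-line entry point
#'
#' Thin, scriptable front end over the package pipeline. Subcommands:
#' \code{simulate} (write a synthetic dataset), \code{qc} (filter + impute a
#' marker panel), \code{kernel} (write additive/epistatic kernels),
#' \code{fit} (fit one model and write its summary), \code{cv} (run a
#' cross-validation experiment) and \code{report} (echo a run log). Every
#' run directory receives a log with input checksums, the seed and QC
#' counts. Returns (rather than calls) the exit code so the function is
#' testable; the installed script \code{inst/scripts/metgp} wraps it with
#' \code{quit(status = ...)}.
#'
#' @param argv character vector of command-line arguments, e.g.
#'   \code{c("simulate", "--out", "simdir", "--seed", "7")}.
#' @return integer exit code, 0 on success.
#' @export
cliMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: metgp <simulate|qc|kernel|fit|cv|report> [options]",
    "  common: --config FILE --seed N --out DIR",
    "  simulate: --n-genotypes N --n-markers N --n-sites N",
    "  data:   --markers FILE --phenotypes FILE",
    "  cv:     --scheme CV1|CV2|CV3 --models A,B --folds N",
    "          --masked-sites a,b --focal-site s --n-train-focal N",
    sep = "\n")
  fail <- function(msg) { message("error: ", msg, "\n", usage); 2L }
  if (!length(argv)) return(fail("no subcommand"))
  cmd <- argv[1]
  if (!cmd %in% c("simulate", "qc", "kernel", "fit", "cv", "report"))
    return(fail(paste("unknown subcommand:", cmd)))

  opts <- list(); i <- 2L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) return(fail(paste("unexpected argument:", a)))
    if (i + 1L > length(argv)) return(fail(paste("missing value for", a)))
    opts[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  get <- function(k, default = NULL) if (!is.null(opts[[k]])) opts[[k]] else default

  out <- tryCatch({
    cfg <- runConfig(file = get("config"))
    if (!is.null(get("seed"))) cfg$seed <- as.integer(get("seed"))
    if (!is.null(get("markers"))) cfg$markers <- get("markers")
    if (!is.null(get("phenotypes"))) cfg$phenotypes <- get("phenotypes")
    if (!is.null(get("out"))) cfg$outDir <- get("out")
    if (!is.null(get("scheme"))) cfg$scheme <- get("scheme")
    if (!is.null(get("models")))
      cfg$models <- strsplit(get("models"), ",")[[1]]
    if (!is.null(get("folds"))) cfg$nFolds <- as.integer(get("folds"))
    if (!is.null(get("masked-sites")))
      cfg$maskedSites <- strsplit(get("masked-sites"), ",")[[1]]
    if (!is.null(get("focal-site"))) cfg$focalSite <- get("focal-site")
    if (!is.null(get("n-train-focal")))
      cfg$nTrainFocal <- as.integer(get("n-train-focal"))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

    switch(cmd,
      simulate = {
        simArgs <- list(seed = cfg$seed)
        if (!is.null(get("n-genotypes")))
          simArgs$nGenotypes <- as.integer(get("n-genotypes"))
        if (!is.null(get("n-markers")))
          simArgs$nMarkers <- as.integer(get("n-markers"))
        if (!is.null(get("n-sites")))
          simArgs$nSites <- as.integer(get("n-sites"))
        sim <- simulateDataset(do.call(simConfig, simArgs))
        writeSimulation(sim, cfg$outDir)
        .logLines(cfg$outDir, c(paste("simulate seed", cfg$seed),
          paste("markers md5", .checksum(file.path(cfg$outDir, "markers.csv")))))
      },
      qc = {
        if (is.null(cfg$markers)) stop("qc requires --markers")
        mm <- readMarkersCSV(cfg$markers)
        mm <- qcFilter(mm, cfg$maxMissing, cfg$minMaf)
        mm <- imputeEM(mm, tol = cfg$imputeTol, rank = cfg$imputeRank)
        writeMarkersCSV(mm, file.path(cfg$outDir, "markers_qc.csv"))
        .logLines(cfg$outDir, c(paste("qc input md5", .checksum(cfg$markers)),
                                unlist(mm@qcLog)))
      },
      kernel = {
        if (is.null(cfg$markers)) stop("kernel requires --markers")
        mm <- readMarkersCSV(cfg$markers, imputed = TRUE)
        GA <- additiveKernel(mm)
        writeKernelCSV(GA, file.path(cfg$outDir, "kernel_additive.csv"))
        writeKernelCSV(epistaticKernel(GA),
                       file.path(cfg$outDir, "kernel_epistatic.csv"))
        .logLines(cfg$outDir, paste("kernel input md5", .checksum(cfg$markers)))
      },
      fit = {
        if (is.null(cfg$markers) || is.null(cfg$phenotypes))
          stop("fit requires --markers and --phenotypes")
        mm <- readMarkersCSV(cfg$markers)
        mm <- qcFilter(mm, cfg$maxMissing, cfg$minMaf)
        mm <- imputeEM(mm, tol = cfg$imputeTol, rank = cfg$imputeRank)
        ph <- readPhenotypes(cfg$phenotypes)
        GA <- stabilizeKernel(additiveKernel(mm), cfg$stabilizeEps)
        fit <- fitFAMM(ph, modelSpec(GA, faOrder = cfg$faOrder),
                       seed = cfg$seed)
        writeFitSummary(fit, cfg$outDir)
        .logLines(cfg$outDir, c(
          paste("fit", fit@modelName, "loglik",
                format(fit@remlLoglik, digits = 10),
                if (fit@converged) "converged" else "NOT-converged")))
      },
      cv = {
        if (is.null(cfg$markers) || is.null(cfg$phenotypes))
          stop("cv requires --markers and --phenotypes")
        mm <- readMarkersCSV(cfg$markers)
        ph <- readPhenotypes(cfg$phenotypes)
        res <- runCV(ph, mm, scheme = cfg$scheme, modelNames = cfg$models,
                     nFolds = cfg$nFolds, seed = cfg$seed,
                     maskedSites = cfg$maskedSites,
                     focalSite = cfg$focalSite,
                     nTrainFocal = cfg$nTrainFocal, faOrder = cfg$faOrder)
        utils::write.csv(res@accuracy,
                         file.path(cfg$outDir, "accuracy.csv"),
                         row.names = FALSE)
        utils::write.csv(res@summary,
                         file.path(cfg$outDir, "accuracy_summary.csv"),
                         row.names = FALSE)
        .logLines(cfg$outDir, c(
          paste("cv", cfg$scheme, "seed", cfg$seed, "models",
                paste(cfg$models, collapse = ",")),
          paste("markers md5", .checksum(cfg$markers)),
          paste("phenotypes md5", .checksum(cfg$phenotypes))))
      },
      report = {
        log <- file.path(cfg$outDir, "run_log.txt")
        if (!file.exists(log)) stop("no run_log.txt in ", cfg$outDir)
        writeLines(readLines(log))
      })
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  out
}

#' Write a fitted-model summary bundle
#'
#' Writes the fixed-effect table, per-term loadings and specific variances,
#' the variance-component table, the BLUP matrix and convergence metadata as
#' plain CSV/text files.
#'
#' @param fit an \linkS4class{FAModelFit}.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
writeFitSummary <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "fixed_effects.csv")
  utils::write.csv(data.frame(site = fit@sites, effect = fit@fixedEffects),
                   f1, row.names = FALSE)
  fs <- character(0)
  for (t in seq_along(fit@fa)) {
    ft <- file.path(dir, sprintf("fa_term%d_%s.csv", t, fit@fa[[t]]$kernel))
    utils::write.csv(data.frame(site = fit@sites, fit@fa[[t]]$loadings,
                                specific_var = fit@fa[[t]]$specificVars),
                     ft, row.names = FALSE)
    fs <- c(fs, ft)
  }
  f2 <- file.path(dir, "variance_components.csv")
  utils::write.csv(data.frame(site = fit@sites, rep_var = fit@repVars,
                              res_var = fit@resVars),
                   f2, row.names = FALSE)
  f3 <- file.path(dir, "blup_total.csv")
  .writeMatrixCSV(fit@blup$total, f3)
  f4 <- file.path(dir, "fit_meta.txt")
  writeLines(c(paste("model:", fit@modelName),
               paste("reml_loglik:", format(fit@remlLoglik, digits = 12)),
               paste("converged:", fit@converged),
               paste("n_iter:", fit@nIter)), f4)
  invisible(c(f1, fs, f2, f3, f4))
}
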