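#' @include AllClasses.R
NULL

## Independent RNG streams derived from the master seed, so that e.g. the
## missingness mask can change without perturbing marker codes or genetic
## effects. Stream seeds are fixed offsets folded into 31 bits.
.streamSeed <- function(seed, stream) {
  offs <- c(codes = 101L, missing = 211L, effects = 307L, noise = 401L)
  as.integer((as.numeric(seed) * 7919 + offs[[stream]]) %% 2147483646) + 1L
}

.withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.streamSeed(seed, stream))
  expr
}

#' Configure the synthetic multi-environment trial generator
#'
#' Builds a validated \linkS4class{SimConfig}. Defaults emulate one target
#' population of environments of a South-Asian bread-wheat trial series:
#' 162 inbred lines, six sites with mean yields near 5.9 t/ha, two replicates
#' per site, a single latent environmental factor giving moderate-to-strong
#' between-site genetic correlations, and line-mean heritability around 0.6.
#'
#' @param nGenotypes,nMarkers,nSites,nReps panel and trial dimensions.
#' @param mafLow,mafHigh minor-allele frequency bounds in (0, 0.5].
#' @param residualHetRate probability a call is heterozygous.
#' @param missingRate probability a call is set missing.
#' @param nQtlAdd,nQtlPairsEpi number of additive QTL / epistatic QTL pairs;
#'   by default 120 additive QTL, reduced to a third of small panels.
#' @param epiVarFrac fraction of latent factor-score variance contributed by
#'   the epistatic pairs when \code{nQtlPairsEpi > 0}.
#' @param loadings true site x q loading matrix; default a single factor with
#'   site-varying loadings around 0.4.
#' @param psi site-specific genetic variances; default 0.06.
#' @param siteMeans fixed site means in t/ha.
#' @param repVar,resVar per-site replicate and plot-residual variances
#'   (scalars are recycled).
#' @param seed master seed for all generator streams.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenotypes = 50, nMarkers = 200, nSites = 3, seed = 1)
#' cfg
#' @export
simConfig <- function(nGenotypes = 162, nMarkers = 1500, nSites = 6,
                      nReps = 2, mafLow = 0.05, mafHigh = 0.5,
                      residualHetRate = 0.02, missingRate = 0.10,
                      nQtlAdd = NULL, nQtlPairsEpi = 0, epiVarFrac = 0.3,
                      loadings = NULL, psi = NULL, siteMeans = NULL,
                      repVar = 0.04, resVar = 0.20, seed = 1) {
  nSites <- as.integer(nSites)
  ## default: 120 additive QTL, or a third of a small panel
  if (is.null(nQtlAdd)) nQtlAdd <- min(120L, max(1L, nMarkers %/% 3))
  if (is.null(loadings)) {
    base <- rep_len(c(1.1, 0.7, 0.9, 1.2, 1.0, 0.8), nSites)
    loadings <- matrix(0.4 * base, ncol = 1)
  }
  loadings <- as.matrix(loadings)
  if (is.null(psi)) psi <- rep(0.06, nSites)
  if (is.null(siteMeans))
    siteMeans <- 5.88 + seq(-0.4, 0.4, length.out = nSites)
  new("SimConfig",
      nGenotypes = as.integer(nGenotypes), nMarkers = as.integer(nMarkers),
      nSites = nSites, nReps = as.integer(nReps),
      mafLow = mafLow, mafHigh = mafHigh,
      residualHetRate = residualHetRate, missingRate = missingRate,
      nQtlAdd = as.integer(nQtlAdd), nQtlPairsEpi = as.integer(nQtlPairsEpi),
      epiVarFrac = epiVarFrac, loadings = loadings, psi = as.numeric(psi),
      siteMeans = as.numeric(siteMeans),
      repVar = rep_len(as.numeric(repVar), nSites),
      resVar = rep_len(as.numeric(resVar), nSites),
      seed = as.integer(seed))
}

.simGenotypeIds <- function(config) sprintf("G%03d", seq_len(config@nGenotypes))
.simMarkerIds   <- function(config) sprintf("M%04d", seq_len(config@nMarkers))
.simSiteIds     <- function(config) sprintf("S%d", seq_len(config@nSites))

## Complete (no-missing) code matrix; the released matrix is this plus a mask.
.simCodes <- function(config) {
  n <- config@nGenotypes; m <- config@nMarkers
  .withStream(config@seed, "codes", {
    p <- runif(m, config@mafLow, config@mafHigh)
    x <- matrix(ifelse(matrix(runif(n * m), n, m) < rep(p, each = n), -1, 1),
                n, m)
    if (config@residualHetRate > 0)
      x[matrix(runif(n * m), n, m) < config@residualHetRate] <- 0
    dimnames(x) <- list(.simGenotypeIds(config), .simMarkerIds(config))
    x
  })
}

.simMask <- function(config) {
  if (config@missingRate <= 0) return(NULL)
  n <- config@nGenotypes; m <- config@nMarkers
  .withStream(config@seed, "missing",
    matrix(runif(n * m), n, m) < config@missingRate)
}

#' Simulate an inbred SNP marker panel
#'
#' Per marker a minor-allele frequency is drawn uniformly in
#' \code{[mafLow, mafHigh]}; each genotype is homozygous major (code 1) with
#' probability \eqn{1-p_j} and homozygous minor (code -1) with probability
#' \eqn{p_j}, a small fraction of calls is flipped to heterozygous (code 0),
#' and calls are set missing independently. Fully reproducible under the
#' config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{MarkerMatrix} (possibly with missing calls).
#' @examples
#' mm <- simulateMarkers(simConfig(nGenotypes = 20, nMarkers = 50, seed = 3))
#' table(markerValues(mm), useNA = "ifany")
#' @export
simulateMarkers <- function(config) {
  x <- .simCodes(config)
  mask <- .simMask(config)
  if (!is.null(mask)) x[mask] <- NA_real_
  MarkerMatrix(x)
}

#' Simulate true genetic values from causal markers
#'
#' Draws additive QTL and epistatic QTL pairs from the marker panel. For each
#' latent factor k the genotype factor score is a linear combination of the
#' additive QTL codes plus (optionally) products of the paired QTL codes,
#' whitened across factors so the genotype-level covariance of
#' \eqn{\Lambda \delta_i} equals \eqn{\Lambda\Lambda'} exactly in-sample. A
#' site-specific deviation with variance \eqn{\psi_j} completes the
#' factor-analytic truth \eqn{\Lambda\Lambda' + \Psi}; it is generated
#' independently of the epistatic pairs and counted with the additive
#' component, so the additive + epistatic decomposition is exact.
#'
#' @param markers a complete (no missing calls) \linkS4class{MarkerMatrix};
#'   use \code{missingRate = 0} or \code{\link{imputeEM}} first.
#' @param config the \linkS4class{SimConfig} used to generate \code{markers}.
#' @return a \linkS4class{SimTruth}.
#' @export
simulateGeneticValues <- function(markers, config) {
  x <- markerValues(markers)
  if (anyNA(x))
    stop("markers must be complete (no missing calls); impute first")
  n <- nrow(x); m <- ncol(x)
  q <- ncol(config@loadings)
  if (config@nQtlAdd > m)
    stop("nQtlAdd exceeds the number of markers")
  if (2L * config@nQtlPairsEpi > m)
    stop("nQtlPairsEpi requires more markers than available")
  sites <- .simSiteIds(config)

  .withStream(config@seed, "effects", {
    addIdx <- sort(sample.int(m, config@nQtlAdd))
    nep <- config@nQtlPairsEpi
    epiPairs <- if (nep > 0)
      matrix(sample.int(m, 2L * nep), ncol = 2) else
      matrix(integer(0), ncol = 2)
    addEff <- matrix(rnorm(config@nQtlAdd * q), ncol = q)
    epiEff <- matrix(rnorm(nep * q), ncol = q)

    A <- x[, addIdx, drop = FALSE] %*% addEff              # n x q raw additive
    P <- if (nep > 0)
      (x[, epiPairs[, 1], drop = FALSE] *
       x[, epiPairs[, 2], drop = FALSE]) %*% epiEff else
      matrix(0, n, q)

    A <- scale(A, center = TRUE, scale = FALSE)
    P <- scale(P, center = TRUE, scale = FALSE)
    f <- if (nep > 0) config@epiVarFrac else 0
    sdA <- apply(A, 2, stats::sd); sdA[sdA == 0] <- 1
    A <- sweep(A, 2, sdA, "/") * sqrt(1 - f)
    if (f > 0) {
      sdP <- apply(P, 2, stats::sd); sdP[sdP == 0] <- 1
      P <- sweep(P, 2, sdP, "/") * sqrt(f)
    } else P[] <- 0
    delta <- A + P
    ## whiten factor scores so cov(delta) = I exactly; the same linear map is
    ## applied to both components, preserving the decomposition
    W <- backsolve(chol(stats::cov(delta)), diag(q))
    A <- A %*% W; P <- P %*% W

    d <- matrix(rnorm(n * config@nSites), n) %*%
      diag(sqrt(config@psi), config@nSites)
    gAdd <- A %*% t(config@loadings) + d
    gEpi <- P %*% t(config@loadings)
    dimnames(gAdd) <- dimnames(gEpi) <- list(rownames(x), sites)

    Sigma <- tcrossprod(config@loadings) +
      diag(config@psi, config@nSites)
    dimnames(Sigma) <- list(sites, sites)
    new("SimTruth", geneticValues = gAdd + gEpi, additiveValues = gAdd,
        epistaticValues = gEpi, siteCovariance = Sigma,
        qtl = list(addIndices = addIdx, addEffects = addEff,
                   epiPairs = epiPairs, epiEffects = epiEff))
  })
}

#' Simulate replicated multi-site trial phenotypes
#'
#' One record per genotype x site x replicate:
#' \code{yield = siteMean + repEffect + geneticValue + residual}, with
#' replicate effects drawn once per (site, replicate) and plot residuals per
#' record.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param config the matching \linkS4class{SimConfig}.
#' @return a phenotype data.frame with columns
#'   \code{genotype, site, rep, yield} (the long "phenotype table" format
#'   used throughout the package).
#' @export
simulateTrial <- function(truth, config) {
  g <- truth@geneticValues
  if (nrow(g) != config@nGenotypes || ncol(g) != config@nSites)
    stop("truth and config dimensions disagree")
  sites <- .simSiteIds(config)
  .withStream(config@seed, "noise", {
    repEff <- matrix(rnorm(config@nSites * config@nReps), config@nSites) *
      sqrt(config@repVar)
    rec <- expand.grid(genotype = rownames(g), site = sites,
                       rep = seq_len(config@nReps),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    j <- match(rec$site, sites); i <- match(rec$genotype, rownames(g))
    rec$yield <- config@siteMeans[j] + repEff[cbind(j, rec$rep)] +
      g[cbind(i, j)] + rnorm(nrow(rec)) * sqrt(config@resVar[j])
    rec
  })
}

#' Simulate a complete dataset: markers, truth and phenotypes
#'
#' Convenience wrapper tying the generator together. Genetic values are
#' computed from the complete (pre-missingness) marker codes; the released
#' marker matrix carries the missing-call mask.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{markers} (masked
#'   \linkS4class{MarkerMatrix}), \code{markersComplete}, \code{truth}
#'   (\linkS4class{SimTruth}), \code{phenotypes} (data.frame) and
#'   \code{config}.
#' @examples
#' sim <- simulateDataset(simConfig(nGenotypes = 30, nMarkers = 100,
#'                                  nSites = 3, seed = 11))
#' head(sim$phenotypes)
#' @export
simulateDataset <- function(config) {
  complete <- MarkerMatrix(.simCodes(config))
  truth <- simulateGeneticValues(complete, config)
  pheno <- simulateTrial(truth, config)
  x <- markerValues(complete)
  mask <- .simMask(config)
  if (!is.null(mask)) x[mask] <- NA_real_
  list(markers = MarkerMatrix(x), markersComplete = complete,
       truth = truth, phenotypes = pheno, config = config)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the marker matrix (rows = genotypes, cells in \{-1,0,1\} or empty
#' for missing), the long phenotype table, the truth matrices and a metadata
#' file echoing the configuration.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("markers.csv", "phenotypes.csv",
                        "truth_genetic_values.csv", "truth_additive.csv",
                        "truth_epistatic.csv", "truth_site_covariance.csv",
                        "sim_config.txt"))
  writeMarkersCSV(sim$markers, f[1])
  writePhenotypes(sim$phenotypes, f[2])
  .writeMatrixCSV(sim$truth@geneticValues, f[3])
  .writeMatrixCSV(sim$truth@additiveValues, f[4])
  .writeMatrixCSV(sim$truth@epistaticValues, f[5])
  .writeMatrixCSV(sim$truth@siteCovariance, f[6])
  cfg <- sim$config
  slots <- slotNames(cfg)
  meta <- vapply(slots, function(s)
    paste(format(slot(cfg, s), digits = 15), collapse = ","), "")
  writeLines(paste0(slots, ": ", meta), f[7])
  invisible(f)
}
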