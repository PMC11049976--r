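#' MarkerMatrix: coded SNP genotypes
#'
#' Genotype-by-marker matrix of biallelic SNP codes. Before imputation every
#' non-missing entry is 1 (homozygous for the major allele), 0 (heterozygous)
#' or -1 (homozygous for the minor allele), with \code{NA} marking missing
#' calls. After EM imputation entries are real-valued dosages in
#' \eqn{[-1, 1]} and no missing entries remain.
#'
#' @slot values numeric matrix, rows named by genotype, columns by marker.
#' @slot imputed logical; \code{TRUE} once missing calls have been imputed.
#' @slot qcLog list of messages recording QC/imputation steps applied.
#' @export
setClass("MarkerMatrix",
  representation(values = "matrix", imputed = "logical", qcLog = "list"),
  prototype(imputed = FALSE, qcLog = list()))

setValidity("MarkerMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("'values' must have genotype rownames and marker colnames")
  if (anyDuplicated(rownames(v))) return("genotype ids must be unique")
  if (anyDuplicated(colnames(v))) return("marker ids must be unique")
  ok <- v[!is.na(v)]
  if (isTRUE(object@imputed)) {
    if (anyNA(v)) return("imputed matrix must not contain missing values")
    if (length(ok) && (min(ok) < -1 - 1e-9 || max(ok) > 1 + 1e-9))
      return("imputed codes must lie in [-1, 1]")
  } else if (length(ok) && !all(ok %in% c(-1, 0, 1))) {
    return("non-missing codes must be in {-1, 0, 1} before imputation")
  }
  TRUE
})

#' Construct a MarkerMatrix
#'
#' @param values numeric genotype x marker matrix with dimnames.
#' @param imputed logical flag, see \linkS4class{MarkerMatrix}.
#' @return a \linkS4class{MarkerMatrix}.
#' @examples
#' m <- MarkerMatrix(matrix(c(1, -1, 1, 0), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("m1", "m2"))))
#' genotypeIds(m)
#' @export
MarkerMatrix <- function(values, imputed = FALSE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%04d", seq_len(ncol(values)))
  new("MarkerMatrix", values = values, imputed = imputed)
}

#' AlleleFrequencySet: per-marker allele frequencies and centering constants
#'
#' Minor-allele frequencies \eqn{p_j \le 0.5} together with the
#' Hardy-Weinberg centering constants \eqn{\mu_{Ej} = 1 - 2 p_j} and the
#' additive-kernel denominator \eqn{2 \sum_j p_j (1 - p_j)}. Markers whose
#' observed frequency of the coded allele exceeded 0.5 are flagged as flipped;
#' kernel construction negates those columns so the coding always refers to
#' the minor allele.
#'
#' @slot freq named numeric vector of minor-allele frequencies.
#' @slot centering named numeric vector \eqn{1 - 2 p_j}.
#' @slot denom scalar \eqn{2 \sum_j p_j (1 - p_j)}.
#' @slot flipped named logical vector; \code{TRUE} where codes were negated.
#' @export
setClass("AlleleFrequencySet",
  representation(freq = "numeric", centering = "numeric", denom = "numeric",
                 flipped = "logical"))

setValidity("AlleleFrequencySet", function(object) {
  p <- object@freq
  if (length(p) && (min(p) < -1e-12 || max(p) > 0.5 + 1e-12))
    return("minor-allele frequencies must lie in [0, 0.5]")
  if (length(object@centering) != length(p))
    return("centering must match freq in length")
  if (length(p) && max(abs(object@centering - (1 - 2 * p))) > 1e-9)
    return("centering must equal 1 - 2*p")
  if (length(object@flipped) != length(p))
    return("flipped must match freq in length")
  TRUE
})

#' GenomicKernel: genotype relationship matrix
#'
#' Symmetric positive semi-definite genotype-by-genotype relationship matrix:
#' the identity, the VanRaden-type additive matrix
#' \eqn{G_A = (X-\mu_E)(X-\mu_E)'/2\sum p_j(1-p_j)}, or its Hadamard square
#' \eqn{G_A \circ G_A} modelling additive-by-additive epistasis.
#'
#' @slot matrix symmetric numeric matrix with matching row/col genotype names.
#' @slot kind one of \code{"identity"}, \code{"additive"}, \code{"epistatic"}.
#' @slot stabilizationEps ridge actually added to the diagonal (0 if none).
#' @export
setClass("GenomicKernel",
  representation(matrix = "matrix", kind = "character",
                 stabilizationEps = "numeric"),
  prototype(stabilizationEps = 0))

setValidity("GenomicKernel", function(object) {
  m <- object@matrix
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("kernel must have identical genotype row and column names")
  if (anyDuplicated(rownames(m))) return("genotype ids must be unique")
  if (nrow(m) && max(abs(m - t(m))) > 1e-10)
    return("kernel must be symmetric to within 1e-10")
  if (!object@kind %in% c("identity", "additive", "epistatic"))
    return("kind must be identity, additive or epistatic")
  if (object@stabilizationEps < 0) return("stabilizationEps must be >= 0")
  TRUE
})

#' SimConfig: synthetic multi-environment trial configuration
#'
#' Parameters of the synthetic wheat-trial generator: an inbred panel of
#' mostly homozygous SNP genotypes, a set of sites with latent-factor
#' genotype-by-environment structure, and replicated plot-level yields.
#' Defaults emulate a South-Asian bread-wheat trial series: 162 lines, six
#' sites with mean yields around 5.9 t/ha, two replicates per site, and
#' between-site genetic correlations in the 0.4-0.8 range.
#'
#' @slot nGenotypes,nMarkers,nSites,nReps panel and trial dimensions.
#' @slot mafLow,mafHigh bounds of the uniform minor-allele frequency draw.
#' @slot residualHetRate probability a call is heterozygous (inbred: small).
#' @slot missingRate probability a call is set missing.
#' @slot nQtlAdd,nQtlPairsEpi number of additive QTL and epistatic QTL pairs.
#' @slot epiVarFrac fraction of factor-score variance contributed by the
#'   epistatic pairs (used only when \code{nQtlPairsEpi > 0}).
#' @slot loadings true site x q latent-factor loading matrix \eqn{\Lambda}.
#' @slot psi site-specific genetic variances (diagonal of \eqn{\Psi}).
#' @slot siteMeans fixed site effects, t/ha.
#' @slot repVar,resVar per-site replicate and plot-residual variances.
#' @slot seed master seed; independent streams for marker codes, missingness,
#'   genetic effects and trial noise are derived from it, so e.g. changing
#'   \code{missingRate} does not perturb the genetic values.
#' @export
setClass("SimConfig",
  representation(nGenotypes = "integer", nMarkers = "integer",
    nSites = "integer", nReps = "integer", mafLow = "numeric",
    mafHigh = "numeric", residualHetRate = "numeric", missingRate = "numeric",
    nQtlAdd = "integer", nQtlPairsEpi = "integer", epiVarFrac = "numeric",
    loadings = "matrix", psi = "numeric", siteMeans = "numeric",
    repVar = "numeric", resVar = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nGenotypes < 2L) return("need at least 2 genotypes")
  if (object@nMarkers < 1L) return("need at least 1 marker")
  if (object@nSites < 1L) return("need at least 1 site")
  if (object@nReps < 1L) return("nReps must be >= 1")
  if (object@mafLow <= 0 || object@mafHigh > 0.5 ||
      object@mafLow > object@mafHigh)
    return("require 0 < mafLow <= mafHigh <= 0.5")
  if (object@residualHetRate < 0 || object@residualHetRate >= 1)
    return("residualHetRate must be in [0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must be in [0, 1)")
  if (object@nQtlAdd < 1L) return("nQtlAdd must be >= 1")
  if (object@nQtlPairsEpi < 0L) return("nQtlPairsEpi must be >= 0")
  if (object@epiVarFrac < 0 || object@epiVarFrac >= 1)
    return("epiVarFrac must be in [0, 1)")
  if (nrow(object@loadings) != object@nSites)
    return("loadings must have nSites rows")
  if (length(object@psi) != object@nSites)
    return("psi must have nSites entries")
  if (any(object@psi < 0)) return("psi entries must be >= 0")
  if (length(object@siteMeans) != object@nSites)
    return("siteMeans must have nSites entries")
  if (length(object@repVar) != object@nSites ||
      length(object@resVar) != object@nSites)
    return("repVar and resVar must have nSites entries")
  if (any(object@repVar < 0) || any(object@resVar < 0))
    return("variance parameters must be >= 0")
  TRUE
})

#' SimTruth: ground truth of a synthetic trial
#'
#' True genotype-by-site genetic values and their exact decomposition into
#' additive and additive-by-additive epistatic contributions, the site
#' covariance \eqn{\Lambda\Lambda' + \Psi} used for generation, and the causal
#' marker model (QTL indices and effects).
#'
#' @slot geneticValues,additiveValues,epistaticValues genotype x site matrices
#'   with \code{geneticValues == additiveValues + epistaticValues} exactly.
#' @slot siteCovariance true sites x sites genetic covariance.
#' @slot qtl list with elements \code{addIndices}, \code{addEffects},
#'   \code{epiPairs} (2-column matrix), \code{epiEffects}.
#' @export
setClass("SimTruth",
  representation(geneticValues = "matrix", additiveValues = "matrix",
    epistaticValues = "matrix", siteCovariance = "matrix", qtl = "list"))

setValidity("SimTruth", function(object) {
  if (max(abs(object@geneticValues -
              (object@additiveValues + object@epistaticValues))) > 1e-10)
    return("geneticValues must equal additiveValues + epistaticValues")
  sc <- object@siteCovariance
  if (max(abs(sc - t(sc))) > 1e-10) return("siteCovariance must be symmetric")
  if (min(eigen(sc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    return("siteCovariance must be positive semi-definite")
  TRUE
})

#' FAModelSpec: which mixed model to fit
#'
#' Selects the kernel terms and factor-analytic order of the
#' multi-environment model. The four named variants are FA (identity kernel),
#' FA+G (additive kernel), FA+GG (epistatic kernel) and FA+G+GG (both).
#'
#' @slot kernels list of one or two \linkS4class{GenomicKernel} objects.
#' @slot faOrder integer vector, FA order q of each kernel term.
#' @slot includeReps logical; fit per-site replicate variances.
#' @slot modelName display name derived from the kernel kinds.
#' @export
setClass("FAModelSpec",
  representation(kernels = "list", faOrder = "integer",
                 includeReps = "logical", modelName = "character"))

setValidity("FAModelSpec", function(object) {
  nt <- length(object@kernels)
  if (nt < 1L || nt > 2L) return("between 1 and 2 kernel terms required")
  if (!all(vapply(object@kernels, is, TRUE, "GenomicKernel")))
    return("kernels must be GenomicKernel objects")
  if (length(object@faOrder) != nt) return("one faOrder per kernel term")
  if (any(object@faOrder < 1L)) return("faOrder must be >= 1")
  ids <- lapply(object@kernels, function(k) rownames(k@matrix))
  if (nt == 2L && !identical(ids[[1]], ids[[2]]))
    return("kernel terms must share identical genotype ids")
  TRUE
})

#' FAModelFit: fitted factor-analytic multi-environment mixed model
#'
#' REML estimates of the fixed site effects, the factor-analytic loadings and
#' specific variances of each kernel term, the per-site replicate and residual
#' variances, and BLUP genetic values for every genotype-by-site cell
#' (including cells never observed, which are predicted through the kernel).
#'
#' @slot modelName e.g. \code{"FA+G"}.
#' @slot sites,genotypeIds site and genotype universes of the fit.
#' @slot fixedEffects named per-site fixed effects (t/ha).
#' @slot fa per-term list with elements \code{loadings} (sites x q) and
#'   \code{specificVars}.
#' @slot repVars,resVars named per-site variance components.
#' @slot blup list of genotype x site BLUP matrices, one per term plus
#'   \code{$total}.
#' @slot remlLoglik restricted log-likelihood at the optimum.
#' @slot converged,nIter optimizer status.
#' @slot predictor internal state (cell weights and kernels) used by
#'   \code{\link{predictGeneticValues}}.
#' @export
setClass("FAModelFit",
  representation(modelName = "character", sites = "character",
    genotypeIds = "character", fixedEffects = "numeric", fa = "list",
    repVars = "numeric", resVars = "numeric", blup = "list",
    remlLoglik = "numeric", converged = "logical", nIter = "integer",
    predictor = "list"))

#' FoldPlan: cross-validation masking plan
#'
#' Which genotype-by-site cells are removed from training (masks) and scored
#' (test sets) in each fold of a CV1, CV2 or CV3 scheme.
#'
#' @slot scheme \code{"CV1"}, \code{"CV2"} or \code{"CV3"}.
#' @slot nFolds number of folds (always 1 for CV3).
#' @slot masks,testSets per-fold data.frames with columns genotype, site.
#' @slot genotypes,sites the universes the plan was built over.
#' @slot seed integer seed that produced the genotype shuffle.
#' @export
setClass("FoldPlan",
  representation(scheme = "character", nFolds = "integer", masks = "list",
    testSets = "list", genotypes = "character", sites = "character",
    seed = "integer"))

setValidity("FoldPlan", function(object) {
  if (!object@scheme %in% c("CV1", "CV2", "CV3"))
    return("scheme must be CV1, CV2 or CV3")
  if (length(object@masks) != object@nFolds ||
      length(object@testSets) != object@nFolds)
    return("one mask and one test set per fold")
  for (f in seq_len(object@nFolds)) {
    m <- object@masks[[f]]; ts <- object@testSets[[f]]
    key <- function(d) paste(d$genotype, d$site, sep = "\r")
    if (!all(key(ts) %in% key(m)))
      return("every test cell must also be masked")
  }
  TRUE
})
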