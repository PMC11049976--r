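#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "MarkerMatrix", function(x) rownames(x@values))

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "GenomicKernel", function(x) rownames(x@matrix))

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "FAModelFit", function(x) x@genotypeIds)

#' @rdname markerIds
#' @export
setMethod("markerIds", "MarkerMatrix", function(x) colnames(x@values))

#' @rdname markerIds
#' @export
setMethod("markerIds", "AlleleFrequencySet", function(x) names(x@freq))

#' @rdname markerValues
#' @export
setMethod("markerValues", "MarkerMatrix", function(x) x@values)

#' @rdname kernelMatrix
#' @export
setMethod("kernelMatrix", "GenomicKernel", function(x) x@matrix)

#' @rdname kernelKind
#' @export
setMethod("kernelKind", "GenomicKernel", function(x) x@kind)

#' @rdname blupValues
#' @export
setMethod("blupValues", "FAModelFit", function(x, term = "total") {
  if (identical(term, "total")) return(x@blup$total)
  x@blup$terms[[term]]
})

#' @rdname fittedSiteCovariance
#' @export
setMethod("fittedSiteCovariance", "FAModelFit", function(fit, term = 1L) {
  term <- as.integer(term)
  if (term < 1L || term > length(fit@fa))
    stop("invalid kernel term index: ", term)
  L <- fit@fa[[term]]$loadings
  d <- fit@fa[[term]]$specificVars
  S <- tcrossprod(L) + diag(d, nrow = length(d))
  dimnames(S) <- list(fit@sites, fit@sites)
  S
})

#' @rdname faLoadings
#' @export
setMethod("faLoadings", "FAModelFit", function(fit, term = 1L)
  fit@fa[[as.integer(term)]]$loadings)

#' @rdname specificVars
#' @export
setMethod("specificVars", "FAModelFit", function(fit, term = 1L)
  fit@fa[[as.integer(term)]]$specificVars)

#' Minor-allele frequencies
#' @param x an \linkS4class{AlleleFrequencySet}.
#' @return named numeric vector of \eqn{p_j \in [0, 0.5]}.
#' @export
minorFreqs <- function(x) x@freq

#' Kernel denominator \eqn{2\sum_j p_j(1-p_j)}
#' @param x an \linkS4class{AlleleFrequencySet}.
#' @return scalar denominator of the additive relationship matrix.
#' @export
kernelDenom <- function(x) x@denom

setMethod("show", "MarkerMatrix", function(object) {
  v <- object@values
  cat("MarkerMatrix:", nrow(v), "genotypes x", ncol(v), "markers\n")
  cat("  missing calls:", sum(is.na(v)),
      if (object@imputed) " (imputed)" else "", "\n", sep = "")
  if (length(object@qcLog))
    cat("  qc log:", paste(unlist(object@qcLog), collapse = "; "), "\n")
})

setMethod("show", "GenomicKernel", function(object) {
  cat("GenomicKernel (", object@kind, "): ",
      nrow(object@matrix), " genotypes", sep = "")
  if (object@stabilizationEps > 0)
    cat(", diagonal ridge ", format(object@stabilizationEps), sep = "")
  cat("\n  mean diagonal:",
      format(mean(diag(object@matrix)), digits = 4), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenotypes, "genotypes,", object@nMarkers,
      "markers,", object@nSites, "sites x", object@nReps, "reps\n")
  cat("  q =", ncol(object@loadings), "latent factor(s);",
      object@nQtlAdd, "additive QTL,",
      object@nQtlPairsEpi, "epistatic pairs; seed", object@seed, "\n")
})

setMethod("show", "FAModelFit", function(object) {
  cat("FAModelFit:", object@modelName, "over", length(object@sites),
      "sites,", length(object@genotypeIds), "genotypes\n")
  cat("  REML log-likelihood:", format(object@remlLoglik, digits = 8),
      if (object@converged) "(converged," else "(NOT converged,",
      object@nIter, "evaluations)\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", object@scheme, "with", object@nFolds, "fold(s) over",
      length(object@genotypes), "genotypes,",
      length(object@sites), "sites (seed ", object@seed, ")\n")
  sizes <- vapply(object@testSets,
                  function(d) length(unique(d$genotype)), 1L)
  cat("  test genotypes per fold:", paste(sizes, collapse = ", "), "\n")
})
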