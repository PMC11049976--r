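#' @include AllClasses.R
NULL

#' Genotype identifiers of an object
#'
#' @param x a \linkS4class{MarkerMatrix}, \linkS4class{GenomicKernel} or
#'   \linkS4class{FAModelFit}.
#' @return character vector of genotype identifiers.
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' Marker identifiers
#' @param x a \linkS4class{MarkerMatrix} or \linkS4class{AlleleFrequencySet}.
#' @return character vector of marker identifiers.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' Numeric marker codes
#'
#' Genotype-by-marker matrix of numeric codes: 1 homozygous for the major
#' allele, 0 heterozygous, -1 homozygous minor; fractional dosages in
#' \eqn{[-1, 1]} after imputation.
#'
#' @param x a \linkS4class{MarkerMatrix}.
#' @return numeric matrix (genotypes x markers).
#' @export
setGeneric("markerValues", function(x) standardGeneric("markerValues"))

#' Relationship matrix stored in a kernel
#' @param x a \linkS4class{GenomicKernel}.
#' @return symmetric numeric matrix (genotypes x genotypes).
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' Kind of genomic kernel
#' @param x a \linkS4class{GenomicKernel}.
#' @return one of \code{"identity"}, \code{"additive"}, \code{"epistatic"}.
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))

#' BLUP genetic values of a fitted model
#'
#' @param x a \linkS4class{FAModelFit}.
#' @param term \code{"total"} for the sum over kernel terms, or the index of a
#'   single kernel term.
#' @return genotype x site matrix of predicted genetic values.
#' @export
setGeneric("blupValues", function(x, term = "total") standardGeneric("blupValues"))

#' Fitted site-by-site genetic covariance
#'
#' Returns the factor-analytic covariance \eqn{\Delta\Delta' + D} over sites
#' implied by a fitted kernel term.
#'
#' @param fit a \linkS4class{FAModelFit}.
#' @param term index of the kernel term (default 1).
#' @return symmetric sites x sites matrix.
#' @export
setGeneric("fittedSiteCovariance", function(fit, term = 1L)
  standardGeneric("fittedSiteCovariance"))

#' Factor-analytic loadings of a fitted kernel term
#' @param fit a \linkS4class{FAModelFit}.
#' @param term kernel term index.
#' @return sites x q loading matrix.
#' @export
setGeneric("faLoadings", function(fit, term = 1L) standardGeneric("faLoadings"))

#' Site-specific variances of a fitted kernel term
#' @param fit a \linkS4class{FAModelFit}.
#' @param term kernel term index.
#' @return named numeric vector, one entry per site.
#' @export
setGeneric("specificVars", function(fit, term = 1L) standardGeneric("specificVars"))
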