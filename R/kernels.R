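#' @include AllClasses.R markers.R
NULL

#' Identity kernel
#'
#' The identity relationship matrix, used by the plain FA model in which
#' genotype effects are exchangeable (no marker information).
#'
#' @param genotypeIds character vector of genotype identifiers.
#' @return a \linkS4class{GenomicKernel} of kind \code{"identity"}.
#' @export
identityKernel <- function(genotypeIds) {
  n <- length(genotypeIds)
  m <- diag(1, n)
  dimnames(m) <- list(genotypeIds, genotypeIds)
  new("GenomicKernel", matrix = m, kind = "identity")
}

#' Additive genomic relationship matrix
#'
#' VanRaden-type additive kernel
#' \deqn{G_A = (X - \mu_E)(X - \mu_E)' / 2\sum_j p_j (1 - p_j)}
#' where each marker column of the \{1,0,-1\}-coded matrix X is centred by its
#' Hardy-Weinberg expectation \eqn{\mu_{Ej} = 1 - 2 p_j} and the denominator
#' sums over the post-QC markers. Columns flagged as flipped in \code{freqs}
#' are negated first so centring always refers to the minor allele. For fully
#' inbred panels the mean diagonal is close to 2 rather than 1, since inbred
#' lines carry twice the heterozygosity-expected homozygosity; the formula is
#' applied as-is.
#'
#' @param markers an imputed (complete) \linkS4class{MarkerMatrix}.
#' @param freqs optional \linkS4class{AlleleFrequencySet} computed from the
#'   same matrix; computed on the fly when omitted.
#' @return a \linkS4class{GenomicKernel} of kind \code{"additive"}.
#' @examples
#' x <- matrix(c(1, 1, -1, 1, -1, -1, 0, 1, 1, -1, 1, 1), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("m", 1:4)))
#' kernelMatrix(additiveKernel(MarkerMatrix(x, imputed = TRUE)))
#' @export
additiveKernel <- function(markers, freqs = NULL) {
  x <- markerValues(markers)
  if (anyNA(x)) stop("markers must be imputed before kernel construction")
  if (is.null(freqs)) freqs <- alleleFrequencies(markers)
  ids <- markerIds(freqs)
  if (!all(ids %in% colnames(x)))
    stop("freqs refer to markers absent from the matrix")
  x <- x[, ids, drop = FALSE]
  if (any(freqs@flipped))
    x[, freqs@flipped] <- -x[, freqs@flipped, drop = FALSE]
  if (freqs@denom <= 0)
    stop("kernel denominator 2*sum(p(1-p)) is not positive; ",
         "all markers are monomorphic")
  w <- sweep(x, 2, freqs@centering)
  g <- tcrossprod(w) / freqs@denom
  g <- (g + t(g)) / 2
  new("GenomicKernel", matrix = g, kind = "additive")
}

#' First-order additive-by-additive epistatic kernel
#'
#' The Hadamard (cell-by-cell) product of the additive kernel with itself,
#' \eqn{G_A \circ G_A}, i.e. the elementwise square. No rescaling is applied.
#' By the Schur product theorem the result of squaring a PSD matrix is PSD.
#'
#' @param g an additive (or identity) \linkS4class{GenomicKernel}.
#' @return a \linkS4class{GenomicKernel}; kind \code{"epistatic"} (the
#'   identity maps to itself).
#' @export
epistaticKernel <- function(g) {
  if (!kernelKind(g) %in% c("additive", "identity"))
    stop("epistatic kernel is defined from the additive kernel")
  new("GenomicKernel", matrix = g@matrix * g@matrix,
      kind = if (kernelKind(g) == "identity") "identity" else "epistatic")
}

#' Stabilize a kernel for mixed-model inversion
#'
#' Adds \code{eps} to every diagonal element if (and only if) the minimum
#' eigenvalue is below 1e-8, recording the ridge actually applied. With
#' \code{eps = 0} a singular kernel is returned unchanged with a warning.
#'
#' @param g a \linkS4class{GenomicKernel}.
#' @param eps ridge to add (default 1e-6).
#' @return a \linkS4class{GenomicKernel} with \code{stabilizationEps} set.
#' @export
stabilizeKernel <- function(g, eps = 1e-6) {
  stopifnot(eps >= 0)
  ev <- min(eigen(g@matrix, symmetric = TRUE, only.values = TRUE)$values)
  if (ev >= 1e-8) return(g)
  if (eps == 0) {
    warning("kernel is numerically singular (min eigenvalue ",
            format(ev, digits = 3), ") and eps = 0; returned unchanged")
    return(g)
  }
  out <- g
  out@matrix <- g@matrix + diag(eps, nrow(g@matrix))
  dimnames(out@matrix) <- dimnames(g@matrix)
  out@stabilizationEps <- g@stabilizationEps + eps
  out
}

.writeMatrixCSV <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.readMatrixCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a genomic kernel as CSV
#'
#' Genotype ids appear as both the header row and the first column; the
#' round trip is lossless to well below 1e-12.
#'
#' @param g a \linkS4class{GenomicKernel}.
#' @param path CSV file path.
#' @return \code{writeKernelCSV} the path invisibly; \code{readKernelCSV}
#'   a \linkS4class{GenomicKernel}.
#' @param kind kernel kind to stamp on the object read back.
#' @export
writeKernelCSV <- function(g, path) {
  .writeMatrixCSV(kernelMatrix(g), path)
  invisible(path)
}

#' @rdname writeKernelCSV
#' @export
readKernelCSV <- function(path, kind = "additive") {
  m <- .readMatrixCSV(path)
  m <- (m + t(m)) / 2
  new("GenomicKernel", matrix = m, kind = kind)
}
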