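#' @include AllClasses.R
NULL

#' Per-marker minor-allele frequencies and centering constants
#'
#' Counts minor alleles under the \{1, 0, -1\} coding (code 1 contributes 0
#' minor alleles, 0 one, -1 two) over the non-missing calls of each marker:
#' \eqn{p_j = (\#0 + 2\,\#(-1)) / (2\, n_{obs})}, equivalently
#' \eqn{p_j = (1 - \bar x_j)/2}, which extends to fractional imputed dosages.
#' Markers whose computed frequency exceeds 0.5 have their allele labelling
#' flipped (codes negated) so that \eqn{p_j \le 0.5} always refers to the
#' minor allele; the flip is recorded and applied automatically during kernel
#' construction. Markers with zero non-missing calls are excluded with a
#' warning.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @return an \linkS4class{AlleleFrequencySet}.
#' @examples
#' m <- MarkerMatrix(cbind(m1 = c(1, 1, 0, -1), m2 = c(1, 1, 1, 1)))
#' minorFreqs(alleleFrequencies(m))   # 0.375, 0
#' @export
alleleFrequencies <- function(markers) {
  x <- markerValues(markers)
  if (ncol(x) == 0L) stop("marker matrix is empty")
  nobs <- colSums(!is.na(x))
  bad <- nobs == 0L
  if (any(bad)) {
    warning(sum(bad), " marker(s) with zero non-missing calls excluded")
    x <- x[, !bad, drop = FALSE]
    nobs <- nobs[!bad]
  }
  p <- (1 - colMeans(x, na.rm = TRUE)) / 2
  flipped <- p > 0.5
  p[flipped] <- 1 - p[flipped]
  p <- pmin(pmax(p, 0), 0.5)
  new("AlleleFrequencySet", freq = p, centering = 1 - 2 * p,
      denom = 2 * sum(p * (1 - p)), flipped = flipped)
}

#' Marker quality control
#'
#' Applies the two panel-editing rules in sequence: first markers with a
#' missing-call fraction strictly above \code{maxMissing} are removed, then
#' markers whose minor-allele frequency (computed on the surviving data) is
#' strictly below \code{minMaf} are removed. The thresholds follow the usual
#' GBS editing practice (40\% missingness, 5\% MAF); a marker at exactly the
#' MAF threshold is retained. Genotype rows are never removed. Counts per
#' rule are logged on the returned object.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param maxMissing maximum tolerated missing fraction (default 0.40).
#' @param minMaf minimum minor-allele frequency (default 0.05).
#' @return the filtered \linkS4class{MarkerMatrix}.
#' @export
qcFilter <- function(markers, maxMissing = 0.40, minMaf = 0.05) {
  stopifnot(maxMissing >= 0, maxMissing <= 1, minMaf >= 0, minMaf <= 1)
  x <- markerValues(markers)
  missFrac <- colMeans(is.na(x))
  keep1 <- missFrac <= maxMissing
  x1 <- x[, keep1, drop = FALSE]
  nMiss <- sum(!keep1)
  if (ncol(x1) == 0L)
    stop("all markers removed by the missingness filter")
  p <- (1 - colMeans(x1, na.rm = TRUE)) / 2
  p <- pmin(p, 1 - p)
  keep2 <- (p - minMaf) >= -1e-12    # strictly-below rule, fp-safe boundary
  nMaf <- sum(!keep2)
  x2 <- x1[, keep2, drop = FALSE]
  if (ncol(x2) == 0L)
    stop("all markers removed by the MAF filter; panel is empty")
  out <- MarkerMatrix(x2, imputed = markers@imputed)
  out@qcLog <- c(markers@qcLog, list(sprintf(
    "qcFilter: %d removed by missingness > %g, then %d by MAF < %g (%d kept)",
    nMiss, maxMissing, nMaf, minMaf, ncol(x2))))
  out
}

## rank needed to explain a given share of variance from a vector of
## singular values; capped
.rankForVariance <- function(d, share = 0.80, cap = 20L) {
  v <- d^2
  if (sum(v) <= 0) return(0L)
  k <- which(cumsum(v) / sum(v) >= share)[1]
  min(as.integer(k), cap, length(d))
}

#' EM imputation of missing marker calls
#'
#' Mean-initialized iterative low-rank EM: missing cells start at the marker
#' mean; each iteration fits a rank-k approximation of the column-centered
#' matrix via its leading singular vectors and replaces the missing cells
#' with the approximation, until the largest absolute change in any imputed
#' cell falls below \code{tol} or \code{maxIter} is reached. Imputed values
#' are fractional dosages clipped to \eqn{[-1, 1]}; observed calls are never
#' altered. Deterministic given its input.
#'
#' @param markers a post-QC \linkS4class{MarkerMatrix}; every marker must
#'   have at least one observed call.
#' @param tol convergence tolerance on imputed cells (default 1e-4).
#' @param maxIter maximum EM iterations (default 100). Non-convergence
#'   returns the current state with a warning, it is not an error.
#' @param rank rank of the approximation; \code{NULL} (default) selects the
#'   number of components explaining 80\% of the variance of the
#'   mean-imputed matrix, capped at 20. \code{rank = 0} is mean imputation.
#' @return an imputed \linkS4class{MarkerMatrix} (\code{imputed = TRUE}).
#' @export
imputeEM <- function(markers, tol = 1e-4, maxIter = 100, rank = NULL) {
  x <- markerValues(markers)
  miss <- is.na(x)
  if (!any(miss)) {
    out <- MarkerMatrix(x, imputed = TRUE)
    out@qcLog <- c(markers@qcLog, list("imputeEM: no missing calls"))
    return(out)
  }
  if (any(colSums(!miss) == 0L))
    stop("every marker needs at least one observed call")
  mu <- colMeans(x, na.rm = TRUE)
  x[miss] <- mu[col(x)][miss]

  center <- function(m) sweep(m, 2, colMeans(m))
  if (is.null(rank)) {
    d0 <- svd(center(x), nu = 0, nv = 0)$d
    rank <- .rankForVariance(d0)
  }
  rank <- min(as.integer(rank), nrow(x) - 1L, ncol(x))
  converged <- TRUE
  iter <- 0L
  if (rank > 0) {
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
      cm <- colMeans(x)
      s <- svd(sweep(x, 2, cm), nu = rank, nv = rank)
      approx <- s$u %*% diag(s$d[seq_len(rank)], rank) %*% t(s$v)
      newvals <- pmin(pmax(sweep(approx, 2, cm, "+")[miss], -1), 1)
      delta <- max(abs(newvals - x[miss]))
      x[miss] <- newvals
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("imputeEM did not converge in ", maxIter, " iterations")
  }
  out <- MarkerMatrix(x, imputed = TRUE)
  out@qcLog <- c(markers@qcLog, list(sprintf(
    "imputeEM: %d cells imputed (rank %d, %d iterations%s)",
    sum(miss), rank, iter, if (converged) "" else ", NOT converged")))
  out
}
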