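#' @include AllClasses.R famm-engine.R kernels.R
NULL

#' Specify a factor-analytic multi-environment mixed model
#'
#' The model for plot-level yields is
#' \deqn{y = Xb + Z_r r + \sum_t Z u_t + e,}
#' with fixed site effects \eqn{b}, random replicate-within-site effects
#' \eqn{r} with per-site variances, residuals with per-site variances, and one
#' or two genotype-within-site genetic terms \eqn{u_t} with separable
#' covariance \eqn{(\Delta_t\Delta_t' + D_t) \otimes K_t}: a factor-analytic
#' FA(q) structure over sites crossed with a genomic kernel over genotypes.
#' A single genotype-within-site effect per kernel term carries both the
#' genetic main effect and the G-by-E interaction: a common-loading factor
#' structure absorbs the main effect, which avoids the non-identifiable
#' split into separate g and ge terms.
#'
#' The four canonical variants are named from their kernels: FA (identity),
#' FA+G (additive), FA+GG (epistatic) and FA+G+GG (additive and epistatic,
#' each with its own independent FA structure).
#'
#' @param kernels a \linkS4class{GenomicKernel} or list of one or two.
#' @param faOrder FA order q per term (recycled; default 1).
#' @param includeReps fit random replicate-within-site effects (default TRUE).
#' @return an \linkS4class{FAModelSpec}.
#' @examples
#' k <- identityKernel(paste0("g", 1:10))
#' modelSpec(k)
#' @export
modelSpec <- function(kernels, faOrder = 1L, includeReps = TRUE) {
  if (is(kernels, "GenomicKernel")) kernels <- list(kernels)
  kinds <- vapply(kernels, kernelKind, "")
  name <- if (identical(kinds, "identity")) "FA"
    else if (identical(kinds, "additive")) "FA+G"
    else if (identical(kinds, "epistatic")) "FA+GG"
    else if (identical(kinds, c("additive", "epistatic"))) "FA+G+GG"
    else paste0("FA+", paste(kinds, collapse = "+"))
  new("FAModelSpec", kernels = kernels,
      faOrder = rep_len(as.integer(faOrder), length(kernels)),
      includeReps = isTRUE(includeReps), modelName = name)
}

#' Restricted log-likelihood of the multi-environment model
#'
#' Evaluates the restricted (REML) log-likelihood of a phenotype table at a
#' given parameter point, through the dense record-level covariance
#' \eqn{V = \sum_t (\Delta_t\Delta_t'+D_t)\otimes K_t} (mapped through the
#' genotype-site incidence) \eqn{+ Z_r R Z_r' + E}:
#' \deqn{-2\ell_R = (N - s)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py.}
#' The genetic covariance between records of genotypes i, i' at sites j, j'
#' is \eqn{\sum_t (\Delta_t\Delta_t'+D_t)[j,j'] \, K_t[i,i']}. This is a pure
#' function of its arguments and serves as the reference for the faster
#' collapsed likelihood used by \code{\link{fitFAMM}}.
#'
#' @param params list with elements \code{fa} (per kernel term, a list with
#'   \code{loadings} sites x q and \code{specificVars}), \code{repVars} and
#'   \code{resVars} (per-site, in the sorted site order of \code{data}).
#' @param data phenotype data.frame (genotype, site, rep, yield).
#' @param spec an \linkS4class{FAModelSpec}.
#' @return the restricted log-likelihood (a scalar).
#' @export
remlLoglik <- function(params, data, spec) {
  data <- .assertPhenotypes(data)
  sites <- sort(unique(data$site))
  if (length(sites) < 1L) stop("no sites in data")
  for (t in seq_along(spec@kernels)) {
    if (nrow(params$fa[[t]]$loadings) != length(sites))
      stop("loadings must have one row per site")
  }
  if (any(params$resVars <= 0)) stop("residual variances must be positive")
  -0.5 * .minus2llRecords(params, data, spec, siteLevels = sites)
}

## Two-stage starting values: residual/replicate variances from within-cell
## and replicate mean squares, genetic covariance from site-centred cell
## means, factor-analysed into loadings + specific variances per term.
.startValues <- function(prep, setup, str) {
  s <- str$s
  nRep <- prep$nRep; nCell <- prep$nCell
  cells <- prep$cells
  resV <- numeric(s); repV <- numeric(s)
  for (j in seq_len(s)) {
    if (nRep[j] >= 2L && nCell[j] > 0) {
      resV[j] <- max(prep$W[j] / (nCell[j] * (nRep[j] - 1)), 1e-4)
      repV[j] <- max((prep$Q[j] / (nRep[j] - 1) - resV[j]) / nCell[j], 1e-4)
    } else {
      v <- stats::var(cells$ybar[cells$siteIdx == j])
      resV[j] <- max(v / 2, 1e-4, na.rm = TRUE)
      repV[j] <- 1e-4
    }
  }
  ## site-centred cell means -> genotype x site matrix, pairwise covariance
  e <- cells$ybar - stats::ave(cells$ybar, cells$siteIdx)
  gmat <- matrix(NA_real_, length(unique(cells$genotype)), s)
  rownames(gmat) <- unique(cells$genotype)
  gmat[cbind(match(cells$genotype, rownames(gmat)), cells$siteIdx)] <- e
  Sg <- suppressWarnings(stats::cov(gmat, use = "pairwise.complete.obs"))
  Sg[!is.finite(Sg)] <- 0
  diag(Sg) <- pmax(diag(Sg) - resV / pmax(nRep, 1L), 0.05 * resV)
  ## project to PSD
  es <- eigen((Sg + t(Sg)) / 2, symmetric = TRUE)
  Sg <- es$vectors %*% diag(pmax(es$values, 1e-6), s) %*% t(es$vectors)

  nt <- str$nt
  fa <- vector("list", nt)
  for (t in seq_len(nt)) {
    kd <- mean(diag(setup$Kbig[[t]]))
    Starget <- Sg / (nt * max(kd, 1e-8))
    q <- str$terms[[t]]$q
    es <- eigen((Starget + t(Starget)) / 2, symmetric = TRUE)
    L <- es$vectors[, seq_len(q), drop = FALSE] %*%
      diag(sqrt(pmax(es$values[seq_len(q)], 1e-6)), q)
    d <- pmax(diag(Starget) - rowSums(L^2), 0.1 * pmax(diag(Starget), 1e-4))
    fa[[t]] <- list(loadings = L, specificVars = d)
  }
  list(fa = fa, repVars = repV, resVars = resV)
}

## enforce the sign convention: first nonzero loading of each column >= 0
.fixLoadingSigns <- function(L) {
  for (k in seq_len(ncol(L))) {
    nz <- which(abs(L[, k]) > 1e-12)
    if (length(nz) && L[nz[1], k] < 0) L[, k] <- -L[, k]
  }
  L
}

#' Fit the factor-analytic multi-environment mixed model by REML
#'
#' Maximizes the restricted log-likelihood over the factor loadings, specific
#' variances, replicate variances and residual variances, with positivity
#' enforced by log-parameterization, the upper triangle of the leading q x q
#' loading block fixed at zero and a positive-leading-entry sign convention.
#' Optimization is bounded quasi-Newton (L-BFGS-B) with analytic gradients on
#' an exact collapsed representation of the likelihood, started from
#' two-stage moment estimates plus seeded jittered restarts (for two-term
#' models one restart starts the second term near zero, which also makes the
#' optimized likelihood of a nested pair monotone in practice). Designs
#' whose sites have unequal replicate sets fall back to numeric-gradient
#' optimization of the dense record-level likelihood.
#'
#' BLUPs of every genotype-by-site cell - including cells never observed,
#' which draw information through the kernel - are computed at the optimum
#' via the conditional mean \eqn{\hat u = C' V^{-1} (y - X\hat b)}.
#'
#' @param data phenotype data.frame (genotype, site, rep, yield). Every site
#'   must have at least two observed genotypes.
#' @param spec an \linkS4class{FAModelSpec}. \code{faOrder} larger than the
#'   number of sites is an error.
#' @param maxIter maximum optimizer iterations per start (default 400).
#' @param tol convergence threshold on the inf-norm of the projected
#'   gradient of \eqn{-2\ell_R} (default 0.5; the optimizer itself runs to
#'   its own tighter relative-change criterion).
#' @param nRestarts number of optimization starts (default 3).
#' @param seed seed for the restart jitter.
#' @param pgtol projected-gradient stopping tolerance handed to L-BFGS-B
#'   (default 1e-3). Loosening it (e.g. 0.02) trades a little likelihood
#'   precision for substantially fewer iterations on flat factor-analytic
#'   ridges; accuracy-level results are insensitive to this.
#' @return an \linkS4class{FAModelFit}. Non-convergence is flagged on the
#'   returned object, not raised.
#' @examples
#' sim <- simulateDataset(simConfig(nGenotypes = 25, nMarkers = 80,
#'                                  nSites = 2, missingRate = 0, seed = 5))
#' G <- additiveKernel(MarkerMatrix(markerValues(sim$markersComplete),
#'                                  imputed = TRUE))
#' fit <- fitFAMM(sim$phenotypes, modelSpec(stabilizeKernel(G)),
#'                nRestarts = 1)
#' fit
#' @export
fitFAMM <- function(data, spec, maxIter = 400, tol = 0.5, nRestarts = 3,
                    seed = 1, pgtol = 1e-3) {
  stopifnot(is(spec, "FAModelSpec"))
  prep <- .prepCells(data)
  sites <- prep$sites
  s <- length(sites)
  if (any(spec@faOrder > s))
    stop("faOrder q = ", max(spec@faOrder), " exceeds the number of sites (",
         s, ")")
  if (any(prep$nCell < 2L))
    stop("every site needs at least 2 observed genotypes")
  spec@kernels <- lapply(spec@kernels, stabilizeKernel)

  if (!prep$balanced)
    return(.fitUnbalanced(prep, spec, maxIter, tol, nRestarts, seed))

  includeReps <- spec@includeReps && any(prep$nRep >= 2L)
  str <- .thetaStructure(spec, sites, prep$nRep, includeReps)
  setup <- .engineSetup(prep, spec)
  start <- .startValues(prep, setup, str)
  bounds <- .thetaBounds(str)

  cache <- new.env(parent = emptyenv())
  fn <- function(th) .engineEval(th, setup, str, "fn", cache)
  gr <- function(th) .engineEval(th, setup, str, "gr", cache)

  starts <- list(.packParams(start, str))
  set.seed(seed)
  if (str$nt == 2L && nRestarts >= 2L) {
    ## second term switched (nearly) off; robustifies nested-model fits
    alt <- start
    alt$fa[[2]]$loadings <- alt$fa[[2]]$loadings * 0.05
    alt$fa[[2]]$specificVars <- pmax(alt$fa[[2]]$specificVars * 1e-4, 1e-8)
    alt$fa[[1]]$loadings <- alt$fa[[1]]$loadings * sqrt(2)
    alt$fa[[1]]$specificVars <- alt$fa[[1]]$specificVars * 2
    starts <- c(starts, list(.packParams(alt, str)))
  }
  while (length(starts) < nRestarts) {
    jit <- starts[[1]] + stats::rnorm(str$nPar, 0, 0.25)
    starts <- c(starts, list(pmin(pmax(jit, bounds$lower), bounds$upper)))
  }

  best <- NULL; nIter <- 0L
  for (th0 in starts) {
    op <- tryCatch(
      stats::optim(th0, fn, gr, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = maxIter, factr = 1e8,
                                  pgtol = pgtol)),
      error = function(e) NULL)
    if (is.null(op)) next
    nIter <- nIter + op$counts[1]
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("all optimization starts failed")

  ## polish from the winning start with a tighter relative-change stop;
  ## cheap (warm start) and removes premature factr terminations
  pol <- tryCatch(
    stats::optim(best$par, fn, gr, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = maxIter, factr = 1e6,
                                pgtol = pgtol)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) {
    nIter <- nIter + pol$counts[1]
    best <- pol
  }

  g <- gr(best$par)
  atLower <- best$par <= bounds$lower + 1e-10
  atUpper <- best$par >= bounds$upper - 1e-10
  pg <- g
  pg[atLower & g > 0] <- 0
  pg[atUpper & g < 0] <- 0
  ## normal termination (or an iteration cap reached on an already-flat
  ## ridge) plus a small projected gradient counts as converged
  converged <- best$convergence %in% c(0L, 1L) && max(abs(pg)) <= tol &&
    is.finite(best$value)

  fitEv <- .engineEval(best$par, setup, str, "fit")
  .buildFit(fitEv, setup, str, spec, converged, as.integer(nIter))
}

## assemble the FAModelFit object (BLUP grids, accessor-friendly naming)
.buildFit <- function(fitEv, setup, str, spec, converged, nIter) {
  prep <- setup$prep
  sites <- prep$sites
  s <- str$s
  ids <- setup$ids
  pr <- fitEv$params
  cells <- prep$cells
  alpha <- fitEv$alpha

  blupTerms <- vector("list", str$nt)
  for (t in seq_len(str$nt)) {
    H <- matrix(0, length(ids), s)
    for (j in seq_len(s)) {
      idx <- which(cells$siteIdx == j)
      if (length(idx))
        H[, j] <- setup$Ks[[t]][, setup$gi[idx], drop = FALSE] %*% alpha[idx]
    }
    B <- H %*% fitEv$St[[t]]
    dimnames(B) <- list(ids, sites)
    blupTerms[[t]] <- B
  }
  total <- Reduce(`+`, blupTerms)

  fa <- lapply(seq_len(str$nt), function(t) {
    L <- .fixLoadingSigns(pr$fa[[t]]$loadings)
    dimnames(L) <- list(sites, paste0("F", seq_len(ncol(L))))
    d <- pr$fa[[t]]$specificVars; names(d) <- sites
    list(loadings = L, specificVars = d,
         kernel = kernelKind(spec@kernels[[t]]))
  })
  b <- fitEv$beta; names(b) <- sites
  repV <- pr$repVars; names(repV) <- sites
  resV <- pr$resVars; names(resV) <- sites

  new("FAModelFit", modelName = spec@modelName, sites = sites,
      genotypeIds = ids, fixedEffects = b, fa = fa,
      repVars = repV, resVars = resV,
      blup = list(terms = blupTerms, total = total),
      remlLoglik = -fitEv$obj / 2, converged = converged, nIter = nIter,
      predictor = list(alpha = alpha,
                       cells = cells[, c("genotype", "site")],
                       St = fitEv$St))
}

## Fallback for designs without within-site replicate balance: numeric
## gradients on the dense record-level likelihood. Slower; rarely needed.
.fitUnbalanced <- function(prep, spec, maxIter, tol, nRestarts, seed) {
  sites <- prep$sites
  includeReps <- spec@includeReps && any(prep$nRepMax >= 2L)
  str <- .thetaStructure(spec, sites, prep$nRepMax, includeReps)
  setup <- .engineSetup(prep, spec)
  start <- .startValues(prep, setup, str)
  bounds <- .thetaBounds(str)
  fn <- function(th) {
    pr <- .unpackParams(th, str)
    tryCatch(.minus2llRecords(pr, prep$data, spec, siteLevels = sites),
             error = function(e) 1e10)
  }
  set.seed(seed)
  op <- stats::optim(.packParams(start, str), fn, method = "L-BFGS-B",
                     lower = bounds$lower, upper = bounds$upper,
                     control = list(maxit = maxIter, factr = 1e7))
  ## BLUPs via the collapsed representation evaluated cellwise is not exact
  ## without balance; use the record-level conditional mean directly.
  pr <- .unpackParams(op$par, str)
  fitEv <- .recordBlups(pr, prep, spec, setup, str)
  fitEv$obj <- op$value
  .buildFit(fitEv, setup, str, spec, op$convergence == 0,
            as.integer(op$counts[1]))
}

.recordBlups <- function(pr, prep, spec, setup, str) {
  data <- prep$data
  sites <- prep$sites
  s <- length(sites)
  N <- nrow(data)
  si <- match(data$site, sites)
  gi <- match(data$genotype, setup$ids)
  St <- lapply(pr$fa, function(f)
    tcrossprod(f$loadings) + diag(f$specificVars, s))
  V <- matrix(0, N, N)
  for (t in seq_len(str$nt))
    V <- V + St[[t]][si, si] * setup$Ks[[t]][gi, gi]
  if (isTRUE(spec@includeReps) && any(pr$repVars > 0)) {
    repKey <- paste(data$site, data$rep, sep = "\r")
    same <- outer(repKey, repKey, "==")
    sr <- sqrt(pmax(pr$repVars, 0))[si]
    V <- V + same * tcrossprod(sr)
  }
  diag(V) <- diag(V) + pr$resVars[si]
  X <- matrix(0, N, s); X[cbind(seq_len(N), si)] <- 1
  R <- chol(V)
  ViX <- backsolve(R, backsolve(R, X, transpose = TRUE))
  Viy <- backsolve(R, backsolve(R, data$yield, transpose = TRUE))
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(X, Viy))
  pRec <- as.vector(Viy - ViX %*% beta)
  ## collapse record weights to cells for the kernel-based BLUP formula
  ckey <- paste(data$genotype, data$site, sep = "\r")
  cellKey <- paste(prep$cells$genotype, prep$cells$site, sep = "\r")
  alpha <- as.vector(rowsum(pRec, factor(ckey, levels = cellKey)))
  list(beta = as.vector(beta), alpha = alpha, St = St, params = pr)
}

#' Predict total genetic values for chosen genotypes and sites
#'
#' Extracts the fitted total genetic value (sum over kernel terms) for the
#' requested genotype-by-site cells, including cells that were never
#' observed: those are genuine kernel-based predictions. Deterministic given
#' the fit.
#'
#' @param fit an \linkS4class{FAModelFit}.
#' @param genotypeIds,siteIds cells to extract; default all.
#' @return genotype x site matrix of predicted genetic values.
#' @export
predictGeneticValues <- function(fit, genotypeIds = NULL, siteIds = NULL) {
  total <- fit@blup$total
  if (is.null(genotypeIds)) genotypeIds <- rownames(total)
  if (is.null(siteIds)) siteIds <- colnames(total)
  unknown <- setdiff(genotypeIds, rownames(total))
  if (length(unknown))
    stop("unknown genotype(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  unknownS <- setdiff(siteIds, colnames(total))
  if (length(unknownS))
    stop("unknown site(s): ", paste(unknownS, collapse = ", "))
  total[genotypeIds, siteIds, drop = FALSE]
}
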