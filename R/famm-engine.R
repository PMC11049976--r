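#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Internal REML engine for the factor-analytic multi-environment mixed model
##
##   y = X b + Z_r r + sum_t Z u_t + e,   u_t ~ N(0, (L_t L_t' + D_t) x K_t)
##   r ~ N(0, diag(s2_r by site) x I),    e ~ N(0, diag(s2_e by site) x I)
##
## When every observed genotype-site cell within a site carries the same set
## of replicate labels, the restricted likelihood factorizes exactly into
## (i) a dense multivariate-normal REML term on the cell means, whose
## covariance is  G_cells + (s2_r/n_j) J_site + (s2_e/n_j) I,  and
## (ii) closed-form per-site replicate-contrast terms involving only the
## within-cell sum of squares W_j and the replicate sum of squares Q_j.
## The replicate-mean and contrast subspaces are orthogonal and the fixed
## site effects lie entirely in the former, so the factorization is exact;
## equality with the record-level restricted likelihood is asserted in the
## test suite. Gradients are analytic throughout.
## ---------------------------------------------------------------------------

.assertPhenotypes <- function(data) {
  data <- as.data.frame(data)
  need <- c("genotype", "site", "rep", "yield")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  data$genotype <- as.character(data$genotype)
  data$site <- as.character(data$site)
  if (!is.numeric(data$yield)) stop("yield must be numeric")
  if (anyNA(data$yield)) stop("yield must not contain missing values")
  key <- paste(data$genotype, data$site, data$rep, sep = "\r")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (genotype, site, rep) records at rows: ",
         paste(utils::head(rows, 10), collapse = ", "))
  }
  data
}

## Cell-level summaries of a phenotype table.
.prepCells <- function(data, siteLevels = NULL) {
  data <- .assertPhenotypes(data)
  sites <- if (is.null(siteLevels)) sort(unique(data$site)) else siteLevels
  if (!all(data$site %in% sites)) stop("data contain unknown sites")
  ckey <- paste(data$genotype, data$site, sep = "\r")
  uk <- unique(ckey)
  ci <- match(ckey, uk)
  first <- match(uk, ckey)
  cells <- data.frame(genotype = data$genotype[first],
                      site = data$site[first], stringsAsFactors = FALSE)
  cells$siteIdx <- match(cells$site, sites)
  cells$n <- tabulate(ci, length(uk))
  cells$ybar <- as.vector(rowsum(data$yield, ci)) / cells$n

  s <- length(sites)
  nRep <- integer(s); nCell <- integer(s); nRepMax <- integer(s)
  W <- numeric(s); Q <- numeric(s)
  balanced <- TRUE
  for (j in seq_len(s)) {
    inS <- cells$siteIdx == j
    nCell[j] <- sum(inS)
    if (!nCell[j]) next
    recj <- data[data$site == sites[j], , drop = FALSE]
    repsByCell <- split(recj$rep, recj$genotype)
    nRepMax[j] <- max(lengths(repsByCell))
    sets <- unique(lapply(repsByCell, function(r) sort(as.character(r))))
    if (length(sets) != 1L || anyDuplicated(sets[[1]])) {
      balanced <- FALSE
      next
    }
    nRep[j] <- length(sets[[1]])
    cen <- recj$yield - cells$ybar[ci[data$site == sites[j]]]
    W[j] <- sum(cen^2)
    if (nRep[j] >= 2L) {
      repMeans <- tapply(recj$yield, as.character(recj$rep), mean)
      Q[j] <- nCell[j] * sum((repMeans - mean(repMeans))^2)
    }
  }
  list(data = data, sites = sites, cells = cells, cellIdx = ci,
       nRep = nRep, nRepMax = nRepMax, nCell = nCell, W = W, Q = Q,
       balanced = balanced)
}

## Free-loading index set: entries (j, k) with j >= k (upper triangle of the
## leading q x q block fixed at zero for identifiability).
.freeLoadings <- function(s, q) which(row(matrix(0, s, q)) >= col(matrix(0, s, q)))

.thetaStructure <- function(spec, sites, nRep, includeRepsEffective) {
  s <- length(sites)
  nt <- length(spec@kernels)
  terms <- lapply(seq_len(nt), function(t)
    list(q = spec@faOrder[t], free = .freeLoadings(s, spec@faOrder[t])))
  repFree <- if (includeRepsEffective) which(nRep >= 2L) else integer(0)
  nl <- vapply(terms, function(tt) length(tt$free), 1L)
  list(s = s, nt = nt, terms = terms, repFree = repFree,
       nPar = sum(nl) + nt * s + length(repFree) + s)
}

.packParams <- function(params, str) {
  th <- numeric(0)
  for (t in seq_len(str$nt)) {
    L <- params$fa[[t]]$loadings
    th <- c(th, L[str$terms[[t]]$free],
            log(pmax(params$fa[[t]]$specificVars, 1e-8)))
  }
  if (length(str$repFree))
    th <- c(th, log(pmax(params$repVars[str$repFree], 1e-8)))
  c(th, log(pmax(params$resVars, 1e-10)))
}

.unpackParams <- function(theta, str) {
  s <- str$s; pos <- 0L
  fa <- vector("list", str$nt)
  for (t in seq_len(str$nt)) {
    q <- str$terms[[t]]$q
    free <- str$terms[[t]]$free
    L <- matrix(0, s, q)
    L[free] <- theta[pos + seq_along(free)]; pos <- pos + length(free)
    d <- exp(theta[pos + seq_len(s)]); pos <- pos + s
    fa[[t]] <- list(loadings = L, specificVars = d)
  }
  repVars <- numeric(s)
  if (length(str$repFree)) {
    repVars[str$repFree] <- exp(theta[pos + seq_along(str$repFree)])
    pos <- pos + length(str$repFree)
  }
  resVars <- exp(theta[pos + seq_len(s)])
  list(fa = fa, repVars = repVars, resVars = resVars)
}

.thetaBounds <- function(str) {
  lower <- numeric(0); upper <- numeric(0)
  for (t in seq_len(str$nt)) {
    nf <- length(str$terms[[t]]$free); s <- str$s
    lower <- c(lower, rep(-30, nf), rep(log(1e-8), s))
    upper <- c(upper, rep(30, nf), rep(8, s))
  }
  lower <- c(lower, rep(log(1e-8), length(str$repFree)), rep(log(1e-10), str$s))
  upper <- c(upper, rep(8, length(str$repFree)), rep(8, str$s))
  list(lower = lower, upper = upper)
}

## Engine setup shared by all evaluations on one training set.
.engineSetup <- function(prep, spec) {
  cells <- prep$cells
  m <- nrow(cells)
  Ks <- lapply(spec@kernels, function(k) kernelMatrix(k))
  ids <- rownames(Ks[[1]])
  if (!all(cells$genotype %in% ids))
    stop("genotypes present in phenotypes but absent from the kernel: ",
         paste(utils::head(setdiff(cells$genotype, ids), 5), collapse = ", "))
  gi <- match(cells$genotype, ids)
  Kbig <- lapply(Ks, function(K) K[gi, gi, drop = FALSE])
  s <- length(prep$sites)
  Agg <- matrix(0, m, s); Agg[cbind(seq_len(m), cells$siteIdx)] <- 1
  X <- Agg
  nRepCell <- prep$nRep[cells$siteIdx]
  list(prep = prep, spec = spec, Ks = Ks, ids = ids, gi = gi, Kbig = Kbig,
       Agg = Agg, X = X, m = m, s = s, nRepCell = nRepCell,
       siteIdx = cells$siteIdx, y = cells$ybar)
}

## Core factorization at one parameter point: covariance build, Cholesky,
## GLS pieces and the -2 restricted log-likelihood (constants included).
.engineCore <- function(theta, setup, str) {
  pr <- .unpackParams(theta, str)
  prep <- setup$prep
  m <- setup$m; s <- setup$s
  si <- setup$siteIdx
  nRep <- prep$nRep; nCell <- prep$nCell

  St <- lapply(pr$fa, function(f)
    tcrossprod(f$loadings) + diag(f$specificVars, s))
  V <- matrix(0, m, m)
  for (t in seq_len(str$nt))
    V <- V + St[[t]][si, si] * setup$Kbig[[t]]
  for (j in seq_len(s)) {
    if (!nCell[j]) next
    idx <- which(si == j)
    if (pr$repVars[j] > 0)
      V[idx, idx] <- V[idx, idx] + pr$repVars[j] / nRep[j]
  }
  diag(V) <- diag(V) + pr$resVars[si] / pmax(nRep[si], 1L)

  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), m)),
                  error = function(e) NULL)
    if (is.null(R)) return(NULL)
  }
  X <- setup$X; y <- setup$y
  ViX <- backsolve(R, backsolve(R, X, transpose = TRUE))
  Viy <- backsolve(R, backsolve(R, y, transpose = TRUE))
  XtViX <- crossprod(X, ViX)
  cX <- chol(XtViX)
  Xty <- crossprod(X, Viy)
  beta <- backsolve(cX, backsolve(cX, Xty, transpose = TRUE))
  quad <- sum(y * Viy) - sum(Xty * beta)

  ## per-site replicate-contrast closed forms
  lam1 <- pr$resVars + nCell * pr$repVars
  cObj <- 0
  for (j in seq_len(s)) {
    if (nRep[j] < 2L || !nCell[j]) next
    cObj <- cObj + (nRep[j] - 1) *
      (nCell[j] * log(2 * pi) + log(lam1[j]) +
       (nCell[j] - 1) * log(pr$resVars[j])) +
      prep$Q[j] / lam1[j] + (prep$W[j] - prep$Q[j]) / pr$resVars[j]
  }
  obj <- (m - s) * log(2 * pi) + sum(log(pmax(setup$nRepCell, 1L))) +
    2 * sum(log(diag(R))) + 2 * sum(log(diag(cX))) + quad + cObj
  list(pr = pr, St = St, R = R, ViX = ViX, Viy = Viy, cX = cX,
       beta = beta, lam1 = lam1, obj = obj)
}

## Objective and gradient; an environment passed as `cache` lets the
## gradient reuse the factorization computed by the objective at the same
## parameter point (the usual L-BFGS-B call pattern).
.engineEval <- function(theta, setup, str, want = c("fn", "gr", "fit"),
                        cache = NULL) {
  want <- match.arg(want)
  core <- NULL
  if (!is.null(cache) && !is.null(cache$theta) &&
      isTRUE(all(cache$theta == theta)))
    core <- cache$core
  if (is.null(core)) {
    core <- .engineCore(theta, setup, str)
    if (!is.null(cache) && !is.null(core)) {
      cache$theta <- theta
      cache$core <- core
    }
  }
  if (is.null(core)) {
    if (want == "gr") return(rep(0, length(theta)))
    if (want == "fn") return(1e10)
    stop("covariance matrix is singular")
  }
  if (want == "fn") return(core$obj)

  pr <- core$pr
  prep <- setup$prep
  m <- setup$m; s <- setup$s
  si <- setup$siteIdx
  nRep <- prep$nRep; nCell <- prep$nCell
  lam1 <- core$lam1
  R <- core$R; ViX <- core$ViX; beta <- core$beta

  p <- as.vector(core$Viy - ViX %*% beta)     # P y at cell level
  if (want == "fit") {
    return(list(obj = core$obj, beta = as.vector(beta), alpha = p,
                St = core$St, params = pr))
  }

  Vi <- chol2inv(R)
  Pfull <- Vi - ViX %*% chol2inv(core$cX) %*% t(ViX)
  E <- Pfull - tcrossprod(p)

  Agg <- setup$Agg
  gr <- numeric(0)
  for (t in seq_len(str$nt)) {
    Ft <- crossprod(Agg, (E * setup$Kbig[[t]]) %*% Agg)
    Ft <- (Ft + t(Ft)) / 2
    L <- pr$fa[[t]]$loadings
    gL <- 2 * (Ft %*% L)
    gD <- diag(Ft) * pr$fa[[t]]$specificVars
    gr <- c(gr, gL[str$terms[[t]]$free], gD)
  }
  Eagg <- crossprod(Agg, E %*% Agg)            # block sums of E by site pair
  dEdiag <- as.vector(rowsum(diag(E), si))     # per-site diagonal sums
  if (length(dEdiag) < s) {                    # sites with no cells
    tmp <- numeric(s); tmp[sort(unique(si))] <- dEdiag; dEdiag <- tmp
  }
  if (length(str$repFree)) {
    gRep <- vapply(str$repFree, function(j) {
      g <- Eagg[j, j] / nRep[j]
      if (nRep[j] >= 2L)
        g <- g + (nRep[j] - 1) * nCell[j] / lam1[j] -
          prep$Q[j] * nCell[j] / lam1[j]^2
      g * pr$repVars[j]
    }, 0)
    gr <- c(gr, gRep)
  }
  gRes <- vapply(seq_len(s), function(j) {
    g <- if (nCell[j]) dEdiag[j] / nRep[j] else 0
    if (nRep[j] >= 2L && nCell[j])
      g <- g + (nRep[j] - 1) * (1 / lam1[j] + (nCell[j] - 1) / pr$resVars[j]) -
        prep$Q[j] / lam1[j]^2 -
        (prep$W[j] - prep$Q[j]) / pr$resVars[j]^2
    g * pr$resVars[j]
  }, 0)
  c(gr, gRes)
}

## Record-level dense -2 restricted log-likelihood (reference path; also the
## fallback objective for designs without within-site replicate balance).
.minus2llRecords <- function(params, data, spec, siteLevels = NULL) {
  data <- .assertPhenotypes(data)
  sites <- if (is.null(siteLevels)) sort(unique(data$site)) else siteLevels
  s <- length(sites)
  N <- nrow(data)
  si <- match(data$site, sites)
  Ks <- lapply(spec@kernels, kernelMatrix)
  ids <- rownames(Ks[[1]])
  if (!all(data$genotype %in% ids))
    stop("genotypes in phenotypes missing from the kernel")
  gi <- match(data$genotype, ids)

  V <- matrix(0, N, N)
  for (t in seq_along(Ks)) {
    f <- params$fa[[t]]
    St <- tcrossprod(f$loadings) + diag(f$specificVars, s)
    V <- V + St[si, si] * Ks[[t]][gi, gi]
  }
  if (isTRUE(spec@includeReps) && any(params$repVars > 0)) {
    repKey <- paste(data$site, data$rep, sep = "\r")
    same <- outer(repKey, repKey, "==")
    sr <- sqrt(pmax(params$repVars, 0))[si]
    V <- V + same * tcrossprod(sr)
  }
  diag(V) <- diag(V) + params$resVars[si]

  X <- matrix(0, N, s); X[cbind(seq_len(N), si)] <- 1
  R <- chol(V)
  ViX <- backsolve(R, backsolve(R, X, transpose = TRUE))
  Viy <- backsolve(R, backsolve(R, data$yield, transpose = TRUE))
  XtViX <- crossprod(X, ViX)
  cX <- chol(XtViX)
  Xty <- crossprod(X, Viy)
  beta <- backsolve(cX, backsolve(cX, Xty, transpose = TRUE))
  quad <- sum(data$yield * Viy) - sum(Xty * beta)
  (N - s) * log(2 * pi) + 2 * sum(log(diag(R))) + 2 * sum(log(diag(cX))) + quad
}
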