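# Shared fixtures and independent oracles used across the suite.

# small inbred trial dataset with genomic signal
smallSim <- function(seed = 7, nGenotypes = 40, nSites = 3, nMarkers = 200,
                     missingRate = 0, ...) {
  simulateDataset(simConfig(nGenotypes = nGenotypes, nMarkers = nMarkers,
                            nSites = nSites, missingRate = missingRate,
                            seed = seed, ...))
}

completeKernel <- function(sim) {
  mm <- MarkerMatrix(markerValues(sim$markersComplete), imputed = TRUE)
  stabilizeKernel(additiveKernel(mm))
}

# scalar (loop-based, no matrix algebra) additive-kernel oracle
bruteForceAdditive <- function(x) {
  n <- nrow(x); m <- ncol(x)
  p <- numeric(m)
  for (j in seq_len(m)) {
    cnt <- 0
    for (i in seq_len(n)) cnt <- cnt + (x[i, j] == 0) + 2 * (x[i, j] == -1)
    p[j] <- cnt / (2 * n)
    if (p[j] > 0.5) {           # minor-allele flip
      for (i in seq_len(n)) x[i, j] <- -x[i, j]
      p[j] <- 1 - p[j]
    }
  }
  denom <- 0
  for (j in seq_len(m)) denom <- denom + 2 * p[j] * (1 - p[j])
  g <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (j in seq_len(m))
      acc <- acc + (x[i, j] - (1 - 2 * p[j])) * (x[k, j] - (1 - 2 * p[j]))
    g[i, k] <- acc / denom
  }
  g
}

# closed-form REML -2 log-likelihood for a balanced one-way random-effects
# layout (a groups, r replicates, grand-mean fixed effect), derived from the
# spectral decomposition of V = s2g Z Z' + s2e I
onewayREMLminus2ll <- function(y, group, s2g, s2e) {
  a <- length(unique(group)); N <- length(y); r <- N / a
  stopifnot(r == round(r))
  lam <- s2e + r * s2g
  gm <- tapply(y, group, mean)
  ssb <- r * sum((gm - mean(y))^2)
  ssw <- sum((y - gm[match(group, names(gm))])^2)
  (N - 1) * log(2 * pi) + a * log(lam) + (N - a) * log(s2e) +
    log(N / lam) + ssb / lam + ssw / s2e
}

# Henderson mixed-model-equation GBLUP oracle (single site, single kernel)
hendersonGBLUP <- function(y, Zidx, K, s2g, s2e) {
  n <- nrow(K); N <- length(y)
  X <- matrix(1, N, 1)
  Z <- matrix(0, N, n); Z[cbind(seq_len(N), Zidx)] <- 1
  Ginv <- solve(s2g * K)
  C <- rbind(cbind(crossprod(X) / s2e, crossprod(X, Z) / s2e),
             cbind(crossprod(Z, X) / s2e, crossprod(Z) / s2e + Ginv))
  rhs <- c(crossprod(X, y), crossprod(Z, y)) / s2e
  sol <- solve(C, rhs)
  list(beta = sol[1], u = sol[-1])
}

paramsFromFit <- function(fit) {
  list(fa = lapply(fit@fa, function(f)
         list(loadings = unname(f$loadings),
              specificVars = unname(f$specificVars))),
       repVars = unname(fit@repVars), resVars = unname(fit@resVars))
}
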