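#' @include AllClasses.R famm.R kernels.R markers.R
NULL

#' Build a cross-validation fold plan
#'
#' Genotypes are shuffled once under \code{seed} and split into
#' \code{nFolds} near-equal groups (sizes differing by at most 1). The three
#' schemes mask genotype-by-site cells as follows:
#' \describe{
#'   \item{CV1}{each fold's test genotypes are masked at \emph{all} sites:
#'     the model predicts lines it has never seen anywhere.}
#'   \item{CV2}{each fold's test genotypes are masked at a designated subset
#'     of sites and remain observed at the others: lines seen at some sites
#'     are predicted at the rest. By default \eqn{\lceil s/2 \rceil} masked
#'     sites rotate across folds; pass \code{maskedSites} to fix them.}
#'   \item{CV3}{sparse testing at one focal site: a single fold keeps
#'     exactly \code{nTrainFocal} genotypes observed at \code{focalSite} and
#'     predicts all the others there, while every other site is fully
#'     observed.}
#' }
#'
#' @param scheme \code{"CV1"}, \code{"CV2"} or \code{"CV3"}.
#' @param genotypeIds,siteIds the universes to plan over.
#' @param nFolds number of folds (default 5; CV3 always uses one fold).
#' @param seed integer seed for the genotype shuffle.
#' @param maskedSites CV2 only: sites at which test genotypes are hidden.
#'   Must be a proper, non-empty subset of \code{siteIds} (masking every
#'   site would be CV1).
#' @param focalSite,nTrainFocal CV3 only: the focal site and the number of
#'   genotypes kept in its training set.
#' @return a \linkS4class{FoldPlan}.
#' @examples
#' plan <- makeFolds("CV1", sprintf("g%03d", 1:162), paste0("S", 1:6),
#'                   seed = 42)
#' plan
#' @export
makeFolds <- function(scheme, genotypeIds, siteIds, nFolds = 5, seed = 1,
                      maskedSites = NULL, focalSite = NULL,
                      nTrainFocal = 20) {
  scheme <- match.arg(scheme, c("CV1", "CV2", "CV3"))
  genotypeIds <- as.character(genotypeIds)
  siteIds <- as.character(siteIds)
  nFolds <- as.integer(nFolds)
  if (scheme != "CV3" && nFolds < 2L) stop("nFolds must be >= 2")
  n <- length(genotypeIds)
  set.seed(as.integer(seed))
  shuffled <- sample(genotypeIds)

  cellsOf <- function(gen, sit)
    expand.grid(genotype = gen, site = sit, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)

  if (scheme == "CV3") {
    if (is.null(focalSite) || !focalSite %in% siteIds)
      stop("CV3 requires a valid focalSite")
    nTrainFocal <- as.integer(nTrainFocal)
    if (nTrainFocal < 1L || nTrainFocal >= n)
      stop("nTrainFocal must be in [1, number of genotypes)")
    test <- shuffled[(nTrainFocal + 1):n]
    masks <- testSets <- list(cellsOf(test, focalSite))
    return(new("FoldPlan", scheme = scheme, nFolds = 1L, masks = masks,
               testSets = testSets, genotypes = genotypeIds,
               sites = siteIds, seed = as.integer(seed)))
  }

  sizes <- rep(n %/% nFolds, nFolds)
  extra <- n %% nFolds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  groups <- split(shuffled, rep(seq_len(nFolds), times = sizes))

  if (scheme == "CV1") {
    masks <- lapply(groups, cellsOf, sit = siteIds)
    return(new("FoldPlan", scheme = scheme, nFolds = nFolds, masks = masks,
               testSets = masks, genotypes = genotypeIds, sites = siteIds,
               seed = as.integer(seed)))
  }

  ## CV2
  s <- length(siteIds)
  if (!is.null(maskedSites)) {
    maskedSites <- as.character(maskedSites)
    if (!length(maskedSites) || !all(maskedSites %in% siteIds))
      stop("maskedSites must be a non-empty subset of siteIds")
    if (length(unique(maskedSites)) >= s)
      stop("masking every site under CV2 would be CV1; choose a proper subset")
    maskList <- rep(list(maskedSites), nFolds)
  } else {
    k <- ceiling(s / 2)
    maskList <- lapply(seq_len(nFolds), function(f)
      siteIds[((f - 1 + seq_len(k) - 1) %% s) + 1])
  }
  masks <- lapply(seq_len(nFolds), function(f)
    cellsOf(groups[[f]], maskList[[f]]))
  new("FoldPlan", scheme = scheme, nFolds = nFolds, masks = masks,
      testSets = masks, genotypes = genotypeIds, sites = siteIds,
      seed = as.integer(seed))
}

#' Remove masked cells from a phenotype table
#'
#' Returns the training records of a fold: all records whose
#' (genotype, site) cell is not masked. The input table is untouched.
#'
#' @param data phenotype data.frame.
#' @param plan a \linkS4class{FoldPlan}.
#' @param fold fold index.
#' @return the training phenotype data.frame.
#' @export
maskRecords <- function(data, plan, fold) {
  fold <- as.integer(fold)
  if (fold < 1L || fold > plan@nFolds) stop("invalid fold index")
  mask <- plan@masks[[fold]]
  if (!nrow(mask)) return(data)
  key <- paste(data$genotype, data$site, sep = "\r")
  mkey <- paste(mask$genotype, mask$site, sep = "\r")
  data[!key %in% mkey, , drop = FALSE]
}

#' Observed breeding values from replicated records
#'
#' The observed value of a genotype at a site is the mean of its replicate
#' yields there, centred (by default) by the site mean of those genotype
#' means; this is the usual two-stage operationalization of "observed
#' breeding value". Cells never observed are \code{NA}.
#'
#' @param data phenotype data.frame.
#' @param center centre by site means (default TRUE); \code{FALSE} returns
#'   raw genotype means.
#' @return genotype x site matrix.
#' @export
observedValues <- function(data, center = TRUE) {
  data <- .assertPhenotypes(data)
  gens <- sort(unique(data$genotype))
  sites <- sort(unique(data$site))
  ckey <- paste(data$genotype, data$site, sep = "\r")
  agg <- rowsum(cbind(data$yield, 1), ckey)
  means <- agg[, 1] / agg[, 2]
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  gi <- match(vapply(parts, `[`, "", 1), gens)
  si <- match(vapply(parts, `[`, "", 2), sites)
  out <- matrix(NA_real_, length(gens), length(sites),
                dimnames = list(gens, sites))
  out[cbind(gi, si)] <- means
  if (center) out <- sweep(out, 2, colMeans(out, na.rm = TRUE))
  out
}

#' Per-site Pearson prediction accuracy over a set of test cells
#'
#' For each site represented in \code{cells}, the Pearson correlation
#' between predicted and observed values over the test genotypes at that
#' site. Sites with fewer than \code{minN} scored cells, or with zero
#' variance in either vector, yield \code{NA} with a warning.
#'
#' @param predicted,observed genotype x site matrices.
#' @param cells data.frame of (genotype, site) test cells.
#' @param minN minimum test cells per site (default 3).
#' @return data.frame with columns \code{site}, \code{pearson_r},
#'   \code{n_test}.
#' @export
cvAccuracy <- function(predicted, observed, cells, minN = 3) {
  sites <- unique(cells$site)
  out <- data.frame(site = sites, pearson_r = NA_real_,
                    n_test = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(sites)) {
    cs <- cells[cells$site == sites[k], , drop = FALSE]
    pred <- predicted[cbind(match(cs$genotype, rownames(predicted)),
                            match(cs$site, colnames(predicted)))]
    obs <- observed[cbind(match(cs$genotype, rownames(observed)),
                          match(cs$site, colnames(observed)))]
    ok <- is.finite(pred) & is.finite(obs)
    out$n_test[k] <- sum(ok)
    if (sum(ok) < minN) {
      warning("fewer than ", minN, " scored cells at site ", sites[k])
      next
    }
    if (stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) {
      warning("zero variance at site ", sites[k],
              "; correlation undefined")
      next
    }
    out$pearson_r[k] <- stats::cor(pred[ok], obs[ok])
  }
  out
}

#' CVResult: cross-validation accuracy tables
#'
#' @slot accuracy tidy per-fold accuracies: scheme, model, site, fold,
#'   pearson_r, n_test, converged.
#' @slot summary per site x model mean and sd across converged folds, with
#'   the number of folds excluded for non-convergence.
#' @slot plan the \linkS4class{FoldPlan} used.
#' @export
setClass("CVResult",
  representation(accuracy = "data.frame", summary = "data.frame",
                 plan = "FoldPlan"))

setMethod("show", "CVResult", function(object) {
  cat("CVResult:", object@plan@scheme, "with", object@plan@nFolds,
      "fold(s)\n")
  print(object@summary, digits = 3)
})

#' Run a cross-validation experiment end to end
#'
#' Builds the kernels once from the marker panel (QC, EM imputation,
#' additive and - where required - epistatic kernels), then for every fold
#' of the plan fits each requested model on the masked training records and
#' scores the test cells against the observed breeding values of the full
#' table. Non-converged fold fits are kept in the tidy table but excluded
#' from the per-site means, with an explicit count. Fully reproducible under
#' \code{seed}.
#'
#' @param data phenotype data.frame (genotype, site, rep, yield).
#' @param markers a \linkS4class{MarkerMatrix} covering the phenotyped
#'   genotypes.
#' @param scheme \code{"CV1"}, \code{"CV2"} or \code{"CV3"}.
#' @param modelNames subset of \code{c("FA", "FA+G", "FA+GG", "FA+G+GG")}.
#' @param nFolds,seed,maskedSites,focalSite,nTrainFocal passed to
#'   \code{\link{makeFolds}}.
#' @param faOrder FA order q for every kernel term.
#' @param qc apply \code{\link{qcFilter}} before imputation (default TRUE).
#' @param observed \code{"centered"} (default) scores against site-centred
#'   genotype means, \code{"raw"} against raw means, or a genotype x site
#'   matrix of true genetic values (e.g. from \linkS4class{SimTruth}).
#' @param fitArgs list of extra arguments for \code{\link{fitFAMM}}.
#' @return a \linkS4class{CVResult}.
#' @export
runCV <- function(data, markers, scheme, modelNames = "FA+G", nFolds = 5,
                  seed = 1, maskedSites = NULL, focalSite = NULL,
                  nTrainFocal = 20, faOrder = 1, qc = TRUE,
                  observed = "centered", fitArgs = list()) {
  data <- .assertPhenotypes(data)
  gens <- sort(unique(data$genotype))
  sites <- sort(unique(data$site))
  if (!all(gens %in% genotypeIds(markers)))
    stop("phenotyped genotypes missing from the marker panel: ",
         paste(utils::head(setdiff(gens, genotypeIds(markers)), 5),
               collapse = ", "))

  if (qc) markers <- qcFilter(markers)
  if (anyNA(markerValues(markers))) markers <- imputeEM(markers)
  else if (!markers@imputed) markers <- MarkerMatrix(markerValues(markers),
                                                     imputed = TRUE)
  needG <- any(modelNames %in% c("FA+G", "FA+G+GG", "FA+GG"))
  GA <- if (needG) stabilizeKernel(additiveKernel(markers)) else NULL
  specs <- lapply(modelNames, function(mn) {
    ker <- switch(mn,
      "FA" = list(identityKernel(genotypeIds(markers))),
      "FA+G" = list(GA),
      "FA+GG" = list(epistaticKernel(GA)),
      "FA+G+GG" = list(GA, epistaticKernel(GA)),
      stop("unknown model name: ", mn))
    modelSpec(ker, faOrder = faOrder)
  })
  names(specs) <- modelNames

  plan <- makeFolds(scheme, gens, sites, nFolds = nFolds, seed = seed,
                    maskedSites = maskedSites, focalSite = focalSite,
                    nTrainFocal = nTrainFocal)
  obsMat <- if (is.matrix(observed)) observed
    else observedValues(data, center = !identical(observed, "raw"))

  rows <- list()
  for (f in seq_len(plan@nFolds)) {
    train <- maskRecords(data, plan, f)
    ## leakage guard: no test cell may appear in the training records
    tkey <- paste(train$genotype, train$site, sep = "\r")
    mkey <- paste(plan@testSets[[f]]$genotype, plan@testSets[[f]]$site,
                  sep = "\r")
    stopifnot(!any(tkey %in% mkey))
    for (mn in modelNames) {
      fit <- tryCatch(
        do.call(fitFAMM, c(list(data = train, spec = specs[[mn]],
                                seed = seed + f), fitArgs)),
        error = function(e) NULL)
      if (is.null(fit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme, model = mn,
          site = unique(plan@testSets[[f]]$site), fold = f,
          pearson_r = NA_real_, n_test = 0L, converged = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      acc <- suppressWarnings(
        cvAccuracy(blupValues(fit), obsMat, plan@testSets[[f]]))
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, model = mn, site = acc$site, fold = f,
        pearson_r = acc$pearson_r, n_test = acc$n_test,
        converged = fit@converged, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  keep <- tab$converged & !is.na(tab$pearson_r)
  if (any(keep)) {
    agg <- stats::aggregate(pearson_r ~ model + site, data = tab[keep, ],
                            FUN = function(r) c(mean = mean(r),
                                                sd = stats::sd(r),
                                                n = length(r)))
    summary <- data.frame(scheme = scheme, model = agg$model, site = agg$site,
                          mean_r = agg$pearson_r[, "mean"],
                          sd_r = agg$pearson_r[, "sd"],
                          n_folds_used = as.integer(agg$pearson_r[, "n"]),
                          stringsAsFactors = FALSE)
    ## a site is only scored in folds whose test set contains it (CV2 masks
    ## rotate); exclusions count scored-but-unusable fold fits
    scored <- stats::aggregate(fold ~ model + site, data = tab, FUN = length)
    idx <- match(paste(summary$model, summary$site),
                 paste(scored$model, scored$site))
    summary$n_folds_excluded <- scored$fold[idx] - summary$n_folds_used
  } else {
    summary <- data.frame(scheme = character(0), model = character(0),
                          site = character(0), mean_r = numeric(0),
                          sd_r = numeric(0), n_folds_used = integer(0),
                          n_folds_excluded = integer(0))
  }
  new("CVResult", accuracy = tab, summary = summary, plan = plan)
}
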