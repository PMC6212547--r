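#' Among-locality differentiation within one ecotype
#'
#' Restricts the data to one ecotype's samples, fits the per-feature
#' among-locality model (2-df moderated F) and applies SGoF at the given
#' level; returns the declared set.
#'
#' @param values feature matrix (features x samples) or [HybSet-class].
#' @param samples per-column metadata with `ecotype` and `locality`.
#' @param ecotype `"crab"` or `"wave"`.
#' @param alpha,gamma SGoF parameters.
#' @return character vector of ids with significant geographic
#'   differentiation.
#' @export
localityDifferentiation <- function(values, samples = NULL, ecotype,
                                    alpha = 0.05, gamma = 0.05) {
  if (is(values, "HybSet")) {
    if (is.null(samples)) samples <- sampleInfo(values)
    values <- intensities(values)
  }
  sel <- samples$ecotype == ecotype
  if (!any(sel)) stop("no samples for ecotype ", ecotype)
  sub <- samples[sel, , drop = FALSE]
  if (length(unique(sub$locality)) != 3L)
    stop("ecotype ", ecotype, " must be present in all three localities")
  fit <- fitRowModels(values[, sel, drop = FALSE], sub,
                      "locality_within_ecotype")
  fit <- moderateVariances(fit)
  pv <- contrastPvalues(fit, paste0("locality_", ecotype))
  declared(sgof(pv[, 1], alpha = alpha, gamma = gamma, ids = rownames(pv)))
}

#' Enrichment of geographic differentiation in a focal set
#'
#' Observed fraction = |sig n focal| / |focal|.  The null resamples B
#' equal-size sets uniformly from the universe and records the significant
#' fraction of each; reported are the null mean, the 2.5/97.5 percentile
#' interval and p = (1 + #\{f* >= f_obs\}) / (B + 1).
#'
#' @param sigSet ids with significant among-locality differentiation.
#' @param focalSet the set whose enrichment is tested (parallel or
#'   nonparallel features); must be non-empty.
#' @param universe all analysed ids.
#' @param B number of resamples.
#' @param seed RNG seed.
#' @param label annotation stored in the result.
#' @return a [GeographyResult-class].
#' @export
parallelEnrichmentResample <- function(sigSet, focalSet, universe, B = 1000,
                                       seed = 1, label = "parallel") {
  if (!length(focalSet)) stop("focal set is empty")
  stopifnot(B >= 1, all(focalSet %in% universe), all(sigSet %in% universe))
  n <- length(focalSet)
  fObs <- length(intersect(sigSet, focalSet)) / n
  inSig <- universe %in% sigSet
  N <- length(universe)
  fNull <- withSeed(seed, {
    vapply(seq_len(B), function(b) sum(inSig[sample.int(N, n)]) / n,
           numeric(1))
  })
  new("GeographyResult", label = label, frac_obs = fObs,
      null_mean = mean(fNull),
      null_ci = unname(quantile(fNull, c(0.025, 0.975))),
      p = (1 + sum(fNull >= fObs)) / (B + 1),
      B = as.integer(B), seed = as.integer(seed))
}
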