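#' Classify parallel features as directional or nondirectional
#'
#' A parallel feature is directional (D) when the signed crab-minus-wave
#' estimate has the same nonzero sign in all three localities, and
#' nondirectional (ND) otherwise; an exactly zero estimate counts as a
#' sign mismatch.
#'
#' @param effects numeric matrix (features x 3 localities) of signed
#'   contrast estimates, rownames = feature ids.
#' @param parallelSet ids to classify (must be rows of `effects`).
#' @return a [DirectionResult-class] (randomization slots NA).
#' @export
classifyDirections <- function(effects, parallelSet) {
  if (ncol(effects) != 3L) stop("one signed estimate per locality is required")
  if (!all(parallelSet %in% rownames(effects)))
    stop("missing locality estimates for some features")
  e <- effects[parallelSet, , drop = FALSE]
  if (anyNA(e)) stop("missing locality estimate")
  s <- sign(e)
  isD <- (abs(rowSums(s)) == 3)
  cls <- ifelse(isD, "D", "ND")
  new("DirectionResult",
      sign_matrix = s, classes = unname(cls),
      D_obs = as.integer(sum(isD)), ND_obs = as.integer(sum(!isD)),
      null_mean_D = NA_real_, null_mean_ND = NA_real_,
      ci_D = c(NA_real_, NA_real_), ci_ND = c(NA_real_, NA_real_),
      p = NA_real_, R = 0L, seed = NA_integer_)
}

#' Randomization test of the directional excess
#'
#' Each replicate independently permutes, within each locality, the signed
#' estimates across the pooled features and recounts directional cases.
#' The null expectation and 95% percentile interval of the D count come
#' from the replicates; p = (1 + #\{D* >= D_obs\}) / (R + 1).
#'
#' @inheritParams classifyDirections
#' @param R number of randomizations.
#' @param seed RNG seed.
#' @param pool permute within the parallel set only (`"parallel"`, the
#'   stricter default) or across all features of `effects` (`"all"`),
#'   recounting D among draws of |parallelSet| features.
#' @return a complete [DirectionResult-class].
#' @export
directionRandomization <- function(effects, parallelSet, R = 10000, seed = 1,
                                   pool = c("parallel", "all")) {
  pool <- match.arg(pool)
  if (length(parallelSet) < 2L)
    stop("need at least 2 parallel features to randomize")
  res <- classifyDirections(effects, parallelSet)
  poolSigns <- if (pool == "parallel") res@sign_matrix
               else sign(effects)
  n <- length(parallelSet)
  m <- nrow(poolSigns)
  Dnull <- withSeed(seed, {
    vapply(seq_len(R), function(r) {
      s <- vapply(1:3, function(j) poolSigns[sample.int(m), j], numeric(m))
      if (pool == "all") s <- s[sample.int(m, n), , drop = FALSE]
      sum(abs(rowSums(s)) == 3)
    }, numeric(1))
  })
  res@null_mean_D <- mean(Dnull)
  res@null_mean_ND <- n - mean(Dnull)
  res@ci_D <- unname(quantile(Dnull, c(0.025, 0.975)))
  res@ci_ND <- unname(n - quantile(Dnull, c(0.975, 0.025)))
  res@p <- (1 + sum(Dnull >= res@D_obs)) / (R + 1)
  res@R <- as.integer(R)
  res@seed <- as.integer(seed)
  res
}

#' Mean intrapopulation variance per feature
#'
#' For each feature, the unbiased sample variance within each ecotype x
#' locality group, averaged over the groups with at least 2 replicates.
#'
#' @param values feature matrix (features x samples) or [HybSet-class].
#' @param samples per-column metadata with `ecotype` and `locality`.
#' @param features optional subset of row ids.
#' @return named numeric vector of per-feature mean within-group variances.
#' @export
intrapopulationVariance <- function(values, samples = NULL, features = NULL) {
  if (is(values, "HybSet")) {
    if (is.null(samples)) samples <- sampleInfo(values)
    values <- intensities(values)
  }
  if (!is.null(features)) values <- values[features, , drop = FALSE]
  grp <- interaction(samples$ecotype, samples$locality, drop = TRUE)
  sizes <- table(grp)
  use <- names(sizes)[sizes >= 2L]
  if (!length(use)) stop("every group has fewer than 2 replicates")
  vs <- vapply(use, function(g)
    matrixStats::rowVars(values[, grp == g, drop = FALSE]),
    numeric(nrow(values)))
  out <- rowMeans(vs)
  names(out) <- rownames(values)
  out
}

#' Compare intrapopulation variances between D and ND features
#'
#' Two-tailed unpaired t test (pooled variance by default, Welch optional)
#' of the per-feature variances of directional vs nondirectional features,
#' a label-permutation p-value for the difference of class means, and the
#' ND/D ratio of class means.
#'
#' @param variances named numeric vector (see [intrapopulationVariance()]).
#' @param classes character vector of `"D"`/`"ND"`, aligned with
#'   `variances`.
#' @param R label permutations.
#' @param seed RNG seed.
#' @param welch use the Welch t instead of the pooled-variance t.
#' @return a [VarianceComparison-class].
#' @export
compareVariances <- function(variances, classes, R = 10000, seed = 1,
                             welch = FALSE) {
  stopifnot(length(variances) == length(classes))
  vD <- variances[classes == "D"]
  vN <- variances[classes == "ND"]
  if (!length(vD) || !length(vN)) stop("both classes must be non-empty")
  n1 <- length(vD); n2 <- length(vN)
  m1 <- mean(vD); m2 <- mean(vN)
  if (welch) {
    se2 <- var(vD) / n1 + var(vN) / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((var(vD) / n1)^2 / (n1 - 1) + (var(vN) / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * var(vD) + (n2 - 1) * var(vN)) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tp <- if (is.nan(tstat)) 1 else 2 * pt(-abs(tstat), df)
  obs <- m1 - m2
  permD <- withSeed(seed, {
    vapply(seq_len(R), function(r) {
      lab <- sample(classes)
      mean(variances[lab == "D"]) - mean(variances[lab == "ND"])
    }, numeric(1))
  })
  permP <- (1 + sum(abs(permD) >= abs(obs))) / (R + 1)
  new("VarianceComparison",
      var_D = unname(vD), var_ND = unname(vN),
      mean_D = m1, mean_ND = m2,
      ratio = if (m1 > 0) m2 / m1 else NA_real_,
      t_stat = tstat, t_df = df, t_p = tp,
      perm_p = permP, R = as.integer(R), seed = as.integer(seed))
}
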