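#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median pnorm dnorm pt pf pbinom qbinom dhyper pchisq
#'   rnorm rchisq runif quantile sd var setNames model.matrix
#' @importFrom utils write.table read.delim head
NULL

.SCALES <- c("linear", "log2")
.LAYOUTS <- c("single", "two_channel", "mvalue")

#' Container for probe- or gene-level hybridization intensities
#'
#' `HybSet` extends [SummarizedExperiment::SummarizedExperiment] with two
#' bookkeeping slots: the measurement scale (`"linear"` or `"log2"`) and the
#' channel layout.  Layout `"single"` holds one column per one-channel array
#' (expression pools), `"two_channel"` one column per channel per array
#' (column names `<sample_id>__cy3` / `<sample_id>__cy5`, the Cy3 channel
#' carrying the individual and Cy5 the common reference), and `"mvalue"` one
#' column of log2 sample/reference ratios per individual.
#'
#' Row metadata is the array design (`probe_id`, `gene_id`, `probe_index`,
#' `is_empty`); column metadata is the sample design.
#'
#' @slot scale character(1), `"linear"` or `"log2"`.
#' @slot layout character(1), `"single"`, `"two_channel"` or `"mvalue"`.
#' @export
setClass("HybSet",
  contains = "SummarizedExperiment",
  representation(scale = "character", layout = "character"))

setValidity("HybSet", function(object) {
  msg <- NULL
  if (length(object@scale) != 1L || !object@scale %in% .SCALES)
    msg <- c(msg, "scale must be one of 'linear', 'log2'")
  if (length(object@layout) != 1L || !object@layout %in% .LAYOUTS)
    msg <- c(msg, "layout must be one of 'single', 'two_channel', 'mvalue'")
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a) || any(!is.finite(a)))
    msg <- c(msg, "intensities must be finite and non-missing")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("probe_id", "gene_id", "probe_index", "is_empty")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (identical(object@layout, "two_channel")) {
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sample_id", "channel") %in% colnames(cd)))
      msg <- c(msg, "two_channel layout needs colData columns sample_id, channel")
    else {
      tab <- table(cd$sample_id)
      if (any(tab != 2L))
        msg <- c(msg, "every two_channel sample must have exactly cy3 and cy5 columns")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a HybSet
#'
#' @param intensities numeric matrix, probes (or genes) x columns.
#' @param design array-design data.frame (see [generateDesign()]); one row per
#'   matrix row.  Gene-level matrices use a design with one pseudo-probe per
#'   gene.
#' @param samples data.frame of per-column metadata; must have as many rows as
#'   the matrix has columns.
#' @param scale `"linear"` or `"log2"`.
#' @param layout `"single"`, `"two_channel"` or `"mvalue"`.
#' @return A [HybSet-class] object.
#' @export
HybSet <- function(intensities, design, samples, scale = "log2",
                   layout = "single") {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(design) == nrow(intensities),
            nrow(samples) == ncol(intensities))
  rownames(intensities) <- design$probe_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(design),
    colData = S4Vectors::DataFrame(samples, row.names = colnames(intensities)))
  new("HybSet", se, scale = scale, layout = layout)
}

#' Row-wise linear-model fit with optional empirical-Bayes moderation
#'
#' One ordinary-least-squares fit per feature (gene or probe) under a
#' group-means parameterization of the ecotype x locality cells, together
#' with the contrast set of one of the three analyses and, after
#' [moderateVariances()], the shrunken variances and prior hyperparameters.
#'
#' @slot coefficients features x cells matrix of cell-mean estimates.
#' @slot cov_unscaled cells x cells unscaled coefficient covariance
#'   \eqn{(X'X)^{-1}}.
#' @slot sigma2 per-feature residual variance.
#' @slot df_residual per-feature residual degrees of freedom.
#' @slot contrasts named list of cells x q contrast matrices.
#' @slot analysis which analysis the contrasts encode.
#' @slot df_prior,s2_prior empirical-Bayes prior df and variance (NA before
#'   moderation; `df_prior` may be `Inf`).
#' @slot s2_post per-feature posterior (moderated) variance.
#' @export
setClass("ModelFit", representation(
  coefficients = "matrix", cov_unscaled = "matrix",
  sigma2 = "numeric", df_residual = "numeric",
  contrasts = "list", analysis = "character",
  df_prior = "numeric", s2_prior = "numeric", s2_post = "numeric"))

setValidity("ModelFit", function(object) {
  msg <- NULL
  if (any(object@sigma2 < 0, na.rm = TRUE)) msg <- c(msg, "sigma2 must be >= 0")
  if (length(object@sigma2) != nrow(object@coefficients))
    msg <- c(msg, "sigma2 length must match coefficient rows")
  if (length(object@s2_post) &&
      length(object@s2_post) != length(object@sigma2))
    msg <- c(msg, "s2_post length must match sigma2")
  if (is.null(msg)) TRUE else msg
})

#' Result of the SGoF sequential binomial multiple-testing correction
#'
#' @slot n_tests number of p-values.
#' @slot alpha level of the sequential binomial metatest.
#' @slot gamma initial p-value threshold (the binomial success probability).
#' @slot F_count number of p-values at or below gamma.
#' @slot n_declared number of features declared significant.
#' @slot declared ids (or indices as character) of the declared features,
#'   the `n_declared` smallest p-values in stable order.
#' @slot approx TRUE if the chi-square (G) approximation replaced the exact
#'   binomial test.
#' @export
setClass("SGoFResult", representation(
  n_tests = "integer", alpha = "numeric", gamma = "numeric",
  F_count = "integer", n_declared = "integer", declared = "character",
  approx = "logical"))

setValidity("SGoFResult", function(object) {
  msg <- NULL
  if (object@n_declared > object@F_count)
    msg <- c(msg, "n_declared cannot exceed the count of p <= gamma")
  if (object@F_count > object@n_tests)
    msg <- c(msg, "F cannot exceed n_tests")
  if (length(object@declared) != object@n_declared)
    msg <- c(msg, "declared set size must equal n_declared")
  if (is.null(msg)) TRUE else msg
})

#' Three-way parallelism of significant sets
#'
#' Intersection of the per-locality significant sets with the exact
#' intersection null (hypergeometric convolution) and, when requested, its
#' permutation counterpart.
#'
#' @slot sets named list of the three per-locality significant id sets.
#' @slot universe ids of the analysis universe.
#' @slot intersection ids significant in all three localities.
#' @slot k observed intersection size.
#' @slot expected null expectation \eqn{N \prod(n_i/N)}.
#' @slot exact_p exact upper-tail probability \eqn{P(K \ge k)}.
#' @slot perm_p permutation p-value (NA unless computed).
#' @slot perm_null null intersection sizes from the permutation run.
#' @slot R,seed permutation replicate count and seed.
#' @export
setClass("ParallelResult", representation(
  sets = "list", universe = "character", intersection = "character",
  k = "integer", expected = "numeric", exact_p = "numeric",
  perm_p = "numeric", perm_null = "integer", R = "integer", seed = "integer"))

setValidity("ParallelResult", function(object) {
  msg <- NULL
  if (length(object@sets) != 3L) msg <- c(msg, "exactly three sets required")
  sizes <- lengths(object@sets)
  if (length(sizes) == 3L && object@k > min(sizes))
    msg <- c(msg, "k cannot exceed the smallest set")
  if (!all(unlist(object@sets) %in% object@universe))
    msg <- c(msg, "sets must be subsets of the universe")
  if (is.null(msg)) TRUE else msg
})

#' Directional vs nondirectional classification of parallel features
#'
#' @slot sign_matrix features x 3 matrix of signs of the crab-minus-wave
#'   contrast estimate per locality (+1/-1; a zero estimate is treated as a
#'   sign mismatch and recorded as 0).
#' @slot classes per-feature class, `"D"` (all three signs equal and nonzero)
#'   or `"ND"`.
#' @slot D_obs,ND_obs observed class counts.
#' @slot null_mean_D,null_mean_ND randomization-null mean counts.
#' @slot ci_D,ci_ND 2.5/97.5 null percentiles.
#' @slot p randomization p-value for the directional excess.
#' @slot R,seed replicate count and seed.
#' @export
setClass("DirectionResult", representation(
  sign_matrix = "matrix", classes = "character",
  D_obs = "integer", ND_obs = "integer",
  null_mean_D = "numeric", null_mean_ND = "numeric",
  ci_D = "numeric", ci_ND = "numeric",
  p = "numeric", R = "integer", seed = "integer"))

setValidity("DirectionResult", function(object) {
  msg <- NULL
  if (object@D_obs + object@ND_obs != length(object@classes))
    msg <- c(msg, "D + ND must equal the number of classified features")
  if (!all(object@classes %in% c("D", "ND")))
    msg <- c(msg, "classes must be 'D' or 'ND'")
  if (is.null(msg)) TRUE else msg
})

#' Intrapopulation-variance comparison between directional and
#' nondirectional parallel features
#'
#' @slot var_D,var_ND per-feature mean within-group variances by class.
#' @slot mean_D,mean_ND class means.
#' @slot ratio ND/D ratio of mean variances.
#' @slot t_stat,t_df,t_p two-tailed unpaired t test (pooled or Welch).
#' @slot perm_p label-permutation p-value (two-tailed, difference of means).
#' @slot R,seed replicate count and seed.
#' @export
setClass("VarianceComparison", representation(
  var_D = "numeric", var_ND = "numeric",
  mean_D = "numeric", mean_ND = "numeric", ratio = "numeric",
  t_stat = "numeric", t_df = "numeric", t_p = "numeric",
  perm_p = "numeric", R = "integer", seed = "integer"))

setValidity("VarianceComparison", function(object) {
  msg <- NULL
  if (any(c(object@var_D, object@var_ND) < 0))
    msg <- c(msg, "variances must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Geographic-differentiation enrichment of a feature set
#'
#' Fraction of a focal set (parallel or nonparallel features) showing
#' significant among-locality differentiation, against a null of equal-size
#' random sets resampled from the universe.
#'
#' @slot label which focal set the fractions describe.
#' @slot frac_obs observed significant fraction of the focal set.
#' @slot null_mean,null_ci resampling-null mean and 2.5/97.5 percentiles.
#' @slot p resampling p-value (upper tail).
#' @slot B,seed resample count and seed.
#' @export
setClass("GeographyResult", representation(
  label = "character", frac_obs = "numeric",
  null_mean = "numeric", null_ci = "numeric",
  p = "numeric", B = "integer", seed = "integer"))

setValidity("GeographyResult", function(object) {
  msg <- NULL
  if (object@frac_obs < 0 || object@frac_obs > 1)
    msg <- c(msg, "fraction must be in [0,1]")
  if (length(object@null_ci) == 2L && diff(object@null_ci) < 0)
    msg <- c(msg, "CI bounds must be ordered")
  if (is.null(msg)) TRUE else msg
})
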