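#' Measurement scale of a HybSet
#' @param x a [HybSet-class].
#' @return `"linear"` or `"log2"`.
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' Channel layout of a HybSet
#' @param x a [HybSet-class].
#' @return `"single"`, `"two_channel"` or `"mvalue"`.
#' @export
setGeneric("channelLayout", function(x) standardGeneric("channelLayout"))

#' Array design of a HybSet
#' @param x a [HybSet-class].
#' @return data.frame with probe_id, gene_id, probe_index, is_empty.
#' @export
setGeneric("arrayDesign", function(x) standardGeneric("arrayDesign"))

#' Per-column sample metadata of a HybSet
#' @param x a [HybSet-class].
#' @return data.frame of column metadata.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Intensity matrix of a HybSet
#' @param x a [HybSet-class].
#' @return numeric matrix.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Ids declared significant by a multiple-testing procedure
#' @param x a result object.
#' @return character vector of ids.
#' @export
setGeneric("declared", function(x) standardGeneric("declared"))

#' @rdname intensityScale
#' @export
setMethod("intensityScale", "HybSet", function(x) x@scale)

#' @rdname channelLayout
#' @export
setMethod("channelLayout", "HybSet", function(x) x@layout)

#' @rdname arrayDesign
#' @export
setMethod("arrayDesign", "HybSet", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "HybSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname intensities
#' @export
setMethod("intensities", "HybSet", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @rdname declared
#' @export
setMethod("declared", "SGoFResult", function(x) x@declared)

setMethod("show", "HybSet", function(object) {
  cat("HybSet:", nrow(object), "features x", ncol(object), "columns\n")
  cat("  scale:", object@scale, " layout:", object@layout, "\n")
  rd <- SummarizedExperiment::rowData(object)
  cat("  genes:", length(unique(rd$gene_id[!rd$is_empty])),
      " empty spots:", sum(rd$is_empty), "\n")
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit (", object@analysis, "): ",
      nrow(object@coefficients), " features, ",
      length(object@contrasts), " contrasts\n", sep = "")
  if (length(object@s2_post))
    cat("  moderated: d0 =", signif(object@df_prior, 4),
        " s0^2 =", signif(object@s2_prior, 4), "\n")
  else cat("  variances not yet moderated\n")
})

setMethod("show", "SGoFResult", function(object) {
  cat("SGoF: ", object@n_declared, "/", object@n_tests,
      " declared (F = ", object@F_count, ", alpha = ", object@alpha,
      ", gamma = ", object@gamma,
      if (object@approx) ", chi-square approximation" else ", exact binomial",
      ")\n", sep = "")
})

setMethod("show", "ParallelResult", function(object) {
  cat("Parallelism: k =", object@k, "of sets sized",
      paste(lengths(object@sets), collapse = "/"),
      "in universe", length(object@universe), "\n")
  cat("  expected =", signif(object@expected, 4),
      " exact p =", format.pval(object@exact_p), "\n")
  if (!is.na(object@perm_p))
    cat("  permutation p =", format.pval(object@perm_p),
        "(R =", object@R, ")\n")
})

setMethod("show", "DirectionResult", function(object) {
  cat("Directionality: D =", object@D_obs, " ND =", object@ND_obs, "\n")
  if (!is.na(object@p))
    cat("  null E[D] =", signif(object@null_mean_D, 4),
        " 95% CI [", paste(signif(object@ci_D, 4), collapse = ", "),
        "]  p =", format.pval(object@p), "\n")
})

setMethod("show", "VarianceComparison", function(object) {
  cat("Intrapopulation variance: mean D =", signif(object@mean_D, 4),
      " mean ND =", signif(object@mean_ND, 4),
      " ratio ND/D =", signif(object@ratio, 3), "\n")
  cat("  t =", signif(object@t_stat, 4), "(df", signif(object@t_df, 4),
      ") p =", format.pval(object@t_p), "; permutation p =",
      format.pval(object@perm_p), "\n")
})

setMethod("show", "GeographyResult", function(object) {
  cat("Geographic differentiation (", object@label, "): observed fraction ",
      signif(object@frac_obs, 4), "\n  null mean ",
      signif(object@null_mean, 4), " 95% CI [",
      paste(signif(object@null_ci, 4), collapse = ", "),
      "]  p = ", format.pval(object@p), "\n", sep = "")
})
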