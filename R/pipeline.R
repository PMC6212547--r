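#' Pipeline configuration
#'
#' Analysis-stage constants: SGoF levels, permutation/resample counts,
#' filter constants and the normexp offset.  The randomization tests were
#' designed around 200,000 resorts; the default here is 10,000 for desk
#' runtime, with the larger value settable.
#'
#' @param alpha,gamma SGoF parameters.
#' @param R_parallel,R_direction,R_variance permutation counts.
#' @param B_geography resample count for the enrichment null.
#' @param max_frac_below expression gene filter rule ("more than 20% of
#'   probes below background" drops the gene).
#' @param cgh_threshold optional fixed CGH background threshold per channel
#'   (e.g. 10.7); NULL estimates it from the normalized empty spots.
#' @param normexp_offset offset added after normexp correction.
#' @param seed master analysis seed (stage seeds are derived from it).
#' @return classed list `"PipelineConfig"`.
#' @export
pipelineConfig <- function(alpha = 0.05, gamma = 0.05,
                           R_parallel = 10000, R_direction = 10000,
                           R_variance = 10000, B_geography = 1000,
                           max_frac_below = 0.20, cgh_threshold = NULL,
                           normexp_offset = 16, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, gamma > 0, gamma < 1,
            R_parallel >= 1, R_direction >= 1, R_variance >= 1,
            B_geography >= 1, normexp_offset >= 0)
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Percentage of a count within a universe
#'
#' 100 * count / universe rounded half-up to `digits` decimals (the
#' reporting convention for universe percentages; within-parallel fractions
#' are reported as integer percentages with `digits = 0`).
#'
#' @param count,universe non-negative counts, `count <= universe`.
#' @param digits decimals to keep.
#' @return numeric percentage.
#' @examples
#' summarizeCounts(146, 17431)   # 0.8
#' summarizeCounts(132, 146, 0)  # 90
#' @export
summarizeCounts <- function(count, universe, digits = 1) {
  if (any(count > universe)) stop("count cannot exceed universe")
  if (any(universe <= 0)) stop("universe must be positive")
  roundHalfUp(100 * count / universe, digits)
}

#' Format a count as "x% (n)"
#'
#' @inheritParams summarizeCounts
#' @return character like `"17.2% (2998)"`; a trailing ".0" is dropped, as
#'   in `"13% (2266)"`.
#' @export
formatCountPercent <- function(count, universe, digits = 1) {
  pct <- summarizeCounts(count, universe, digits)
  s <- formatC(pct, format = "f", digits = digits)
  s <- sub("\\.0+$", "", s)
  sprintf("%s%% (%d)", s, count)
}

.sgofSets <- function(pv, alpha, gamma) {
  sets <- lapply(seq_len(ncol(pv)), function(j)
    declared(sgof(pv[, j], alpha, gamma, ids = rownames(pv))))
  names(sets) <- colnames(pv)
  sets
}

.writeTsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

.setTsv <- function(ids, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  .writeTsv(data.frame(id = ids), dir, name)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates: simulation of both assays, preprocessing (thresholds,
#' filters, normalization, summarization, M-values, joint filter), the
#' per-locality ecotype models with empirical-Bayes moderation and SGoF,
#' the parallelism tests (exact and permutation), the
#' directional/nondirectional classification and randomization, the
#' intrapopulation-variance comparison, and the geographic-differentiation
#' enrichment.  All tabular artifacts are written under `outDir` when
#' given; reruns with the same configurations are identical.
#'
#' @param simConfig a [simulationConfig()].
#' @param pipeConfig a [pipelineConfig()].
#' @param outDir optional artifact directory.
#' @param assays which assays to analyse (`"expression"`, `"cgh"` or both);
#'   restricting to one shortens null-calibration runs.
#' @return a list report (class `"parasnailReport"`): per-assay universes,
#'   per-locality significant sets and counts, [ParallelResult-class]s,
#'   [DirectionResult-class]s, [VarianceComparison-class]s, geography
#'   results, the G test of count heterogeneity, a Table-1-style count
#'   table, the moderation hyperparameters and the truth table.
#' @export
runPipeline <- function(simConfig = simulationConfig(),
                        pipeConfig = pipelineConfig(),
                        outDir = NULL,
                        assays = c("expression", "cgh")) {
  assays <- match.arg(assays, several.ok = TRUE)
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  design <- generateDesign(simConfig$n_genes, simConfig$probes_per_gene,
                           simConfig$n_empty_spots)
  truth <- generateTruth(design, simConfig)
  report <- list(simConfig = simConfig, pipeConfig = pipeConfig,
                 truth = truth)
  localities <- c("Burela", "Roncudo", "Silleiro")
  ps <- pipeConfig$seed

  analyseAssay <- function(values, samples, universe, assayName, effectsFit) {
    pv <- contrastPvalues(effectsFit)
    sets <- .sgofSets(pv, pipeConfig$alpha, pipeConfig$gamma)
    par <- testParallelism(sets, universe,
                           R = pipeConfig$R_parallel,
                           seed = childSeed(ps, 11))
    effects <- contrastEstimates(effectsFit)
    direction <- NULL
    varcmp <- NULL
    if (par@k >= 2L) {
      direction <- directionRandomization(effects, par@intersection,
                                          R = pipeConfig$R_direction,
                                          seed = childSeed(ps, 12))
      if (direction@D_obs > 0L && direction@ND_obs > 0L) {
        iv <- intrapopulationVariance(values, samples, par@intersection)
        varcmp <- compareVariances(iv, direction@classes,
                                   R = pipeConfig$R_variance,
                                   seed = childSeed(ps, 13))
      }
    }
    geoSets <- lapply(c("crab", "wave"), function(e)
      localityDifferentiation(values, samples, e,
                              pipeConfig$alpha, pipeConfig$gamma))
    names(geoSets) <- c("crab", "wave")
    nonparallel <- setdiff(Reduce(union, sets), par@intersection)
    geo <- list()
    for (e in c("crab", "wave")) {
      if (length(par@intersection))
        geo[[paste0(e, "_parallel")]] <- parallelEnrichmentResample(
          geoSets[[e]], par@intersection, universe,
          B = pipeConfig$B_geography, seed = childSeed(ps, 14),
          label = paste0(assayName, " ", e, " parallel"))
      if (length(nonparallel))
        geo[[paste0(e, "_nonparallel")]] <- parallelEnrichmentResample(
          geoSets[[e]], nonparallel, universe,
          B = pipeConfig$B_geography, seed = childSeed(ps, 15),
          label = paste0(assayName, " ", e, " nonparallel"))
    }
    list(universe = universe, pvalues = pv, sets = sets,
         parallel = par, effects = effects, direction = direction,
         variance = varcmp, geography_sets = geoSets, geography = geo,
         hyper = c(d0 = effectsFit@df_prior, s02 = effectsFit@s2_prior))
  }

  # -- preprocessing ---------------------------------------------------------
  geneSet <- NULL; repE <- NULL; thrE <- NULL
  if ("expression" %in% assays) {
    sdE <- generateSampleDesign("expression")
    exprSet <- simulateExpression(design, truth, sdE, simConfig)
    thrE <- backgroundThreshold(exprSet)
    repE <- filterExpressionGenes(exprSet, thrE, pipeConfig$max_frac_below)
    qnE <- quantileNormalize(exprSet, includeEmpty = FALSE)
    geneSet <- summarizeGenes(qnE, repE$kept_probes)
  }
  mset <- NULL; repC <- NULL; thrC <- NULL
  if ("cgh" %in% assays) {
    sdC <- generateSampleDesign("cgh")
    cghSet <- simulateCGH(design, truth, sdC, simConfig)
    lin <- HybSet(2^intensities(cghSet), arrayDesign(cghSet),
                  sampleInfo(cghSet), scale = "linear",
                  layout = "two_channel")
    corSet <- normexpCorrect(lin, offset = pipeConfig$normexp_offset)
    lg <- HybSet(log2(intensities(corSet)), arrayDesign(corSet),
                 sampleInfo(corSet), scale = "log2", layout = "two_channel")
    qnC <- quantileNormalize(lg, includeEmpty = TRUE)
    thrC <- if (!is.null(pipeConfig$cgh_threshold)) pipeConfig$cgh_threshold
            else c(cy3 = backgroundThreshold(qnC, "cy3"),
                   cy5 = backgroundThreshold(qnC, "cy5"))
    repC <- filterCGHProbes(qnC, thrC)
    mset <- computeLogRatios(qnC)
  }

  # only features passing both assays' filters enter the joint analyses
  exprGenes <- if (!is.null(repE)) repE$kept_genes else NULL
  cghProbes <- if (!is.null(repC)) repC$kept_probes else NULL
  if (all(c("expression", "cgh") %in% assays)) {
    joint <- intersectFilters(repE, repC, design)
    exprGenes <- joint$genes
    cghProbes <- joint$probes
    report$joint_filter <- joint
  }

  # -- analyses --------------------------------------------------------------
  if ("expression" %in% assays) {
    evals <- intensities(geneSet)[exprGenes, , drop = FALSE]
    esamples <- sampleInfo(geneSet)
    fitE <- moderateVariances(
      fitRowModels(evals, esamples, "ecotype_within_locality"))
    report$expression <- analyseAssay(evals, esamples, exprGenes,
                                      "expression", fitE)
    report$expression$threshold <- thrE
    report$expression$filter <- repE
    report$expr_matrix <- geneSet
  }

  if ("cgh" %in% assays) {
    mvals <- intensities(mset)[cghProbes, , drop = FALSE]
    msamples <- sampleInfo(mset)
    fitC <- moderateVariances(
      fitRowModels(mvals, msamples, "ecotype_within_locality"))
    report$cgh <- analyseAssay(mvals, msamples, cghProbes, "cgh", fitC)
    report$cgh$threshold <- thrC
    report$cgh$filter <- repC
    report$cgh$gene_sets <- lapply(report$cgh$sets, geneLevelCalls, design)
    report$cgh$gene_parallel <- Reduce(intersect, report$cgh$gene_sets)
    report$cgh_matrix <- mset
  }

  if (all(c("expression", "cgh") %in% assays)) {
    jointGenes <- report$joint_filter$genes
    exprSets <- lapply(report$expression$sets, intersect, jointGenes)
    cghGeneSets <- lapply(report$cgh$gene_sets, intersect, jointGenes)
    perLoc <- data.frame(
      locality = localities,
      transcriptomic = unname(lengths(exprSets)),
      genomic = unname(lengths(cghGeneSets)),
      both = unname(lengths(Map(intersect, exprSets, cghGeneSets))),
      row.names = NULL)
    N <- length(jointGenes)
    parE <- intersect(Reduce(intersect, exprSets), jointGenes)
    parC <- intersect(Reduce(intersect, cghGeneSets), jointGenes)
    parBoth <- intersect(parE, parC)
    counts <- rbind(perLoc,
                    data.frame(locality = "parallel",
                               transcriptomic = length(parE),
                               genomic = length(parC),
                               both = length(parBoth)))
    counts$transcriptomic_pct <- summarizeCounts(counts$transcriptomic, N)
    counts$genomic_pct <- summarizeCounts(counts$genomic, N)
    counts$both_pct <- summarizeCounts(counts$both, N)
    report$count_table <- counts
    report$universe_size <- N
    gtab <- cbind(sig = perLoc$transcriptomic,
                  nonsig = N - perLoc$transcriptomic)
    report$g_test_expression <- gTestHeterogeneity(gtab)
    gtabC <- cbind(sig = perLoc$genomic, nonsig = N - perLoc$genomic)
    report$g_test_cgh <- gTestHeterogeneity(gtabC)
  }

  if (!is.null(outDir)) .writeReport(report, outDir)
  class(report) <- "parasnailReport"
  report
}

.writeReport <- function(report, dir) {
  if (!is.null(report$count_table))
    .writeTsv(report$count_table, dir, "count_table.tsv")
  for (assayName in c("expression", "cgh")) {
    a <- report[[assayName]]
    if (is.null(a)) next
    for (l in names(a$sets))
      .setTsv(a$sets[[l]], dir, sprintf("%s_sig_%s.tsv", assayName, l))
    .setTsv(a$parallel@intersection, dir,
            sprintf("%s_parallel.tsv", assayName))
    if (!is.null(a$direction)) {
      sm <- data.frame(id = rownames(a$direction@sign_matrix),
                       a$direction@sign_matrix, class = a$direction@classes)
      colnames(sm)[2:4] <- paste0("sign_", seq_len(3))
      .writeTsv(sm, dir, sprintf("%s_sign_matrix.tsv", assayName))
    }
    par <- a$parallel
    .writeTsv(data.frame(
      n1 = lengths(par@sets)[1], n2 = lengths(par@sets)[2],
      n3 = lengths(par@sets)[3], N = length(par@universe), k = par@k,
      expected = par@expected, exact_p = par@exact_p, perm_p = par@perm_p,
      R = par@R, seed = par@seed), dir,
      sprintf("%s_parallelism.tsv", assayName))
  }
  invisible(dir)
}

#' @export
print.parasnailReport <- function(x, ...) {
  cat("parasnail pipeline report\n")
  if (!is.null(x$count_table)) {
    cat("joint universe:", x$universe_size, "genes\n")
    print(x$count_table, row.names = FALSE)
  }
  for (a in c("expression", "cgh")) {
    if (is.null(x[[a]])) next
    cat("\n==", a, "==\n")
    show(x[[a]]$parallel)
    if (!is.null(x[[a]]$direction)) show(x[[a]]$direction)
    if (!is.null(x[[a]]$variance)) show(x[[a]]$variance)
  }
  invisible(x)
}
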