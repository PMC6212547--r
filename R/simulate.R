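#' Generate a synthetic array design
#'
#' Builds a probe-to-gene map in the style of an oligonucleotide expression
#' array: each gene is represented by a fixed number of probes (five by
#' default, as on typical NimbleGen designs) and the array additionally
#' carries empty spots -- positions with no probe, used downstream to
#' estimate the background hybridization signal.
#'
#' @param nGenes number of genes (>= 1).
#' @param probesPerGene probes per gene (>= 1).
#' @param nEmptySpots number of empty spots (>= 0).
#' @param seed unused randomness hook kept for interface symmetry; the design
#'   is deterministic.
#' @return data.frame with columns `probe_id`, `gene_id` (NA for empty
#'   spots), `probe_index`, `is_empty`.
#' @examples
#' d <- generateDesign(10, 5, 2)
#' table(d$is_empty)
#' @export
generateDesign <- function(nGenes, probesPerGene = 5, nEmptySpots = 0,
                           seed = NULL) {
  if (nGenes < 1 || probesPerGene < 1 || nEmptySpots < 0)
    stop("nGenes and probesPerGene must be >= 1 and nEmptySpots >= 0")
  gene_id <- sprintf("G%05d", seq_len(nGenes))
  probes <- data.frame(
    probe_id = sprintf("%s_P%d", rep(gene_id, each = probesPerGene),
                       rep(seq_len(probesPerGene), nGenes)),
    gene_id = rep(gene_id, each = probesPerGene),
    probe_index = rep(seq_len(probesPerGene), nGenes),
    is_empty = FALSE, stringsAsFactors = FALSE)
  if (nEmptySpots > 0) {
    empty <- data.frame(
      probe_id = sprintf("EMPTY_%05d", seq_len(nEmptySpots)),
      gene_id = NA_character_, probe_index = 1L, is_empty = TRUE,
      stringsAsFactors = FALSE)
    probes <- rbind(probes, empty)
  }
  assertArrayDesign(probes)
  probes
}

#' Validate an array-design data.frame
#'
#' Checks the design invariants: required columns, non-empty probes mapping
#' to exactly one gene, empty spots mapping to none.
#'
#' @param design data.frame as returned by [generateDesign()].
#' @return the design, invisibly; errors if invalid.
#' @export
assertArrayDesign <- function(design) {
  need <- c("probe_id", "gene_id", "probe_index", "is_empty")
  if (!all(need %in% colnames(design)))
    stop("array design needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$probe_id)) stop("probe ids must be unique")
  if (any(is.na(design$gene_id) & !design$is_empty))
    stop("non-empty probes must map to a gene")
  if (any(!is.na(design$gene_id) & design$is_empty))
    stop("empty spots must not map to a gene")
  if (sum(!design$is_empty) < 1) stop("design must contain at least one gene probe")
  invisible(design)
}

#' Generate the sample design of one assay
#'
#' The experimental structure: two ecotypes ("crab", "wave") sampled in each
#' of three localities.  Expression is assayed on pooled samples (four pools
#' per ecotype and locality by default, each pool of 15 individuals);
#' genomic divergence (CGH) on single individuals (12 per group by default),
#' each hybridized on a two-colour array against a common reference.
#'
#' @param assay `"expression"` or `"cgh"`.
#' @param nReplicates replicates per ecotype x locality group; defaults to 4
#'   pools (expression) or 12 individuals (cgh).
#' @param localities three locality labels.
#' @return data.frame with columns `sample_id`, `assay`, `ecotype`,
#'   `locality`, `replicate`.
#' @export
generateSampleDesign <- function(assay = c("expression", "cgh"),
                                 nReplicates = NULL,
                                 localities = c("Burela", "Roncudo", "Silleiro")) {
  assay <- match.arg(assay)
  if (length(localities) != 3L) stop("exactly three localities are required")
  if (is.null(nReplicates))
    nReplicates <- if (assay == "expression") 4L else 12L
  if (nReplicates < 2L) stop("each group needs at least 2 replicates")
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      ecotype = c("crab", "wave"), locality = localities,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prefix <- if (assay == "expression") "expr" else "cgh"
  data.frame(
    sample_id = sprintf("%s_%s_%s_%02d", prefix, grid$locality, grid$ecotype,
                        grid$replicate),
    assay = assay, ecotype = grid$ecotype, locality = grid$locality,
    replicate = grid$replicate, stringsAsFactors = FALSE)
}

#' Configuration of the synthetic-data generator
#'
#' Fixes every parameter of the simulated study: array size, truth-class
#' fractions, effect sizes (log2 units), the baseline/affinity/background
#' model, the scaled-inverse-chi-square prior on within-group variances
#' (the prior the moderation model assumes), sample dropout emulating
#' quality-control losses, and the master seed.
#'
#' @param n_genes,probes_per_gene,n_empty_spots array dimensions.
#' @param frac_parallel_directional,frac_parallel_nondirectional,frac_locality_specific
#'   fractions of genes in each non-null truth class (must sum to <= 1; the
#'   remainder is null).  The same fractions drive an independent class draw
#'   for the CGH assay.
#' @param effect_size ecotype-effect magnitude Delta, in log2 units by
#'   default.
#' @param effect_in_sd_units if TRUE, `effect_size` is expressed in units
#'   of each gene's own within-group sd (Delta_g = effect_size * sigma_g;
#'   CGH effects scale with the M-value sd, sqrt(2) * sigma_g), making
#'   detection power independent of the gene's noise level.
#' @param baseline_mean,baseline_sd gene baseline distribution (log2).
#' @param probe_affinity_sd per-probe affinity spread (log2).
#' @param d0_true,s02_true prior df and scale of the within-group variance
#'   prior: sigma_g^2 ~ s02_true * d0_true / chisq(d0_true).
#' @param background_mean,background_sd empty-spot signal (log2).
#' @param dropout_expression,dropout_cgh number of randomly dropped columns
#'   per assay (never emptying a group below 2 replicates); defaults 2 and 3
#'   emulate retaining 22 of 24 pools and 69 of 72 individuals.
#' @param pool_size_effect noise-variance divisor for pooled expression
#'   samples (sd scaled by 1/sqrt of this; 1 = no reduction).
#' @param directional_sd_factor multiplier on the within-group sd of
#'   parallel-directional genes (1 = same as other classes).
#' @param locality_shift sd of per-locality baseline shifts added to
#'   parallel-class genes (both ecotypes), creating geographic
#'   differentiation; 0 disables.
#' @param cgh_probe_prob probability that each probe of a CGH-affected gene
#'   carries the effect (at least one probe always does).
#' @param seed master seed; fixes all randomness.
#' @return classed list `"SimulationConfig"`.
#' @export
simulationConfig <- function(n_genes = 2000, probes_per_gene = 5,
    n_empty_spots = 200,
    frac_parallel_directional = 0, frac_parallel_nondirectional = 0,
    frac_locality_specific = 0,
    effect_size = 1,
    baseline_mean = 12.5, baseline_sd = 1.2, probe_affinity_sd = 0.7,
    d0_true = 4, s02_true = 0.05,
    background_mean = 10, background_sd = 0.3,
    dropout_expression = 2, dropout_cgh = 3,
    pool_size_effect = 1, directional_sd_factor = 1,
    locality_shift = 0, cgh_probe_prob = 0.5,
    effect_in_sd_units = FALSE, seed = 1) {
  fr <- c(frac_parallel_directional, frac_parallel_nondirectional,
          frac_locality_specific)
  if (any(fr < 0) || sum(fr) > 1)
    stop("class fractions must be non-negative and sum to <= 1")
  if (any(c(baseline_sd, probe_affinity_sd, background_sd, s02_true) <= 0))
    stop("all sds and s02_true must be > 0")
  if (d0_true <= 0 || pool_size_effect <= 0 || directional_sd_factor <= 0)
    stop("d0_true, pool_size_effect and directional_sd_factor must be > 0")
  structure(as.list(environment())[setdiff(names(formals()), "fr")],
            class = "SimulationConfig")
}

.signTriples <- function() {
  s <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  colnames(s) <- NULL
  list(all = s, mixed = s[rowSums(s) != 3 & rowSums(s) != -3, , drop = FALSE])
}

.drawClassEffects <- function(genes, classes, delta) {
  n <- length(genes)
  e <- matrix(0, n, 3)
  tri <- .signTriples()
  iD <- which(classes == "parallel_directional")
  if (length(iD)) {
    s <- sample(c(-1, 1), length(iD), replace = TRUE)
    e[iD, ] <- s * delta
  }
  iN <- which(classes == "parallel_nondirectional")
  if (length(iN)) {
    rows <- tri$mixed[sample.int(nrow(tri$mixed), length(iN), replace = TRUE),
                      , drop = FALSE]
    e[iN, ] <- rows * delta
  }
  iL <- which(classes == "locality_specific")
  if (length(iL)) {
    loc <- sample.int(3, length(iL), replace = TRUE)
    sgn <- sample(c(-1, 1), length(iL), replace = TRUE)
    e[cbind(iL, loc)] <- sgn * delta
  }
  e
}

.assignClasses <- function(geneIds, config) {
  n <- length(geneIds)
  counts <- round(n * c(config$frac_parallel_directional,
                        config$frac_parallel_nondirectional,
                        config$frac_locality_specific))
  if (sum(counts) > n) stop("class fractions allocate more genes than exist")
  classes <- rep("null", n)
  pool <- sample.int(n, sum(counts))
  idx <- split(pool, factor(rep(seq_along(counts), counts),
                            levels = seq_along(counts)))
  labs <- c("parallel_directional", "parallel_nondirectional",
            "locality_specific")
  for (j in seq_along(counts)) if (counts[j] > 0) classes[idx[[j]]] <- labs[j]
  classes
}

#' Generate the ground-truth table for a synthetic dataset
#'
#' Assigns each gene a truth class for the expression assay and,
#' independently, for the CGH assay; draws the signed per-locality effect
#' triples consistent with each class (directional: all three effects equal
#' sign; nondirectional: all nonzero, signs mixed; locality-specific:
#' exactly one nonzero); draws per-gene within-group standard deviations
#' from the scaled-inverse-chi-square prior; and picks which probes of each
#' CGH-affected gene carry the sequence-divergence effect.
#'
#' @param design array design from [generateDesign()].
#' @param config a [simulationConfig()].
#' @return list of class `"TruthTable"` with elements `genes` (gene-level
#'   truth) and `probes` (per-probe CGH effects).
#' @export
generateTruth <- function(design, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  assertArrayDesign(design)
  geneIds <- unique(design$gene_id[!design$is_empty])
  withSeed(childSeed(config$seed, 1), {
    n <- length(geneIds)
    expr_class <- .assignClasses(geneIds, config)
    expr_e <- .drawClassEffects(geneIds, expr_class, config$effect_size)
    cgh_class <- .assignClasses(geneIds, config)
    cgh_e <- .drawClassEffects(geneIds, cgh_class, config$effect_size)
    within_sd <- sqrt(config$s02_true * config$d0_true /
                        rchisq(n, df = config$d0_true))
    within_sd[expr_class == "parallel_directional"] <-
      within_sd[expr_class == "parallel_directional"] *
      config$directional_sd_factor
    cgh_within_sd <- sqrt(config$s02_true * config$d0_true /
                            rchisq(n, df = config$d0_true))
    cgh_within_sd[cgh_class == "parallel_directional"] <-
      cgh_within_sd[cgh_class == "parallel_directional"] *
      config$directional_sd_factor
    if (isTRUE(config$effect_in_sd_units)) {
      expr_e <- expr_e * within_sd
      cgh_e <- cgh_e * (sqrt(2) * cgh_within_sd)
    }
    parallel <- expr_class %in% c("parallel_directional",
                                  "parallel_nondirectional")
    loc_shift <- matrix(0, n, 3)
    cgh_parallel <- cgh_class %in% c("parallel_directional",
                                     "parallel_nondirectional")
    cgh_loc_shift <- matrix(0, n, 3)
    if (config$locality_shift > 0) {
      loc_shift[parallel, ] <- rnorm(3 * sum(parallel),
                                     sd = config$locality_shift)
      cgh_loc_shift[cgh_parallel, ] <- rnorm(3 * sum(cgh_parallel),
                                             sd = config$locality_shift)
    }
    genes <- data.frame(
      gene_id = geneIds, expr_class = expr_class,
      expr_e1 = expr_e[, 1], expr_e2 = expr_e[, 2], expr_e3 = expr_e[, 3],
      loc_shift1 = loc_shift[, 1], loc_shift2 = loc_shift[, 2],
      loc_shift3 = loc_shift[, 3],
      cgh_class = cgh_class,
      cgh_e1 = cgh_e[, 1], cgh_e2 = cgh_e[, 2], cgh_e3 = cgh_e[, 3],
      cgh_loc_shift1 = cgh_loc_shift[, 1], cgh_loc_shift2 = cgh_loc_shift[, 2],
      cgh_loc_shift3 = cgh_loc_shift[, 3],
      within_sd = within_sd, cgh_within_sd = cgh_within_sd,
      stringsAsFactors = FALSE)
    gp <- design[!design$is_empty, ]
    affected <- logical(nrow(gp))
    hit <- geneIds[cgh_class != "null"]
    for (g in hit) {
      rows <- which(gp$gene_id == g)
      a <- runif(length(rows)) < config$cgh_probe_prob
      if (!any(a)) a[sample.int(length(rows), 1)] <- TRUE
      affected[rows] <- a
    }
    probes <- data.frame(probe_id = gp$probe_id, gene_id = gp$gene_id,
                         cgh_affected = affected, stringsAsFactors = FALSE)
    structure(list(genes = genes, probes = probes), class = "TruthTable")
  })
}

# Drop `nDrop` random columns, never leaving any ecotype x locality group
# with fewer than 2 columns.
.dropColumns <- function(samples, nDrop) {
  if (nDrop <= 0) return(seq_len(nrow(samples)))
  keep <- rep(TRUE, nrow(samples))
  grp <- interaction(samples$ecotype, samples$locality, drop = TRUE)
  cand <- sample.int(nrow(samples))
  dropped <- 0L
  for (i in cand) {
    if (dropped >= nDrop) break
    if (sum(keep[grp == grp[i]]) > 2L) {
      keep[i] <- FALSE
      dropped <- dropped + 1L
    }
  }
  which(keep)
}

.baselineDraws <- function(design, config) {
  geneIds <- unique(design$gene_id[!design$is_empty])
  baseline <- rnorm(length(geneIds), config$baseline_mean, config$baseline_sd)
  names(baseline) <- geneIds
  affinity <- rnorm(nrow(design), 0, config$probe_affinity_sd)
  affinity[design$is_empty] <- 0
  list(baseline = baseline, affinity = affinity)
}

#' Simulate one-channel expression intensities
#'
#' Probe intensity = gene baseline + probe affinity + per-locality shift +
#' ecotype effect (added to the crab samples, so the signed truth effect is
#' the crab-minus-wave difference) + Gaussian noise with the gene's
#' within-group sd (divided by sqrt(pool_size_effect) for pooled samples).
#' Empty spots are background noise.  Data are on the log2 scale.
#'
#' @param design array design.
#' @param truth a `"TruthTable"` from [generateTruth()].
#' @param sampleDesign expression sample design.
#' @param config the [simulationConfig()].
#' @return a [HybSet-class], scale `"log2"`, layout `"single"`, with the
#'   post-dropout sample columns.
#' @export
simulateExpression <- function(design, truth, sampleDesign, config) {
  if (!all(sampleDesign$assay == "expression"))
    stop("sampleDesign must describe the expression assay")
  localities <- unique(sampleDesign$locality)
  withSeed(childSeed(config$seed, 2), {
    keep <- .dropColumns(sampleDesign, config$dropout_expression)
    samples <- sampleDesign[keep, , drop = FALSE]
    bd <- .baselineDraws(design, config)
    g <- match(design$gene_id, truth$genes$gene_id)  # NA for empty spots
    nP <- nrow(design); nS <- nrow(samples)
    locIdx <- match(samples$locality, localities)
    eMat <- as.matrix(truth$genes[, c("expr_e1", "expr_e2", "expr_e3")])
    sMat <- as.matrix(truth$genes[, c("loc_shift1", "loc_shift2", "loc_shift3")])
    vals <- matrix(0, nP, nS,
                   dimnames = list(design$probe_id, samples$sample_id))
    noise_sd <- truth$genes$within_sd / sqrt(config$pool_size_effect)
    for (j in seq_len(nS)) {
      l <- locIdx[j]
      mu <- bd$baseline[design$gene_id] + bd$affinity + sMat[g, l]
      if (samples$ecotype[j] == "crab") mu <- mu + eMat[g, l]
      mu[design$is_empty] <- config$background_mean
      sdj <- noise_sd[g]
      sdj[design$is_empty] <- config$background_sd
      vals[, j] <- rnorm(nP, mu, sdj)
    }
    HybSet(vals, design, samples, scale = "log2", layout = "single")
  })
}

#' Simulate two-channel CGH intensities
#'
#' Each retained individual contributes two columns, `<id>__cy3` (the
#' individual's genomic DNA) and `<id>__cy5` (the common reference pool).
#' Both channels share the probe baseline, so the log-ratio
#' M = cy3 - cy5 isolates the injected sequence-divergence effect, which is
#' added to the crab individuals' sample channel on affected probes.
#' Data are on the log2 scale.
#'
#' @inheritParams simulateExpression
#' @param sampleDesign CGH sample design (one row per individual).
#' @return a [HybSet-class], scale `"log2"`, layout `"two_channel"`.
#' @export
simulateCGH <- function(design, truth, sampleDesign, config) {
  if (!all(sampleDesign$assay == "cgh"))
    stop("sampleDesign must describe the cgh assay")
  localities <- unique(sampleDesign$locality)
  withSeed(childSeed(config$seed, 3), {
    keep <- .dropColumns(sampleDesign, config$dropout_cgh)
    samples <- sampleDesign[keep, , drop = FALSE]
    bd <- .baselineDraws(design, config)
    g <- match(design$gene_id, truth$genes$gene_id)
    pa <- match(design$probe_id, truth$probes$probe_id)  # NA for empty
    affected <- truth$probes$cgh_affected[pa]
    affected[is.na(affected)] <- FALSE
    nP <- nrow(design); nI <- nrow(samples)
    locIdx <- match(samples$locality, localities)
    eMat <- as.matrix(truth$genes[, c("cgh_e1", "cgh_e2", "cgh_e3")])
    sMat <- as.matrix(truth$genes[, c("cgh_loc_shift1", "cgh_loc_shift2",
                                      "cgh_loc_shift3")])
    base <- bd$baseline[design$gene_id] + bd$affinity
    base[design$is_empty] <- config$background_mean
    sd_g <- truth$genes$cgh_within_sd[g]
    sd_g[design$is_empty] <- config$background_sd
    cols <- character(2 * nI)
    vals <- matrix(0, nP, 2 * nI)
    chan <- data.frame(sample_id = rep(samples$sample_id, each = 2),
                       channel = rep(c("cy3", "cy5"), nI),
                       ecotype = rep(samples$ecotype, each = 2),
                       locality = rep(samples$locality, each = 2),
                       replicate = rep(samples$replicate, each = 2),
                       assay = "cgh", stringsAsFactors = FALSE)
    for (i in seq_len(nI)) {
      l <- locIdx[i]
      muS <- base
      shift <- sMat[g, l]
      shift[design$is_empty] <- 0
      muS <- muS + shift
      if (samples$ecotype[i] == "crab") {
        eff <- eMat[g, l] * affected
        eff[design$is_empty] <- 0
        muS <- muS + eff
      }
      vals[, 2 * i - 1] <- rnorm(nP, muS, sd_g)
      vals[, 2 * i] <- rnorm(nP, base, sd_g)
      cols[2 * i - 1] <- paste0(samples$sample_id[i], "__cy3")
      cols[2 * i] <- paste0(samples$sample_id[i], "__cy5")
    }
    colnames(vals) <- cols
    rownames(vals) <- design$probe_id
    HybSet(vals, design, chan, scale = "log2", layout = "two_channel")
  })
}

#' Write a simulated dataset as TSV files
#'
#' Emits `expression.tsv` and `cgh.tsv` (probe_id plus one column per
#' sample/channel), `array_design.tsv`, `samples_expression.tsv`,
#' `samples_cgh.tsv` and `truth_genes.tsv` / `truth_probes.tsv`.
#' Output is byte-identical for identical seeds.
#'
#' @param dir output directory (created if missing).
#' @param exprSet,cghSet HybSets from the simulators.
#' @param truth the `"TruthTable"`.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(dir, exprSet, cghSet, truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  mtx <- function(s) data.frame(probe_id = rownames(intensities(s)),
                                format(intensities(s), digits = 10,
                                       trim = TRUE, scientific = FALSE),
                                check.names = FALSE)
  wr(mtx(exprSet), "expression.tsv")
  wr(mtx(cghSet), "cgh.tsv")
  wr(arrayDesign(exprSet), "array_design.tsv")
  wr(sampleInfo(exprSet), "samples_expression.tsv")
  wr(sampleInfo(cghSet), "samples_cgh.tsv")
  wr(truth$genes, "truth_genes.tsv")
  wr(truth$probes, "truth_probes.tsv")
  invisible(dir)
}
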