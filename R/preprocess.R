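#' Background threshold from empty spots
#'
#' The background signal of a channel is the mean log2 intensity of the
#' array's empty spots, averaged over probes and samples.  A user override
#' (e.g. a previously established constant such as 10.7 for a CGH channel)
#' is returned unchanged.
#'
#' @param x a [HybSet-class] on the log2 scale.
#' @param channel for two-channel layouts, `"cy3"` or `"cy5"`; ignored
#'   otherwise.
#' @param override optional numeric threshold that short-circuits the
#'   computation.
#' @return numeric(1) threshold in log2 units.
#' @export
backgroundThreshold <- function(x, channel = NULL, override = NULL) {
  if (!is.null(override)) {
    stopifnot(is.numeric(override), length(override) == 1L, is.finite(override))
    return(override)
  }
  if (intensityScale(x) != "log2")
    stop("background thresholds are defined on the log2 scale")
  d <- arrayDesign(x)
  if (!any(d$is_empty))
    stop("design has no empty spots; supply a threshold via 'override'")
  m <- intensities(x)[d$is_empty, , drop = FALSE]
  if (channelLayout(x) == "two_channel" && !is.null(channel)) {
    ch <- sampleInfo(x)$channel
    m <- m[, ch == channel, drop = FALSE]
    if (ncol(m) == 0L) stop("channel not present: ", channel)
  }
  mean(m)
}

.filterReport <- function(threshold, kept_genes, kept_probes, frac_below) {
  structure(list(threshold = threshold, kept_genes = kept_genes,
                 kept_probes = kept_probes, frac_below = frac_below),
            class = "FilterReport")
}

#' Filter expression genes on the background threshold
#'
#' A probe is below background if its mean log2 signal across samples is
#' below the threshold.  A gene is disregarded iff strictly more than 20% of
#' its probes are below background (so exactly 20% is kept).
#'
#' @param x expression [HybSet-class], log2 scale.
#' @param threshold log2 background threshold (see [backgroundThreshold()]).
#' @param maxFracBelow drop rule cutoff; a gene is dropped when its fraction
#'   of below-background probes exceeds this value strictly.
#' @return a `FilterReport` list: `threshold`, `kept_genes`, `kept_probes`,
#'   `frac_below` (per gene).
#' @export
filterExpressionGenes <- function(x, threshold, maxFracBelow = 0.20) {
  if (intensityScale(x) != "log2") stop("expression filter expects log2 data")
  d <- arrayDesign(x)
  gp <- !d$is_empty
  pm <- rowMeans(intensities(x)[gp, , drop = FALSE])
  below <- pm < threshold
  gene <- d$gene_id[gp]
  nbelow <- tapply(below, gene, sum)
  ntot <- tapply(below, gene, length)
  if (any(ntot == 0)) stop("gene with zero probes in design")
  frac <- nbelow / ntot
  kept <- names(frac)[frac <= maxFracBelow]
  keptProbes <- d$probe_id[gp][gene %in% kept]
  .filterReport(threshold, kept, keptProbes, frac)
}

# E[S | X = x] for the normal-plus-exponential convolution model, computed
# on the log scale for numerical stability at very negative a/sigma.
.normexpPosterior <- function(x, mu, sigma, theta) {
  a <- x - mu - sigma^2 / theta
  z <- a / sigma
  # dnorm(z)/pnorm(z), stable for z << 0
  ratio <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  a + sigma * ratio
}

#' Normexp background correction with offset
#'
#' Models each observed linear-scale intensity as X = S + B with signal
#' S ~ Exponential(theta) and background B ~ Normal(mu, sigma^2).  The
#' background parameters are estimated from the empty spots of each channel;
#' theta is the mean gene-probe intensity minus mu (floored at a small
#' positive value).  Every intensity is replaced by the posterior mean
#' E[S | X = x] plus the offset, which is strictly positive.
#'
#' @param x a [HybSet-class] on the linear scale.
#' @param offset positive stabilizing constant added after correction.
#' @return corrected [HybSet-class], linear scale.
#' @export
normexpCorrect <- function(x, offset = 16) {
  if (intensityScale(x) != "linear")
    stop("normexp correction operates on linear-scale intensities")
  if (offset < 0) stop("offset must be >= 0")
  d <- arrayDesign(x)
  if (!any(d$is_empty))
    stop("normexp background estimation needs empty spots")
  v <- intensities(x)
  out <- v
  groups <- if (channelLayout(x) == "two_channel")
    split(seq_len(ncol(v)), sampleInfo(x)$channel)
  else list(all = seq_len(ncol(v)))
  for (cols in groups) {
    emp <- v[d$is_empty, cols, drop = FALSE]
    mu <- mean(emp)
    sigma <- sd(as.vector(emp))
    theta <- max(mean(v[!d$is_empty, cols, drop = FALSE]) - mu, 1e-6)
    if (!is.finite(sigma) || sigma <= 0) {
      warning("non-positive background sd estimate; using subtract-and-floor")
      out[, cols] <- pmax(v[, cols, drop = FALSE] - mu, 1e-6) + offset
    } else {
      out[, cols] <- .normexpPosterior(v[, cols, drop = FALSE], mu, sigma,
                                       theta) + offset
    }
  }
  HybSet(out, d, sampleInfo(x), scale = "linear", layout = channelLayout(x))
}

#' Quantile normalization
#'
#' Forces all columns to share the mean quantile distribution.  For
#' one-channel data the columns are the arrays; for two-channel data both
#' channels of all arrays are pooled as columns and normalized jointly (the
#' two-channel method).  Ties receive the mean of their tied quantile
#' values.  Empty spots can be excluded from (and left untouched by) the
#' normalization.
#'
#' @param x a [HybSet-class].
#' @param includeEmpty normalize empty-spot rows together with gene probes
#'   (default TRUE keeps every row on the common distribution).
#' @return normalized [HybSet-class]; sorted column vectors are identical
#'   afterwards.
#' @export
quantileNormalize <- function(x, includeEmpty = TRUE) {
  v <- intensities(x)
  if (ncol(v) < 2L) {
    warning("only one column; quantile normalization is the identity")
    return(x)
  }
  d <- arrayDesign(x)
  rows <- if (includeEmpty) seq_len(nrow(v)) else which(!d$is_empty)
  v[rows, ] <- limma::normalizeQuantiles(v[rows, , drop = FALSE], ties = TRUE)
  HybSet(v, d, sampleInfo(x), scale = intensityScale(x),
         layout = channelLayout(x))
}

# Vectorized Tukey median polish over many equally sized blocks.
# y: (nGenes*p) x nSamples matrix, rows probe-fastest within gene.
# Returns fitted summaries: overall + column effects, an nGenes x nSamples
# matrix.  Mirrors the classic algorithm: row sweep first, then column
# sweep, stopping per block when the absolute-residual sum changes by less
# than eps * sum (or after maxiter iterations).
.medpolishBlocks <- function(y, p, nGenes, eps = 1e-4, maxiter = 10L) {
  nS <- ncol(y)
  t_all <- numeric(nGenes)
  r_all <- numeric(nGenes * p)
  c_all <- matrix(0, nGenes, nS)
  z <- y
  geneOfRow <- rep(seq_len(nGenes), each = p)
  oldsum <- numeric(nGenes)
  active <- rep(TRUE, nGenes)
  for (iter in seq_len(maxiter)) {
    act_rows <- active[geneOfRow]
    idx <- which(active)
    # row sweep
    rd <- rowMeds(z[act_rows, , drop = FALSE])
    z[act_rows, ] <- z[act_rows, , drop = FALSE] - rd
    r_all[act_rows] <- r_all[act_rows] + rd
    cm <- rowMeds(c_all[idx, , drop = FALSE])
    c_all[idx, ] <- c_all[idx, , drop = FALSE] - cm
    t_all[idx] <- t_all[idx] + cm
    # column sweep: per (gene, sample) median across the p probes
    zi <- z[act_rows, , drop = FALSE]
    cd <- colMeds(matrix(zi, nrow = p))           # length nAct*nS
    cd <- matrix(cd, nrow = length(idx), ncol = nS)
    z[act_rows, ] <- zi - cd[rep(seq_along(idx), each = p), , drop = FALSE]
    c_all[idx, ] <- c_all[idx, , drop = FALSE] + cd
    rm_ <- colMeds(matrix(r_all[act_rows], nrow = p))
    r_all[act_rows] <- r_all[act_rows] - rep(rm_, each = p)
    t_all[idx] <- t_all[idx] + rm_
    newsum <- rowsum(rowSums(abs(z[act_rows, , drop = FALSE])),
                     geneOfRow[act_rows])[, 1]
    conv <- newsum == 0 | abs(newsum - oldsum[idx]) < eps * newsum
    active[idx[conv]] <- FALSE
    oldsum[idx] <- newsum
    if (!any(active)) break
  }
  t_all + c_all
}

#' Summarize probe-level data to gene level by median polish
#'
#' For each gene, a Tukey median polish is run on its probes x samples
#' block (row sweep first, at most 10 iterations, relative tolerance 1e-4
#' on the absolute-residual sum) and the summarized value for each sample
#' is the overall effect plus that sample's column effect -- one value per
#' gene per sample, as in RMA.  Single-probe genes pass through unchanged.
#'
#' @param x probe-level expression [HybSet-class], log2 scale.
#' @param keptProbes optional probe ids to use (e.g. a filter report's
#'   `kept_probes`); defaults to all non-empty probes.
#' @return gene-level [HybSet-class] (one pseudo-probe per gene).
#' @export
summarizeGenes <- function(x, keptProbes = NULL) {
  if (intensityScale(x) != "log2") stop("summarization expects log2 data")
  d <- arrayDesign(x)
  use <- !d$is_empty
  if (!is.null(keptProbes)) use <- use & d$probe_id %in% keptProbes
  d2 <- d[use, , drop = FALSE]
  v <- intensities(x)[use, , drop = FALSE]
  ord <- order(d2$gene_id, d2$probe_index)
  d2 <- d2[ord, , drop = FALSE]
  v <- v[ord, , drop = FALSE]
  cnt <- table(d2$gene_id)
  geneIds <- names(cnt)
  out <- matrix(NA_real_, length(geneIds), ncol(v),
                dimnames = list(geneIds, colnames(v)))
  gidx <- match(d2$gene_id, geneIds)
  for (p in sort(unique(as.integer(cnt)))) {
    gsel <- geneIds[cnt == p]
    rows <- gidx %in% match(gsel, geneIds)
    if (p == 1L) {
      out[gsel, ] <- v[rows, , drop = FALSE]
    } else {
      out[gsel, ] <- .medpolishBlocks(v[rows, , drop = FALSE], p,
                                      length(gsel))
    }
  }
  gdesign <- data.frame(probe_id = geneIds, gene_id = geneIds,
                        probe_index = 1L, is_empty = FALSE,
                        stringsAsFactors = FALSE)
  HybSet(out, gdesign, sampleInfo(x), scale = "log2", layout = "single")
}

#' Filter CGH probes on per-channel background thresholds
#'
#' A probe is kept iff its mean log2 signal across samples is at or above
#' the background threshold in both channels.
#'
#' @param x two-channel [HybSet-class], log2 scale.
#' @param thresholds numeric(1) applied to both channels, or named
#'   numeric(2) (`cy3`, `cy5`).
#' @return a `FilterReport` with `kept_probes` and the per-channel means.
#' @export
filterCGHProbes <- function(x, thresholds) {
  if (channelLayout(x) != "two_channel")
    stop("CGH probe filter expects a two-channel HybSet")
  if (intensityScale(x) != "log2") stop("CGH filter expects log2 data")
  ch <- sampleInfo(x)$channel
  if (!all(c("cy3", "cy5") %in% ch)) stop("both channels must be present")
  if (length(thresholds) == 1L)
    thresholds <- c(cy3 = unname(thresholds), cy5 = unname(thresholds))
  v <- intensities(x)
  d <- arrayDesign(x)
  m3 <- rowMeans(v[, ch == "cy3", drop = FALSE])
  m5 <- rowMeans(v[, ch == "cy5", drop = FALSE])
  ok <- !d$is_empty & m3 >= thresholds["cy3"] & m5 >= thresholds["cy5"]
  kept <- d$probe_id[ok]
  genes <- unique(d$gene_id[ok])
  out <- .filterReport(thresholds, genes, kept, frac_below = NULL)
  out$channel_means <- data.frame(probe_id = d$probe_id, cy3 = m3, cy5 = m5)
  out
}

#' Log-ratios (M-values) of a two-channel HybSet
#'
#' M = log2(sample channel) - log2(reference channel) per probe per
#' individual.  Linear-scale input must be strictly positive
#' (background-correct with an offset first).
#'
#' @param x two-channel [HybSet-class].
#' @return [HybSet-class] of M-values, layout `"mvalue"`, one column per
#'   individual.
#' @export
computeLogRatios <- function(x) {
  if (channelLayout(x) != "two_channel")
    stop("log-ratios need a two-channel HybSet")
  v <- intensities(x)
  if (intensityScale(x) == "linear") {
    if (any(v <= 0))
      stop("non-positive linear intensities; background-correct with an offset first")
    v <- log2(v)
  }
  si <- sampleInfo(x)
  ids <- unique(si$sample_id)
  i3 <- match(paste0(ids, "cy3"), paste0(si$sample_id, si$channel))
  i5 <- match(paste0(ids, "cy5"), paste0(si$sample_id, si$channel))
  m <- v[, i3, drop = FALSE] - v[, i5, drop = FALSE]
  colnames(m) <- ids
  samples <- si[i3, setdiff(colnames(si), "channel"), drop = FALSE]
  rownames(samples) <- NULL
  HybSet(m, arrayDesign(x), samples, scale = "log2", layout = "mvalue")
}

#' Intersect expression and CGH filters
#'
#' Retained genes are the expression-kept genes that still have at least one
#' CGH-kept probe; retained probes are the CGH-kept probes of those genes.
#' Only features passing both assays' filters enter the joint analyses.
#'
#' @param exprReport `FilterReport` from [filterExpressionGenes()].
#' @param cghReport `FilterReport` from [filterCGHProbes()].
#' @param design array design.
#' @return list with `genes` and `probes` (the analysis sets).
#' @export
intersectFilters <- function(exprReport, cghReport, design) {
  cghGenes <- unique(design$gene_id[design$probe_id %in% cghReport$kept_probes])
  genes <- intersect(exprReport$kept_genes, cghGenes)
  if (length(genes) == 0L)
    stop("no gene passed both the expression and CGH filters")
  probes <- cghReport$kept_probes[
    design$gene_id[match(cghReport$kept_probes, design$probe_id)] %in% genes]
  list(genes = genes, probes = probes)
}
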