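makeHyb <- function(values, nEmpty = 0, layout = "single", scale = "log2",
                    channels = NULL) {
  nr <- nrow(values)
  ng <- nr - nEmpty
  design <- data.frame(
    probe_id = c(sprintf("P%03d", seq_len(ng)),
                 if (nEmpty) sprintf("EMPTY_%03d", seq_len(nEmpty))),
    gene_id = c(sprintf("G%03d", seq_len(ng)), rep(NA_character_, nEmpty)),
    probe_index = 1L,
    is_empty = c(rep(FALSE, ng), rep(TRUE, nEmpty)))
  samples <- if (is.null(channels))
    data.frame(sample_id = colnames(values))
  else channels
  HybSet(values, design, samples, scale = scale, layout = layout)
}

test_that("background threshold averages empty spots and honours overrides", {
  v <- matrix(12, 4, 3, dimnames = list(NULL, paste0("s", 1:3)))
  v[3:4, ] <- 10
  h <- makeHyb(v, nEmpty = 2)
  expect_equal(backgroundThreshold(h), 10)

  v[3, ] <- 10; v[4, ] <- 11
  h2 <- makeHyb(v, nEmpty = 2)
  expect_equal(backgroundThreshold(h2), 10.5)

  expect_equal(backgroundThreshold(h2, override = 10.7), 10.7)

  h3 <- makeHyb(v[1:2, , drop = FALSE], nEmpty = 0)
  expect_error(backgroundThreshold(h3), "supply a threshold")
})

test_that("expression gene filter uses the strict more-than-20% rule", {
  # two genes x 5 probes; gene 1 has exactly one probe below (20% -> kept),
  # gene 2 has two probes below (40% -> dropped)
  v <- matrix(12, 10, 4)
  v[1, ] <- 8            # gene 1, probe 1 below
  v[6:7, ] <- 8          # gene 2, probes 1-2 below
  design <- data.frame(
    probe_id = sprintf("P%02d", 1:10),
    gene_id = rep(c("G1", "G2"), each = 5),
    probe_index = rep(1:5, 2), is_empty = FALSE)
  h <- HybSet(v, design, data.frame(sample_id = paste0("s", 1:4)))
  rep <- filterExpressionGenes(h, threshold = 10)
  expect_setequal(rep$kept_genes, "G1")
  expect_equal(sum(rep$kept_probes %in% design$probe_id[1:5]), 5L)

  repAll <- filterExpressionGenes(h, threshold = 5)
  expect_setequal(repAll$kept_genes, c("G1", "G2"))

  # idempotence: filtering the kept data again changes nothing
  keep <- design$probe_id %in% rep$kept_probes
  h2 <- HybSet(v[keep, , drop = FALSE], design[keep, ],
               data.frame(sample_id = paste0("s", 1:4)))
  rep2 <- filterExpressionGenes(h2, threshold = 10)
  expect_setequal(rep2$kept_genes, rep$kept_genes)
})

test_that("normexp correction matches quadrature and limma, and is monotone", {
  mu <- 100; sigma <- 40; thetaTrue <- 900
  set.seed(3)
  ng <- 500; nEmpty <- 200
  signal <- rexp(ng, 1 / thetaTrue)
  x <- matrix(signal + rnorm(ng, mu, sigma), ncol = 1,
              dimnames = list(NULL, "s1"))
  emp <- matrix(rnorm(nEmpty, mu, sigma), ncol = 1,
                dimnames = list(NULL, "s1"))
  h <- makeHyb(rbind(x, emp), nEmpty = nEmpty, scale = "linear")
  out <- normexpCorrect(h, offset = 0)
  v <- intensities(out)[seq_len(ng), 1]
  expect_true(all(intensities(out) > 0))

  # oracle 1: numerical integration of E[S|X] at the estimated parameters
  muHat <- mean(emp); sigmaHat <- sd(as.vector(emp))
  thetaHat <- mean(x) - muHat
  for (xx in c(muHat, muHat + 2 * sigmaHat, muHat + 1000)) {
    ours <- parasnail:::.normexpPosterior(xx, muHat, sigmaHat, thetaHat)
    expect_equal(ours, normexpQuadrature(xx, muHat, sigmaHat, thetaHat),
                 tolerance = 1e-6)
  }
  # oracle 2: limma's normexp.signal with the same parameters
  par <- c(muHat, log(sigmaHat), log(thetaHat))
  ref <- limma::normexp.signal(par, as.vector(x))
  expect_equal(unname(v), ref, tolerance = 1e-8)

  # monotone increasing in x
  grid <- seq(muHat - 5 * sigmaHat, muHat + 2000, length.out = 200)
  fx <- parasnail:::.normexpPosterior(grid, muHat, sigmaHat, thetaHat)
  expect_true(all(diff(fx) > 0))

  # sigma -> 0 limit: max(x - mu, 0+) like behaviour
  lim <- parasnail:::.normexpPosterior(c(muHat - 50, muHat + 50), muHat,
                                       1e-4, thetaHat)
  expect_equal(lim[2], 50, tolerance = 1e-3)
  expect_lt(lim[1], 1e-3)
})

test_that("quantile normalization matches the hand-worked example and its defining property", {
  v <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  h <- makeHyb(v)
  out <- intensities(quantileNormalize(h))
  expect_equal(unname(out[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, 2]), c(1.5, 3, 4.5))

  vc <- matrix(rep(c(5, 1, 3), 3), 3, 3,
               dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(unname(intensities(quantileNormalize(makeHyb(vc)))),
               unname(vc))

  set.seed(8)
  r <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("s", 1:6)))
  qn <- intensities(quantileNormalize(makeHyb(r)))
  sorted <- apply(qn, 2, sort)
  for (j in 2:6) expect_equal(unname(sorted[, j]), unname(sorted[, 1]),
                              tolerance = 1e-9)
  for (j in 1:6) expect_equal(unname(rank(qn[, j])), rank(r[, j]))

  expect_warning(quantileNormalize(makeHyb(r[, 1, drop = FALSE])),
                 "one column")
})

test_that("median-polish summarization matches stats::medpolish and its identities", {
  # random blocks, several probe counts, against the classic implementation
  set.seed(21)
  for (p in c(2, 3, 5)) {
    for (rep_i in 1:5) {
      block <- matrix(rnorm(p * 6, 12, 1), p, 6)
      design <- data.frame(probe_id = paste0("P", seq_len(p)), gene_id = "G1",
                           probe_index = seq_len(p), is_empty = FALSE)
      h <- HybSet(block, design, data.frame(sample_id = paste0("s", 1:6)))
      ours <- intensities(summarizeGenes(h))[1, ]
      mp <- suppressWarnings(
        stats::medpolish(block, eps = 1e-4, maxiter = 10, trace.iter = FALSE))
      expect_equal(unname(ours), unname(mp$overall + mp$col), tolerance = 1e-10)
    }
  }

  # constant block summarizes to the constant
  cblock <- matrix(7, 4, 5)
  design <- data.frame(probe_id = paste0("P", 1:4), gene_id = "G1",
                       probe_index = 1:4, is_empty = FALSE)
  h <- HybSet(cblock, design, data.frame(sample_id = paste0("s", 1:5)))
  expect_equal(unname(intensities(summarizeGenes(h))[1, ]), rep(7, 5))

  # single-probe gene passes through unchanged
  h1 <- HybSet(matrix(1:6, 1, 6), design[1, ],
               data.frame(sample_id = paste0("s", 1:6)))
  expect_equal(unname(intensities(summarizeGenes(h1))[1, ]), as.numeric(1:6))

  # rank-one block (probe effect + sample effect) recovers sample effects
  probeEff <- c(0, 1, -0.5, 2)
  sampEff <- c(10, 11, 12, 9, 10.5)
  block <- outer(probeEff, rep(1, 5)) + outer(rep(1, 4), sampEff)
  h <- HybSet(block, design, data.frame(sample_id = paste0("s", 1:5)))
  out <- intensities(summarizeGenes(h))[1, ]
  expect_equal(unname(diff(out)), diff(sampEff), tolerance = 1e-10)
})

test_that("vectorized summarization equals per-gene summarization on mixed designs", {
  set.seed(31)
  design <- rbind(
    data.frame(probe_id = paste0("A", 1:5), gene_id = "GA",
               probe_index = 1:5, is_empty = FALSE),
    data.frame(probe_id = paste0("B", 1:3), gene_id = "GB",
               probe_index = 1:3, is_empty = FALSE),
    data.frame(probe_id = "C1", gene_id = "GC", probe_index = 1L,
               is_empty = FALSE))
  v <- matrix(rnorm(9 * 4, 10), 9, 4)
  h <- HybSet(v, design, data.frame(sample_id = paste0("s", 1:4)))
  out <- intensities(summarizeGenes(h))
  for (g in c("GA", "GB")) {
    block <- v[design$gene_id == g, , drop = FALSE]
    mp <- suppressWarnings(stats::medpolish(block, eps = 1e-4, maxiter = 10,
                                            trace.iter = FALSE))
    expect_equal(unname(out[g, ]), unname(mp$overall + mp$col),
                 tolerance = 1e-10)
  }
  expect_equal(unname(out["GC", ]), unname(v[9, ]))
})

test_that("CGH probe filter requires both channels at or above threshold", {
  v <- cbind(s1__cy3 = c(11, 11, 9), s1__cy5 = c(11, 10.5, 9),
             s2__cy3 = c(11, 11, 9), s2__cy5 = c(11, 10.5, 9))
  design <- data.frame(probe_id = paste0("P", 1:3),
                       gene_id = paste0("G", 1:3),
                       probe_index = 1L, is_empty = FALSE)
  ch <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                   channel = rep(c("cy3", "cy5"), 2))
  h <- HybSet(v, design, ch, scale = "log2", layout = "two_channel")
  rep <- filterCGHProbes(h, 10.7)
  expect_setequal(rep$kept_probes, "P1")  # P2 fails cy5, P3 fails both
  repAll <- filterCGHProbes(h, -Inf)
  expect_setequal(repAll$kept_probes, paste0("P", 1:3))
})

test_that("log-ratios are antisymmetric and require positive linear input", {
  v <- cbind(s1__cy3 = c(4, 8), s1__cy5 = c(4, 2))
  design <- data.frame(probe_id = c("P1", "P2"), gene_id = c("G1", "G2"),
                       probe_index = 1L, is_empty = FALSE)
  ch <- data.frame(sample_id = c("s1", "s1"), channel = c("cy3", "cy5"))
  h <- HybSet(v, design, ch, scale = "linear", layout = "two_channel")
  m <- intensities(computeLogRatios(h))
  expect_equal(unname(m[, 1]), c(0, 2))  # equal channels -> 0; 4x -> 2

  # relabelling sample as reference and vice versa negates M
  hswap <- HybSet(v, design,
                  data.frame(sample_id = c("s1", "s1"),
                             channel = c("cy5", "cy3")),
                  scale = "linear", layout = "two_channel")
  expect_equal(unname(intensities(computeLogRatios(hswap))[, 1]), -c(0, 2))

  vneg <- v; vneg[1, 1] <- 0
  hneg <- HybSet(vneg, design, ch, scale = "linear", layout = "two_channel")
  expect_error(computeLogRatios(hneg), "non-positive")
})

test_that("joint filter keeps genes passing both assays and errors when disjoint", {
  design <- generateDesign(3, 2, 0)
  exprRep <- list(kept_genes = c("G00001", "G00002"))
  cghRep <- list(kept_probes = c("G00002_P1", "G00003_P1", "G00003_P2"))
  out <- intersectFilters(exprRep, cghRep, design)
  expect_equal(out$genes, "G00002")
  expect_equal(out$probes, "G00002_P1")

  cghRep2 <- list(kept_probes = c("G00003_P1"))
  expect_error(intersectFilters(exprRep, cghRep2, design), "no gene passed")
})
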