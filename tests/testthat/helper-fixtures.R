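# Shared fixtures and independent oracles.

# Tiny two-assay configuration used by several interface tests.
tinyConfig <- function(...) {
  simulationConfig(n_genes = 60, probes_per_gene = 5, n_empty_spots = 20,
                   dropout_expression = 0, dropout_cgh = 0, seed = 11, ...)
}

tinyDataset <- function(config = tinyConfig()) {
  design <- generateDesign(config$n_genes, config$probes_per_gene,
                           config$n_empty_spots)
  truth <- generateTruth(design, config)
  sdE <- generateSampleDesign("expression")
  sdC <- generateSampleDesign("cgh")
  list(design = design, truth = truth, sdE = sdE, sdC = sdC,
       expr = simulateExpression(design, truth, sdE, config),
       cgh = simulateCGH(design, truth, sdC, config),
       config = config)
}

# Brute-force SGoF: literal while-loop over binomial survival tests.
sgofOracle <- function(p, alpha = 0.05, gamma = 0.05) {
  n <- length(p)
  f <- sum(p <= gamma)
  c <- f
  declared <- 0L
  while (c > 0 && pbinom(c - 1, n, gamma, lower.tail = FALSE) <= alpha) {
    declared <- declared + 1L
    c <- c - 1L
  }
  declared
}

# Monte-Carlo tail of the three-way intersection size.
mcDeromeTail <- function(N, n1, n2, n3, k, reps = 20000) {
  hits <- 0L
  ks <- integer(reps)
  for (r in seq_len(reps)) {
    tab <- tabulate(c(sample.int(N, n1), sample.int(N, n2),
                      sample.int(N, n3)), N)
    ks[r] <- sum(tab == 3L)
  }
  list(p = mean(ks >= k), mean = mean(ks), se = sd(ks) / sqrt(reps),
       pse = sqrt(mean(ks >= k) * (1 - mean(ks >= k)) / reps))
}

# Quadrature oracle for the normexp posterior mean E[S | X = x],
# S ~ Exp(theta), B ~ N(mu, sigma^2), X = S + B.
normexpQuadrature <- function(x, mu, sigma, theta) {
  # the integrand is concentrated near s = x - mu (width sigma); a finite
  # upper bound keeps the adaptive quadrature on the peak
  upper <- max(x - mu, 0) + 30 * sigma + theta
  num <- integrate(function(s) s * dexp(s, 1 / theta) *
                     dnorm(x - mu - s, 0, sigma), 0, upper,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
  den <- integrate(function(s) dexp(s, 1 / theta) *
                     dnorm(x - mu - s, 0, sigma), 0, upper,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
  num / den
}

# One gene-level expression matrix with its sample design, fitted models.
fittedExpression <- function(config = tinyConfig()) {
  d <- tinyDataset(config)
  thr <- backgroundThreshold(d$expr)
  rep <- filterExpressionGenes(d$expr, thr)
  qn <- quantileNormalize(d$expr, includeEmpty = FALSE)
  g <- summarizeGenes(qn, rep$kept_probes)
  fit <- moderateVariances(fitRowModels(g, analysis = "ecotype_within_locality"))
  list(data = d, genes = g, fit = fit)
}
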