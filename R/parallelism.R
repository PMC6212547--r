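#' Intersection of three per-locality significant sets
#'
#' Parallel features are those significant between ecotypes in all three
#' localities.  Returns a [ParallelResult-class] with the intersection, its
#' size and the closed-form null expectation; the exact and permutation
#' tails are filled by [testParallelism()].
#'
#' @param sigSets named list of three character vectors (ids).
#' @param universe character vector of all analysed ids.
#' @return a [ParallelResult-class] (`exact_p`/`perm_p` set to NA).
#' @export
intersectSignificant <- function(sigSets, universe) {
  if (length(sigSets) != 3L) stop("exactly three significant sets are required")
  sigSets <- lapply(sigSets, unique)
  if (!all(unlist(sigSets) %in% universe))
    stop("significant sets must be subsets of the universe")
  inter <- Reduce(intersect, sigSets)
  N <- length(universe)
  expected <- N * prod(lengths(sigSets) / N)
  new("ParallelResult", sets = sigSets, universe = universe,
      intersection = inter, k = length(inter), expected = expected,
      exact_p = NA_real_, perm_p = NA_real_, perm_null = integer(0),
      R = 0L, seed = NA_integer_)
}

#' Map significant probes to gene-level calls
#'
#' A gene is called significant when at least one of its probes is (the
#' "any-probe" rule), giving the many-to-one probe/gene mapping used for
#' gene-level CGH summaries.
#'
#' @param probeSet character vector of significant probe ids.
#' @param design array design.
#' @return character vector of gene ids.
#' @export
geneLevelCalls <- function(probeSet, design) {
  unique(design$gene_id[match(probeSet, design$probe_id)])
}

#' Exact null distribution of a three-way set intersection
#'
#' For three independent uniformly random subsets of fixed sizes n1, n2, n3
#' from a universe of size N, the intersection size K = |A n B n C| has
#' the hypergeometric-convolution distribution
#' P(K = k) = sum_m HG(m; N, n1, n2) HG(k; N, m, n3),
#' where HG(j; N, a, b) is the probability that two independent subsets of
#' sizes a and b overlap in j elements.  Returns the pmf, the mean
#' N (n1/N)(n2/N)(n3/N) and, when `k` is given, the upper tail P(K >= k).
#'
#' @param N universe size.
#' @param n1,n2,n3 subset sizes (each between 0 and N).
#' @param k optional observed intersection size.
#' @return list with `support`, `pmf`, `expected`, `p.value` (NA without k).
#' @export
derome3Null <- function(N, n1, n2, n3, k = NULL) {
  sizes <- c(n1, n2, n3)
  if (any(sizes < 0) || any(sizes > N)) stop("subset sizes must be in [0, N]")
  kmax <- min(sizes)
  support <- 0:kmax
  # overlap M of sets 1 and 2: hypergeometric
  mSupport <- max(0, n1 + n2 - N):min(n1, n2)
  pM <- dhyper(mSupport, n1, N - n1, n2)
  pmf <- vapply(support, function(kk) {
    sum(pM * dhyper(kk, mSupport, N - mSupport, n3))
  }, numeric(1))
  pmf <- pmf / sum(pmf)
  expected <- N * prod(sizes / N)
  p <- NA_real_
  if (!is.null(k)) {
    if (k < 0 || k > kmax) {
      if (k > kmax) stop("k cannot exceed min(n1, n2, n3)")
      stop("k must be >= 0")
    }
    p <- sum(pmf[support >= k])
  }
  list(support = support, pmf = pmf, expected = expected, p.value = p)
}

# Null intersection sizes from R independent redraws of the three sets.
.shuffleNullK <- function(N, sizes, R) {
  k <- integer(R)
  for (r in seq_len(R)) {
    tab <- tabulate(c(sample.int(N, sizes[1]), sample.int(N, sizes[2]),
                      sample.int(N, sizes[3])), N)
    k[r] <- sum(tab == 3L)
  }
  k
}

#' Permutation test of three-way parallelism
#'
#' Mode `"gene_shuffle"` (default) preserves the observed per-locality
#' significant counts and permutes which features carry the calls,
#' independently within each locality, recomputing the intersection size
#' each time -- the permutation analogue of [derome3Null()].  Mode
#' `"label"` permutes ecotype labels within each locality's samples,
#' refits the per-locality ecotype contrasts, re-applies SGoF and
#' recomputes the intersection (much slower; for calibration studies).
#' The p-value is (1 + #\{k* >= k_obs\}) / (R + 1) and is never 0.
#'
#' @param parallel a [ParallelResult-class] from [intersectSignificant()].
#' @param R number of permutations (>= 1).
#' @param seed RNG seed.
#' @param mode `"gene_shuffle"` or `"label"`.
#' @param values,samples feature matrix (features x samples) and per-column
#'   metadata, required for mode `"label"`.
#' @param alpha,gamma SGoF parameters for mode `"label"`.
#' @return the [ParallelResult-class] with `perm_p`, `perm_null`, `R`,
#'   `seed` filled.
#' @export
permutationParallel <- function(parallel, R = 10000, seed = 1,
                                mode = c("gene_shuffle", "label"),
                                values = NULL, samples = NULL,
                                alpha = 0.05, gamma = 0.05) {
  mode <- match.arg(mode)
  stopifnot(R >= 1)
  N <- length(parallel@universe)
  kObs <- parallel@k
  nullK <- withSeed(seed, {
    if (mode == "gene_shuffle") {
      .shuffleNullK(N, lengths(parallel@sets), R)
    } else {
      if (is.null(values) || is.null(samples))
        stop("mode 'label' needs the data matrix and sample metadata")
      localities <- unique(samples$locality)
      vapply(seq_len(R), function(r) {
        perm <- samples
        for (l in localities) {
          i <- which(samples$locality == l)
          perm$ecotype[i] <- samples$ecotype[sample(i)]
        }
        fit <- moderateVariances(
          fitRowModels(values, perm, "ecotype_within_locality"))
        pv <- contrastPvalues(fit)
        sets <- lapply(seq_len(ncol(pv)), function(j)
          declared(sgof(pv[, j], alpha, gamma, ids = rownames(pv))))
        length(Reduce(intersect, sets))
      }, integer(1))
    }
  })
  parallel@perm_null <- as.integer(nullK)
  parallel@perm_p <- (1 + sum(nullK >= kObs)) / (R + 1)
  parallel@R <- as.integer(R)
  parallel@seed <- as.integer(seed)
  parallel
}

#' Full parallelism assessment
#'
#' Convenience wrapper: intersects the three per-locality significant sets,
#' attaches the exact hypergeometric-convolution tail and runs the
#' permutation test.
#'
#' @inheritParams intersectSignificant
#' @inheritParams permutationParallel
#' @return a complete [ParallelResult-class].
#' @export
testParallelism <- function(sigSets, universe, R = 10000, seed = 1,
                            mode = "gene_shuffle", values = NULL,
                            samples = NULL) {
  res <- intersectSignificant(sigSets, universe)
  sizes <- lengths(res@sets)
  ex <- derome3Null(length(universe), sizes[1], sizes[2], sizes[3], k = res@k)
  res@exact_p <- ex$p.value
  res@expected <- ex$expected
  permutationParallel(res, R = R, seed = seed, mode = mode,
                      values = values, samples = samples)
}
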