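#' SGoF sequential binomial multiple-testing correction
#'
#' Counts F = #\{p <= gamma\} and compares it with its expectation under the
#' global null, Binomial(n, gamma).  While the one-sided exact binomial
#' test of the current count c rejects at level alpha (P[X >= c] <= alpha,
#' inclusive), one more feature is declared significant and c decreases by
#' one.  The declared features are the n_declared smallest p-values, ties
#' resolved by stable input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha level of the sequential binomial metatest.
#' @param gamma initial threshold (conventionally equal to alpha).
#' @param ids optional feature ids (defaults to names(p) or indices).
#' @param approx use the one-sided G (likelihood-ratio chi-square)
#'   approximation of the binomial test instead of the exact tail, for
#'   cross-checking large-n behaviour.
#' @return an [SGoFResult-class].
#' @examples
#' p <- c(rep(1e-4, 30), runif(170))
#' sgof(p)
#' @export
sgof <- function(p, alpha = 0.05, gamma = 0.05, ids = NULL, approx = FALSE) {
  stopIfNot01(p)
  stopifnot(alpha > 0, alpha < 1, gamma > 0, gamma < 1)
  n <- length(p)
  if (is.null(ids)) ids <- if (!is.null(names(p))) names(p) else as.character(seq_len(n))
  Fcnt <- sum(p <= gamma)
  nDecl <- 0L
  if (Fcnt > 0L) {
    cs <- Fcnt:0L
    rej <- if (!approx) {
      pbinom(cs - 1L, n, gamma, lower.tail = FALSE) <= alpha
    } else {
      e1 <- n * gamma
      G <- ifelse(cs > e1,
                  2 * (ifelse(cs > 0, cs * log(cs / e1), 0) +
                         ifelse(n - cs > 0,
                                (n - cs) * log((n - cs) / (n - e1)), 0)),
                  0)
      cs > e1 & pchisq(G, df = 1, lower.tail = FALSE) / 2 <= alpha
    }
    # declarations proceed from c = F downwards while the test rejects
    stopAt <- which(!rej)[1]
    nDecl <- if (is.na(stopAt)) Fcnt else as.integer(stopAt - 1L)
  }
  declared <- if (nDecl > 0L) ids[order(p)[seq_len(nDecl)]] else character(0)
  new("SGoFResult", n_tests = as.integer(n), alpha = alpha, gamma = gamma,
      F_count = as.integer(Fcnt), n_declared = as.integer(nDecl),
      declared = as.character(declared), approx = approx)
}

#' G test of count heterogeneity
#'
#' Likelihood-ratio (G) test of independence for a contingency table:
#' G = 2 sum O log(O/E) with the independence-model expectations, df =
#' (r-1)(c-1), p from the upper chi-square tail.  Zero cells contribute 0.
#'
#' @param counts non-negative integer matrix with positive margins.
#' @return list with `G`, `df`, `p.value`, `expected`.
#' @examples
#' gTestHeterogeneity(rbind(c(30, 10), c(10, 30)))
#' @export
gTestHeterogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in count table")
  E <- outer(rs, cs) / sum(counts)
  terms <- ifelse(counts > 0, counts * log(counts / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(G = G, df = df,
       p.value = pchisq(G, df = df, lower.tail = FALSE), expected = E)
}
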