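# Row-wise linear models under a group-means (cell-means) parameterization
# of the ecotype x locality design, with contrasts for the three analyses:
#   factorial_interaction  : ecotype main effect (1 df), locality main
#                            effect (2 df), ecotype x locality interaction
#                            (2 df)
#   ecotype_within_locality: crab - wave within each locality (3 x 1 df)
#   locality_within_ecotype: among-locality differences within each ecotype
#                            (2 x 2 df)

.cellNames <- function(samples) {
  paste(samples$ecotype, samples$locality, sep = ".")
}

.buildContrasts <- function(cells, analysis, localities, ecotypes) {
  cmat <- function(pairs) {
    m <- matrix(0, length(cells), length(pairs), dimnames = list(cells, NULL))
    for (j in seq_along(pairs)) m[names(pairs[[j]]), j] <- pairs[[j]]
    m
  }
  cell <- function(e, l) paste(e, l, sep = ".")
  switch(analysis,
    ecotype_within_locality = {
      cl <- lapply(localities, function(l)
        cmat(list(setNames(c(1, -1), c(cell("crab", l), cell("wave", l))))))
      names(cl) <- paste0("ecotype_", localities)
      cl
    },
    factorial_interaction = {
      k <- length(localities)
      eco <- cmat(list(setNames(
        c(rep(1 / k, k), rep(-1 / k, k)),
        c(cell("crab", localities), cell("wave", localities)))))
      locPairs <- lapply(localities[-k], function(l) {
        v <- c(0.5, 0.5, -0.5, -0.5)
        setNames(v, c(cell("crab", l), cell("wave", l),
                      cell("crab", localities[k]), cell("wave", localities[k])))
      })
      loc <- cmat(locPairs)
      intPairs <- lapply(localities[-k], function(l)
        setNames(c(1, -1, -1, 1),
                 c(cell("crab", l), cell("wave", l),
                   cell("crab", localities[k]), cell("wave", localities[k]))))
      intr <- cmat(intPairs)
      list(ecotype = eco, locality = loc, interaction = intr)
    },
    locality_within_ecotype = {
      k <- length(localities)
      cl <- lapply(ecotypes, function(e) {
        pairs <- lapply(localities[-k], function(l)
          setNames(c(1, -1), c(cell(e, l), cell(e, localities[k]))))
        cmat(pairs)
      })
      names(cl) <- paste0("locality_", ecotypes)
      cl
    },
    stop("unknown analysis: ", analysis))
}

#' Fit row-wise linear models
#'
#' Ordinary least squares per feature on the group-means design (one
#' coefficient per ecotype x locality cell), via [limma::lmFit].  Residual
#' df is n_samples - number of cells.
#'
#' @param values numeric matrix (features x samples) or a single-layout /
#'   mvalue [HybSet-class].
#' @param samples per-column data.frame with `ecotype` and `locality`;
#'   taken from the HybSet if omitted.
#' @param analysis one of `"factorial_interaction"`,
#'   `"ecotype_within_locality"`, `"locality_within_ecotype"`.
#' @return a [ModelFit-class] (variances not yet moderated).
#' @export
fitRowModels <- function(values, samples = NULL,
                         analysis = c("ecotype_within_locality",
                                      "factorial_interaction",
                                      "locality_within_ecotype")) {
  analysis <- match.arg(analysis)
  if (is(values, "HybSet")) {
    if (is.null(samples)) samples <- sampleInfo(values)
    values <- intensities(values)
  }
  stopifnot(ncol(values) == nrow(samples))
  localities <- sort(unique(samples$locality))
  ecotypes <- sort(unique(samples$ecotype))
  if (analysis != "locality_within_ecotype" && length(ecotypes) != 2L)
    stop("both ecotypes are required for analysis ", analysis)
  if (length(localities) != 3L)
    stop("exactly three localities are required")
  group <- factor(.cellNames(samples),
                  levels = unique(as.vector(outer(
                    ecotypes, localities, paste, sep = "."))))
  tab <- table(group)
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  design <- model.matrix(~ 0 + group)
  colnames(design) <- levels(group)
  if (qr(design)$rank < ncol(design)) stop("rank-deficient design matrix")
  fit <- limma::lmFit(values, design)
  contrasts <- .buildContrasts(levels(group), analysis, localities, ecotypes)
  new("ModelFit",
      coefficients = fit$coefficients,
      cov_unscaled = fit$cov.coefficients,
      sigma2 = fit$sigma^2,
      df_residual = fit$df.residual,
      contrasts = contrasts, analysis = analysis,
      df_prior = NA_real_, s2_prior = NA_real_, s2_post = numeric(0))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Assumes s^2 | sigma^2 ~ sigma^2 chisq_d / d with the conjugate
#' scaled-inverse-chi-square prior sigma^2 ~ s0^2 d0 / chisq_{d0}, estimates
#' (d0, s0^2) by matching the moments of log s^2 (digamma/trigamma, Newton
#' inversion) via [limma::squeezeVar], and shrinks each variance to
#' s2_post = (d0 s0^2 + d s^2) / (d0 + d).  If all variances coincide the
#' prior df is infinite and every posterior variance equals the common
#' value.  Supplying `d0`/`s02` bypasses estimation (d0 = 0 reproduces the
#' ordinary variances, d0 = Inf the fully pooled ones).
#'
#' @param fit a [ModelFit-class].
#' @param d0,s02 optional fixed hyperparameters.
#' @return the fit with `df_prior`, `s2_prior`, `s2_post` filled.
#' @export
moderateVariances <- function(fit, d0 = NULL, s02 = NULL) {
  s2 <- fit@sigma2
  d <- fit@df_residual
  if (sum(d > 0) < 2L) stop("need at least 2 features with residual df > 0")
  if (is.null(d0) != is.null(s02))
    stop("supply both d0 and s02, or neither")
  if (is.null(d0)) {
    sq <- limma::squeezeVar(s2, d)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
    post <- sq$var.post
  } else {
    post <- if (is.infinite(d0)) rep(s02, length(s2))
            else (d0 * s02 + d * s2) / (d0 + d)
  }
  fit@df_prior <- unname(d0[1])
  fit@s2_prior <- unname(s02[1])
  fit@s2_post <- as.numeric(post)
  fit
}

#' Moderated contrast tests and p-values
#'
#' Single-df contrasts give two-sided moderated t tests on d0 + d degrees
#' of freedom; multi-df contrasts give moderated F tests with (q, d0 + d)
#' df.  Run [moderateVariances()] first.
#'
#' @param fit a moderated [ModelFit-class].
#' @param contrasts optional subset of contrast names.
#' @return matrix of p-values (features x contrasts) with attributes
#'   `statistic` (t or F values) and `type` (per-contrast `"t"`/`"F"`).
#' @export
contrastPvalues <- function(fit, contrasts = NULL) {
  if (!length(fit@s2_post))
    stop("variances are not moderated; run moderateVariances() first")
  cl <- fit@contrasts
  if (!is.null(contrasts)) {
    if (!all(contrasts %in% names(cl)))
      stop("unknown contrast(s): ",
           paste(setdiff(contrasts, names(cl)), collapse = ", "))
    cl <- cl[contrasts]
  }
  dftot <- fit@df_prior + fit@df_residual
  p <- stat <- matrix(NA_real_, nrow(fit@coefficients), length(cl),
                      dimnames = list(rownames(fit@coefficients), names(cl)))
  type <- character(length(cl))
  for (j in seq_along(cl)) {
    C <- cl[[j]]
    B <- fit@coefficients %*% C
    V <- t(C) %*% fit@cov_unscaled %*% C
    if (ncol(C) == 1L) {
      tval <- B[, 1] / sqrt(V[1, 1] * fit@s2_post)
      stat[, j] <- tval
      p[, j] <- 2 * pt(-abs(tval), df = dftot)
      type[j] <- "t"
    } else {
      Vi <- solve(V)
      Fval <- rowSums((B %*% Vi) * B) / (ncol(C) * fit@s2_post)
      stat[, j] <- Fval
      p[, j] <- pf(Fval, ncol(C), dftot, lower.tail = FALSE)
      type[j] <- "F"
    }
  }
  attr(p, "statistic") <- stat
  attr(p, "type") <- setNames(type, names(cl))
  p
}

#' Estimates of single-df contrasts
#'
#' @param fit a [ModelFit-class].
#' @return matrix of contrast estimates (features x single-df contrasts).
#' @export
contrastEstimates <- function(fit) {
  cl <- Filter(function(C) ncol(C) == 1L, fit@contrasts)
  if (!length(cl)) stop("no single-df contrasts in this analysis")
  out <- vapply(cl, function(C) (fit@coefficients %*% C)[, 1],
                numeric(nrow(fit@coefficients)))
  rownames(out) <- rownames(fit@coefficients)
  out
}
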