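sixCellSamples <- function(n = 4, localities = c("Burela", "Roncudo", "Silleiro")) {
  expand.grid(replicate = seq_len(n), ecotype = c("crab", "wave"),
              locality = localities, stringsAsFactors = FALSE)
}

test_that("row-wise OLS recovers exact small-sample cases and df accounting", {
  samples <- data.frame(ecotype = rep(c("crab", "wave"), each = 2),
                        locality = "Burela")
  # single-locality designs are rejected (three localities required)
  v <- matrix(c(1, 1, 0, 0), 1, 4)
  expect_error(fitRowModels(v, samples), "three localities")

  samples6 <- sixCellSamples(2)
  v <- matrix(rnorm(12 * 5), 5, 12)
  v[1, ] <- ifelse(samples6$ecotype == "crab", 1, 0)  # exact effect, no noise
  fit <- fitRowModels(v, samples6, "ecotype_within_locality")
  est <- contrastEstimates(fit)
  expect_equal(unname(est[1, ]), c(1, 1, 1))
  expect_equal(fit@sigma2[1], 0)
  expect_equal(unname(fit@df_residual[1]), 12 - 6)

  # the retained-pools design: 22 samples, 6 cells -> 16 residual df
  s22 <- sixCellSamples(4)[-c(1, 5), ]
  v22 <- matrix(rnorm(22 * 3), 3, 22)
  fit22 <- fitRowModels(v22, s22, "ecotype_within_locality")
  expect_true(all(fit22@df_residual == 16))

  # permutation invariance: same fit under matched reordering
  perm <- sample(nrow(samples6))
  fitP <- fitRowModels(v[, perm], samples6[perm, ], "ecotype_within_locality")
  expect_equal(contrastEstimates(fitP), est)
  expect_equal(fitP@sigma2, fit@sigma2)

  # too-small groups are refused with a clear message
  bad <- sixCellSamples(2)[-1, ]
  expect_error(fitRowModels(v[, -1, drop = FALSE], bad, "ecotype_within_locality"),
               "fewer than 2 replicates")
})

test_that("moderated statistics agree with limma's eBayes pipeline", {
  set.seed(41)
  samples <- sixCellSamples(4)
  sdg <- sqrt(0.05 * 4 / rchisq(400, 4))
  v <- matrix(rnorm(400 * 24, 0, rep(sdg, 24)), 400, 24)
  fit <- moderateVariances(fitRowModels(v, samples, "ecotype_within_locality"))
  p <- contrastPvalues(fit)

  design <- model.matrix(~ 0 + factor(paste(samples$ecotype, samples$locality)))
  colnames(design) <- levels(factor(paste(samples$ecotype, samples$locality)))
  lf <- limma::lmFit(v, design)
  cm <- matrix(0, 6, 3, dimnames = list(colnames(design), NULL))
  locs <- unique(samples$locality)
  for (j in 1:3) {
    cm[paste("crab", locs[j]), j] <- 1
    cm[paste("wave", locs[j]), j] <- -1
  }
  eb <- limma::eBayes(limma::contrasts.fit(lf, cm))
  expect_equal(unname(fit@df_prior), unname(eb$df.prior), tolerance = 1e-8)
  expect_equal(unname(fit@s2_post), unname(eb$s2.post), tolerance = 1e-8)
  expect_equal(unname(attr(p, "statistic")), unname(eb$t), tolerance = 1e-8)
  expect_equal(as.vector(p), as.vector(eb$p.value), tolerance = 1e-8)

  # multi-df contrast F agrees with eBayes F on the locality contrast
  fitL <- moderateVariances(fitRowModels(v[, samples$ecotype == "crab"],
                                         samples[samples$ecotype == "crab", ],
                                         "locality_within_ecotype"))
  pL <- contrastPvalues(fitL, "locality_crab")
  subd <- model.matrix(~ 0 + factor(samples$locality[samples$ecotype == "crab"]))
  lfL <- limma::lmFit(v[, samples$ecotype == "crab"], subd)
  cmL <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  ebL <- limma::eBayes(limma::contrasts.fit(lfL, cmL))
  expect_equal(unname(attr(pL, "statistic")[, 1]), unname(ebL$F),
               tolerance = 1e-8)
  expect_equal(unname(pL[, 1]), unname(ebL$F.p.value), tolerance = 1e-8)
})

test_that("moderation limits behave as the formula dictates", {
  set.seed(5)
  samples <- sixCellSamples(3)
  v <- matrix(rnorm(18 * 50), 50, 18)
  fit <- fitRowModels(v, samples, "ecotype_within_locality")

  f0 <- moderateVariances(fit, d0 = 0, s02 = 1)     # no shrinkage
  expect_equal(f0@s2_post, fit@sigma2)
  p0 <- contrastPvalues(f0)
  tt <- attr(p0, "statistic")
  # d0 = 0 moderated t is the ordinary t
  est <- contrastEstimates(fit)
  u <- sqrt(2 / 3)  # contrast unscaled sd with n = 3 per cell
  expect_equal(unname(tt[, 1]), unname(est[, 1] / (u * sqrt(fit@sigma2))),
               tolerance = 1e-10)

  fInf <- moderateVariances(fit, d0 = Inf, s02 = 0.5)
  expect_true(all(fInf@s2_post == 0.5))

  # s2_post strictly monotone in s2 and between s2 and s02
  f4 <- moderateVariances(fit, d0 = 4, s02 = 0.5)
  o <- order(fit@sigma2)
  expect_true(all(diff(f4@s2_post[o]) > 0))
  expect_true(all(f4@s2_post >= pmin(fit@sigma2, 0.5) &
                    f4@s2_post <= pmax(fit@sigma2, 0.5)))

  # equal variances -> infinite prior df branch (duplicate one row)
  vdup <- matrix(rnorm(18), 1, 18)[rep(1, 5), ]
  fdup <- fitRowModels(vdup, samples, "ecotype_within_locality")
  mdup <- moderateVariances(fdup)
  expect_true(is.infinite(mdup@df_prior))
  expect_equal(mdup@s2_post, fdup@sigma2)
})

test_that("hyperparameters are recovered from prior-simulated fits", {
  set.seed(7)
  n <- 5000; d0 <- 4; s02 <- 0.05
  samples <- sixCellSamples(4)[-c(1, 5), ]  # 22 samples, d = 16
  sdg <- sqrt(s02 * d0 / rchisq(n, d0))
  v <- matrix(rnorm(n * 22, 0, rep(sdg, 22)), n, 22)
  fit <- moderateVariances(fitRowModels(v, samples, "ecotype_within_locality"))
  expect_lt(abs(fit@df_prior - d0) / d0, 0.15)
  expect_lt(abs(fit@s2_prior - s02) / s02, 0.15)
})

test_that("contrast p-values are exact at the boundaries and calibrated under the null", {
  samples <- sixCellSamples(2)
  v <- matrix(0, 2, 12)
  v[2, ] <- rnorm(12)
  fit <- moderateVariances(fitRowModels(v, samples, "ecotype_within_locality"),
                           d0 = 2, s02 = 0.1)
  p <- contrastPvalues(fit)
  expect_equal(unname(p[1, ]), c(1, 1, 1))  # zero estimate -> p = 1

  expect_error(contrastPvalues(fit, "interaction"), "unknown contrast")
  expect_error(contrastPvalues(fitRowModels(v, samples)), "not moderated")

  # null calibration at nominal 0.05 over 10,000 prior-simulated rows,
  # and uniformity of the moderated p-values
  set.seed(13)
  n <- 10000
  sdg <- sqrt(0.05 * 4 / rchisq(n, 4))
  samples22 <- sixCellSamples(4)[-c(2, 9), ]
  vn <- matrix(rnorm(n * 22, 0, rep(sdg, 22)), n, 22)
  fitn <- moderateVariances(fitRowModels(vn, samples22,
                                         "ecotype_within_locality"))
  pn <- contrastPvalues(fitn)
  rate <- mean(pn[, 1] <= 0.05)
  expect_gt(rate, 0.04); expect_lt(rate, 0.06)
  expect_gt(ks.test(pn[, 2], "punif")$p.value, 0.01)

  # p-values invariant to adding a constant to all samples of a row
  vshift <- vn + 3
  fits <- moderateVariances(fitRowModels(vshift, samples22,
                                         "ecotype_within_locality"))
  expect_equal(contrastPvalues(fits), pn, tolerance = 1e-10)
})

test_that("factorial analysis separates main effects from interaction", {
  samples <- sixCellSamples(4)
  mu <- setNames(rep(0, 6), unique(paste(samples$ecotype, samples$locality,
                                         sep = ".")))
  # row 1: pure ecotype effect; row 2: pure locality effect;
  # row 3: pure interaction (ecotype effect varying across localities)
  eff <- function(f) vapply(seq_len(nrow(samples)), function(i)
    f(samples$ecotype[i], samples$locality[i]), numeric(1))
  v <- rbind(eff(function(e, l) (e == "crab") * 2),
             eff(function(e, l) (l == "Roncudo") * 2),
             eff(function(e, l) (e == "crab") * (l == "Roncudo") * 2))
  v <- v + matrix(rnorm(length(v), 0, 0.05), nrow(v))
  fit <- moderateVariances(fitRowModels(v, samples, "factorial_interaction"))
  p <- contrastPvalues(fit)
  expect_true(all(colnames(p) == c("ecotype", "locality", "interaction")))
  expect_lt(p[1, "ecotype"], 1e-6)
  expect_gt(p[1, "interaction"], 0.01)
  expect_lt(p[2, "locality"], 1e-6)
  expect_gt(p[2, "ecotype"], 0.01)
  expect_lt(p[3, "interaction"], 1e-6)
})
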