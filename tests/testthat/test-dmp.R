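test_that("the group coefficient reduces to a mean difference without covariates", {
  m <- rbind(p1 = c(1, 2, 3, 7, 8, 9), p2 = c(5, 5, 5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:6)
  ss <- data.frame(sample_id = colnames(m),
                   group = rep(c("control", "case"), each = 3))
  design <- buildDesign(ss)
  fits <- fitProbeModels(m, design)
  expect_equal(fits$coef, c(8 - 2, 0))
  expect_equal(fits$df, rep(4L, 2))
  expect_equal(fits$sigma2[2], 0)          # exact fit -> zero residual
})

test_that("OLS fits agree with an explicit pseudo-inverse oracle", {
  set.seed(7)
  n <- 6L
  ss <- data.frame(sample_id = paste0("s", 1:n),
                   group = c("case", "case", "case", "control", "control",
                             "control"))
  covar <- cbind(CD4T = runif(n))
  rownames(covar) <- ss$sample_id
  design <- buildDesign(ss, covar)
  m <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("p", 1:5),
                                                  ss$sample_id))
  fits <- fitProbeModels(m, design)
  ## independent oracle: Moore-Penrose solve per probe
  G <- MASS::ginv(design)
  for (i in 1:5) {
    bHat <- drop(G %*% m[i, ])
    expect_equal(fits$coef[i], bHat[2], tolerance = 1e-10)
    r <- m[i, ] - drop(design %*% bHat)
    expect_equal(fits$sigma2[i], sum(r^2) / (n - ncol(design)),
                 tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are refused with the offending column", {
  ss <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("case", "control"), 3))
  design <- buildDesign(ss)
  design <- cbind(design, dup = design[, "group"])
  m <- matrix(rnorm(12), 2, 6, dimnames = list(c("a", "b"), ss$sample_id))
  expect_error(fitProbeModels(m, design), "dup")
})

test_that("the variance prior is recovered from simulated residual variances", {
  set.seed(101)
  d0 <- 4; s02 <- 1; dg <- 10; n <- 20000
  ## s^2 ~ s02 * (chisq_dg/dg) * (d0/chisq_d0)
  s2 <- s02 * (rchisq(n, dg) / dg) * (d0 / rchisq(n, d0))
  fits <- data.frame(sigma2 = s2, df = dg)
  prior <- estimateModerationPrior(fits)
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s02 - s02) / s02, 0.05)
})

test_that("the prior estimate agrees with limma's squeezeVar hyperparameters", {
  set.seed(55)
  s2 <- 0.8 * (rchisq(5000, 8) / 8) * (6 / rchisq(5000, 6))
  prior <- estimateModerationPrior(data.frame(sigma2 = s2, df = 8))
  sq <- limma::squeezeVar(s2, df = 8)
  expect_equal(prior$d0, sq$df.prior, tolerance = 0.02)
  expect_equal(prior$s02, sq$var.prior, tolerance = 0.02)
})

test_that("zero dispersion collapses to an infinite prior at the common value", {
  fits <- data.frame(sigma2 = rep(1.7, 50), df = 10)
  prior <- estimateModerationPrior(fits)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s02, 1.7, tolerance = 1e-12)
  ## permutation invariance on a two-probe instance
  p1 <- estimateModerationPrior(data.frame(sigma2 = c(1, 1), df = 10))
  expect_identical(p1$d0, Inf)
  expect_equal(p1$s02, 1)
  expect_error(estimateModerationPrior(data.frame(sigma2 = c(0, 0), df = 4)),
               "degenerate")
})

test_that("posterior variances follow the stated shrinkage formula", {
  fits <- data.frame(probe_id = "p1", coef = 1, stdev_unscaled = 0.5,
                     sigma2 = 4, df = 4)
  mod <- moderateStatistics(fits, list(d0 = 4, s02 = 1))
  expect_equal(mod$s2_post, (4 * 1 + 4 * 4) / 8)      # 2.5
  expect_equal(mod$df_total, 8)
  ## d0 -> 0: ordinary t on dg degrees of freedom
  mod0 <- moderateStatistics(fits, list(d0 = 1e-12, s02 = 1))
  expect_equal(mod0$t, 1 / (0.5 * 2), tolerance = 1e-6)
  expect_equal(mod0$s2_post, 4, tolerance = 1e-6)
  ## d0 = Inf: every probe uses s0^2 exactly, normal reference
  fitsMany <- data.frame(probe_id = c("a", "b"), coef = c(1, 2),
                         stdev_unscaled = 0.5, sigma2 = c(2, 9), df = 4)
  modInf <- moderateStatistics(fitsMany, list(d0 = Inf, s02 = 1))
  expect_equal(modInf$s2_post, c(1, 1))
  expect_equal(modInf$p_value, 2 * pnorm(-abs(modInf$t)))
  ## convexity: posterior between prior and observed variance
  s2 <- runif(20, 0.1, 5)
  fitsC <- data.frame(probe_id = paste0("p", 1:20), coef = 1,
                      stdev_unscaled = 1, sigma2 = s2, df = 6)
  modC <- moderateStatistics(fitsC, list(d0 = 3, s02 = 1))
  expect_true(all(modC$s2_post >= pmin(1, s2) - 1e-12))
  expect_true(all(modC$s2_post <= pmax(1, s2) + 1e-12))
})

test_that("moderated p-values are uniform under the null", {
  set.seed(202)
  n <- 5000; ns <- 20
  m <- matrix(rnorm(n * ns), n, ns,
              dimnames = list(sprintf("p%04d", 1:n), paste0("s", 1:ns)))
  ss <- data.frame(sample_id = colnames(m),
                   group = rep(c("case", "control"), each = ns / 2))
  fits <- fitProbeModels(m, buildDesign(ss))
  mod <- moderateStatistics(fits, estimateModerationPrior(fits))
  ks <- suppressWarnings(stats::ks.test(mod$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("delta-beta is the beta-scale group mean difference", {
  beta <- rbind(p1 = c(0.8, 0.8, 0.6, 0.6), p2 = c(0.4, 0.4, 0.4, 0.4))
  groups <- c("case", "case", "control", "control")
  dB <- computeDeltaBeta(beta, groups)
  expect_equal(unname(dB), c(0.2, 0))
  swapped <- computeDeltaBeta(beta, rev(groups))
  expect_equal(unname(swapped), c(-0.2, 0))
  expect_error(computeDeltaBeta(beta, rep("case", 4)), "non-empty")
})

test_that("AUROC equals brute-force pair counting with half ties", {
  expect_equal(computeAuroc(c(3, 1, 2, 0),
                            c("case", "case", "control", "control")), 0.75)
  expect_equal(computeAuroc(rep(1, 6), rep(c("case", "control"), 3)), 0.5)
  expect_equal(computeAuroc(c(5, 6, 1, 2),
                            c("case", "case", "control", "control")), 1)
  bruteAuroc <- function(v, lab) {
    ca <- v[lab == "case"]; co <- v[lab == "control"]
    mean(outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    v <- sample(0:5, n, replace = TRUE)          # heavy ties
    lab <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(computeAuroc(v, lab), bruteAuroc(v, lab))
    expect_equal(computeAuroc(-v, lab), 1 - computeAuroc(v, lab))
  }
})

test_that("the DMP table is invariant to sample order and scores rank sensibly", {
  cohort <- smallCohort()
  ss <- sampleSheet(cohort)
  disc <- ss[ss$group %in% c("case", "control"), ][1:40, ]
  beta <- betaValues(cohort)[1:300, disc$sample_id]
  tab <- buildDmpTable(beta, disc)
  perm <- sample(nrow(disc))
  tab2 <- buildDmpTable(beta[, disc$sample_id[perm]], disc[perm, ])
  expect_equal(tab, tab2, tolerance = 1e-12)
  expect_true(all(tab$auroc >= 0 & tab$auroc <= 1))
  expect_true(all(tab$rank_score >= 0))
  expect_equal(tab$rank_score,
               abs(tab$delta_beta) * -log10(pmax(tab$p_value, 1e-300)))
})
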