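## Shared small-cohort training setup: signature + plan on the small cohort.
.trainSetup <- function() {
  memo("trainSetup", {
    cfg <- smallConfig(nControls = 96L)
    cohort <- combineCohorts(simulateCohort(cfg), simulateConfounders(cfg))
    ss <- sampleSheet(cohort)
    beta <- betaValues(cohort)
    cases <- ss[ss$group == "case", ]
    matched <- selectMatchedControls(cases, ss[ss$group == "control", ])
    disc <- ss[ss$sample_id %in% c(cases$sample_id, matched), ]
    dmp <- buildDmpTable(beta[, disc$sample_id], disc)
    sig <- selectFeatures(dmp, beta[, disc$sample_id], disc$group,
                          selectionParams(nRank = 200L, nAuroc = 60L))
    other <- setdiff(ss$sample_id[ss$group == "control"], matched)
    dis <- ss$sample_id[ss$group == "disorder"]
    names(dis) <- ss$disorder[ss$group == "disorder"]
    plan <- trainingPlan(cases$sample_id, matched, other, dis, seed = 3L)
    list(cohort = cohort, ss = ss, beta = beta, sig = sig, plan = plan,
         disc = disc)
  })
}

test_that("training plans validate composition", {
  expect_error(trainingPlan("a", c("a", "b")), "disjoint")
  expect_error(trainingPlan("a", "b", trainFraction = 1), "trainFraction")
})

test_that("the plan split respects the train fraction per pool", {
  s <- .trainSetup()
  split <- episig:::.splitPlan(s$plan)
  nOther <- length(s$plan$otherControlIds)
  perDis <- table(names(s$plan$disorderIds))
  expectedTrainNeg <- length(s$plan$matchedControlIds) +
    floor(0.75 * nOther) + sum(floor(0.75 * perDis))
  expect_length(split$trainNeg, expectedTrainNeg)
  expect_length(split$testIds,
                nOther + length(s$plan$disorderIds) -
                  floor(0.75 * nOther) - sum(floor(0.75 * perDis)))
  expect_length(intersect(split$testIds,
                          c(split$trainPos, split$trainNeg)), 0L)
})

test_that("training separates cases from all held-out negatives", {
  s <- .trainSetup()
  fit <- trainClassifier(s$beta, s$sig, s$plan)
  sc <- scoreSamples(fit$model, s$beta)
  scores <- stats::setNames(sc$mvp_score, sc$sample_id)
  expect_true(all(scores[s$plan$caseIds] > 0.5))
  expect_true(all(scores[fit$test_ids] < 0.5))
  ## calibration sanity
  expect_lt(mean(scores[fit$test_ids]), 0.5)
  expect_gt(mean(scores[s$plan$caseIds]), 0.5)
  ## VUS-like samples score near zero
  vus <- s$ss$sample_id[s$ss$group == "test"]
  expect_true(all(scores[vus] < 0.5))
})

test_that("identical plan and seed reproduce scores exactly", {
  s <- .trainSetup()
  f1 <- trainClassifier(s$beta, s$sig, s$plan)
  f2 <- trainClassifier(s$beta, s$sig, s$plan)
  s1 <- scoreSamples(f1$model, s$beta)$mvp_score
  s2 <- scoreSamples(f2$model, s$beta)$mvp_score
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_identical(f1$train_ids, f2$train_ids)
})

test_that("scoring is invariant to probe order and strict about missing probes", {
  s <- .trainSetup()
  fit <- trainClassifier(s$beta, s$sig, s$plan)
  perm <- sample(nrow(s$beta))
  sc1 <- scoreSamples(fit$model, s$beta)
  sc2 <- scoreSamples(fit$model, s$beta[perm, ])
  expect_equal(sc1$mvp_score, sc2$mvp_score, tolerance = 1e-12)
  probes <- signatureProbes(s$sig)
  crippled <- s$beta[setdiff(rownames(s$beta), probes[1:2]), ]
  expect_error(scoreSamples(fit$model, crippled), probes[1])
})

test_that("duplicating a training sample barely moves the decision function", {
  s <- .trainSetup()
  fit <- trainClassifier(s$beta, s$sig, s$plan)
  ## duplicate the negative farthest from the margin (not a support vector)
  scCtrl <- scoreSamples(fit$model, s$beta[, s$plan$matchedControlIds])
  dupId <- scCtrl$sample_id[which.min(scCtrl$mvp_score)]
  beta2 <- cbind(s$beta, dup_sample = s$beta[, dupId])
  plan2 <- s$plan
  plan2$matchedControlIds <- c(plan2$matchedControlIds, "dup_sample")
  fit2 <- trainClassifier(beta2, s$sig, plan2)
  dec <- function(model, beta) {
    xs <- scale(t(beta[model@probes, , drop = FALSE]), model@center,
                model@scale)
    drop(xs %*% model@weights) - model@rho
  }
  common <- c(s$plan$caseIds, fit$test_ids)
  d1 <- dec(fit$model, s$beta[, common])
  d2 <- dec(fit2$model, s$beta[, common])
  ## separating hyperplane essentially unmoved (relative to its scale);
  ## only the Platt recalibration may drift
  expect_lt(max(abs(d1 - d2)) / max(abs(d1)), 1e-3)
  expect_identical(scoreSamples(fit$model, s$beta[, common])$call,
                   scoreSamples(fit2$model, s$beta[, common])$call)
})

test_that("label-shuffled training collapses to chance performance", {
  s <- .trainSetup()
  disc <- s$disc
  beta <- s$beta[signatureProbes(s$sig), disc$sample_id]
  set.seed(404)
  accs <- replicate(10, {
    lab <- sample(disc$group)                     # break label/feature link
    test <- sort(sample(nrow(disc), 16))
    train <- setdiff(seq_len(nrow(disc)), test)
    if (length(unique(lab[train])) < 2 || length(unique(lab[test])) < 2)
      return(NA_real_)
    planS <- trainingPlan(disc$sample_id[train][lab[train] == "case"],
                          disc$sample_id[train][lab[train] == "control"],
                          seed = 7L)
    sigS <- s$sig
    fitS <- trainClassifier(beta, sigS, planS)
    sc <- scoreSamples(fitS$model, beta[, disc$sample_id[test]])
    pred <- ifelse(sc$mvp_score >= 0.5, "case", "control")
    truth <- lab[test]
    (mean(pred[truth == "case"] == "case") +
       mean(pred[truth == "control"] == "control")) / 2
  })
  expect_lt(abs(mean(accs, na.rm = TRUE) - 0.5), 0.25)
})

test_that("MVP models survive a JSON round trip", {
  s <- .trainSetup()
  fit <- trainClassifier(s$beta, s$sig, s$plan)
  f <- tempfile(fileext = ".json")
  writeMvpModel(fit$model, f)
  model2 <- readMvpModel(f)
  expect_equal(scoreSamples(model2, s$beta)$mvp_score,
               scoreSamples(fit$model, s$beta)$mvp_score, tolerance = 1e-12)
})
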