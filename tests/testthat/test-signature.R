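.fakeSheet <- function(ids, age, sex, array = "EPIC") {
  data.frame(sample_id = ids, age = age, sex = sex, array_type = array,
             stringsAsFactors = FALSE)
}

test_that("exact metadata clones are selected as matched controls", {
  cases <- .fakeSheet(c("c1", "c2"), c(10, 40), c("F", "M"))
  clones <- .fakeSheet(sprintf("k%02d", 1:14),
                       rep(c(10, 40), each = 7), rep(c("F", "M"), each = 7))
  decoys <- .fakeSheet(sprintf("z%02d", 1:20), 25, "F", array = "450k")
  pool <- rbind(decoys, clones)
  sel <- selectMatchedControls(cases, pool, ratio = 7)
  expect_setequal(sel, clones$sample_id)
  ## pool row order must not matter
  sel2 <- selectMatchedControls(cases, pool[rev(seq_len(nrow(pool))), ],
                                ratio = 7)
  expect_identical(sel2, sel)
})

test_that("the default ratio yields 56 controls for 8 cases", {
  cohort <- smallCohort()
  ss <- sampleSheet(cohort)
  sel <- selectMatchedControls(ss[ss$group == "case", ],
                               ss[ss$group == "control", ])
  expect_length(sel, 56L)
  expect_equal(anyDuplicated(sel), 0L)
  expect_error(selectMatchedControls(ss[ss$group == "case", ],
                                     ss[ss$group == "control", ][1:10, ]),
               "too small")
})

test_that("selection parameters are validated", {
  expect_error(selectionParams(nAuroc = 2000L), "nAuroc")
  expect_error(selectionParams(corrThreshold = 1.2), "corrThreshold")
})

test_that("correlation pruning removes planted duplicates and is idempotent", {
  set.seed(61)
  n <- 120; ns <- 24
  groups <- rep(c("case", "control"), each = ns / 2)
  base <- matrix(runif(80 * ns, 0.2, 0.8), 80, ns)
  dup <- base[1:40, ] # exact copies of the 40 strongest probes
  beta <- rbind(base, dup)
  rownames(beta) <- sprintf("p%03d", seq_len(nrow(beta)))
  colnames(beta) <- paste0("s", seq_len(ns))
  ## rank scores descending with probe index so originals outrank duplicates
  dmp <- data.frame(probe_id = rownames(beta),
                    delta_beta = 0.1,
                    p_value = 10^-(seq(nrow(beta), 1)),
                    auroc = seq(0.99, 0.5, length.out = nrow(beta)),
                    stringsAsFactors = FALSE)
  dmp$rank_score <- abs(dmp$delta_beta) * -log10(dmp$p_value)
  params <- selectionParams(nRank = 120L, nAuroc = 120L)
  sig <- selectFeatures(dmp, beta, groups, params)
  expect_length(signatureProbes(sig), 80L)
  expect_false(any(sprintf("p%03d", 81:120) %in% signatureProbes(sig)))
  ## no retained pair exceeds the threshold in both groups (brute force)
  kept <- beta[signatureProbes(sig), ]
  cc <- cor(t(kept[, groups == "case"])); cl <- cor(t(kept[, groups == "control"]))
  diag(cc) <- diag(cl) <- 0
  expect_false(any(cc > 0.9 & cl > 0.9))
  ## idempotence: reselecting from the retained set changes nothing
  dmp2 <- dmp[dmp$probe_id %in% signatureProbes(sig), ]
  sig2 <- suppressWarnings(selectFeatures(dmp2, kept, groups, params))
  expect_identical(signatureProbes(sig2), signatureProbes(sig))
})

test_that("raising the correlation threshold never shrinks the signature", {
  cohort <- smallCohort()
  ss <- sampleSheet(cohort)
  disc <- ss[ss$group %in% c("case", "control"), ]
  beta <- betaValues(cohort)[, disc$sample_id]
  dmp <- buildDmpTable(beta, disc)
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.99), function(thr) {
    p <- selectionParams(nRank = 300L, nAuroc = 150L, corrThreshold = thr)
    length(signatureProbes(selectFeatures(dmp, beta, disc$group, p)))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("selection recovers the planted probes under the small cohort", {
  cohort <- smallCohort()
  ss <- sampleSheet(cohort)
  disc <- ss[ss$group %in% c("case", "control"), ]
  beta <- betaValues(cohort)[, disc$sample_id]
  dmp <- buildDmpTable(beta, disc)
  params <- selectionParams(nRank = 200L, nAuroc = 60L)
  sig <- selectFeatures(dmp, beta, disc$group, params)
  truth <- S4Vectors::metadata(cohort)$truth$signature_probes
  expect_gte(mean(sig@provenance$step2_probes %in% truth), 0.9)
  ## directions match the planted truth
  dirTruth <- S4Vectors::metadata(cohort)$truth$direction
  hits <- intersect(signatureProbes(sig), names(dirTruth))
  expect_gte(mean(signatureDirections(sig)[hits] == dirTruth[hits]), 0.95)
})

test_that("fewer probes than nRank proceeds with a warning", {
  cohort <- smallCohort()
  ss <- sampleSheet(cohort)
  disc <- ss[ss$group %in% c("case", "control"), ]
  beta <- betaValues(cohort)[1:100, disc$sample_id]
  dmp <- buildDmpTable(beta, disc)
  expect_warning(sig <- selectFeatures(dmp, beta, disc$group,
                                       selectionParams()), "using all")
  expect_lte(length(signatureProbes(sig)), 100L)
})

test_that("Ward clustering separates well-separated groups and is stable", {
  x <- rbind(matrix(rnorm(40, 0), 8, 5), matrix(rnorm(40, 6), 8, 5))
  rownames(x) <- paste0("s", 1:16)
  wc <- wardCluster(x)
  expect_true(all(wc$hclust$height >= 0))
  expect_true(!is.unsorted(wc$hclust$height))
  expect_equal(length(unique(wc$clusters[1:8])), 1L)
  expect_equal(length(unique(wc$clusters[9:16])), 1L)
  expect_false(wc$clusters[1] == wc$clusters[16])
  ## identical samples merge at height zero
  wc0 <- wardCluster(rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9)))
  expect_equal(min(wc0$hclust$height), 0)
  ## permutation invariance up to label swap
  perm <- sample(16)
  wcP <- wardCluster(x[perm, ])
  agree <- mean((wcP$clusters[rownames(x)] == 1) == (wc$clusters == 1))
  expect_true(agree %in% c(0, 1))
})

test_that("classical MDS preserves planar distances", {
  ## 3-4-5 right triangle embeds exactly
  x <- rbind(a = c(0, 0, 0), b = c(3, 0, 0), c = c(0, 4, 0))
  emb <- mdsEmbed(x)
  expect_equal(sort(as.numeric(dist(emb))), c(3, 4, 5), tolerance = 1e-8)
  ## translation invariance of the embedding distances
  emb2 <- mdsEmbed(x + 100)
  expect_equal(as.numeric(dist(emb2)), as.numeric(dist(emb)),
               tolerance = 1e-8)
  ## degenerate input maps to the origin
  same <- matrix(0.5, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  expect_true(all(mdsEmbed(same) == 0))
  ## collinear points have one positive eigenvalue
  line <- cbind(c(0, 1, 2, 3))
  expect_warning(e1 <- mdsEmbed(line), "positive eigenvalue")
  expect_equal(ncol(e1), 1L)
})

test_that("MDS sign split agrees with the Ward cut on separated data", {
  cohort <- smallCohort()
  ss <- sampleSheet(cohort)
  disc <- ss[ss$group %in% c("case", "control"), ]
  truth <- S4Vectors::metadata(cohort)$truth$signature_probes
  x <- t(betaValues(cohort)[truth, disc$sample_id])
  wc <- wardCluster(x)
  emb <- mdsEmbed(x)
  side <- emb[, 1] > 0
  agree <- mean(side == (wc$clusters == wc$clusters[1]))
  expect_true(agree %in% c(0, 1))
  ## and both reproduce the case/control labels
  caseCluster <- wc$clusters[disc$sample_id[disc$group == "case"]]
  ctrlCluster <- wc$clusters[disc$sample_id[disc$group == "control"]]
  expect_equal(length(unique(caseCluster)), 1L)
  expect_equal(length(unique(ctrlCluster)), 1L)
  expect_false(caseCluster[1] == ctrlCluster[1])
})

test_that("a null cohort sends held-out cases to chance-level assignment", {
  misassigned <- 0L
  for (seed in 1:10) {
    cohort <- simulateCohort(cohortConfig(
      nProbes = 600L, nCases = 4L, nControls = 28L, nSignatureProbes = 40L,
      effectLogit = 0, nVusLike = 0L, nReferenceProbes = 60L,
      nOtherDisorders = 1L, probesPerDisorder = 10L, seed = seed))
    ss <- sampleSheet(cohort)
    folds <- runLoocv(betaValues(cohort), ss, NULL,
                      selectionParams(nRank = 100L, nAuroc = 40L))
    misassigned <- misassigned + sum(folds$assigned != "case", na.rm = TRUE)
  }
  expect_gte(misassigned, 1L)
})

test_that("episignatures round-trip through JSON", {
  cohort <- smallCohort()
  ss <- sampleSheet(cohort)
  disc <- ss[ss$group %in% c("case", "control"), ]
  beta <- betaValues(cohort)[, disc$sample_id]
  dmp <- buildDmpTable(beta, disc)
  sig <- selectFeatures(dmp, beta, disc$group,
                        selectionParams(nRank = 200L, nAuroc = 60L))
  f <- tempfile(fileext = ".json")
  writeEpisignature(sig, f)
  sig2 <- readEpisignature(f)
  expect_identical(signatureProbes(sig2), signatureProbes(sig))
  expect_identical(signatureDirections(sig2), signatureDirections(sig))
  expect_equal(sig2@caseMean, sig@caseMean, tolerance = 1e-12)
})
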