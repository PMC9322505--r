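## Episignature construction: matched-control selection, the three-step
## feature selection (rank score -> AUROC -> correlation pruning), and
## unsupervised validation by Ward clustering, classical MDS and
## leave-one-out cross-validation.

#' Select age/sex/array-matched controls
#'
#' Greedy matching: cases are processed in lexicographic sample-id order and
#' each receives the `ratio` as-yet-unused pool samples with the lowest
#' matching cost, defined as |age difference| / pooled age range, plus 1 for
#' a sex mismatch and 1 for an array-type mismatch. Ties break on
#' lexicographic sample id, so the selection is invariant to pool row order.
#'
#' @param cases,pool data frames with `sample_id`, `age`, `sex`,
#'   `array_type`
#' @param ratio controls per case (default 7)
#' @return character vector of selected control sample ids
#' @examples
#' cohort <- simulateCohort(cohortConfig(nProbes = 2000, nControls = 80))
#' ss <- sampleSheet(cohort)
#' ids <- selectMatchedControls(ss[ss$group == "case", ],
#'                              ss[ss$group == "control", ])
#' length(ids)   # 56
#' @export
selectMatchedControls <- function(cases, pool, ratio = 7L) {
  ratio <- .stopifnotScalarCount(ratio, "ratio", 1L)
  if (nrow(pool) < ratio * nrow(cases))
    .dataError(sprintf(
      "control pool too small: %d candidates for %d cases at ratio %d (need %d)",
      nrow(pool), nrow(cases), ratio, ratio * nrow(cases)))
  ageRange <- diff(range(c(cases$age, pool$age)))
  if (ageRange == 0) ageRange <- 1
  used <- character(0)
  selected <- character(0)
  for (ci in order(cases$sample_id)) {
    cost <- abs(pool$age - cases$age[ci]) / ageRange +
      (pool$sex != cases$sex[ci]) +
      (pool$array_type != cases$array_type[ci])
    ord <- order(cost, pool$sample_id)
    avail <- ord[!(pool$sample_id[ord] %in% used)]
    take <- pool$sample_id[avail[seq_len(ratio)]]
    used <- c(used, take)
    selected <- c(selected, take)
  }
  selected
}

#' Feature-selection parameters
#'
#' @param nRank probes kept in step 1 (highest rank score; default 1000)
#' @param nAuroc probes kept in step 2 (most discriminative AUROC;
#'   default 250)
#' @param corrThreshold Pearson correlation above which a probe is redundant
#'   (default 0.9)
#' @param bothGroups discard a probe only when it exceeds the threshold in
#'   the case group AND the control group (default TRUE); FALSE discards on
#'   either
#' @param signedRank rank step 1 by signed delta-beta instead of |delta-beta|
#'   (default FALSE: a hypomethylated probe is as informative as a
#'   hypermethylated one)
#' @param corrOn correlation scale, `"beta"` (default) or `"m"`
#' @return list of class `SelectionParams`
#' @export
selectionParams <- function(nRank = 1000L, nAuroc = 250L,
                            corrThreshold = 0.9, bothGroups = TRUE,
                            signedRank = FALSE, corrOn = c("beta", "m")) {
  nRank <- .stopifnotScalarCount(nRank, "nRank", 1L)
  nAuroc <- .stopifnotScalarCount(nAuroc, "nAuroc", 1L)
  if (nAuroc > nRank)
    .configError("'nAuroc' must not exceed 'nRank'", "nAuroc")
  if (!is.numeric(corrThreshold) || corrThreshold <= 0 || corrThreshold >= 1)
    .configError("'corrThreshold' must lie in (0, 1)", "corrThreshold")
  structure(list(nRank = nRank, nAuroc = nAuroc,
                 corrThreshold = corrThreshold,
                 bothGroups = isTRUE(bothGroups),
                 signedRank = isTRUE(signedRank),
                 corrOn = match.arg(corrOn)),
            class = "SelectionParams")
}

#' Three-step feature selection
#'
#' Step 1 keeps the `nRank` probes with the highest rank score
#' (|delta beta| x -log10 p, or signed delta-beta if `signedRank`). Step 2
#' keeps the `nAuroc` of those with the most discriminative AUROC, ranked by
#' max(AUROC, 1 - AUROC) so hypo- and hypermethylated probes compete
#' equally. Step 3 walks the survivors in descending step-2 rank and
#' discards any probe whose beta correlation with an already-kept probe
#' exceeds `corrThreshold` within the case group and within the control
#' group (both required by default). Ties break on probe id throughout, so
#' selection is deterministic.
#'
#' @param dmp data frame from [buildDmpTable()]
#' @param beta beta matrix covering the dmp probes and the modelled samples
#' @param groups "case"/"control" per beta column
#' @param params a [selectionParams()] list
#' @param provenance optional list stored on the signature
#' @return an [Episignature-class]
#' @export
selectFeatures <- function(dmp, beta, groups, params = selectionParams(),
                           provenance = list()) {
  if (!inherits(params, "SelectionParams")) params <- do.call(selectionParams, params)
  if (!all(dmp$probe_id %in% rownames(beta)))
    .dataError("every dmp probe must be present in the beta matrix")
  if (!any(groups == "case") || !any(groups == "control"))
    .dataError("both groups must be non-empty")

  score1 <- if (params$signedRank)
    dmp$delta_beta * (-log10(pmax(dmp$p_value, 1e-300))) else dmp$rank_score
  if (nrow(dmp) < params$nRank)
    warning(sprintf("only %d probes available for step 1 (nRank = %d); using all",
                    nrow(dmp), params$nRank))
  step1 <- dmp[order(-score1, dmp$probe_id), , drop = FALSE]
  step1 <- step1[seq_len(min(params$nRank, nrow(step1))), , drop = FALSE]

  discr <- pmax(step1$auroc, 1 - step1$auroc)
  step2 <- step1[order(-discr, -step1$rank_score, step1$probe_id), ,
                 drop = FALSE]
  step2 <- step2[seq_len(min(params$nAuroc, nrow(step2))), , drop = FALSE]

  caseIdx <- which(groups == "case"); ctrlIdx <- which(groups == "control")
  mat <- beta[step2$probe_id, , drop = FALSE]
  if (params$corrOn == "m") mat <- betaToM(mat)
  ## probes x probes correlation within each group, NA (zero variance) -> 0
  corOf <- function(idx) {
    cc <- suppressWarnings(stats::cor(t(mat[, idx, drop = FALSE])))
    cc[is.na(cc)] <- 0
    cc
  }
  corCase <- corOf(caseIdx); corCtrl <- corOf(ctrlIdx)
  kept <- integer(0)
  for (i in seq_len(nrow(step2))) {
    redundant <- if (length(kept) == 0L) FALSE else {
      rc <- corCase[i, kept] > params$corrThreshold
      rk <- corCtrl[i, kept] > params$corrThreshold
      if (params$bothGroups) any(rc & rk) else any(rc | rk)
    }
    if (!redundant) kept <- c(kept, i)
  }
  sel <- step2[kept, , drop = FALSE]

  dirs <- ifelse(sel$delta_beta < 0, -1L, 1L)
  bSel <- beta[sel$probe_id, , drop = FALSE]
  caseMean <- rowMeans(bSel[, caseIdx, drop = FALSE])
  ctrlMean <- rowMeans(bSel[, ctrlIdx, drop = FALSE])
  provenance$dataset_hash <- .contentHash(list(dim(beta), dimnames(beta)))
  provenance$n_cases <- length(caseIdx)
  provenance$n_controls <- length(ctrlIdx)
  provenance$n_step1 <- nrow(step1)
  provenance$n_step2 <- nrow(step2)
  provenance$step2_probes <- step2$probe_id
  new("Episignature", probes = sel$probe_id,
      direction = stats::setNames(dirs, sel$probe_id),
      caseMean = caseMean, controlMean = ctrlMean,
      params = unclass(params), provenance = provenance)
}

#' Ward hierarchical clustering with a two-cluster cut
#'
#' Agglomerative clustering of samples by Ward's minimum-variance criterion
#' on Euclidean distances (`hclust` method `"ward.D2"`, which operates on
#' the distances themselves), plus the two-cluster cut used to compare
#' against case/control labels.
#'
#' @param x samples x features matrix (e.g. beta at signature probes)
#' @return list: `hclust` (merge tree with heights), `clusters` (named
#'   two-cluster assignment)
#' @export
wardCluster <- function(x) {
  if (nrow(x) < 2L) .dataError("need at least 2 samples to cluster")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  list(hclust = hc, clusters = stats::cutree(hc, k = 2L))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds samples by double-centring the squared Euclidean distance matrix
#' and taking the top-`k` eigenpairs. Coordinates are defined up to
#' rotation/reflection; planar configurations embed exactly. If fewer than
#' `k` positive eigenvalues exist, the available dimensions are returned
#' (zero-filled for fully degenerate input) with a warning.
#'
#' @param x samples x features matrix
#' @param k target dimension (default 2)
#' @return samples x k coordinate matrix with rownames preserved
#' @export
mdsEmbed <- function(x, k = 2L) {
  if (nrow(x) < 3L) .dataError("need at least 3 samples for MDS")
  d <- stats::dist(x)
  if (max(d) < 1e-12) {
    out <- matrix(0, nrow(x), k, dimnames = list(rownames(x), NULL))
    return(out)
  }
  fit <- stats::cmdscale(d, k = min(k, nrow(x) - 1L), eig = TRUE)
  pts <- fit$points
  npos <- sum(fit$eig > max(fit$eig) * 1e-9)
  if (npos < k) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    npos, min(npos, ncol(pts))))
    pts <- pts[, seq_len(min(npos, ncol(pts))), drop = FALSE]
  } else if (ncol(pts) > k) {
    pts <- pts[, seq_len(k), drop = FALSE]
  }
  pts
}

#' Leave-one-out cross-validation of the episignature
#'
#' One fold per case: the held-out case is removed, the differential model
#' is refit and features reselected on the remaining cases and all matched
#' controls, every sample (training plus held-out) is embedded by classical
#' MDS on the fold's probes, and the held-out sample is assigned to the
#' nearer of the case and control centroids in the embedding. A fold whose
#' feature selection returns an empty set is marked failed and the run
#' continues.
#'
#' @param beta beta matrix covering cases and matched controls
#' @param samples sample sheet rows for those samples (`group` in
#'   case/control)
#' @param proportions cell-proportion matrix (or NULL)
#' @param params a [selectionParams()] list
#' @return data frame, one row per fold: `held_out_id`, `n_probes`,
#'   `dist_case`, `dist_control`, `assigned` ("case"/"control"/NA),
#'   `failed`
#' @export
runLoocv <- function(beta, samples, proportions = NULL,
                     params = selectionParams()) {
  caseIds <- samples$sample_id[samples$group == "case"]
  if (length(caseIds) < 3L) .dataError("need at least 3 cases for LOOCV")
  folds <- lapply(caseIds, function(heldOut) {
    train <- samples[samples$sample_id != heldOut, , drop = FALSE]
    fold <- tryCatch({
      dmp <- buildDmpTable(beta[, train$sample_id, drop = FALSE], train,
                           proportions)
      sig <- suppressWarnings(
        selectFeatures(dmp, beta[, train$sample_id, drop = FALSE],
                       train$group, params))
      probes <- signatureProbes(sig)
      if (length(probes) == 0L) stop("empty fold signature")
      ids <- c(train$sample_id, heldOut)
      emb <- mdsEmbed(t(beta[probes, ids, drop = FALSE]))
      trCase <- train$sample_id[train$group == "case"]
      trCtrl <- train$sample_id[train$group == "control"]
      centCase <- colMeans(emb[trCase, , drop = FALSE])
      centCtrl <- colMeans(emb[trCtrl, , drop = FALSE])
      p <- emb[heldOut, ]
      dCase <- sqrt(sum((p - centCase)^2))
      dCtrl <- sqrt(sum((p - centCtrl)^2))
      data.frame(held_out_id = heldOut, n_probes = length(probes),
                 dist_case = dCase, dist_control = dCtrl,
                 assigned = if (dCase <= dCtrl) "case" else "control",
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(held_out_id = heldOut, n_probes = 0L, dist_case = NA_real_,
                 dist_control = NA_real_, assigned = NA_character_,
                 failed = TRUE, stringsAsFactors = FALSE))
    fold
  })
  do.call(rbind, folds)
}

#' Serialise / restore an episignature as JSON
#' @param signature an [Episignature-class]
#' @param file path
#' @export
writeEpisignature <- function(signature, file) {
  jsonlite::write_json(list(
    probes = signature@probes,
    direction = as.list(signature@direction),
    case_mean = as.list(signature@caseMean),
    control_mean = as.list(signature@controlMean),
    params = signature@params,
    provenance = signature@provenance), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeEpisignature
#' @export
readEpisignature <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("Episignature", probes = x$probes,
      direction = stats::setNames(as.integer(x$direction), x$probes),
      caseMean = stats::setNames(as.numeric(x$case_mean), x$probes),
      controlMean = stats::setNames(as.numeric(x$control_mean), x$probes),
      params = as.list(x$params), provenance = as.list(x$provenance))
}
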