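## Binary SVM classifier over signature probes, emitting calibrated
## methylation variant pathogenicity (MVP) scores with the 0.5 decision
## rule. The fitted machine is reduced to a JSON-serialisable linear scorer
## (weights, intercept, Platt sigmoid, feature standardisation).

#' Training plan for the MVP classifier
#'
#' Makes the negative-set composition explicit: the discovery cases train
#' against their matched controls plus `trainFraction` (default 75%) of the
#' other-control pool and of each other-disorder cohort; the remaining 25%
#' of the pools form the held-out test set.
#'
#' @param caseIds discovery case sample ids (positives)
#' @param matchedControlIds matched controls (all in training)
#' @param otherControlIds other-control pool, split by `trainFraction`
#' @param disorderIds named character vector of other-disorder sample ids,
#'   names giving the disorder (split stratified per disorder), or plain ids
#' @param trainFraction fraction of each pool used for training, in (0, 1)
#' @param seed integer seed controlling the split
#' @return list of class `TrainingPlan`
#' @export
trainingPlan <- function(caseIds, matchedControlIds,
                         otherControlIds = character(0),
                         disorderIds = character(0),
                         trainFraction = 0.75, seed = 1L) {
  if (!is.numeric(trainFraction) || trainFraction <= 0 || trainFraction >= 1)
    .configError("'trainFraction' must lie in (0, 1)", "trainFraction")
  seed <- .stopifnotScalarCount(seed, "seed")
  sets <- list(caseIds, matchedControlIds, otherControlIds,
               unname(disorderIds))
  all <- unlist(sets)
  if (anyDuplicated(all))
    .configError("sample id sets of the training plan must be disjoint",
                 "caseIds")
  structure(list(caseIds = caseIds, matchedControlIds = matchedControlIds,
                 otherControlIds = otherControlIds,
                 disorderIds = disorderIds,
                 trainFraction = trainFraction, seed = seed),
            class = "TrainingPlan")
}

## 75/25-style split of the negative pools, stratified by disorder;
## deterministic for a fixed plan seed.
.splitPlan <- function(plan) {
  set.seed(plan$seed)
  takeTrain <- function(ids) {
    n <- length(ids)
    if (n == 0L) return(character(0))
    ids[sort(sample.int(n, floor(plan$trainFraction * n)))]
  }
  trainOther <- takeTrain(plan$otherControlIds)
  dis <- plan$disorderIds
  if (is.null(names(dis)) && length(dis)) names(dis) <- rep("disorder", length(dis))
  trainDis <- unlist(lapply(split(unname(dis), names(dis)), takeTrain),
                     use.names = FALSE)
  trainNeg <- c(plan$matchedControlIds, trainOther, trainDis)
  testIds <- setdiff(c(plan$otherControlIds, unname(dis)),
                     c(trainOther, trainDis))
  list(trainPos = plan$caseIds, trainNeg = trainNeg, testIds = testIds)
}

#' Train the MVP support vector machine
#'
#' Features are beta values at the signature probes, standardised by
#' training mean/SD. A linear-kernel SVM (cost 1 by default) with
#' inverse-frequency class weights is fitted on cases against the plan's
#' negative composition, with Platt sigmoid probability calibration. The
#' fitted machine is collapsed to its weight vector, intercept and sigmoid
#' coefficients, stored in an [MvpModel-class] together with the feature
#' order and scaling, so scoring is a pure linear-plus-sigmoid computation
#' and the model round-trips through JSON.
#'
#' @param beta beta matrix covering all plan samples at signature probes
#' @param signature an [Episignature-class]
#' @param plan a [trainingPlan()] list
#' @param cost SVM regularisation cost (default 1)
#' @param cutoff MVP class cut-off stored on the model (default 0.5)
#' @return list: `model` ([MvpModel-class]), `train_ids`, `test_ids`
#' @export
trainClassifier <- function(beta, signature, plan, cost = 1, cutoff = 0.5) {
  probes <- signatureProbes(signature)
  missing <- setdiff(probes, rownames(beta))
  if (length(missing))
    .dataError(sprintf("signature probe(s) absent from beta: %s",
                       paste(utils::head(missing, 5), collapse = ", ")))
  split <- .splitPlan(plan)
  trainIds <- c(split$trainPos, split$trainNeg)
  missingS <- setdiff(c(trainIds, split$testIds), colnames(beta))
  if (length(missingS))
    .dataError(sprintf("plan sample(s) absent from beta: %s",
                       paste(utils::head(missingS, 5), collapse = ", ")))
  if (length(split$trainPos) < 2L || length(split$trainNeg) < 2L)
    .dataError("each training class needs at least 2 samples")

  x <- t(beta[probes, trainIds, drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- scale(x, center = center, scale = scale)
  y <- factor(c(rep("case", length(split$trainPos)),
                rep("other", length(split$trainNeg))),
              levels = c("case", "other"))
  n <- length(y)
  cw <- c(case = n / (2 * sum(y == "case")),
          other = n / (2 * sum(y == "other")))
  set.seed(plan$seed)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE,
                    probability = TRUE, class.weights = cw)
  if (is.null(fit$probA))
    .dataError("probability calibration failed during SVM training")

  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  ## canonicalise sign conventions against e1071's own predictions
  decManual <- drop(xs %*% w) - rho
  pref <- attr(stats::predict(fit, xs, decision.values = TRUE),
               "decision.values")
  if (stats::cor(decManual, drop(pref)) < 0) {
    w <- -w; rho <- -rho; decManual <- -decManual
  }
  pCase <- attr(stats::predict(fit, xs, probability = TRUE),
                "probabilities")[, "case"]
  cand <- list(c(fit$probA, fit$probB), c(-fit$probA, -fit$probB))
  errs <- vapply(cand, function(ab)
    max(abs(1 / (1 + exp(ab[1] * decManual + ab[2])) - pCase)), numeric(1))
  ab <- cand[[which.min(errs)]]

  model <- new("MvpModel", probes = probes, center = unname(center),
               scale = unname(scale), weights = unname(w), rho = rho,
               probA = ab[1], probB = ab[2], cutoff = cutoff)
  list(model = model, train_ids = trainIds, test_ids = split$testIds)
}

#' Score samples against a trained MVP model
#'
#' Standardises beta values at the signature probes with the training
#' constants, applies the linear decision function and the Platt sigmoid,
#' and calls the class at the cut-off. Any signature probe absent from the
#' input is an error (no silent imputation); probe order in the input is
#' irrelevant.
#'
#' @param model an [MvpModel-class]
#' @param beta beta matrix for the samples to score
#' @param cutoff decision cut-off (default: the model's, normally 0.5)
#' @return data frame: `sample_id`, `mvp_score` in \[0, 1\], `call`
#'   ("positive"/"negative")
#' @export
scoreSamples <- function(model, beta, cutoff = model@cutoff) {
  missing <- setdiff(model@probes, rownames(beta))
  if (length(missing))
    .dataError(sprintf("signature probe(s) missing from input: %s",
                       paste(missing, collapse = ", ")))
  x <- t(beta[model@probes, , drop = FALSE])
  xs <- scale(x, center = model@center, scale = model@scale)
  dec <- drop(xs %*% model@weights) - model@rho
  score <- 1 / (1 + exp(model@probA * dec + model@probB))
  score <- pmin(pmax(score, 0), 1)
  data.frame(sample_id = colnames(beta), mvp_score = unname(score),
             call = ifelse(score >= cutoff, "positive", "negative"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialise / restore an MVP model as JSON
#'
#' No opaque binary state: the JSON carries probes, scaling, weights,
#' intercept, sigmoid coefficients and cut-off.
#'
#' @param model an [MvpModel-class]
#' @param file path
#' @export
writeMvpModel <- function(model, file) {
  jsonlite::write_json(list(
    probes = model@probes, center = model@center, scale = model@scale,
    weights = model@weights, rho = model@rho, probA = model@probA,
    probB = model@probB, cutoff = model@cutoff), file,
    auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeMvpModel
#' @export
readMvpModel <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("MvpModel", probes = x$probes, center = as.numeric(x$center),
      scale = as.numeric(x$scale), weights = as.numeric(x$weights),
      rho = x$rho, probA = x$probA, probB = x$probB, cutoff = x$cutoff)
}
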