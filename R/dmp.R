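## Per-probe differential methylation: ordinary least squares on M-values
## with cell-proportion covariates, empirical-Bayes moderation of the
## residual variances, delta-beta and AUROC per probe, and the rank score
## |delta beta| * (-log10 p) that drives feature selection.

#' Build the per-probe linear model design matrix
#'
#' Intercept, a case indicator (case = 1), and one column per cell-type
#' proportion; optionally batch and/or array-type factor columns.
#'
#' @param samples sample sheet rows for the modelled samples (needs
#'   `sample_id` and `group` with values "case"/"control")
#' @param proportions samples x cell types matrix from
#'   [estimateProportions()], or NULL for no composition adjustment
#' @param batch,arrayType include batch / array type as factor covariates
#' @return numeric design matrix with rownames = sample ids
#' @export
buildDesign <- function(samples, proportions = NULL, batch = FALSE,
                        arrayType = FALSE) {
  if (!all(samples$group %in% c("case", "control")))
    .dataError("design samples must be labelled 'case' or 'control'")
  X <- cbind(intercept = 1, group = as.numeric(samples$group == "case"))
  rownames(X) <- samples$sample_id
  if (!is.null(proportions)) {
    missing <- setdiff(samples$sample_id, rownames(proportions))
    if (length(missing))
      .dataError(sprintf("no cell proportions for sample(s): %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
    X <- cbind(X, proportions[samples$sample_id, , drop = FALSE])
  }
  addFactor <- function(X, v, prefix) {
    f <- factor(v)
    if (nlevels(f) > 1L) {
      d <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(d) <- paste0(prefix, levels(f)[-1])
      X <- cbind(X, d)
    }
    X
  }
  if (batch) X <- addFactor(X, samples$batch, "batch")
  if (arrayType) X <- addFactor(X, samples$array_type, "array")
  X
}

#' Fit per-probe linear models
#'
#' Ordinary least squares of each probe's M-values on the design matrix,
#' returning for the coefficient of interest its estimate, unscaled standard
#' deviation, residual variance and residual degrees of freedom — the
#' sufficient statistics for empirical-Bayes moderation.
#'
#' @param m M-value matrix, probes x samples
#' @param design design matrix from [buildDesign()] (rows = samples, full
#'   column rank)
#' @param coef name of the tested coefficient (default `"group"`)
#' @return data frame: `probe_id`, `coef`, `stdev_unscaled` (so that
#'   se = stdev_unscaled * s), `se`, `sigma2` (residual variance s^2),
#'   `df` (residual degrees of freedom)
#' @export
fitProbeModels <- function(m, design, coef = "group") {
  if (ncol(m) != nrow(design))
    .dataError("design rows must match M-value samples")
  if (!is.null(rownames(design)) && !is.null(colnames(m)) &&
      !identical(colnames(m), rownames(design)))
    m <- m[, rownames(design), drop = FALSE]
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
    .dataError(sprintf("design is rank-deficient; dependent column(s): %s",
                       paste(bad, collapse = ", ")))
  }
  if (!coef %in% colnames(design))
    .dataError(sprintf("coefficient '%s' not in design", coef))
  n <- nrow(design); p <- ncol(design)
  dg <- n - p
  if (dg <= 0) .dataError("no residual degrees of freedom")
  fit <- stats::lm.fit(design, t(m))
  B <- t(fit$coefficients)                       # probes x p
  rss <- colSums(fit$residuals^2)
  s2 <- rss / dg
  xtxInv <- chol2inv(chol(crossprod(design)))
  cUnscaled <- sqrt(xtxInv[match(coef, colnames(design)),
                           match(coef, colnames(design))])
  data.frame(probe_id = rownames(m), coef = B[, coef],
             stdev_unscaled = cUnscaled, se = cUnscaled * sqrt(s2),
             sigma2 = s2, df = dg, row.names = NULL,
             stringsAsFactors = FALSE)
}

## Invert the trigamma function by Newton iteration on 1/trigamma scale.
.trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-inverse-chi-squared prior (d0, s0^2) to the observed
#' residual variances by matching the theoretical mean and variance of
#' log s^2: under the prior, Var(log s^2) = trigamma(d/2) + trigamma(d0/2),
#' so excess dispersion of log s^2 beyond the chi-squared sampling noise
#' determines d0 via the inverse trigamma. When the observed dispersion does
#' not exceed trigamma(d/2), d0 = +Inf (no excess dispersion) and s0^2 is
#' the geometric mean of the residual variances.
#'
#' @param fits data frame from [fitProbeModels()] (`sigma2`, `df`)
#' @return list with `d0` (prior df, possibly `Inf`) and `s02`
#'   (prior variance)
#' @export
estimateModerationPrior <- function(fits) {
  s2 <- fits$sigma2; dg <- fits$df
  ok <- s2 > 0
  if (!any(ok)) .dataError("all residual variances are zero; degenerate data")
  if (sum(ok) < 2L) .dataError("need at least 2 probes with positive variance")
  z <- log(s2[ok]); d <- dg[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(z) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(z))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each probe's residual variance towards the prior:
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}, forms the moderated
#' statistic \eqn{\tilde t = \hat\beta / (c \tilde s)} (with c the unscaled
#' coefficient standard deviation) and two-sided p-values from the t
#' distribution on \eqn{d_0 + d} degrees of freedom (normal reference when
#' \eqn{d_0 = \infty}).
#'
#' @param fits data frame from [fitProbeModels()]
#' @param prior list from [estimateModerationPrior()]
#' @return data frame: `probe_id`, `t`, `p_value`, `s2_post`, `df_total`
#' @export
moderateStatistics <- function(fits, prior) {
  d0 <- prior$d0; s02 <- prior$s02
  if (!(length(d0) == 1L && d0 >= 0) || !(length(s02) == 1L && s02 > 0))
    .configError("prior must have d0 >= 0 and s02 > 0", "prior")
  d <- fits$df
  s2post <- if (is.infinite(d0)) rep(s02, nrow(fits)) else
    (d0 * s02 + d * fits$sigma2) / (d0 + d)
  tmod <- fits$coef / (fits$stdev_unscaled * sqrt(s2post))
  dfTotal <- d0 + d
  p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
  data.frame(probe_id = fits$probe_id, t = tmod, p_value = p,
             s2_post = s2post, df_total = dfTotal, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mean beta difference between cases and controls
#'
#' @param beta beta matrix, probes x samples
#' @param groups character/factor per sample: "case" or "control" (other
#'   labels are ignored)
#' @return named numeric: mean(case beta) - mean(control beta) per probe,
#'   on the beta scale
#' @export
computeDeltaBeta <- function(beta, groups) {
  caseIdx <- which(groups == "case"); ctrlIdx <- which(groups == "control")
  if (!length(caseIdx) || !length(ctrlIdx))
    .dataError("both case and control groups must be non-empty")
  rowMeans(beta[, caseIdx, drop = FALSE]) -
    rowMeans(beta[, ctrlIdx, drop = FALSE])
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUROC = U / (n_case * n_control) with ties counted one half: the
#' probability that a randomly drawn case value exceeds a randomly drawn
#' control value.
#'
#' @param values numeric vector, one value per sample
#' @param labels "case"/"control" per sample
#' @return AUROC in \[0, 1\]
#' @examples
#' computeAuroc(c(3, 1, 2, 0), c("case", "case", "control", "control")) # 0.75
#' @export
computeAuroc <- function(values, labels) {
  caseIdx <- labels == "case"; ctrlIdx <- labels == "control"
  n1 <- sum(caseIdx); n0 <- sum(ctrlIdx)
  if (n1 == 0L || n0 == 0L)
    .dataError("both case and control labels must be present")
  r <- rank(values[caseIdx | ctrlIdx])
  lab <- labels[caseIdx | ctrlIdx]
  (sum(r[lab == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Row-wise AUROC over a beta matrix (midrank ties).
.aurocMatrix <- function(beta, groups) {
  use <- groups %in% c("case", "control")
  b <- beta[, use, drop = FALSE]
  lab <- groups[use]
  n1 <- sum(lab == "case"); n0 <- sum(lab == "control")
  caseCols <- lab == "case"
  apply(b, 1L, function(v) {
    r <- rank(v)
    (sum(r[caseCols]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
}

#' Assemble the differential-methylation probe table
#'
#' Runs the full per-probe analysis — OLS fits on M-values with covariates,
#' empirical-Bayes moderation, delta-beta on the beta scale, AUROC, and the
#' selection rank score |delta beta| * (-log10 p) (p floored at 1e-300) —
#' and returns one row per probe.
#'
#' @param beta beta matrix (probes x samples) for the modelled samples
#' @param samples sample sheet rows aligned with `beta` columns
#' @param proportions cell-proportion matrix (or NULL)
#' @param batch,arrayType optional design covariates, see [buildDesign()]
#' @param clamp beta clamp used for the M transform
#' @return data frame: `probe_id`, `delta_beta`, `t`, `p_value`, `auroc`,
#'   `rank_score`
#' @export
buildDmpTable <- function(beta, samples, proportions = NULL, batch = FALSE,
                          arrayType = FALSE, clamp = 1e-6) {
  use <- samples$group %in% c("case", "control")
  samples <- samples[use, , drop = FALSE]
  beta <- beta[, samples$sample_id, drop = FALSE]
  design <- buildDesign(samples, proportions, batch = batch,
                        arrayType = arrayType)
  m <- betaToM(beta, clamp)
  fits <- fitProbeModels(m, design)
  prior <- estimateModerationPrior(fits)
  mod <- moderateStatistics(fits, prior)
  dB <- computeDeltaBeta(beta, samples$group)
  auroc <- .aurocMatrix(beta, samples$group)
  p <- pmax(mod$p_value, 1e-300)
  data.frame(probe_id = fits$probe_id, delta_beta = unname(dB),
             t = mod$t, p_value = mod$p_value, auroc = unname(auroc),
             rank_score = abs(unname(dB)) * (-log10(p)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a DMP table (TSV)
#' @param dmp data frame from [buildDmpTable()]
#' @param file path
#' @param provenance optional provenance comment lines
#' @export
writeDmpTable <- function(dmp, file, provenance = NULL)
  .writeTableFile(dmp, file, "\t", provenance)

#' @rdname writeDmpTable
#' @export
readDmpTable <- function(file)
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
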