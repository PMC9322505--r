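## Probe-level quality control, beta -> M transformation, PCA outlier screen.

#' Probe-level quality control
#'
#' Removes probes that are annotated to the allosomes, carry a SNP at or near
#' the interrogation/extension site, are known to cross-react, or exceed the
#' detection p-value threshold in any sample. Removal reasons are counted
#' once per probe under the declared precedence
#' allosomal > snp > crossreactive > detection, so the [QcReport-class]
#' counts are reproducible. Retained probe order and values are untouched.
#'
#' @param x a [MethylExperiment-class], or a beta matrix (then `detp` and
#'   `manifest` are required).
#' @param detp detection p-value matrix, same shape as the beta matrix.
#' @param manifest probe manifest data frame covering every beta probe.
#' @param detpAlpha detection p-value threshold (default 0.01); a probe with
#'   detection p above it in any sample is removed.
#' @param ... passed between methods.
#' @return a list with elements `object` (the filtered input, same class)
#'   and `report` (a [QcReport-class]).
#' @examples
#' cohort <- simulateCohort(cohortConfig(nProbes = 2000, seed = 2))
#' qc <- filterProbes(cohort)
#' qc$report
#' @export
setGeneric("filterProbes", function(x, ...) standardGeneric("filterProbes"))

.filterProbesCore <- function(beta, detp, manifest, detpAlpha) {
  if (!identical(dim(beta), dim(detp)))
    .dataError("detp must have the same dimensions as beta")
  missing <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing))
    .dataError(sprintf("probe(s) missing from manifest: %s",
                       paste(utils::head(missing, 5), collapse = ", ")))
  man <- manifest[match(rownames(beta), manifest$probe_id), ]
  detFail <- apply(detp > detpAlpha, 1L, any)
  ## precedence: each probe counted once under its first matching reason
  reason <- rep(NA_character_, nrow(beta))
  reason[detFail] <- "detection"
  reason[man$is_crossreactive] <- "crossreactive"
  reason[man$is_snp] <- "snp"
  reason[man$is_allosomal] <- "allosomal"
  keep <- is.na(reason)
  removed <- vapply(c("allosomal", "snp", "crossreactive", "detection"),
                    function(r) sum(reason == r, na.rm = TRUE), integer(1))
  report <- new("QcReport", nInputProbes = nrow(beta), removed = removed,
                retainedProbes = rownames(beta)[keep],
                outlierSamples = character(0))
  list(keep = keep, report = report)
}

#' @rdname filterProbes
setMethod("filterProbes", "MethylExperiment",
          function(x, detpAlpha = 0.01, ...) {
  res <- .filterProbesCore(betaValues(x), detpValues(x), probeManifest(x),
                           detpAlpha)
  list(object = x[res$keep, ], report = res$report)
})

#' @rdname filterProbes
setMethod("filterProbes", "matrix",
          function(x, detp, manifest, detpAlpha = 0.01, ...) {
  res <- .filterProbesCore(x, detp, manifest, detpAlpha)
  list(object = x[res$keep, , drop = FALSE], report = res$report)
})

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)), after clamping beta into
#' \[clamp, 1 - clamp\] so the transform stays finite. Strictly increasing
#' in beta; M(0.5) = 0 and M(beta) = -M(1 - beta).
#'
#' @param beta numeric vector or matrix of methylation fractions in \[0, 1\]
#' @param clamp clamping bound, must lie in (0, 0.5)
#' @return M-values with the same shape and dimnames as `beta`
#' @examples
#' betaToM(c(0.2, 0.5, 0.8))   # -2, 0, 2
#' @export
betaToM <- function(beta, clamp = 1e-6) {
  if (!is.numeric(clamp) || length(clamp) != 1L || clamp <= 0 || clamp >= 0.5)
    .configError("'clamp' must lie in (0, 0.5)", "clamp")
  if (min(beta) < 0 || max(beta) > 1)
    .dataError("beta values must lie in [0, 1]")
  b <- .clampBeta(beta, clamp)
  log2(b / (1 - b))
}

#' Invert the M-value transform
#' @param m M-values
#' @return beta values (the clamped beta that produced `m`)
#' @export
mToBeta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' PCA-based sample outlier screen
#'
#' Projects samples onto the first `nComponents` principal components of the
#' M-value matrix and flags any sample whose score on any component exceeds
#' `sdThreshold` times that component's score standard deviation. Components
#' with (near-)zero variance flag nothing. The flag set is invariant under
#' the sign ambiguity of PCA. Outliers are reported, not dropped — exclusion
#' is an explicit caller decision.
#'
#' @param m M-value matrix, probes x samples (or a
#'   [MethylExperiment-class], in which case M-values are computed from beta)
#' @param nComponents number of leading components examined (default 2)
#' @param sdThreshold flagging multiplier (default 3)
#' @return character vector of flagged sample ids
#' @export
pcaOutlierScreen <- function(m, nComponents = 2L, sdThreshold = 3) {
  if (is(m, "MethylExperiment")) m <- betaToM(betaValues(m))
  nComponents <- .stopifnotScalarCount(nComponents, "nComponents", 1L)
  if (ncol(m) < 3L)
    .configError("need at least 3 samples for the outlier screen", "m")
  if (ncol(m) < nComponents)
    .configError("fewer samples than components requested", "nComponents")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  flagged <- logical(ncol(m))
  for (j in seq_len(k)) {
    s <- stats::sd(pc$x[, j])
    if (s > 1e-12)
      flagged <- flagged | abs(pc$x[, j]) > sdThreshold * s
  }
  colnames(m)[flagged]
}
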