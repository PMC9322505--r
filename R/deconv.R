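## Reference-based blood cell-type deconvolution: constrained projection of
## each sample's beta profile onto cell-type reference profiles (the
## Houseman estimator), solved as non-negative least squares with the
## sum-to-at-most-one constraint handled by a heavily weighted slack row.

## Solve min ||R w - b||^2 s.t. w >= 0 and (sum w <= 1 | sum w = 1).
## The simplex constraint is encoded as an equality row  lambda*(1'w + s) =
## lambda  with non-negative slack s (omitted when sumToOne): at the NNLS
## optimum the slack absorbs any shortfall exactly, so the penalty row is
## inactive for interior solutions and binding otherwise.
.solveConstrainedProjection <- function(R, b, sumToOne = FALSE,
                                        lambda = 1e6) {
  k <- ncol(R)
  scale <- max(abs(R), 1)
  A <- rbind(R, lambda * scale * rep(1, k))
  if (!sumToOne) A <- cbind(A, c(rep(0, nrow(R)), lambda * scale))
  rhs <- c(b, lambda * scale)
  w <- pracma::lsqnonneg(A, rhs)$x[seq_len(k)]
  pmax(w, 0)
}

#' Estimate blood cell-type proportions (Houseman method)
#'
#' For each sample, solves the constrained least-squares projection
#' minimise \eqn{\|\beta_s - R w\|^2} subject to \eqn{w \ge 0} and
#' \eqn{\sum w \le 1} (or \eqn{= 1} when `sumToOne = TRUE`), over the
#' reference probes. The solution is unique when the reference profile has
#' full column rank.
#'
#' @param beta beta matrix (probes x samples) containing every reference
#'   probe, or a [MethylExperiment-class]
#' @param reference a [CellTypeReference-class]
#' @param sumToOne force proportions to sum exactly to one (default FALSE,
#'   the projection form \eqn{\sum w \le 1})
#' @return numeric matrix, samples x cell types, of estimated proportions
#' @examples
#' cohort <- simulateCohort(cohortConfig(nProbes = 2000, seed = 3))
#' ref <- S4Vectors::metadata(cohort)$reference
#' head(estimateProportions(cohort, ref), 3)
#' @export
estimateProportions <- function(beta, reference, sumToOne = FALSE) {
  if (is(beta, "MethylExperiment")) beta <- betaValues(beta)
  missing <- setdiff(reference@probes, rownames(beta))
  if (length(missing))
    .dataError(sprintf("reference probe(s) absent from beta matrix: %s",
                       paste(utils::head(missing, 5), collapse = ", ")))
  R <- reference@profile
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    bad <- reference@cellTypes[qrR$pivot[(qrR$rank + 1L):ncol(R)]]
    .dataError(sprintf("reference is rank-deficient; collinear cell type(s): %s",
                       paste(bad, collapse = ", ")))
  }
  B <- beta[reference@probes, , drop = FALSE]
  w <- t(vapply(seq_len(ncol(B)),
                function(j) .solveConstrainedProjection(R, B[, j], sumToOne),
                numeric(ncol(R))))
  dimnames(w) <- list(colnames(B), reference@cellTypes)
  w
}

#' Write / read estimated cell proportions as CSV
#' @param w samples x cell types matrix from [estimateProportions()]
#' @param file path
#' @param provenance optional provenance comment lines
#' @export
writeProportions <- function(w, file, provenance = NULL) {
  df <- data.frame(sample_id = rownames(w), w, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTableFile(df, file, ",", provenance)
}

#' @rdname writeProportions
#' @export
readProportions <- function(file) {
  df <- utils::read.csv(file, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
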