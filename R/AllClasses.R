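#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @import SummarizedExperiment
NULL

#' MethylExperiment: a probes-by-samples methylation experiment
#'
#' Thin extension of [SummarizedExperiment::RangedSummarizedExperiment-class]
#' holding a `beta` assay (methylation fractions in \[0, 1\]), optionally a
#' `detp` assay of detection p-values of the same shape, per-probe genomic
#' coordinates and QC exclusion flags (`is_allosomal`, `is_snp`,
#' `is_crossreactive`) in `rowRanges`, and the sample sheet in `colData`.
#' Synthetic cohorts additionally carry a `truth` list and the generating
#' cell-type reference in `metadata()`.
#'
#' @aliases MethylExperiment-class
#' @exportClass MethylExperiment
setClass("MethylExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylExperiment", function(object) {
  msg <- character(0)
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (anyNA(b) || min(b) < 0 || max(b) > 1)
      msg <- c(msg, "beta values must lie in [0, 1] with no NA")
  }
  if ("detp" %in% SummarizedExperiment::assayNames(object)) {
    p <- SummarizedExperiment::assay(object, "detp")
    if (anyNA(p) || min(p) < 0 || max(p) > 1)
      msg <- c(msg, "detection p-values must lie in [0, 1] with no NA")
  }
  flags <- c("is_allosomal", "is_snp", "is_crossreactive")
  if (!all(flags %in% colnames(mcols(SummarizedExperiment::rowRanges(object)))))
    msg <- c(msg, sprintf("rowRanges must carry flags: %s",
                          paste(flags, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylExperiment from plain matrices and tables
#'
#' @param beta numeric matrix, probes x samples, values in \[0, 1\]; rownames
#'   are probe ids, colnames sample ids.
#' @param manifest data frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based), logical `is_allosomal`, `is_snp`, `is_crossreactive`,
#'   covering every row of `beta`.
#' @param samples data frame with a `sample_id` column covering every column
#'   of `beta`; typically also `group`, `age`, `sex`, `batch`, `array_type`.
#' @param detp optional matrix of detection p-values, same shape as `beta`.
#' @param metadata optional list stored in `metadata()`.
#' @return a [MethylExperiment-class] object
#' @examples
#' cohort <- simulateCohort(cohortConfig(nProbes = 2000, seed = 1))
#' cohort
#' @export
MethylExperiment <- function(beta, manifest, samples, detp = NULL,
                             metadata = list()) {
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    .dataError("beta matrix must have probe rownames and sample colnames")
  missing <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing))
    .dataError(sprintf("probe(s) missing from manifest: %s",
                       paste(utils::head(missing, 5), collapse = ", ")))
  manifest <- manifest[match(rownames(beta), manifest$probe_id), ]
  gr <- GRanges(seqnames = manifest$chrom,
                ranges = IRanges(start = manifest$pos, width = 1L))
  names(gr) <- manifest$probe_id
  mcols(gr)$is_allosomal <- as.logical(manifest$is_allosomal)
  mcols(gr)$is_snp <- as.logical(manifest$is_snp)
  mcols(gr)$is_crossreactive <- as.logical(manifest$is_crossreactive)
  if (!all(colnames(beta) %in% samples$sample_id))
    .dataError("every beta column must appear in the sample sheet")
  samples <- samples[match(colnames(beta), samples$sample_id), ]
  assays <- list(beta = beta)
  if (!is.null(detp)) {
    if (!identical(dim(detp), dim(beta)))
      .dataError("detp must have the same dimensions as beta")
    dimnames(detp) <- dimnames(beta)
    assays$detp <- detp
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = gr,
                             colData = DataFrame(samples, row.names = samples$sample_id))
  S4Vectors::metadata(se) <- metadata
  new("MethylExperiment", se)
}

#' CellTypeReference: mean methylation profiles of blood cell types
#'
#' Reference beta profiles used by the constrained-projection (Houseman)
#' deconvolution: one column per cell type, one row per reference probe.
#'
#' @slot probes character vector of reference probe ids
#' @slot cellTypes character vector of cell-type names
#' @slot profile numeric matrix (probes x cell types) of mean beta values
#' @aliases CellTypeReference-class
#' @exportClass CellTypeReference
setClass("CellTypeReference",
         slots = c(probes = "character", cellTypes = "character",
                   profile = "matrix"))

setValidity("CellTypeReference", function(object) {
  msg <- character(0)
  p <- object@profile
  if (nrow(p) != length(object@probes) || ncol(p) != length(object@cellTypes))
    msg <- c(msg, "profile dimensions must match probes x cellTypes")
  if (length(object@probes) && (min(p) < 0 || max(p) > 1))
    msg <- c(msg, "profile values must lie in [0, 1]")
  if (anyDuplicated(object@probes))
    msg <- c(msg, "reference probes must be unique")
  if (nrow(p) < ncol(p))
    msg <- c(msg, "need at least as many reference probes as cell types")
  if (length(msg)) msg else TRUE
})

#' @param probes,cellTypes,profile see slot descriptions
#' @rdname CellTypeReference-class
#' @export
CellTypeReference <- function(probes, cellTypes, profile) {
  dimnames(profile) <- list(probes, cellTypes)
  new("CellTypeReference", probes = as.character(probes),
      cellTypes = as.character(cellTypes), profile = profile)
}

#' QcReport: outcome of probe-level quality control
#'
#' @slot nInputProbes number of probes entering QC
#' @slot removed named integer vector of removal counts by reason, with the
#'   declared precedence allosomal > snp > crossreactive > detection
#' @slot retainedProbes ids of probes surviving all filters
#' @slot outlierSamples sample ids flagged by PCA screening (filled in by
#'   [pcaOutlierScreen()]; empty until then)
#' @aliases QcReport-class
#' @exportClass QcReport
setClass("QcReport",
         slots = c(nInputProbes = "integer", removed = "integer",
                   retainedProbes = "character", outlierSamples = "character"))

setValidity("QcReport", function(object) {
  if (object@nInputProbes !=
      length(object@retainedProbes) + sum(object@removed))
    "input probe count must equal retained + sum(removed)" else TRUE
})

#' Episignature: an ordered, directional selected-probe set
#'
#' The portable artifact of discovery: probes ordered by final selection
#' rank, the direction of methylation change in cases (+1 hyper, -1 hypo),
#' per-probe reference mean beta in cases and controls, the selection
#' parameters and provenance of the training data.
#'
#' @slot probes character, ordered by retained rank
#' @slot direction named integer (+1/-1) per probe
#' @slot caseMean,controlMean named numeric mean beta per probe
#' @slot params list of selection parameters (see [selectionParams()])
#' @slot provenance list (dataset hash, seed, group sizes)
#' @aliases Episignature-class
#' @exportClass Episignature
setClass("Episignature",
         slots = c(probes = "character", direction = "integer",
                   caseMean = "numeric", controlMean = "numeric",
                   params = "list", provenance = "list"))

setValidity("Episignature", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@probes)) msg <- c(msg, "duplicate probes")
  if (!all(object@direction %in% c(-1L, 1L)))
    msg <- c(msg, "direction must be +1 or -1 for every probe")
  n <- length(object@probes)
  if (length(object@direction) != n || length(object@caseMean) != n ||
      length(object@controlMean) != n)
    msg <- c(msg, "per-probe slots must align with probes")
  if (length(msg)) msg else TRUE
})

#' MvpModel: serialisable linear SVM scorer for MVP scores
#'
#' A trained linear-kernel support vector machine reduced to its weight
#' vector, intercept and Platt sigmoid calibration, together with the
#' feature order and standardisation constants, so the model round-trips
#' through JSON with no opaque binary state.
#'
#' @slot probes feature order (signature probes)
#' @slot center,scale training mean / sd per probe (beta scale)
#' @slot weights linear weight per probe (standardised feature space)
#' @slot rho decision-function intercept
#' @slot probA,probB Platt sigmoid coefficients:
#'   score = 1 / (1 + exp(probA * decision + probB))
#' @slot cutoff MVP class cut-off (default 0.5)
#' @aliases MvpModel-class
#' @exportClass MvpModel
setClass("MvpModel",
         slots = c(probes = "character", center = "numeric", scale = "numeric",
                   weights = "numeric", rho = "numeric", probA = "numeric",
                   probB = "numeric", cutoff = "numeric"))

setValidity("MvpModel", function(object) {
  n <- length(object@probes)
  if (length(object@weights) != n || length(object@center) != n ||
      length(object@scale) != n)
    return("weights/center/scale must align with probes")
  if (object@cutoff < 0 || object@cutoff > 1)
    return("cutoff must lie in [0, 1]")
  TRUE
})
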