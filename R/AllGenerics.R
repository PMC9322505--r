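#' @include AllClasses.R
NULL

#' Accessors for methylation experiment content
#'
#' `betaValues()` and `detpValues()` return the beta / detection-p assay;
#' `sampleSheet()` the sample metadata as a base data frame;
#' `probeManifest()` the per-probe coordinates and QC flags as a data frame
#' (the same shape accepted by [MethylExperiment()]).
#'
#' @param x a [MethylExperiment-class]
#' @return matrix or data frame, see details
#' @name methyl-accessors
NULL

#' @rdname methyl-accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname methyl-accessors
#' @export
setGeneric("detpValues", function(x) standardGeneric("detpValues"))

#' @rdname methyl-accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname methyl-accessors
#' @export
setGeneric("probeManifest", function(x) standardGeneric("probeManifest"))

#' @rdname methyl-accessors
setMethod("betaValues", "MethylExperiment", function(x)
  SummarizedExperiment::assay(x, "beta"))

#' @rdname methyl-accessors
setMethod("detpValues", "MethylExperiment", function(x) {
  if (!"detp" %in% SummarizedExperiment::assayNames(x))
    .dataError("no 'detp' assay present")
  SummarizedExperiment::assay(x, "detp")
})

#' @rdname methyl-accessors
setMethod("sampleSheet", "MethylExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname methyl-accessors
setMethod("probeManifest", "MethylExperiment", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  data.frame(probe_id = names(gr),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             is_allosomal = mcols(gr)$is_allosomal,
             is_snp = mcols(gr)$is_snp,
             is_crossreactive = mcols(gr)$is_crossreactive,
             stringsAsFactors = FALSE)
})

#' Episignature accessors
#' @param x an [Episignature-class]
#' @return `signatureProbes()`: ordered probe ids; `signatureDirections()`:
#'   named +1/-1 vector; `signatureParams()`: the parameter list.
#' @name episignature-accessors
NULL

#' @rdname episignature-accessors
#' @export
setGeneric("signatureProbes", function(x) standardGeneric("signatureProbes"))

#' @rdname episignature-accessors
#' @export
setGeneric("signatureDirections", function(x)
  standardGeneric("signatureDirections"))

#' @rdname episignature-accessors
#' @export
setGeneric("signatureParams", function(x) standardGeneric("signatureParams"))

#' @rdname episignature-accessors
setMethod("signatureProbes", "Episignature", function(x) x@probes)

#' @rdname episignature-accessors
setMethod("signatureDirections", "Episignature", function(x) x@direction)

#' @rdname episignature-accessors
setMethod("signatureParams", "Episignature", function(x) x@params)

#' CellTypeReference accessors and subsetting
#' @param x a [CellTypeReference-class]
#' @name reference-accessors
NULL

#' @rdname reference-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname reference-accessors
setMethod("cellTypes", "CellTypeReference", function(x) x@cellTypes)

#' @rdname reference-accessors
#' @export
setGeneric("referenceProfile", function(x) standardGeneric("referenceProfile"))

#' @rdname reference-accessors
setMethod("referenceProfile", "CellTypeReference", function(x) x@profile)

#' @param i probe ids (character) or indices to keep
#' @param j,drop,... ignored
#' @rdname reference-accessors
#' @export
setMethod("[", "CellTypeReference", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@probes)
  if (anyNA(i)) .dataError("unknown reference probe in subset")
  CellTypeReference(x@probes[i], x@cellTypes, x@profile[i, , drop = FALSE])
})

## --- show methods ----------------------------------------------------------

setMethod("show", "CellTypeReference", function(object) {
  cat(sprintf("CellTypeReference: %d probes x %d cell types (%s)\n",
              length(object@probes), length(object@cellTypes),
              paste(object@cellTypes, collapse = ", ")))
})

setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport: %d probes in, %d retained\n",
              object@nInputProbes, length(object@retainedProbes)))
  for (r in names(object@removed))
    cat(sprintf("  removed (%s): %d\n", r, object@removed[[r]]))
  if (length(object@outlierSamples))
    cat("  outlier samples:", paste(object@outlierSamples, collapse = ", "),
        "\n")
})

setMethod("show", "Episignature", function(object) {
  cat(sprintf("Episignature: %d probes (%d hyper, %d hypo in cases)\n",
              length(object@probes), sum(object@direction == 1L),
              sum(object@direction == -1L)))
  p <- object@params
  cat(sprintf("  selection: top %s by rank score, top %s by AUROC, r > %s pruned\n",
              p$nRank, p$nAuroc, p$corrThreshold))
})

setMethod("show", "MvpModel", function(object) {
  cat(sprintf("MvpModel: linear SVM on %d signature probes, MVP cut-off %.2f\n",
              length(object@probes), object@cutoff))
})
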