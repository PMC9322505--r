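## Region-level analysis: significance-based DMR detection (positional
## probe runs, mean methylation difference, Fisher's combined probability
## with Benjamini-Hochberg correction across candidate regions) and the
## ad-hoc adjacency rule over selected signature probes.

#' Fisher's combined probability test
#'
#' \eqn{X^2 = -2 \sum \ln p_i} referred to the chi-squared distribution on
#' 2k degrees of freedom.
#'
#' @param p vector of per-probe p-values in (0, 1]
#' @return list: `statistic`, `df`, `p_value`
#' @examples
#' fisherCombinedP(c(0.1, 0.1, 0.1))$p_value   # ~0.0319
#' @export
fisherCombinedP <- function(p) {
  if (any(p <= 0 | p > 1)) .dataError("p-values must lie in (0, 1]")
  x2 <- -2 * sum(log(p))
  k <- length(p)
  list(statistic = x2, df = 2L * k,
       p_value = stats::pchisq(x2, df = 2L * k, lower.tail = FALSE))
}

## Join a dmp table with manifest coordinates, sorted by (chrom, pos).
.locateProbes <- function(dmp, manifest) {
  missing <- setdiff(dmp$probe_id, manifest$probe_id)
  if (length(missing))
    .dataError(sprintf("probe(s) not located in manifest: %s",
                       paste(utils::head(missing, 5), collapse = ", ")))
  man <- manifest[match(dmp$probe_id, manifest$probe_id), ]
  if (any(is.na(man$chrom)) || any(!nzchar(man$chrom)))
    .dataError("manifest chromosome vocabulary contains empty values")
  df <- cbind(dmp, chrom = man$chrom, pos = man$pos)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

## Group positionally sorted probes of one chromosome into runs.
## chain = TRUE: break where the gap to the previous probe exceeds window.
## chain = FALSE: greedy maximal blocks with total span <= window.
.positionRuns <- function(pos, window, chain = TRUE) {
  n <- length(pos)
  if (chain) {
    brk <- c(FALSE, diff(pos) > window)
    cumsum(brk)
  } else {
    run <- integer(n); id <- 0L; start <- 1L
    for (i in seq_len(n)) {
      if (pos[i] - pos[start] > window) { id <- id + 1L; start <- i }
      run[i] <- id
    }
    run
  }
}

#' Detect differentially methylated regions
#'
#' Probes are sorted per chromosome by position and chained into candidate
#' regions wherever consecutive inter-probe gaps are at most `window` bp
#' (set `chain = FALSE` for the total-span variant). Candidates need at
#' least `minCpgs` probes and an absolute mean delta-beta of at least
#' `minDelta` (`perProbeDelta = TRUE` demands it of every probe). Each
#' candidate's per-probe p-values are combined by Fisher's method, the
#' combined p-values are Benjamini-Hochberg adjusted across candidates, and
#' regions with adjusted p below `alpha` are returned.
#'
#' @param dmp data frame from [buildDmpTable()]
#' @param manifest probe manifest locating every dmp probe
#' @param minCpgs minimum probes per region (default 3)
#' @param window maximum gap (or span) in bp (default 1000)
#' @param minDelta minimum |mean delta-beta| (default 0.05)
#' @param alpha adjusted-p threshold (default 0.01)
#' @param chain gap-chaining (default) vs total-span grouping
#' @param perProbeDelta require `minDelta` per probe rather than on the mean
#' @return a [GenomicRanges::GRanges-class] of significant regions with
#'   metadata columns `probe_ids` (comma-separated), `n_probes`,
#'   `mean_delta_beta`, `p_fisher`, `p_adj`, `direction_consistent`
#' @export
findDmrs <- function(dmp, manifest, minCpgs = 3L, window = 1000L,
                     minDelta = 0.05, alpha = 0.01, chain = TRUE,
                     perProbeDelta = FALSE) {
  df <- .locateProbes(dmp, manifest)
  cand <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    runs <- .positionRuns(sub$pos, window, chain)
    for (g in split(seq_len(nrow(sub)), runs)) {
      if (length(g) < minCpgs) next
      block <- sub[g, , drop = FALSE]
      meanDelta <- mean(block$delta_beta)
      passDelta <- if (perProbeDelta) all(abs(block$delta_beta) >= minDelta)
                   else abs(meanDelta) >= minDelta
      if (!passDelta) next
      fish <- fisherCombinedP(pmax(block$p_value, 1e-300))
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch, start = min(block$pos), end = max(block$pos),
        probe_ids = paste(block$probe_id, collapse = ","),
        n_probes = nrow(block), mean_delta_beta = meanDelta,
        p_fisher = fish$p_value,
        direction_consistent = length(unique(sign(block$delta_beta))) == 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(.emptyDmrGRanges())
  tab <- do.call(rbind, cand)
  tab$p_adj <- stats::p.adjust(tab$p_fisher, method = "BH")
  tab <- tab[tab$p_adj < alpha, , drop = FALSE]
  .dmrGRanges(tab)
}

.emptyDmrGRanges <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(probe_ids = character(0), n_probes = integer(0),
                         mean_delta_beta = numeric(0),
                         p_fisher = numeric(0), p_adj = numeric(0),
                         direction_consistent = logical(0))
  gr
}

.dmrGRanges <- function(tab) {
  if (!nrow(tab)) return(.emptyDmrGRanges())
  gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
  mcols(gr) <- DataFrame(probe_ids = tab$probe_ids, n_probes = tab$n_probes,
                         mean_delta_beta = tab$mean_delta_beta,
                         p_fisher = if ("p_fisher" %in% names(tab))
                           tab$p_fisher else NA_real_,
                         p_adj = if ("p_adj" %in% names(tab))
                           tab$p_adj else NA_real_,
                         direction_consistent = tab$direction_consistent)
  gr
}

#' Signature-probe adjacency regions
#'
#' The descriptive rule applied to the selected episignature probes only:
#' runs of more than two signature probes in direct vicinity (consecutive
#' gaps at most `window` bp) with an identical delta-beta sign are reported;
#' no significance test is performed.
#'
#' @param signature an [Episignature-class]
#' @param dmp data frame providing `delta_beta` per probe
#' @param manifest probe manifest locating the signature probes
#' @param window maximum consecutive gap in bp (default 1000)
#' @return a [GenomicRanges::GRanges-class] with `probe_ids`, `n_probes`,
#'   `mean_delta_beta`, `direction_consistent` (always TRUE by construction)
#' @export
findSignatureRegions <- function(signature, dmp, manifest, window = 1000L) {
  probes <- signatureProbes(signature)
  df <- .locateProbes(dmp[dmp$probe_id %in% probes, , drop = FALSE],
                      manifest)
  cand <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    ## break runs on distance or on a change of effect direction
    brk <- c(FALSE, diff(sub$pos) > window |
               diff(sign(sub$delta_beta)) != 0)
    for (g in split(seq_len(nrow(sub)), cumsum(brk))) {
      if (length(g) < 3L) next            # ">2 probes in direct vicinity"
      block <- sub[g, , drop = FALSE]
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch, start = min(block$pos), end = max(block$pos),
        probe_ids = paste(block$probe_id, collapse = ","),
        n_probes = nrow(block), mean_delta_beta = mean(block$delta_beta),
        direction_consistent = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(.emptyDmrGRanges())
  .dmrGRanges(do.call(rbind, cand))
}

#' Write DMRs as BED plus a statistics TSV
#'
#' BED is 0-based half-open (converted from the internal 1-based inclusive
#' coordinates); the TSV keeps the full statistics.
#'
#' @param dmrs a GRanges from [findDmrs()] or [findSignatureRegions()]
#' @param bedFile,tsvFile output paths (either may be NULL to skip)
#' @param provenance optional provenance comment lines for the TSV
#' @export
writeDmrs <- function(dmrs, bedFile = NULL, tsvFile = NULL,
                      provenance = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(dmrs)),
                   start = GenomicRanges::start(dmrs),
                   end = GenomicRanges::end(dmrs),
                   as.data.frame(mcols(dmrs)),
                   stringsAsFactors = FALSE)
  if (!is.null(bedFile)) {
    bed <- data.frame(df$chrom, df$start - 1L, df$end,
                      sprintf("dmr_%d", seq_len(nrow(df))),
                      ifelse(is.na(df$p_adj), 0,
                             round(pmin(1000, -10 * log10(pmax(df$p_adj,
                                                               1e-100))))))
    utils::write.table(bed, bedFile, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsvFile)) .writeTableFile(df, tsvFile, "\t", provenance)
  invisible(df)
}
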