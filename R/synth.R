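## Synthetic cohort generator. Emulates the statistical structure the
## downstream analysis assumes: a small case group against a larger matched
## control pool, beta values composed as mixtures of blood cell-type
## reference profiles with Dirichlet-drawn proportions, batch offsets and
## Gaussian noise on the logit scale, a planted set of differentially
## methylated probes with randomised direction, VUS-like samples drawn from
## the control model, and confounder cohorts from other disorders each with
## its own disjoint planted probe set.

#' Configuration of a synthetic methylation cohort
#'
#' Default values define the study conditions emulated throughout the
#' package: 8 cases against controls at a 7:1 matching ratio, 20,000 probes
#' of which 300 carry a planted case effect of 1.5 on the logit(beta) scale,
#' six blood cell types, and three VUS-like samples carrying no signature.
#'
#' @param nProbes total number of probes.
#' @param nCases number of discovery cases.
#' @param controlRatio controls selected per case by matching.
#' @param nControls size of the generated control pool; defaults to
#'   `nCases * controlRatio` (a pool exactly consumed by matching). Larger
#'   pools leave unmatched controls for classifier training.
#' @param nSignatureProbes number of planted differentially methylated probes.
#' @param effectLogit mean case shift at signature probes on the logit(beta)
#'   scale; the sign is randomised per probe and recorded in the truth. May
#'   be 0 for null cohorts.
#' @param noiseSd within-group logit-scale standard deviation.
#' @param nCellTypes number of blood cell types in the generating reference.
#' @param batchCount number of processing batches.
#' @param nVusLike samples drawn from the control model but labelled
#'   `group = "test"` (variants of uncertain significance analogue).
#' @param nOtherDisorders number of confounder disorders (see
#'   [simulateConfounders()]).
#' @param samplesPerDisorder samples per confounder disorder.
#' @param probesPerDisorder size of each disorder's planted probe set,
#'   disjoint from the main signature and from each other.
#' @param nReferenceProbes probes exposed in the cell-type reference panel.
#' @param fracAllosomal,fracSnp,fracCrossreactive fraction of probes flagged
#'   for QC exclusion (flags never hit signature/reference/disorder probes so
#'   the planted structure survives QC by design).
#' @param fracDetpFail per-(probe, sample) probability of an injected
#'   detection failure (p drawn above 0.01).
#' @param batchSd per-(batch, probe) logit-scale offset SD.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return a validated list of class `CohortConfig`
#' @export
cohortConfig <- function(nProbes = 20000L, nCases = 8L, controlRatio = 7L,
                         nControls = NULL, nSignatureProbes = 300L,
                         effectLogit = 1.5, noiseSd = 0.3, nCellTypes = 6L,
                         batchCount = 4L, nVusLike = 3L,
                         nOtherDisorders = 8L, samplesPerDisorder = 8L,
                         probesPerDisorder = 100L, nReferenceProbes = 300L,
                         fracAllosomal = 0.03, fracSnp = 0.02,
                         fracCrossreactive = 0.01, fracDetpFail = 1e-4,
                         batchSd = 0.15, seed = 1L) {
  cfg <- list(nProbes = .stopifnotScalarCount(nProbes, "nProbes", 1L),
              nCases = .stopifnotScalarCount(nCases, "nCases"),
              controlRatio = .stopifnotScalarCount(controlRatio,
                                                   "controlRatio", 1L),
              nControls = if (is.null(nControls)) NULL else
                .stopifnotScalarCount(nControls, "nControls"),
              nSignatureProbes = .stopifnotScalarCount(nSignatureProbes,
                                                       "nSignatureProbes"),
              effectLogit = effectLogit, noiseSd = noiseSd,
              nCellTypes = .stopifnotScalarCount(nCellTypes, "nCellTypes", 1L),
              batchCount = .stopifnotScalarCount(batchCount, "batchCount", 1L),
              nVusLike = .stopifnotScalarCount(nVusLike, "nVusLike"),
              nOtherDisorders = .stopifnotScalarCount(nOtherDisorders,
                                                      "nOtherDisorders"),
              samplesPerDisorder = .stopifnotScalarCount(samplesPerDisorder,
                                                         "samplesPerDisorder"),
              probesPerDisorder = .stopifnotScalarCount(probesPerDisorder,
                                                        "probesPerDisorder"),
              nReferenceProbes = .stopifnotScalarCount(nReferenceProbes,
                                                       "nReferenceProbes",
                                                       1L),
              fracAllosomal = fracAllosomal, fracSnp = fracSnp,
              fracCrossreactive = fracCrossreactive,
              fracDetpFail = fracDetpFail, batchSd = batchSd,
              seed = .stopifnotScalarCount(seed, "seed"))
  if (is.null(cfg$nControls))
    cfg$nControls <- cfg$nCases * cfg$controlRatio
  if (!is.numeric(effectLogit) || length(effectLogit) != 1L || effectLogit < 0)
    .configError("'effectLogit' must be a single value >= 0", "effectLogit")
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
    .configError("'noiseSd' must be a single value >= 0", "noiseSd")
  if (cfg$nSignatureProbes >= cfg$nProbes)
    .configError("'nSignatureProbes' must be smaller than 'nProbes'",
                 "nSignatureProbes")
  for (f in c("fracAllosomal", "fracSnp", "fracCrossreactive",
              "fracDetpFail")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      .configError(sprintf("'%s' must be a probability", f), f)
  }
  structure(cfg, class = "CohortConfig")
}

## Dirichlet draws via normalised gammas.
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sw <- rowSums(g)
  ## degenerate all-zero rows cannot occur for alpha >= 1 in practice
  g / sw
}

## Deterministic "world" shared by the main and confounder cohorts: probe
## manifest, baseline means, cell-type profiles, batch offsets, planted sets.
.cohortWorld <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$nProbes

  ## chromosome / position layout: mixture of tight CpG-island-like gaps and
  ## long intergenic gaps, so positional adjacency exists but is sparse
  chroms <- sort(sample(paste0("chr", 1:22), n, replace = TRUE))
  pos <- integer(n)
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    gaps <- ifelse(stats::runif(length(idx)) < 0.12,
                   sample(50:400, length(idx), replace = TRUE),
                   round(stats::rexp(length(idx), rate = 1 / 5e4)) + 1000)
    pos[idx] <- 1L + cumsum(as.integer(gaps))
  }
  ids <- sprintf("cg%08d", seq_len(n))

  ## bimodal baseline: array probes concentrate near beta 0.1 and 0.9
  comp <- stats::runif(n) < 0.5
  mu <- ifelse(comp, stats::rnorm(n, .logit(0.1), 0.8),
               stats::rnorm(n, .logit(0.9), 0.8))

  ## cell-type profiles: strong divergence at the reference panel probes,
  ## mild divergence elsewhere (residual cell-composition signal)
  k <- cfg$nCellTypes
  refIdx <- sample.int(n, cfg$nReferenceProbes)
  delta <- matrix(stats::rnorm(n * k, 0, 0.15), n, k)
  delta[refIdx, ] <- stats::rnorm(length(refIdx) * k, 0, 1.2)
  profile <- .expit(matrix(mu, n, k) + delta)
  cellNames <- c("CD4T", "CD8T", "NK", "Mono", "Gran", "Bcell")
  cellNames <- if (k <= 6L) cellNames[seq_len(k)] else
    c(cellNames, sprintf("Cell%d", seq_len(k - 6L)))
  dimnames(profile) <- list(ids, cellNames)

  ## planted sets: main signature, then one disjoint set per disorder
  free <- setdiff(seq_len(n), refIdx)
  need <- cfg$nSignatureProbes + cfg$nOtherDisorders * cfg$probesPerDisorder
  if (need > length(free))
    .configError(sprintf(
      "requested disjoint planted sets (%d probes) exceed available probes (%d)",
      need, length(free)), "probesPerDisorder")
  planted <- sample(free, need)
  sigIdx <- planted[seq_len(cfg$nSignatureProbes)]
  disorderIdx <- if (cfg$nOtherDisorders > 0L)
    split(planted[-seq_len(cfg$nSignatureProbes)],
          rep(seq_len(cfg$nOtherDisorders), each = cfg$probesPerDisorder))
  else list()
  sigDirection <- sample(c(-1L, 1L), length(sigIdx), replace = TRUE)

  ## QC exclusion flags never touch planted or reference probes
  flagPool <- setdiff(free, planted)
  isAllosomal <- isSnp <- isCross <- logical(n)
  pick <- function(frac) sample(flagPool, min(length(flagPool),
                                              round(frac * n)))
  isAllosomal[pick(cfg$fracAllosomal)] <- TRUE
  isSnp[pick(cfg$fracSnp)] <- TRUE
  isCross[pick(cfg$fracCrossreactive)] <- TRUE
  chroms[isAllosomal] <- sample(c("chrX", "chrY"), sum(isAllosomal),
                                replace = TRUE, prob = c(0.9, 0.1))

  batchOffsets <- matrix(stats::rnorm(n * cfg$batchCount, 0, cfg$batchSd),
                         n, cfg$batchCount)

  manifest <- data.frame(probe_id = ids, chrom = chroms, pos = pos,
                         is_allosomal = isAllosomal, is_snp = isSnp,
                         is_crossreactive = isCross,
                         stringsAsFactors = FALSE)
  list(manifest = manifest, mu = mu, profile = profile,
       refIdx = refIdx, sigIdx = sigIdx, sigDirection = sigDirection,
       disorderIdx = disorderIdx, batchOffsets = batchOffsets,
       ## Dirichlet concentration: typical adult blood composition
       alpha = c(4.5, 2.4, 1.5, 2.4, 18, 1.2)[
         rep_len(seq_len(6), cfg$nCellTypes)])
}

## Draw demographics mirroring the emulated control cohort (ages 2-50,
## skewed young, ~46% female).
.drawDemographics <- function(n, batchCount, arrayEpicFrac = 1) {
  data.frame(
    age = pmax(2, pmin(50, round(stats::rgamma(n, shape = 2.2,
                                               rate = 0.11)))),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.46, 0.54)),
    batch = sample.int(batchCount, n, replace = TRUE),
    array_type = ifelse(stats::runif(n) < arrayEpicFrac, "EPIC", "450k"),
    stringsAsFactors = FALSE)
}

## Compose beta for a block of samples: cell-type mixture, batch offset,
## optional per-probe logit shift for "affected" columns, Gaussian noise.
.composeBeta <- function(world, w, batch, shiftIdx = integer(0),
                         shiftValue = numeric(0), affected = logical(nrow(w)),
                         noiseSd) {
  base <- world$profile %*% t(w)                       # probes x samples
  eta <- .logit(.clampBeta(base))
  eta <- eta + world$batchOffsets[, batch, drop = FALSE]
  if (length(shiftIdx) && any(affected))
    eta[shiftIdx, affected] <- eta[shiftIdx, affected] + shiftValue
  eta <- eta + matrix(stats::rnorm(length(eta), 0, noiseSd), nrow(eta))
  .clampBeta(.expit(eta))
}

.makeDetp <- function(dim, fracFail) {
  p <- matrix(stats::runif(prod(dim), 0, 0.005), dim[1], dim[2])
  fail <- stats::runif(length(p)) < fracFail
  p[fail] <- stats::runif(sum(fail), 0.011, 0.5)
  p
}

#' Generate the main synthetic cohort
#'
#' Produces a [MethylExperiment-class] with `nCases` case samples, a control
#' pool, and VUS-like samples drawn from the control model but labelled
#' `group = "test"`. Cases carry a `effectLogit` shift at the planted
#' signature probes (sign randomised per probe). The generating truth —
#' signature probe ids and directions, true cell proportions, the cell-type
#' reference — is stored in `metadata()`.
#'
#' @param config a [cohortConfig()] list
#' @return a [MethylExperiment-class]; `metadata(x)$truth` holds
#'   `signature_probes`, `direction`, `cell_proportions`;
#'   `metadata(x)$reference` the [CellTypeReference-class].
#' @examples
#' cohort <- simulateCohort(cohortConfig(nProbes = 2000, seed = 7))
#' table(sampleSheet(cohort)$group)
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "CohortConfig")) config <- do.call(cohortConfig, config)
  world <- .cohortWorld(config)
  set.seed(config$seed + 1L)

  nC <- config$nCases; nK <- config$nControls; nV <- config$nVusLike
  n <- nC + nK + nV
  groups <- c(rep("case", nC), rep("control", nK), rep("test", nV))
  ids <- c(sprintf("case%02d", seq_len(nC)),
           sprintf("ctrl%03d", seq_len(nK)),
           sprintf("vus%02d", seq_len(nV)))

  demo <- .drawDemographics(n, config$batchCount,
                            arrayEpicFrac = 0.85)
  demo$array_type[groups != "control"] <- "EPIC"   # study samples on EPIC

  w <- .rdirichlet(n, world$alpha)
  colnames(w) <- colnames(world$profile); rownames(w) <- ids
  beta <- .composeBeta(world, w, demo$batch,
                       shiftIdx = world$sigIdx,
                       shiftValue = world$sigDirection * config$effectLogit,
                       affected = groups == "case",
                       noiseSd = config$noiseSd)
  dimnames(beta) <- list(world$manifest$probe_id, ids)
  detp <- .makeDetp(dim(beta), config$fracDetpFail)

  samples <- data.frame(sample_id = ids, group = groups,
                        disorder = NA_character_, demo,
                        stringsAsFactors = FALSE)
  sigIds <- world$manifest$probe_id[world$sigIdx]
  reference <- CellTypeReference(world$manifest$probe_id[world$refIdx],
                                 colnames(world$profile),
                                 world$profile[world$refIdx, , drop = FALSE])
  truth <- list(signature_probes = sigIds,
                direction = stats::setNames(world$sigDirection, sigIds),
                cell_proportions = w)
  MethylExperiment(beta, world$manifest, samples, detp = detp,
                   metadata = list(truth = truth, reference = reference,
                                   config = unclass(config)))
}

#' Generate confounder cohorts from other disorders
#'
#' Each of `nOtherDisorders` disorders receives its own planted probe set,
#' disjoint from the main signature and from every other disorder's set, and
#' `samplesPerDisorder` affected samples. Probes, manifest and cell-type
#' reference are identical to the [simulateCohort()] output for the same
#' config, so the two objects can be combined with [combineCohorts()].
#'
#' @param config a [cohortConfig()] list with `nOtherDisorders >= 1`
#' @return a [MethylExperiment-class]; `metadata(x)$truth$disorder_probes`
#'   holds the per-disorder planted sets.
#' @export
simulateConfounders <- function(config) {
  if (!inherits(config, "CohortConfig")) config <- do.call(cohortConfig, config)
  if (config$nOtherDisorders < 1L)
    .configError("'nOtherDisorders' must be >= 1", "nOtherDisorders")
  world <- .cohortWorld(config)
  set.seed(config$seed + 2L)

  nd <- config$nOtherDisorders; m <- config$samplesPerDisorder
  n <- nd * m
  disorder <- rep(sprintf("D%02d", seq_len(nd)), each = m)
  ids <- sprintf("%s_s%02d", disorder, rep(seq_len(m), nd))

  demo <- .drawDemographics(n, config$batchCount, arrayEpicFrac = 1)
  w <- .rdirichlet(n, world$alpha)
  colnames(w) <- colnames(world$profile); rownames(w) <- ids

  ## compose per disorder so each block gets its own planted shift
  beta <- matrix(0, config$nProbes, n)
  for (d in seq_len(nd)) {
    cols <- which(disorder == sprintf("D%02d", d))
    idx <- world$disorderIdx[[d]]
    dir <- sample(c(-1L, 1L), length(idx), replace = TRUE)
    beta[, cols] <- .composeBeta(world, w[cols, , drop = FALSE],
                                 demo$batch[cols], shiftIdx = idx,
                                 shiftValue = dir * config$effectLogit,
                                 affected = rep(TRUE, length(cols)),
                                 noiseSd = config$noiseSd)
  }
  dimnames(beta) <- list(world$manifest$probe_id, ids)
  detp <- .makeDetp(dim(beta), config$fracDetpFail)

  samples <- data.frame(sample_id = ids, group = "disorder",
                        disorder = disorder, demo, stringsAsFactors = FALSE)
  dsets <- lapply(world$disorderIdx, function(i) world$manifest$probe_id[i])
  names(dsets) <- sprintf("D%02d", seq_len(nd))
  reference <- CellTypeReference(world$manifest$probe_id[world$refIdx],
                                 colnames(world$profile),
                                 world$profile[world$refIdx, , drop = FALSE])
  truth <- list(disorder_probes = dsets, cell_proportions = w,
                signature_probes = world$manifest$probe_id[world$sigIdx])
  MethylExperiment(beta, world$manifest, samples, detp = detp,
                   metadata = list(truth = truth, reference = reference,
                                   config = unclass(config)))
}

#' Combine two cohorts sharing the same probes
#'
#' Column-binds two [MethylExperiment-class] objects generated from the same
#' config (e.g. main cohort and confounders), merging their truth metadata.
#'
#' @param x,y MethylExperiment objects with identical probes
#' @return a combined [MethylExperiment-class]
#' @export
combineCohorts <- function(x, y) {
  if (!identical(rownames(x), rownames(y)))
    .dataError("cohorts must share an identical probe set")
  mx <- metadata(x); my <- metadata(y)
  combined <- BiocGenerics::cbind(as(x, "RangedSummarizedExperiment"),
                                  as(y, "RangedSummarizedExperiment"))
  truth <- mx$truth
  truth$disorder_probes <- my$truth$disorder_probes
  truth$cell_proportions <- rbind(mx$truth$cell_proportions,
                                  my$truth$cell_proportions)
  metadata(combined) <- list(truth = truth, reference = mx$reference,
                             config = mx$config)
  new("MethylExperiment", combined)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `beta.tsv`, `detp.tsv`, `manifest.tsv`, `samples.csv`,
#' `reference.tsv` and `truth.json` under `dir`, in the dialects accepted by
#' the corresponding readers.
#'
#' @param cohort a [MethylExperiment-class] from the simulator
#' @param dir output directory (created if needed)
#' @param provenance optional named list stamped as comment headers
#' @return `dir`, invisibly
#' @export
writeCohort <- function(cohort, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTsv(betaValues(cohort), file.path(dir, "beta.tsv"),
                 provenance = provenance)
  writeMatrixTsv(detpValues(cohort), file.path(dir, "detp.tsv"),
                 provenance = provenance)
  writeProbeManifest(probeManifest(cohort), file.path(dir, "manifest.tsv"),
                     provenance = provenance)
  writeSampleSheet(sampleSheet(cohort), file.path(dir, "samples.csv"),
                   provenance = provenance)
  ref <- metadata(cohort)$reference
  if (!is.null(ref))
    writeMatrixTsv(referenceProfile(ref), file.path(dir, "reference.tsv"),
                   provenance = provenance)
  truth <- metadata(cohort)$truth
  if (!is.null(truth)) {
    truth$cell_proportions <- as.data.frame(truth$cell_proportions)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cell-type reference panel from TSV
#' @param file TSV with probe ids in the first column, one column per cell type
#' @return a [CellTypeReference-class]
#' @export
readCellTypeReference <- function(file) {
  m <- readMatrixTsv(file)
  CellTypeReference(rownames(m), colnames(m), m)
}
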