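## Shared fixtures, built in code and memoised across test files so the
## expensive default-scale discovery run happens once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## A small cohort for unit-level tests: fast, but with every structural
## feature (planted signature, confounders, flags, detection failures).
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nProbes = 2000L, nControls = 80L,
                   nSignatureProbes = 80L, nOtherDisorders = 3L,
                   samplesPerDisorder = 5L, probesPerDisorder = 40L,
                   nReferenceProbes = 120L, seed = 42L)
  do.call(cohortConfig, utils::modifyList(defaults, args))
}

smallCohort <- function() memo("smallCohort", simulateCohort(smallConfig()))

## The default-condition discovery analysis (20,000 probes, 8 cases,
## 7:1 matching against a 120-control pool, 8 confounder disorders),
## seed 1, run end to end through the pipeline orchestrator.
defaultDiscovery <- function() memo("defaultDiscovery", {
  out <- file.path(tempdir(), "episig-default-run")
  runDiscovery(list(seed = 1L, cohort = list(nControls = 120L)),
               outDir = out)
})

## A tiny deterministic manifest builder for DMR tests.
toyManifest <- function(pos, chrom = "chr1", ids = NULL) {
  ids <- ids %||% sprintf("p%02d", seq_along(pos))
  data.frame(probe_id = ids, chrom = chrom, pos = pos,
             is_allosomal = FALSE, is_snp = FALSE,
             is_crossreactive = FALSE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
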