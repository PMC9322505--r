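## End-to-end orchestration: qc -> deconvolution -> differential
## methylation -> feature selection -> unsupervised validation -> classifier
## training and scoring -> DMR detection, with provenance-stamped artifacts
## and a content-hash manifest for reproducibility checks.

.pkgVersion <- function()
  as.character(utils::packageVersion("episig"))

#' Run the full discovery pipeline
#'
#' Executes every stage on either a synthetic cohort (default; generated
#' from the `cohort` section of the config together with confounder
#' disorders) or user-supplied input files (`inputs` section with paths
#' `beta`, `detp`, `manifest`, `samples`, `reference`). Each artifact is
#' written under `out_dir` with a provenance header; a final
#' `manifest.json` lists every output with its MD5 content hash, so an
#' identical config and seed reproduce identical hashes. On a stage
#' failure, artifacts already produced are retained with a `.partial`
#' suffix and the error names the failing stage.
#'
#' @param config path to a YAML file or an equivalent named list. Recognised
#'   sections: `seed`, `out_dir`, `cohort` (see [cohortConfig()]),
#'   `inputs`, `qc` (`detpAlpha`, `excludeOutliers`), `matching` (`ratio`),
#'   `selection` (see [selectionParams()]), `classifier` (`trainFraction`,
#'   `cost`, `cutoff`), `dmr` (`minCpgs`, `window`, `minDelta`, `alpha`),
#'   `loocv` (logical, default TRUE).
#' @param outDir overrides `config$out_dir`
#' @return invisibly, a list with the in-memory stage results and the
#'   artifact manifest
#' @export
runDiscovery <- function(config, outDir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      .configError(sprintf("config file not found: %s", config), "config")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .configError("config must be a list or a YAML path",
                                     "config")
  outDir <- outDir %||% config$out_dir
  if (is.null(outDir))
    .configError("output directory missing", "out_dir")
  seed <- config$seed %||% 1L
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ## hash the scientific configuration only, not output locations
  configHash <- .contentHash(config[setdiff(names(config), "out_dir")])
  prov <- list(tool = "episig", version = .pkgVersion(),
               config_hash = configHash, seed = seed)
  artifacts <- character(0)
  logCon <- file(file.path(outDir, "log.jsonl"), "w")
  on.exit(close(logCon), add = TRUE)
  stageLog <- function(stage, status, secs = NA) {
    writeLines(jsonlite::toJSON(list(stage = stage, status = status,
                                     elapsed_s = round(secs, 3),
                                     seed = seed), auto_unbox = TRUE,
                                digits = NA), logCon)
  }
  emit <- function(name, writer) {
    path <- file.path(outDir, paste0(name, ".partial"))
    writer(path)
    artifacts <<- c(artifacts, name)
    invisible(path)
  }
  runStage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stageLog(stage, "failed", proc.time()[["elapsed"]] - t0)
      stop(structure(class = c("episig_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", stage,
                                            conditionMessage(e)),
                          call = NULL)))
    })
    secs <- proc.time()[["elapsed"]] - t0
    stageLog(stage, "ok", secs)
    message(sprintf("[episig] %-10s %.1fs", stage, secs))
    res
  }

  ## --- input acquisition ---------------------------------------------------
  world <- runStage("input", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      for (f in c("beta", "detp", "manifest", "samples", "reference")) {
        if (is.null(inp[[f]]))
          .configError("input path missing", paste0("inputs.", f))
        if (!file.exists(inp[[f]]))
          .configError(sprintf("input file not found: %s", inp[[f]]),
                       paste0("inputs.", f))
      }
      beta <- readMatrixTsv(inp$beta)
      cohort <- MethylExperiment(beta, readProbeManifest(inp$manifest),
                                 readSampleSheet(inp$samples),
                                 detp = readMatrixTsv(inp$detp))
      metadata(cohort)$reference <- readCellTypeReference(inp$reference)
      cohort
    } else {
      cc <- do.call(cohortConfig, c(config$cohort %||% list(),
                                    list(seed = seed)))
      main <- simulateCohort(cc)
      if (cc$nOtherDisorders > 0L)
        combineCohorts(main, simulateConfounders(cc)) else main
    }
  })

  ## --- qc -------------------------------------------------------------------
  qcCfg <- config$qc %||% list()
  qc <- runStage("qc", {
    res <- filterProbes(world, detpAlpha = qcCfg$detpAlpha %||% 0.01)
    res$report@outlierSamples <- pcaOutlierScreen(res$object)
    if (isTRUE(qcCfg$excludeOutliers) && length(res$report@outlierSamples)) {
      drop <- setdiff(res$report@outlierSamples,
                      sampleSheet(res$object)$sample_id[
                        sampleSheet(res$object)$group == "case"])
      res$object <- res$object[, !colnames(res$object) %in% drop]
    }
    emit("qc_report.json", function(p) jsonlite::write_json(
      list(provenance = prov, n_input_probes = res$report@nInputProbes,
           removed = as.list(res$report@removed),
           n_retained = length(res$report@retainedProbes),
           outlier_samples = res$report@outlierSamples),
      p, auto_unbox = TRUE, digits = NA))
    res
  })
  cohort <- qc$object
  beta <- betaValues(cohort)
  ss <- sampleSheet(cohort)

  ## --- matched controls ----------------------------------------------------
  ratio <- (config$matching %||% list())$ratio %||% 7L
  matchedIds <- runStage("matching", {
    ids <- selectMatchedControls(ss[ss$group == "case", ],
                                 ss[ss$group == "control", ], ratio = ratio)
    emit("matched_controls.tsv", function(p) .writeTableFile(
      data.frame(sample_id = ids), p, "\t", prov))
    ids
  })
  caseIds <- ss$sample_id[ss$group == "case"]
  otherControlIds <- setdiff(ss$sample_id[ss$group == "control"], matchedIds)

  ## --- cell-type deconvolution ---------------------------------------------
  props <- runStage("deconv", {
    ref <- metadata(cohort)$reference
    if (is.null(ref)) .dataError("no cell-type reference available")
    ref <- ref[intersect(ref@probes, rownames(beta))]
    w <- estimateProportions(beta, ref)
    emit("proportions.csv", function(p) writeProportions(w, p, prov))
    w
  })

  ## --- differential methylation --------------------------------------------
  discovery <- ss[ss$sample_id %in% c(caseIds, matchedIds), ]
  dmp <- runStage("dmp", {
    tab <- buildDmpTable(beta[, discovery$sample_id, drop = FALSE],
                         discovery, props)
    emit("dmp.tsv", function(p) writeDmpTable(tab, p, prov))
    tab
  })

  ## --- feature selection ---------------------------------------------------
  selCfg <- config$selection %||% list()
  signature <- runStage("select", {
    sig <- selectFeatures(dmp, beta[, discovery$sample_id, drop = FALSE],
                          discovery$group, do.call(selectionParams, selCfg),
                          provenance = prov)
    emit("signature.json", function(p) writeEpisignature(sig, p))
    sig
  })

  ## --- unsupervised validation ---------------------------------------------
  validation <- runStage("validate", {
    x <- t(beta[signatureProbes(signature), discovery$sample_id,
                drop = FALSE])
    wc <- wardCluster(x)
    emb <- mdsEmbed(x)
    emit("mds.tsv", function(p) .writeTableFile(
      data.frame(sample_id = rownames(emb), dim1 = emb[, 1],
                 dim2 = if (ncol(emb) > 1) emb[, 2] else 0,
                 group = discovery$group,
                 cluster = wc$clusters[rownames(emb)]), p, "\t", prov))
    folds <- if (isTRUE(config$loocv %||% TRUE))
      runLoocv(beta[, discovery$sample_id, drop = FALSE], discovery, props,
               do.call(selectionParams, selCfg)) else NULL
    if (!is.null(folds))
      emit("loocv.tsv", function(p) .writeTableFile(folds, p, "\t", prov))
    list(ward = wc, mds = emb, loocv = folds)
  })

  ## --- classifier ----------------------------------------------------------
  clsCfg <- config$classifier %||% list()
  disorderIds <- stats::setNames(ss$sample_id[ss$group == "disorder"],
                                 ss$disorder[ss$group == "disorder"])
  fit <- runStage("train", {
    plan <- trainingPlan(caseIds, matchedIds, otherControlIds, disorderIds,
                         trainFraction = clsCfg$trainFraction %||% 0.75,
                         seed = seed)
    f <- trainClassifier(beta, signature, plan,
                         cost = clsCfg$cost %||% 1,
                         cutoff = clsCfg$cutoff %||% 0.5)
    emit("model.json", function(p) writeMvpModel(f$model, p))
    f
  })

  scores <- runStage("score", {
    sc <- scoreSamples(fit$model, beta)
    sc$membership <- ifelse(sc$sample_id %in% fit$train_ids, "training",
                     ifelse(sc$sample_id %in% fit$test_ids, "testing",
                            "supplementary"))
    sc$group <- ss$group[match(sc$sample_id, ss$sample_id)]
    emit("mvp_scores.tsv", function(p) .writeTableFile(sc, p, "\t", prov))
    sc
  })

  ## --- DMR detection -------------------------------------------------------
  dmrCfg <- config$dmr %||% list()
  dmrs <- runStage("dmr", {
    man <- probeManifest(cohort)
    sig.. <- findDmrs(dmp, man, minCpgs = dmrCfg$minCpgs %||% 3L,
                      window = dmrCfg$window %||% 1000L,
                      minDelta = dmrCfg$minDelta %||% 0.05,
                      alpha = dmrCfg$alpha %||% 0.01)
    sregs <- findSignatureRegions(signature, dmp, man,
                                  window = dmrCfg$window %||% 1000L)
    emit("dmrs.tsv", function(p) writeDmrs(sig.., tsvFile = p,
                                           provenance = prov))
    emit("dmrs.bed", function(p) writeDmrs(sig.., bedFile = p))
    emit("signature_regions.tsv", function(p) writeDmrs(
      sregs, tsvFile = p, provenance = prov))
    list(significant = sig.., signature_regions = sregs)
  })

  ## --- finalise: promote .partial artifacts, hash, manifest ----------------
  for (name in artifacts)
    file.rename(file.path(outDir, paste0(name, ".partial")),
                file.path(outDir, name))
  hashes <- tools::md5sum(file.path(outDir, artifacts))
  manifest <- list(provenance = prov,
                   artifacts = lapply(seq_along(artifacts), function(i)
                     list(name = artifacts[i], md5 = unname(hashes[i]))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stageLog("manifest", "ok", 0)

  invisible(list(cohort = cohort, qc = qc$report, matched = matchedIds,
                 proportions = props, dmp = dmp, signature = signature,
                 validation = validation, fit = fit, scores = scores,
                 dmrs = dmrs, manifest = manifest, out_dir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
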