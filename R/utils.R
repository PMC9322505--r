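## Shared internal helpers: link functions, conditions, hashing, TSV/CSV I/O
## conventions used by every stage.

#' @importFrom stats plogis qlogis
.logit <- function(p) qlogis(p)

.expit <- function(x) plogis(x)

## Clamp beta values into the open unit interval so that M-values stay finite.
.clampBeta <- function(beta, eps = 1e-6) {
  pmin(pmax(beta, eps), 1 - eps)
}

## Structured conditions; the CLI maps these classes onto exit codes.
.configError <- function(msg, field = NULL, call. = FALSE) {
  stop(structure(
    class = c("episig_config_error", "error", "condition"),
    list(message = if (is.null(field)) msg else
      sprintf("%s [field: %s]", msg, field), call = NULL)
  ))
}

.dataError <- function(msg) {
  stop(structure(
    class = c("episig_data_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

## MD5 of an arbitrary R object via a temporary file (tools::md5sum is
## file-based); used only for provenance stamps, never for correctness.
.contentHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

.stopifnotScalarCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    .configError(sprintf("'%s' must be a single integer >= %d", name, min),
                 field = name)
  invisible(as.integer(x))
}

## --- plain-text readers/writers -------------------------------------------
## All emitted tables carry '# key: value' provenance comment lines which the
## readers skip.

.provenanceHeader <- function(provenance) {
  if (is.null(provenance)) return(character(0))
  vapply(names(provenance), function(k)
    sprintf("# %s: %s", k, paste(format(provenance[[k]]), collapse = " ")),
    character(1))
}

#' Write a numeric matrix as TSV with row names in the first column
#' @param x matrix with dimnames
#' @param file output path
#' @param idColumn name for the row-identifier column
#' @param provenance named list written as leading comment lines
#' @export
writeMatrixTsv <- function(x, file, idColumn = "probe_id",
                           provenance = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(provenance), con)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a matrix TSV written by [writeMatrixTsv()] (or any TSV whose first
#' column holds row identifiers)
#' @param file input path
#' @return numeric matrix with row and column names
#' @export
readMatrixTsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.writeTableFile <- function(df, file, sep, provenance = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(provenance), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write/read a sample sheet (CSV)
#' @param df data frame of per-sample metadata
#' @param file path
#' @param provenance named list of provenance comment lines
#' @export
writeSampleSheet <- function(df, file, provenance = NULL)
  .writeTableFile(df, file, ",", provenance)

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(file)
  utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)

#' Write/read a probe manifest (TSV)
#' @param df manifest data frame (probe_id, chrom, pos, is_allosomal,
#'   is_snp, is_crossreactive)
#' @param file path
#' @param provenance named list of provenance comment lines
#' @export
writeProbeManifest <- function(df, file, provenance = NULL)
  .writeTableFile(df, file, "\t", provenance)

#' @rdname writeProbeManifest
#' @export
readProbeManifest <- function(file)
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
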