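# Single-file session archive: tar of TSV members plus a JSON manifest.
# A plain-text container was chosen over a binary serialization so other
# languages can unpack a session with standard tools.

ARCHIVE_FORMAT <- "mbkit-session"
ARCHIVE_VERSION <- "1.0"

fmt_cell <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

write_member_tsv <- function(df, path, id_header) {
  out <- data.frame(id = rownames(df), stringsAsFactors = FALSE)
  names(out) <- id_header
  for (nm in colnames(df)) out[[nm]] <- vapply(df[[nm]], fmt_cell, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Save / load a session archive
#'
#' `saveArchive()` bundles the experiment into a single portable tar file
#' holding `counts.tsv`, `metadata.tsv`, optionally `taxonomy.tsv`, and a
#' JSON manifest recording the format version, the rank list, metadata
#' column types and provenance. `loadArchive()` restores the experiment;
#' counts round-trip bit-exactly and metadata value-exactly (numeric
#' columns are serialized at full precision and their types recorded in
#' the manifest).
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param path Archive file path (conventionally `.tar`).
#' @return `saveArchive()`: `path` invisibly. `loadArchive()`: the restored
#'   [MicrobiomeExperiment-class].
#' @export
saveArchive <- function(exp, path) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  stage <- tempfile("mbkit_archive_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  cts <- meCounts(exp)
  cts_df <- as.data.frame(cts)
  rownames(cts_df) <- rownames(cts)
  write_member_tsv(cts_df, file.path(stage, "counts.tsv"), "feature_id")

  md <- sampleData(exp)
  write_member_tsv(md, file.path(stage, "metadata.tsv"), "sample_id")
  md_types <- vapply(md, function(v) class(v)[1L], character(1))

  tax <- taxonomyTable(exp)
  members <- c("manifest.json", "counts.tsv", "metadata.tsv")
  if (!is.null(tax)) {
    write_member_tsv(tax, file.path(stage, "taxonomy.tsv"), "feature_id")
    members <- c(members, "taxonomy.tsv")
  }

  manifest <- list(
    format = ARCHIVE_FORMAT,
    version = ARCHIVE_VERSION,
    ranks = if (is.null(tax)) character() else colnames(tax),
    metadata_columns = as.list(md_types),
    provenance = list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      generated_by = paste0("mbkit ",
                            as.character(utils::packageVersion("mbkit"))),
      n_features = nrow(exp),
      n_samples = ncol(exp)
    )
  )
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                    basename(path))
  oldwd <- setwd(stage)
  on.exit(setwd(oldwd), add = TRUE)
  utils::tar(path, files = members, tar = "internal")
  invisible(path)
}

#' @rdname saveArchive
#' @export
loadArchive <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  stage <- tempfile("mbkit_unarchive_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  utils::untar(path, exdir = stage, tar = "internal")

  man_path <- file.path(stage, "manifest.json")
  if (!file.exists(man_path)) {
    stop_parse(sprintf("%s: archive has no manifest.json", path))
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(manifest$format, ARCHIVE_FORMAT)) {
    stop_parse(sprintf("%s: not a session archive (format '%s')",
                       path, manifest$format %||% "?"))
  }
  major <- sub("\\..*$", "", as.character(manifest$version))
  if (!identical(major, sub("\\..*$", "", ARCHIVE_VERSION))) {
    stop_parse(sprintf(
      "%s: archive version %s is not supported by this package (supports %s.x)",
      path, manifest$version, sub("\\..*$", "", ARCHIVE_VERSION)))
  }

  for (member in c("counts.tsv", "metadata.tsv")) {
    if (!file.exists(file.path(stage, member))) {
      stop_parse(sprintf("%s: corrupted archive, missing member %s",
                         path, member))
    }
  }
  cts <- readCountTable(file.path(stage, "counts.tsv"))

  md_raw <- utils::read.delim(file.path(stage, "metadata.tsv"), sep = "\t",
                              row.names = 1L, check.names = FALSE,
                              colClasses = "character")
  md <- md_raw
  types <- manifest$metadata_columns
  for (nm in colnames(md)) {
    ty <- types[[nm]] %||% "character"
    md[[nm]] <- switch(ty,
                       numeric = as.numeric(md_raw[[nm]]),
                       integer = as.integer(md_raw[[nm]]),
                       logical = as.logical(md_raw[[nm]]),
                       factor = factor(md_raw[[nm]]),
                       md_raw[[nm]])
  }

  tax <- NULL
  if (file.exists(file.path(stage, "taxonomy.tsv"))) {
    tax <- readTaxonomyTable(file.path(stage, "taxonomy.tsv"))
  }
  MicrobiomeExperiment(cts, taxonomy = tax, metadata = md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
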