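# BIOM v1 (JSON) import/export via the biomformat package.

# Map greengenes-style prefixes to canonical ranks; "d__" (domain, SILVA
# style) also maps to superkingdom.
GG_PREFIX <- c(k = "superkingdom", d = "superkingdom", p = "phylum",
               c = "class", o = "order", f = "family", g = "genus",
               s = "species")

# Parse one observation's taxonomy labels (vector of rank-prefixed or bare
# strings) into a named lineage across the canonical ranks.
parse_taxonomy_labels <- function(labels) {
  out <- stats::setNames(rep(NA_character_, length(taxonomyRanks())),
                         taxonomyRanks())
  bare_pos <- 1L
  for (lab in labels) {
    lab <- trimws(lab)
    m <- regmatches(lab, regexec("^([A-Za-z])__(.*)$", lab))[[1L]]
    if (length(m) == 3L) {
      rank <- GG_PREFIX[tolower(m[2L])]
      if (!is.na(rank)) {
        val <- trimws(m[3L])
        out[rank] <- if (nzchar(val)) val else unclassifiedMarker()
      }
    } else if (nzchar(lab)) {
      # Bare labels are assigned positionally along the rank order.
      if (bare_pos <= length(out)) out[bare_pos] <- lab
    }
    bare_pos <- bare_pos + 1L
  }
  out
}

# Pull a taxonomy table out of BIOM observation metadata. Handles both the
# rectangular form (data frame: rank-named columns, or taxonomy1..N columns
# from greengenes-style lists) and the ragged form (a list per observation,
# as returned when lineages have unequal depth).
extract_biom_taxonomy <- function(om, ids) {
  if (is.null(om) || !length(om)) return(NULL)
  one <- function(v) {
    v <- unlist(v)
    if (is.null(v) || !length(v)) {
      return(stats::setNames(rep(NA_character_, length(taxonomyRanks())),
                             taxonomyRanks()))
    }
    nm <- tolower(names(v))
    if (!is.null(names(v)) && all(nm %in% taxonomyRanks())) {
      out <- stats::setNames(rep(NA_character_, length(taxonomyRanks())),
                             taxonomyRanks())
      out[nm] <- as.character(v)
      out
    } else {
      parse_taxonomy_labels(as.character(v))
    }
  }
  lin <- if (is.data.frame(om)) {
    t(vapply(seq_len(nrow(om)), function(i) {
      one(stats::setNames(as.character(unlist(om[i, , drop = TRUE])),
                          colnames(om)))
    }, character(length(taxonomyRanks()))))
  } else {
    t(vapply(ids, function(id) one(om[[id]]),
             character(length(taxonomyRanks()))))
  }
  keep <- colSums(!is.na(lin)) > 0L
  if (!any(keep)) return(NULL)
  tax <- as.data.frame(lin[, keep, drop = FALSE], stringsAsFactors = FALSE)
  rownames(tax) <- ids
  tax
}

# Re-coerce character columns that are entirely numeric back to numeric
# (BIOM JSON metadata values arrive as strings).
autotype_columns <- function(df) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num[!is.na(v) & nzchar(v)]) && any(!is.na(num))) {
        df[[j]] <- num
      }
    }
  }
  df
}

#' Read a BIOM file into a MicrobiomeExperiment
#'
#' Supports BIOM v1 (JSON), dense or sparse, via the biomformat package
#' (v2 HDF5 files are read when biomformat's HDF5 backend can handle
#' them). Observation metadata named after taxonomy ranks, or a
#' greengenes-style `taxonomy` list (`"k__Bacteria"`, ...), is parsed into
#' the taxonomy table; sample metadata becomes covariates.
#'
#' @param path Path to a `.biom` file.
#' @return A [MicrobiomeExperiment-class].
#' @export
readBiom <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  b <- tryCatch(biomformat::read_biom(path),
                error = function(e) stop_parse(sprintf(
                  "failed to parse BIOM file %s: %s", path, conditionMessage(e))))
  m <- as(biomformat::biom_data(b), "matrix")
  storage.mode(m) <- "double"

  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  tax <- extract_biom_taxonomy(om, rownames(m))

  sm <- tryCatch(biomformat::sample_metadata(b), error = function(e) NULL)
  md <- if (is.null(sm)) {
    data.frame(row.names = colnames(m))
  } else {
    autotype_columns(as.data.frame(sm, stringsAsFactors = FALSE))
  }
  MicrobiomeExperiment(m, taxonomy = tax, metadata = md)
}

#' Write a MicrobiomeExperiment as BIOM v1 (JSON, sparse)
#'
#' Taxonomy ranks are written as named observation-metadata fields and
#' sample covariates as named sample-metadata fields, so
#' `readBiom(writeBiom(exp))` reproduces counts, ids and taxonomy exactly.
#'
#' @param exp A [MicrobiomeExperiment-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBiom <- function(exp, path) {
  stopifnot(is(exp, "MicrobiomeExperiment"))
  cts <- meCounts(exp)
  tax <- taxonomyTable(exp)
  md <- sampleData(exp)

  rows <- lapply(seq_len(nrow(cts)), function(i) {
    meta <- if (is.null(tax)) NULL else as.list(tax[i, , drop = FALSE])
    list(id = rownames(cts)[i], metadata = meta)
  })
  cols <- lapply(seq_len(ncol(cts)), function(j) {
    meta <- if (ncol(md) == 0L) NULL else as.list(md[j, , drop = FALSE])
    list(id = colnames(cts)[j], metadata = meta)
  })
  nz <- which(cts != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(nz)), function(k) {
    c(nz[k, 1L] - 1L, nz[k, 2L] - 1L, cts[nz[k, 1L], nz[k, 2L]])
  })
  x <- list(
    id = "mbkit export",
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = paste0("mbkit ",
                          as.character(utils::packageVersion("mbkit"))),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    matrix_type = "sparse",
    matrix_element_type = "int",
    shape = dim(cts),
    rows = rows,
    columns = cols,
    data = data
  )
  biomformat::write_biom(biomformat::biom(x), path)
  invisible(path)
}
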