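# Small in-code fixtures shared across test files.

# Quick experiment builder: counts matrix with optional taxonomy/metadata.
make_me <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (is.null(metadata)) {
    metadata <- data.frame(row.names = colnames(counts))
  }
  MicrobiomeExperiment(counts, taxonomy = taxonomy, metadata = metadata)
}

# 3 features x 4 samples toy with taxonomy and a 2-level group.
toy_me <- function() {
  cts <- matrix(c(5, 0, 2,
                  3, 1, 0,
                  8, 2, 4,
                  1, 6, 3), nrow = 3,
                dimnames = list(c("sp1", "sp2", "sp3"),
                                c("S1", "S2", "S3", "S4")))
  tax <- data.frame(
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
    genus = c("GenA", "GenA", "GenB"),
    species = c("sp1", "sp2", "sp3"),
    row.names = rownames(cts)
  )
  md <- data.frame(group = c("case", "case", "ctrl", "ctrl"),
                   age = c(31, 45, 52, 28),
                   row.names = colnames(cts))
  MicrobiomeExperiment(cts, taxonomy = tax, metadata = md)
}

# Write a delimited file from lines.
write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
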