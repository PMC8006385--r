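# Shared constants and error helpers.

#' Canonical taxonomy ranks, coarsest to finest
#'
#' The fixed, ordered set of taxonomic ranks recognised by the package.
#' Taxonomy tables may populate any subset of these ranks, but columns are
#' always stored in this order.
#'
#' @return Character vector of rank names.
#' @export
#' @examples
#' taxonomyRanks()
taxonomyRanks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Marker used for missing taxonomy assignments
#' @return The string used to mark unassigned taxonomy entries.
#' @export
unclassifiedMarker <- function() "unclassified"

# Typed conditions -------------------------------------------------------

stop_mbkit <- function(msg, class, call. = FALSE) {
  cnd <- structure(
    class = c(class, "mbkit_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

stop_validation <- function(msg) stop_mbkit(msg, "mbkit_validation_error")
stop_parse <- function(msg) stop_mbkit(msg, "mbkit_parse_error")
stop_capability <- function(msg) stop_mbkit(msg, "mbkit_capability_error")

# Check a numeric matrix/vector holds integral values (within tol) and
# return it cast to integral doubles; used by count validation and parsers.
as_integral <- function(x, tol = 1e-9, what = "counts") {
  if (!is.numeric(x)) {
    stop_validation(sprintf("%s must be numeric", what))
  }
  dev <- abs(x - round(x))
  if (any(dev > tol, na.rm = TRUE)) {
    bad <- which(dev > tol)[1L]
    stop_validation(sprintf(
      "%s must be integral: value %g is not a whole number", what, x[bad]
    ))
  }
  round(x)
}

# Scalar flag helpers
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
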