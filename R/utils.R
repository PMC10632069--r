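#' @keywords internal
"_PACKAGE"

# CURIE helpers -----------------------------------------------------------

#' Test whether strings are well-formed CURIEs
#'
#' A compact URI (CURIE) has the form `PREFIX:LOCAL` with exactly one colon
#' and nonempty prefix and local part, e.g. `GO:0015979` or `NCBITaxon:1218`.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_curie <- function(x) {
  grepl("^[^:[:space:]]+:[^:[:space:]]+$", x)
}

assert_curie <- function(x, what = "term id") {
  bad <- x[!is_curie(x)]
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s CURIE(s): %s", what,
                 paste(utils::head(unique(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

curie_prefix <- function(x) sub(":.*$", "", x)

#' Expand a CURIE to an OBO PURL-style IRI
#'
#' `GO:0015979` becomes `http://purl.obolibrary.org/obo/GO_0015979`.
#'
#' @param x character vector of CURIEs.
#' @return character vector of IRIs.
#' @export
curie_to_iri <- function(x) {
  assert_curie(x)
  paste0("http://purl.obolibrary.org/obo/", sub(":", "_", x, fixed = TRUE))
}

# TSV I/O -----------------------------------------------------------------

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""),
                          fileEncoding = "UTF-8", quote = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# numeric parsing that flags failures with a line context
parse_num <- function(x, what, lines = NULL) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    where <- if (is.null(lines)) bad[1L] else lines[bad[1L]]
    stop(sprintf("non-numeric %s at line %d: '%s'", what, where, x[bad[1L]]),
         call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
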