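# RDF export of a sample store as W3C N-Triples.
#
# The vocabulary is this package's own minimal namespace (documented in
# the README): ontology classes expand to OBO PURL-style IRIs, and the
# graph shape mirrors the triplestore idiom of one node per observation —
# a count node per (sample, term) typed by the term's class, and a
# measurement node per (sample, parameter) typed by the parameter's class.

OM_NS <- "http://purl.example.org/ontomarine/"
RDF_TYPE <- "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>"
XSD_INT <- "<http://www.w3.org/2001/XMLSchema#integer>"
XSD_DOUBLE <- "<http://www.w3.org/2001/XMLSchema#double>"

om_iri <- function(...) {
  paste0("<", OM_NS, paste0(vapply(list(...), function(x)
    utils::URLencode(as.character(x), reserved = TRUE), character(1L)),
    collapse = "/"), ">")
}

om_pred <- function(name) paste0("<", OM_NS, name, ">")

fmt_double <- function(x) sprintf("\"%.15g\"^^%s", x, XSD_DOUBLE)
fmt_int <- function(x) sprintf("\"%d\"^^%s", as.integer(x), XSD_INT)

#' Export a sample store as N-Triples
#'
#' Emits, per (sample, term) count entry, a count node carrying the
#' term's class as `rdf:type` and the raw count as an integer literal;
#' per (sample, parameter) measurement, a measurement node with the
#' parameter class and a double literal; and per metadata sample, its
#' type, project link and environment-class links. Triples are written in
#' lexicographic order so repeated exports are byte-identical.
#'
#' @param store a `sample_store`.
#' @param path output file path.
#' @return the number of triples written, invisibly usable as a value.
#' @export
export_ntriples <- function(store, path) {
  stopifnot(inherits(store, "sample_store"))
  lines <- character()

  emit_counts <- function(table) {
    e <- table$entries
    if (nrow(e) == 0L) return(character())
    node <- mapply(function(s, t) om_iri("sample", s, "count", sub(":", "_", t)),
                   e$sample_id, e$term_id, USE.NAMES = FALSE)
    subj <- vapply(e$sample_id, function(s) om_iri("sample", s), character(1L),
                   USE.NAMES = FALSE)
    c(paste(subj, om_pred("has_count"), node, "."),
      paste(node, RDF_TYPE, paste0("<", curie_to_iri(e$term_id), ">"), "."),
      paste(node, om_pred("count"), vapply(e$count, fmt_int, character(1L)), "."))
  }
  lines <- c(lines, emit_counts(store$functions), emit_counts(store$taxa))

  md <- store$metadata
  if (!is.null(md)) {
    s <- md$samples
    if (nrow(s) > 0L) {
      subj <- vapply(s$sample_id, function(x) om_iri("sample", x), character(1L),
                     USE.NAMES = FALSE)
      lines <- c(lines,
                 paste(subj, RDF_TYPE, om_iri("Sample"), "."),
                 paste(subj, om_pred("from_project"),
                       vapply(s$project_id, function(p) om_iri("project", p),
                              character(1L), USE.NAMES = FALSE), "."))
    }
    if (nrow(md$env) > 0L) {
      subj <- vapply(md$env$sample_id, function(x) om_iri("sample", x),
                     character(1L), USE.NAMES = FALSE)
      lines <- c(lines, paste(subj, om_pred("has_env_class"),
                              paste0("<", curie_to_iri(md$env$term_id), ">"), "."))
    }
    m <- md$measurements
    if (nrow(m) > 0L) {
      node <- mapply(function(s, t) om_iri("sample", s, "measurement",
                                           sub(":", "_", t)),
                     m$sample_id, m$term_id, USE.NAMES = FALSE)
      subj <- vapply(m$sample_id, function(s) om_iri("sample", s),
                     character(1L), USE.NAMES = FALSE)
      lines <- c(lines,
                 paste(subj, om_pred("has_measurement"), node, "."),
                 paste(node, RDF_TYPE, paste0("<", curie_to_iri(m$term_id), ">"), "."),
                 paste(node, om_pred("value"),
                       vapply(m$value, fmt_double, character(1L)), "."))
    }
  }

  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- sort(lines, method = "radix")
  writeLines(lines, con, useBytes = TRUE)
  length(lines)
}

#' Parse an N-Triples file
#'
#' Minimal conformant reader for the line-based N-Triples grammar as this
#' package emits it (IRI or literal objects; no blank nodes, no language
#' tags). Mainly used to verify round-trips.
#'
#' @param path N-Triples file.
#' @return data.frame with columns `subject`, `predicate`, `object`,
#'   `object_kind` (`"iri"` or `"literal"`), `value`, `datatype`.
#' @export
read_ntriples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pat <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+",
                "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"",
                "(?:\\^\\^<([^>]*)>)?)\\s*\\.$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, integer(1L)) != 6L)
  if (length(bad) > 0L) {
    stop("not a valid N-Triples line (", bad[1L], "): ", lines[bad[1L]],
         call. = FALSE)
  }
  get <- function(i) vapply(m, `[[`, character(1L), i)
  obj_iri <- get(4L)
  lit <- get(5L)
  is_iri <- nzchar(obj_iri)
  data.frame(subject = get(2L), predicate = get(3L),
             object = ifelse(is_iri, obj_iri, lit),
             object_kind = ifelse(is_iri, "iri", "literal"),
             value = ifelse(is_iri, NA_character_, lit),
             datatype = ifelse(is_iri, NA_character_, get(6L)),
             stringsAsFactors = FALSE)
}
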