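# OBO 1.2/1.4 flat-file reading and writing.
#
# Only the tags the subclass-query engine needs are interpreted: id, name,
# is_a, is_obsolete, and has_rank carried on property_value (NCBI
# Taxonomy style) or xref lines. Everything else in a [Term] stanza is
# skipped; non-[Term] stanzas (e.g. [Typedef]) are ignored wholesale.

#' Parse an OBO flat file into an ontology graph
#'
#' @param path path to an OBO file, or a character vector of OBO lines via
#'   `text`.
#' @param text optional character vector of OBO source lines (overrides
#'   `path`).
#' @return an `onto_graph`; acyclicity is verified on load.
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "[Term]", "id: GO:0000002", "name: child", "is_a: GO:0000001")
#' g <- parse_obo(text = obo)
#' descendants(g, "GO:0000001")
#' @export
parse_obo <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else {
    if (is.null(path)) stop("either path or text must be given", call. = FALSE)
    readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  lines <- sub("\\s+$", "", lines)
  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    return(onto_graph(ids = character()))
  }
  ends <- vapply(term_starts, function(s) {
    nxt <- stanza_starts[stanza_starts > s]
    if (length(nxt) == 0L) length(lines) else nxt[[1L]] - 1L
  }, integer(1L))

  n <- length(term_starts)
  ids <- character(n); labs <- character(n); ranks <- character(n)
  obs <- logical(n); pars <- vector("list", n)
  for (k in seq_len(n)) {
    body <- lines[(term_starts[[k]] + 1L):ends[[k]]]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    tagval <- regmatches(body, regexec("^([A-Za-z_]+): *(.*)$", body))
    tags <- vapply(tagval, function(m) if (length(m) == 3L) m[[2L]] else "",
                   character(1L))
    vals <- vapply(tagval, function(m) if (length(m) == 3L) m[[3L]] else "",
                   character(1L))
    id <- vals[tags == "id"]
    if (length(id) == 0L || !nzchar(id[[1L]])) {
      stop(sprintf("malformed [Term] stanza with no id at line %d",
                   term_starts[[k]]), call. = FALSE)
    }
    ids[[k]] <- strip_comment(id[[1L]])
    nm <- vals[tags == "name"]
    labs[[k]] <- if (length(nm) > 0L) nm[[1L]] else ""
    obs[[k]] <- any(tags == "is_obsolete" &
                      startsWith(trimws(vals), "true"))
    isa <- vals[tags == "is_a"]
    pars[[k]] <- vapply(isa, strip_comment, character(1L), USE.NAMES = FALSE)
    ranks[[k]] <- parse_rank(vals[tags %in% c("property_value", "xref")])
  }
  onto_graph(ids = ids, labels = labs, parents = pars,
             rank = ranks, obsolete = obs)
}

# drop trailing "! label" comments and whitespace from a tag value
strip_comment <- function(x) trimws(sub("!.*$", "", x))

# NCBITaxon style: property_value: has_rank NCBITaxon:genus
# tolerate a bare "has_rank genus" or xref-carried rank
parse_rank <- function(vals) {
  for (v in vals) {
    m <- regmatches(v, regexec("has_rank[ :]+(?:NCBITaxon:)?([A-Za-z_ ]+)", v))[[1L]]
    if (length(m) == 2L) return(trimws(gsub("_", " ", m[[2L]])))
  }
  "no rank"
}

#' Write an ontology graph as an OBO flat file
#'
#' Stanzas are emitted sorted by term id so the output is byte-stable for
#' a given graph: exporting the same subset twice yields identical files.
#'
#' @param g an `onto_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  out <- c("format-version: 1.2", "")
  for (id in sort(g$ids)) {
    st <- c("[Term]", paste0("id: ", id))
    if (nzchar(g$labels[[id]])) st <- c(st, paste0("name: ", g$labels[[id]]))
    for (p in sort(g$parents[[id]])) st <- c(st, paste0("is_a: ", p))
    if (!identical(g$rank[[id]], "no rank")) {
      st <- c(st, paste0("property_value: has_rank NCBITaxon:",
                         gsub(" ", "_", g$rank[[id]])))
    }
    if (g$obsolete[[id]]) st <- c(st, "is_obsolete: true")
    out <- c(out, st, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
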