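# Sparse per-sample feature count tables (functions annotated with GO
# terms, taxa with NCBI Taxonomy nodes), stored long: one row per
# (sample, term) with a nonzero value.

#' Construct a feature count table
#'
#' @param entries data.frame with columns `sample_id`, `term_id`, `count`.
#'   Duplicate (sample, term) keys are summed with a warning: sharded
#'   annotation runs can legitimately split one term across rows.
#' @param kind `"function"` or `"taxon"`.
#' @param normalized `FALSE` for raw integer counts, `TRUE` for
#'   relativized real abundances in `[0, 1]`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(entries, kind = c("function", "taxon"),
                          normalized = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(entries),
            all(c("sample_id", "term_id", "count") %in% names(entries)))
  entries <- entries[, c("sample_id", "term_id", "count")]
  entries$sample_id <- as.character(entries$sample_id)
  entries$term_id <- as.character(entries$term_id)
  entries$count <- as.numeric(entries$count)
  if (nrow(entries) > 0L) {
    assert_curie(entries$term_id)
    if (any(entries$count < 0)) stop("negative counts", call. = FALSE)
    if (!normalized && any(entries$count != round(entries$count))) {
      stop("raw counts must be integers", call. = FALSE)
    }
    if (normalized && any(entries$count > 1)) {
      stop("normalized abundances must lie in [0, 1]", call. = FALSE)
    }
    key <- paste(entries$sample_id, entries$term_id, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate (sample, term) rows summed", call. = FALSE)
      agg <- rowsum(entries$count, key)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      entries <- data.frame(
        sample_id = vapply(parts, `[[`, character(1L), 1L),
        term_id = vapply(parts, `[[`, character(1L), 2L),
        count = as.numeric(agg[, 1L]),
        stringsAsFactors = FALSE)
    }
    entries <- entries[order(entries$sample_id, entries$term_id), ]
    rownames(entries) <- NULL
  }
  structure(list(kind = kind, entries = entries, normalized = normalized),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> kind=%s %s: %d entries, %d samples, %d terms\n",
              x$kind, if (x$normalized) "relativized" else "raw counts",
              nrow(x$entries), length(table_samples(x)), length(table_terms(x))))
  invisible(x)
}

#' Samples present in a feature table
#' @param table a `feature_table`.
#' @return sorted character vector of sample ids.
#' @export
table_samples <- function(table) sort(unique(table$entries$sample_id))

#' Terms present in a feature table
#' @param table a `feature_table`.
#' @return sorted character vector of term CURIEs.
#' @export
table_terms <- function(table) sort(unique(table$entries$term_id))

#' Read a feature count table from TSV
#'
#' Expects a UTF-8, tab-delimited file with header columns `sample_id`,
#' `term_id`, `count`. Counts must be nonnegative integers; term ids must
#' be CURIEs.
#'
#' @param path TSV path.
#' @param kind `"function"` or `"taxon"`.
#' @return a raw `feature_table`.
#' @export
read_count_table <- function(path, kind = c("function", "taxon")) {
  kind <- match.arg(kind)
  df <- read_tsv_checked(path, c("sample_id", "term_id", "count"))
  if (nrow(df) == 0L) {
    return(feature_table(data.frame(sample_id = character(),
                                    term_id = character(),
                                    count = numeric()), kind = kind))
  }
  cnt <- parse_num(df$count, "count", lines = seq_len(nrow(df)) + 1L)
  if (any(is.na(cnt)) || any(cnt != round(cnt)) || any(cnt < 0)) {
    bad <- which(is.na(cnt) | cnt != round(cnt) | cnt < 0)[1L]
    stop(sprintf("%s: non-integer count at line %d", path, bad + 1L),
         call. = FALSE)
  }
  bad_curie <- which(!is_curie(df$term_id))
  if (length(bad_curie) > 0L) {
    stop(sprintf("%s: malformed CURIE at line %d: '%s'", path,
                 bad_curie[1L] + 1L, df$term_id[bad_curie[1L]]), call. = FALSE)
  }
  feature_table(data.frame(sample_id = df$sample_id, term_id = df$term_id,
                           count = cnt, stringsAsFactors = FALSE),
                kind = kind)
}

#' Write a feature count table as TSV
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  write_tsv_plain(table$entries, path)
}

#' Annotation richness of one sample
#'
#' Number of distinct terms with a positive value for the sample — the
#' per-sample richness statistic the read-depth quality control is based
#' on.
#'
#' @param table a `feature_table`.
#' @param sample_id a sample present in the table.
#' @return integer count of distinct nonzero terms.
#' @export
annotation_richness <- function(table, sample_id) {
  if (!sample_id %in% table$entries$sample_id) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  e <- table$entries
  length(unique(e$term_id[e$sample_id == sample_id & e$count > 0]))
}

#' Densify a feature table
#'
#' @param table a `feature_table`.
#' @param samples,terms optional orderings; default all present, sorted.
#' @return numeric matrix samples x terms with zeros filled in.
#' @export
as_matrix <- function(table, samples = NULL, terms = NULL) {
  samples <- samples %||% table_samples(table)
  terms <- terms %||% table_terms(table)
  m <- matrix(0, nrow = length(samples), ncol = length(terms),
              dimnames = list(samples, terms))
  e <- table$entries
  e <- e[e$sample_id %in% samples & e$term_id %in% terms, ]
  if (nrow(e) > 0L) {
    m[cbind(match(e$sample_id, samples), match(e$term_id, terms))] <- e$count
  }
  m
}

# restrict a table to a sample and/or term subset, preserving class fields
subset_table <- function(table, samples = NULL, terms = NULL) {
  e <- table$entries
  if (!is.null(samples)) e <- e[e$sample_id %in% samples, ]
  if (!is.null(terms)) e <- e[e$term_id %in% terms, ]
  feature_table(e, kind = table$kind, normalized = table$normalized)
}
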