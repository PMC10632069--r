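# Normalization, aggregation, filtering and transformation of count
# tables: relativization by per-sample denominators, clade-level
# aggregation over the taxonomy, rank filtering, prevalence filtering,
# the centered log-ratio transform, variance-based feature exclusion and
# threshold binning of continuous covariates.

#' Construct a normalized matrix
#'
#' @param values numeric samples x terms matrix with dimnames.
#' @param transform_tag `"relabund"` (relative abundances in `[0, 1]`) or
#'   `"clr"` (centered log-ratios; rows sum to zero).
#' @return an object of class `norm_matrix`.
#' @export
norm_matrix <- function(values, transform_tag = c("relabund", "clr")) {
  transform_tag <- match.arg(transform_tag)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (transform_tag == "relabund" &&
      (any(values < 0) || any(values > 1 + 1e-12))) {
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  }
  if (transform_tag == "clr" && any(abs(rowSums(values)) > 1e-9)) {
    stop("clr rows must sum to zero", call. = FALSE)
  }
  structure(list(samples = rownames(values), terms = colnames(values),
                 values = values, transform_tag = transform_tag),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %s: %d samples x %d terms\n",
              x$transform_tag, length(x$samples), length(x$terms)))
  invisible(x)
}

denominators <- function(stats, samples, col) {
  idx <- match(samples, stats$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from stats: ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  d <- stats[[col]][idx]
  names(d) <- samples
  d
}

relativize <- function(m, denom, what) {
  zero <- denom == 0 & rowSums(m) > 0
  if (any(zero)) {
    stop(sprintf("zero %s with nonzero counts for: %s", what,
                 paste(names(denom)[zero], collapse = ", ")), call. = FALSE)
  }
  denom[denom == 0] <- 1  # all-zero rows stay all-zero
  norm_matrix(m / denom, "relabund")
}

#' Relativize functional counts by ORF totals
#'
#' Each sample's GO-annotated gene counts are divided by the number of
#' ORFs the annotation pipeline predicted for that sample.
#'
#' @param table raw `feature_table` of kind `"function"`.
#' @param stats a `sample_stats` data.frame covering all table samples.
#' @return a `norm_matrix` of relative abundances.
#' @export
relativize_functions <- function(table, stats) {
  stopifnot(table$kind == "function", !table$normalized)
  m <- as_matrix(table)
  relativize(m, denominators(stats, rownames(m), "n_orfs"), "n_orfs")
}

#' Relativize taxonomic counts by post-QC read totals
#'
#' Each sample's taxon counts are divided by the number of reads that
#' survived the taxonomic pipeline's quality-control steps.
#'
#' @inheritParams relativize_functions
#' @return a `norm_matrix` of relative abundances.
#' @export
relativize_taxa <- function(table, stats) {
  stopifnot(table$kind == "taxon", !table$normalized)
  m <- as_matrix(table)
  relativize(m, denominators(stats, rownames(m), "n_reads_qc"), "n_reads_qc")
}

#' Aggregate relative abundances over a clade
#'
#' Per-sample sum of the relativized counts of every taxonomic node at or
#' below `clade_root` — the "genus level and below" summation used for
#' genus depth profiles. Counts assigned above the clade root are
#' excluded; the per-node assignment contract (each read counted at
#' exactly one node) makes the subtree sum double-count free.
#'
#' @param norm a `norm_matrix` with `transform_tag == "relabund"`.
#' @param taxonomy an `onto_graph` carrying the taxonomy.
#' @param clade_root CURIE of the clade's root term.
#' @return named numeric vector, one value per sample.
#' @export
aggregate_clade <- function(norm, taxonomy, clade_root) {
  stopifnot(inherits(norm, "norm_matrix"), norm$transform_tag == "relabund")
  assert_term(taxonomy, clade_root, "clade root")
  members <- descendants(taxonomy, clade_root, include_self = TRUE)
  cols <- intersect(norm$terms, members)
  out <- rowSums(norm$values[, cols, drop = FALSE])
  names(out) <- norm$samples
  out
}

is_species_or_below <- function(taxonomy, terms) {
  vapply(terms, function(t) {
    if (!has_term(taxonomy, t)) return(FALSE)
    if (identical(taxonomy$rank[[t]], "species")) return(TRUE)
    anc <- ancestors(taxonomy, t)
    any(taxonomy$rank[anc] == "species")
  }, logical(1L))
}

#' Keep only species- and strain-level taxa
#'
#' Retains terms ranked `species` and any term below a species-ranked
#' ancestor (strains, subspecies); genus-level and higher assignments are
#' dropped. Terms absent from the taxonomy are dropped as unplaceable.
#'
#' @param x a `feature_table` or `norm_matrix`.
#' @param taxonomy an `onto_graph` with ranks.
#' @return the same type as `x`, restricted to species/strain terms.
#' @export
filter_species_level <- function(x, taxonomy) {
  if (inherits(x, "feature_table")) {
    terms <- table_terms(x)
    keep <- terms[is_species_or_below(taxonomy, terms)]
    subset_table(x, terms = keep)
  } else if (inherits(x, "norm_matrix")) {
    keep <- x$terms[is_species_or_below(taxonomy, x$terms)]
    norm_matrix(x$values[, keep, drop = FALSE], x$transform_tag)
  } else {
    stop("x must be a feature_table or norm_matrix", call. = FALSE)
  }
}

#' Prevalence filter on raw counts
#'
#' Removes low-prevalence terms as potential contaminants: a term is
#' retained iff it reaches at least `min_cpm` counts per million (of the
#' sample's table total) in at least `min_fraction` of the samples.
#' Samples with a zero table total cannot contribute and are excluded
#' from the denominator with a warning.
#'
#' @param table raw `feature_table`.
#' @param min_cpm counts-per-million threshold (default 1).
#' @param min_fraction minimum fraction of samples at or above the CPM
#'   threshold (default 0.05).
#' @return list with `table` (filtered) and `removed` (character vector
#'   of dropped terms).
#' @export
prevalence_filter <- function(table, min_cpm = 1.0, min_fraction = 0.05) {
  stopifnot(inherits(table, "feature_table"), !table$normalized)
  m <- as_matrix(table)
  if (nrow(m) == 0L) return(list(table = table, removed = character()))
  totals <- rowSums(m)
  if (any(totals == 0)) {
    warning("samples with zero total excluded from prevalence denominator: ",
            paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (nrow(m) == 0L) return(list(table = table, removed = table_terms(table)))
  cpm <- m / totals * 1e6
  frac <- colMeans(cpm >= min_cpm)
  keep <- colnames(m)[frac >= min_fraction]
  removed <- setdiff(table_terms(table), keep)
  list(table = subset_table(table, terms = keep), removed = removed)
}

#' Centered log-ratio (Aitchison) transform
#'
#' Per sample, each part is replaced by the log of its ratio to the
#' sample's geometric mean, accounting for the compositional nature of
#' sequencing data. Zeros must be handled first: either a pseudocount
#' (default: half the smallest nonzero value of the matrix) added to
#' zero cells only, or multiplicative replacement (zeros set to a small
#' delta, nonzero parts scaled down to preserve the unit sum).
#'
#' @param x a `norm_matrix` (relabund), `feature_table` or nonnegative
#'   matrix with dimnames.
#' @param zero_policy `"pseudocount"` or `"multiplicative"`.
#' @param pseudocount explicit pseudocount; default `0.5 *` smallest
#'   nonzero value.
#' @return a `norm_matrix` with `transform_tag == "clr"`; rows sum to
#'   zero within 1e-9.
#' @export
clr_transform <- function(x, zero_policy = c("pseudocount", "multiplicative"),
                          pseudocount = NULL) {
  zero_policy <- match.arg(zero_policy)
  m <- if (inherits(x, "norm_matrix")) x$values
  else if (inherits(x, "feature_table")) as_matrix(x)
  else x
  stopifnot(is.matrix(m))
  if (any(m < 0)) stop("clr requires nonnegative values", call. = FALSE)
  all_zero <- rowSums(m) == 0
  if (any(all_zero)) {
    stop("sample(s) with no nonzero parts cannot be transformed: ",
         paste(rownames(m)[all_zero], collapse = ", "), call. = FALSE)
  }
  if (any(m == 0)) {
    if (zero_policy == "pseudocount") {
      c0 <- pseudocount %||% (0.5 * min(m[m > 0]))
      m[m == 0] <- c0
    } else {
      delta <- pseudocount %||% (0.5 * min(m[m > 0]))
      for (i in seq_len(nrow(m))) {
        z <- m[i, ] == 0
        if (!any(z)) next
        tot <- sum(m[i, ])
        m[i, !z] <- m[i, !z] * (1 - sum(z) * delta / tot)
        m[i, z] <- delta
      }
    }
  }
  lm <- log(m)
  clr <- lm - rowMeans(lm)
  norm_matrix(clr, "clr")
}

#' Drop the highest-variance features
#'
#' Ranks features by across-sample variance and removes the top
#' `drop_fraction` (ceiling of the feature count), the exclusion applied
#' before regression-based feature selection on genomic data. Ties are
#' broken by term id, lexicographically (the later id is considered more
#' variable).
#'
#' @param x a `norm_matrix` or numeric matrix with dimnames.
#' @param drop_fraction fraction in `[0, 1)` of features to remove
#'   (default 0.30).
#' @return same type as `x` with the high-variance features removed.
#' @export
variance_filter <- function(x, drop_fraction = 0.30) {
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1) {
    stop("drop_fraction must lie in [0, 1)", call. = FALSE)
  }
  m <- if (inherits(x, "norm_matrix")) x$values else x
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  n_drop <- ceiling(drop_fraction * ncol(m))
  if (n_drop == 0L) return(x)
  v <- apply(m, 2L, stats::var)
  ord <- order(v, colnames(m), decreasing = TRUE)  # ties: later id drops first
  drop <- colnames(m)[ord[seq_len(n_drop)]]
  keep <- setdiff(colnames(m), drop)
  if (inherits(x, "norm_matrix")) {
    norm_matrix(m[, keep, drop = FALSE], x$transform_tag)
  } else {
    m[, keep, drop = FALSE]
  }
}

#' Bin continuous values at fixed thresholds
#'
#' Assigns each value to one of `length(thresholds) + 1` ordered bins
#' using half-open intervals `[t_{i-1}, t_i)`: a value exactly at a
#' threshold falls in the upper bin. Used to split samples into e.g.
#' oxic/anoxic oxygen groups or shallow/intermediate/deep depth ranges.
#'
#' @param values named numeric vector (names = sample ids); `NA`s are
#'   left unassigned and reported.
#' @param thresholds strictly increasing cut points.
#' @param labels bin labels, one more than `thresholds`.
#' @return list with `bins` (named character vector over non-missing
#'   samples), `unassigned` (names of `NA` values), `thresholds`,
#'   `labels`.
#' @export
bin_values <- function(values, thresholds, labels) {
  if (length(thresholds) > 0L && any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (length(labels) != length(thresholds) + 1L) {
    stop("need exactly one more label than thresholds", call. = FALSE)
  }
  miss <- names(values)[is.na(values)] %||% character()
  v <- values[!is.na(values)]
  idx <- findInterval(v, thresholds, left.open = FALSE) + 1L
  bins <- labels[idx]
  names(bins) <- names(v)
  list(bins = bins, unassigned = miss, thresholds = thresholds,
       labels = labels)
}
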