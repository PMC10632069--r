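# The sample store: count tables + pipeline statistics + environmental
# metadata for a cohort of metagenomic samples, with the quality-control
# rules and the ontology-driven intersection query.

#' Construct per-sample pipeline statistics
#'
#' @param df data.frame with columns `sample_id`, `n_reads_raw`,
#'   `n_reads_qc`, `n_orfs` and optionally `n_unique_taxa`, `n_unique_go`
#'   (filled from the count tables by [build_store()] when absent).
#' @return validated data.frame of class `sample_stats`.
#' @export
sample_stats <- function(df) {
  req <- c("sample_id", "n_reads_raw", "n_reads_qc", "n_orfs")
  stopifnot(is.data.frame(df), all(req %in% names(df)))
  for (col in c("n_unique_taxa", "n_unique_go")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  }
  df <- df[, c(req, "n_unique_taxa", "n_unique_go")]
  df$sample_id <- as.character(df$sample_id)
  for (col in setdiff(names(df), "sample_id")) df[[col]] <- as.numeric(df[[col]])
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in stats", call. = FALSE)
  num <- df[, c("n_reads_raw", "n_reads_qc", "n_orfs")]
  if (any(is.na(num)) || any(num < 0) || any(num != round(num))) {
    stop("read/ORF totals must be nonnegative integers", call. = FALSE)
  }
  if (any(df$n_reads_qc > df$n_reads_raw)) {
    stop("n_reads_qc exceeds n_reads_raw for: ",
         paste(df$sample_id[df$n_reads_qc > df$n_reads_raw], collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("sample_stats", "data.frame")
  df
}

#' Read per-sample pipeline statistics from TSV
#' @param path TSV with the columns described in [sample_stats()].
#' @return a `sample_stats` data.frame.
#' @export
read_sample_stats <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "n_reads_raw", "n_reads_qc",
                                 "n_orfs"))
  for (col in setdiff(names(df), "sample_id")) {
    df[[col]] <- parse_num(df[[col]], col)
  }
  sample_stats(df)
}

#' Read sample metadata from TSV
#'
#' The expected columns are `sample_id`, `project_id`, `env_classes`
#' (pipe-separated ENVO-style CURIEs), `depth_m`, `latitude`, `longitude`,
#' `collected_at`, plus any number of measurement columns named
#' `CURIE[unit]`, e.g. `ENVO:3100011[umol/kg]`. Empty cells become `NA`.
#'
#' @param path TSV path.
#' @param env_ontology optional `onto_graph`; when given, every
#'   environment class and measurement CURIE must resolve in it.
#' @return an object of class `sample_metadata`: a list with `samples`
#'   (one row per sample), `env` (long sample/class pairs) and
#'   `measurements` (long sample/parameter/value/unit rows).
#' @export
read_sample_metadata <- function(path, env_ontology = NULL) {
  fixed <- c("sample_id", "project_id", "env_classes", "depth_m",
             "latitude", "longitude", "collected_at")
  df <- read_tsv_checked(path, fixed)
  meas_cols <- setdiff(names(df), fixed)
  meas_info <- regmatches(meas_cols, regexec("^([^\\[]+)\\[([^]]*)\\]$", meas_cols))
  bad <- meas_cols[vapply(meas_info, length, integer(1L)) != 3L]
  if (length(bad) > 0L) {
    stop("measurement columns must be named CURIE[unit]; offenders: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  samples <- data.frame(
    sample_id = as.character(df$sample_id),
    project_id = as.character(df$project_id),
    depth_m = parse_num(df$depth_m, "depth_m"),
    latitude = parse_num(df$latitude, "latitude"),
    longitude = parse_num(df$longitude, "longitude"),
    collected_at = as.character(df$collected_at),
    stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  ok_lat <- is.na(samples$latitude) | abs(samples$latitude) <= 90
  ok_lon <- is.na(samples$longitude) | abs(samples$longitude) <= 180
  ok_dep <- is.na(samples$depth_m) | samples$depth_m >= 0
  if (!all(ok_lat & ok_lon & ok_dep)) {
    stop("out-of-range coordinates or depth for: ",
         paste(samples$sample_id[!(ok_lat & ok_lon & ok_dep)], collapse = ", "),
         call. = FALSE)
  }

  env_rows <- lapply(seq_len(nrow(df)), function(i) {
    cls <- df$env_classes[[i]]
    if (is.na(cls) || !nzchar(cls)) return(NULL)
    data.frame(sample_id = samples$sample_id[[i]],
               term_id = trimws(strsplit(cls, "|", fixed = TRUE)[[1L]]),
               stringsAsFactors = FALSE)
  })
  env <- do.call(rbind, env_rows) %||%
    data.frame(sample_id = character(), term_id = character())
  if (nrow(env) > 0L) assert_curie(env$term_id, "env class")

  meas_rows <- lapply(seq_along(meas_cols), function(j) {
    curie <- meas_info[[j]][[2L]]
    unit <- meas_info[[j]][[3L]]
    val <- parse_num(df[[meas_cols[[j]]]], meas_cols[[j]])
    keep <- !is.na(val)
    if (!any(keep)) return(NULL)
    data.frame(sample_id = samples$sample_id[keep], term_id = curie,
               value = val[keep], unit = unit, stringsAsFactors = FALSE)
  })
  measurements <- do.call(rbind, meas_rows) %||%
    data.frame(sample_id = character(), term_id = character(),
               value = numeric(), unit = character())
  if (nrow(measurements) > 0L) assert_curie(measurements$term_id, "measurement")

  if (!is.null(env_ontology)) {
    unresolved <- setdiff(unique(c(env$term_id, measurements$term_id)),
                          env_ontology$ids)
    if (length(unresolved) > 0L) {
      stop("CURIEs not resolvable in the environment ontology: ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(samples = samples, env = env, measurements = measurements),
            class = "sample_metadata")
}

#' Assemble a sample store
#'
#' Bundles the functional table, taxonomic table, pipeline statistics and
#' metadata. Missing richness fields in the statistics (`n_unique_taxa`,
#' `n_unique_go`) are computed from the corresponding tables; a provided
#' richness that disagrees with the loaded table triggers a warning.
#'
#' @param functions raw `feature_table` of kind `"function"` (or `NULL`).
#' @param taxa raw `feature_table` of kind `"taxon"` (or `NULL`).
#' @param stats a `sample_stats` data.frame.
#' @param metadata a `sample_metadata` object (or `NULL`).
#' @return an object of class `sample_store`.
#' @export
build_store <- function(functions = NULL, taxa = NULL, stats = NULL,
                        metadata = NULL) {
  empty <- function(kind) feature_table(
    data.frame(sample_id = character(), term_id = character(),
               count = numeric()), kind = kind)
  functions <- functions %||% empty("function")
  taxa <- taxa %||% empty("taxon")
  stopifnot(inherits(functions, "feature_table"), functions$kind == "function",
            inherits(taxa, "feature_table"), taxa$kind == "taxon")
  if (!is.null(stats)) {
    stats <- sample_stats(as.data.frame(stats))
    stats <- fill_richness(stats, "n_unique_taxa", taxa)
    stats <- fill_richness(stats, "n_unique_go", functions)
  }
  structure(list(functions = functions, taxa = taxa, stats = stats,
                 metadata = metadata),
            class = "sample_store")
}

fill_richness <- function(stats, col, table) {
  if (nrow(table$entries) == 0L) return(stats)
  e <- table$entries[table$entries$count > 0, ]
  rich <- tapply(e$term_id, e$sample_id, function(x) length(unique(x)))
  observed <- as.numeric(rich[stats$sample_id])
  observed[is.na(observed)] <- 0
  has_sample <- stats$sample_id %in% table$entries$sample_id
  fill <- is.na(stats[[col]]) & has_sample
  stats[[col]][fill] <- observed[fill]
  mismatch <- has_sample & !is.na(stats[[col]]) & stats[[col]] != observed
  if (any(mismatch)) {
    warning(sprintf("%s in stats disagrees with loaded table for: %s", col,
                    paste(stats$sample_id[mismatch], collapse = ", ")),
            call. = FALSE)
  }
  stats
}

#' @export
print.sample_store <- function(x, ...) {
  cat(sprintf("<sample_store> %d function entries, %d taxon entries, %d samples with stats, %d with metadata\n",
              nrow(x$functions$entries), nrow(x$taxa$entries),
              if (is.null(x$stats)) 0L else nrow(x$stats),
              if (is.null(x$metadata)) 0L else nrow(x$metadata$samples)))
  invisible(x)
}

store_samples <- function(store) {
  sort(unique(c(store$functions$entries$sample_id,
                store$taxa$entries$sample_id,
                if (!is.null(store$stats)) store$stats$sample_id,
                if (!is.null(store$metadata)) store$metadata$samples$sample_id)))
}

#' Quality-control filter on samples
#'
#' Removes samples sequenced too shallowly or with too few distinct
#' taxonomic annotations, following the read-depth cutoffs established
#' for the marine corpus: at least 5 million raw reads and at least
#' 10,000 unique taxon annotations per sample. Both bounds are inclusive
#' (a sample exactly at a threshold is retained).
#'
#' @param store a `sample_store` with statistics for every sample that
#'   appears in a count table.
#' @param min_raw_reads minimum raw read count (default 5e6).
#' @param min_unique_taxa minimum distinct taxon annotations (default 10000).
#' @return list with `store` (filtered; retained order preserved) and
#'   `report` (data.frame of removed samples with `reason`).
#' @export
qc_filter_samples <- function(store, min_raw_reads = 5e6,
                              min_unique_taxa = 1e4) {
  stopifnot(inherits(store, "sample_store"))
  if (is.null(store$stats)) stop("store has no sample statistics", call. = FALSE)
  table_ids <- unique(c(store$functions$entries$sample_id,
                        store$taxa$entries$sample_id))
  missing <- setdiff(table_ids, store$stats$sample_id)
  if (length(missing) > 0L) {
    stop("samples present in count tables but missing statistics: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  st <- store$stats
  low_reads <- st$n_reads_raw < min_raw_reads
  rich <- st$n_unique_taxa
  rich[is.na(rich)] <- Inf  # no taxon table loaded: rule cannot fire
  low_taxa <- rich < min_unique_taxa
  r1 <- st$sample_id[low_reads]
  r2 <- st$sample_id[low_taxa & !low_reads]
  report <- data.frame(
    sample_id = c(r1, r2),
    reason = c(rep("min_raw_reads", length(r1)),
               rep("min_unique_taxa", length(r2))),
    stringsAsFactors = FALSE)
  drop <- st$sample_id[low_reads | low_taxa]
  keep <- setdiff(st$sample_id, drop)

  out <- store
  out$stats <- st[st$sample_id %in% keep, ]
  class(out$stats) <- class(st)
  out$functions <- subset_table(store$functions, samples = keep)
  out$taxa <- subset_table(store$taxa, samples = keep)
  if (!is.null(store$metadata)) {
    md <- store$metadata
    md$samples <- md$samples[!md$samples$sample_id %in% drop, ]
    md$env <- md$env[!md$env$sample_id %in% drop, ]
    md$measurements <- md$measurements[!md$measurements$sample_id %in% drop, ]
    out$metadata <- md
  }
  list(store = out, report = report)
}

#' Ontology-driven intersection query
#'
#' The core discovery operation: a recursive subclass query over the
#' feature ontology (all descendants of `feature_class`, including
#' itself) intersected with the annotated count data, restricted to
#' samples satisfying every metadata constraint. Matched samples must
#' carry at least one nonzero count for a descendant term; matched terms
#' are the descendants with at least one nonzero count among the matched
#' samples.
#'
#' @param store a `sample_store` with metadata.
#' @param ontologies named list with elements `functions`, `taxa`, `env`
#'   (each an `onto_graph`; only those needed by the query are required).
#' @param feature_class CURIE of the queried class; its prefix's ontology
#'   determines whether the functional or taxonomic table is searched.
#' @param constraints optional list: `project_id` (exact match);
#'   `env_class` with `expand_env` (default `TRUE`: a sample matches if
#'   any of its environment classes is a subclass of `env_class`);
#'   `required_measurements` (character vector of parameter CURIEs the
#'   sample must carry); `depth_range` (`c(lo, hi)`, half-open `[lo, hi)`);
#'   `measurement_range` (named list of `c(lo, hi)` per parameter CURIE,
#'   half-open).
#' @return an object of class `query_result`: `samples`, `terms`,
#'   `counts` (dense samples x terms), `measurements` (named list of
#'   vectors aligned to `samples`, `NA` where missing), `kind`,
#'   `feature_class`.
#' @export
query_store <- function(store, ontologies, feature_class,
                        constraints = list()) {
  stopifnot(inherits(store, "sample_store"))
  known <- c("project_id", "env_class", "expand_env", "required_measurements",
             "depth_range", "measurement_range", "measurements")
  unknown <- setdiff(names(constraints), known)
  if (length(unknown) > 0L) {
    stop("unknown constraint(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  feat_onto <- NULL; table <- NULL; kind <- NULL
  if (!is.null(ontologies$functions) && has_term(ontologies$functions, feature_class)) {
    feat_onto <- ontologies$functions; table <- store$functions; kind <- "function"
  } else if (!is.null(ontologies$taxa) && has_term(ontologies$taxa, feature_class)) {
    feat_onto <- ontologies$taxa; table <- store$taxa; kind <- "taxon"
  } else {
    stop("feature class not found in any supplied ontology: ", feature_class,
         call. = FALSE)
  }
  terms_all <- descendants(feat_onto, feature_class, include_self = TRUE)

  md <- store$metadata
  if (is.null(md)) stop("store has no sample metadata", call. = FALSE)
  cand <- md$samples$sample_id
  ok <- rep(TRUE, length(cand))

  if (!is.null(constraints$project_id)) {
    ok <- ok & md$samples$project_id == constraints$project_id
  }
  if (!is.null(constraints$env_class)) {
    env_onto <- ontologies$env
    if (is.null(env_onto)) stop("env_class constraint needs an env ontology",
                                call. = FALSE)
    assert_term(env_onto, constraints$env_class, "env class")
    expand <- constraints$expand_env %||% TRUE
    classes <- if (expand) {
      descendants(env_onto, constraints$env_class, include_self = TRUE)
    } else constraints$env_class
    tagged <- unique(md$env$sample_id[md$env$term_id %in% classes])
    ok <- ok & cand %in% tagged
  }
  for (m in constraints$required_measurements %||% character()) {
    have <- unique(md$measurements$sample_id[md$measurements$term_id == m &
                                               !is.na(md$measurements$value)])
    ok <- ok & cand %in% have
  }
  if (!is.null(constraints$depth_range)) {
    r <- constraints$depth_range
    d <- md$samples$depth_m
    ok <- ok & !is.na(d) & d >= r[[1L]] & d < r[[2L]]
  }
  for (m in names(constraints$measurement_range %||% list())) {
    r <- constraints$measurement_range[[m]]
    rows <- md$measurements[md$measurements$term_id == m, ]
    vals <- rows$value[match(cand, rows$sample_id)]
    ok <- ok & !is.na(vals) & vals >= r[[1L]] & vals < r[[2L]]
  }
  cand <- cand[ok]

  # intersection with the annotated data
  e <- table$entries
  e <- e[e$sample_id %in% cand & e$term_id %in% terms_all & e$count > 0, ]
  samples <- cand[cand %in% e$sample_id]
  terms <- sort(unique(e$term_id))
  counts <- as_matrix(table, samples = samples, terms = terms)

  want <- unique(c(constraints$required_measurements %||% character(),
                   names(constraints$measurement_range %||% list()),
                   constraints$measurements %||% character()))
  meas <- lapply(want, function(m) {
    rows <- md$measurements[md$measurements$term_id == m, ]
    rows$value[match(samples, rows$sample_id)]
  })
  names(meas) <- want

  structure(list(samples = samples, terms = terms, counts = counts,
                 measurements = meas, kind = kind,
                 feature_class = feature_class),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %s:%s -> %d samples x %d terms\n",
              x$kind, x$feature_class, length(x$samples), length(x$terms)))
  invisible(x)
}

#' Per-sample depth vector aligned to a query result
#' @param store a `sample_store`.
#' @param samples sample ids.
#' @return numeric depths in meters (`NA` where unknown).
#' @export
sample_depths <- function(store, samples) {
  md <- store$metadata$samples
  md$depth_m[match(samples, md$sample_id)]
}
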