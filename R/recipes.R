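# Parameterized analysis recipes: the query -> preprocess -> analyze
# chains for the six case-study question patterns, each a pure function
# of (store, ontologies, config). Every run can write its result tables
# plus a JSON manifest capturing all parameters and seeds, so re-runs
# are byte-identical.

recipe_names <- c("gene-vs-gradient", "species-vs-species", "omz-species",
                  "anoxic-indicators", "cross-env-taxa", "cross-env-genes")

recipe_defaults <- function(name) {
  switch(name,
    "gene-vs-gradient" = list(
      feature_class = "GO:0043169", response = "ENVO:3100031",
      project_id = NULL, variance_drop = 0.30, alpha = 1, n_folds = 10L,
      rule = "lambda_1se", seed = 1L),
    "species-vs-species" = list(
      feature_class = "NCBITaxon:1117", response_term = "NCBITaxon:1501269",
      project_id = NULL, min_cpm = 1.0, min_fraction = 0.05,
      variance_drop = 0.30, alpha = 1, n_folds = 10L, rule = "lambda_1se",
      seed = 1L),
    "omz-species" = list(
      feature_class = "NCBITaxon:1117", response = "ENVO:3100011",
      env_class = "ENVO:00000213", depth_range = c(300, 600),
      min_cpm = 1.0, min_fraction = 0.05, variance_drop = 0.30, alpha = 1,
      n_folds = 10L, rule = "lambda_1se", seed = 1L),
    "anoxic-indicators" = list(
      feature_class = "GO:0016491", bin_measurement = "ENVO:3100011",
      thresholds = 20, labels = c("anoxic", "oxic"),
      env_class = NULL, depth_range = NULL, n_perm = 999L, seed = 1L),
    "cross-env-taxa" = list(
      feature_class = "NCBITaxon:2", bin_measurement = "PMO:00000142",
      thresholds = 1975, labels = c("river", "marine"),
      depth_range = c(0, 30), min_cpm = 1.0, min_fraction = 0.05,
      variance_drop = 0.30, alpha = 1, n_folds = 10L, rule = "lambda_1se",
      seed = 1L),
    "cross-env-genes" = list(
      feature_class = "GO:0005488", bin_measurement = "PMO:00000142",
      thresholds = 1975, labels = c("river", "marine"),
      depth_range = c(0, 30), variance_drop = 0.30, alpha = 1,
      n_folds = 10L, rule = "lambda_1se", seed = 1L),
    stop("unknown recipe: ", name, call. = FALSE))
}

empty_result_error <- function(msg) {
  stop(structure(class = c("ontomarine_empty_result", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# relativize a query result's counts by the sample's pipeline denominator
relativize_result <- function(qr, store) {
  col <- if (qr$kind == "function") "n_orfs" else "n_reads_qc"
  denom <- denominators(store$stats, qr$samples, col)
  relativize(qr$counts, denom, col)
}

# samples left with no nonzero parts after column filtering cannot be
# CLR-transformed and drop out of that analysis
drop_empty_samples <- function(nm) {
  keep <- rowSums(nm$values) > 0
  norm_matrix(nm$values[keep, , drop = FALSE], nm$transform_tag)
}

# query counts as a raw feature_table (for prevalence filtering)
result_table <- function(qr) {
  m <- qr$counts
  long <- data.frame(sample_id = rep(rownames(m), times = ncol(m)),
                     term_id = rep(colnames(m), each = nrow(m)),
                     count = as.vector(m), stringsAsFactors = FALSE)
  feature_table(long[long$count > 0, ],
                kind = if (qr$kind == "function") "function" else "taxon")
}

#' Run a named analysis recipe
#'
#' Executes one of the six packaged question patterns against a store:
#'
#' * `gene-vs-gradient`: recursive-subclass gene query, relativize by
#'   ORFs, variance-filter, CLR, gaussian elastic net against a measured
#'   gradient (default: depth).
#' * `species-vs-species`: clade query, species/strain filter,
#'   prevalence filter, relativize by reads, CLR, gaussian elastic net
#'   with one target species as response and the rest as predictors.
#' * `omz-species`: clade query constrained to an environment class and
#'   depth window, taxonomic preprocessing as above, gaussian elastic
#'   net against dissolved oxygen, z-scaled coefficients.
#' * `anoxic-indicators`: gene query, bin samples by a measured
#'   parameter (default: oxygen at 20 umol/kg), indicator value analysis
#'   on the raw counts.
#' * `cross-env-taxa` / `cross-env-genes`: shallow-sample query across
#'   projects, bin by dissolved inorganic carbon, binomial elastic net
#'   against the bins.
#'
#' @param name one of `"gene-vs-gradient"`, `"species-vs-species"`,
#'   `"omz-species"`, `"anoxic-indicators"`, `"cross-env-taxa"`,
#'   `"cross-env-genes"`.
#' @param store a QC'd `sample_store`.
#' @param ontologies list with `functions`, `taxa`, `env` graphs.
#' @param config named list overriding the recipe's defaults.
#' @param out_dir optional directory; when given, result tables (TSV)
#'   and a run manifest (JSON) are written there.
#' @return list with `recipe`, `config`, `query` (the `query_result`)
#'   and a recipe-specific `result` (an `enet_result` with `z` scores,
#'   or an `indicator_result` with the bin assignment).
#' @export
run_recipe <- function(name, store, ontologies, config = list(),
                       out_dir = NULL) {
  name <- match.arg(name, recipe_names)
  cfg <- utils::modifyList(recipe_defaults(name), config)
  resolve_cfg_curies(cfg, ontologies)

  out <- switch(name,
    "gene-vs-gradient" = recipe_gradient_enet(store, ontologies, cfg,
                                              kind = "function"),
    "species-vs-species" = recipe_species_vs_species(store, ontologies, cfg),
    "omz-species" = recipe_omz_species(store, ontologies, cfg),
    "anoxic-indicators" = recipe_indicators(store, ontologies, cfg),
    "cross-env-taxa" = recipe_binned_enet(store, ontologies, cfg,
                                          kind = "taxon"),
    "cross-env-genes" = recipe_binned_enet(store, ontologies, cfg,
                                           kind = "function"))
  out$recipe <- name
  out$config <- cfg
  if (!is.null(out_dir)) write_recipe_output(out, out_dir)
  out
}

# fail fast if any configured CURIE is unknown to every supplied ontology
resolve_cfg_curies <- function(cfg, ontologies) {
  fields <- c("feature_class", "response", "response_term", "env_class",
              "bin_measurement")
  for (f in intersect(fields, names(cfg))) {
    v <- cfg[[f]]
    if (is.null(v) || !is_curie(v)) next
    known <- any(vapply(ontologies, function(g) has_term(g, v), logical(1L)))
    if (!known) {
      stop(sprintf("config field %s: CURIE %s does not resolve in any supplied ontology",
                   f, v), call. = FALSE)
    }
  }
  invisible(cfg)
}

base_constraints <- function(cfg) {
  cons <- list()
  if (!is.null(cfg$project_id)) cons$project_id <- cfg$project_id
  if (!is.null(cfg$env_class)) cons$env_class <- cfg$env_class
  if (!is.null(cfg$depth_range)) cons$depth_range <- cfg$depth_range
  cons
}

recipe_gradient_enet <- function(store, ontologies, cfg, kind) {
  cons <- base_constraints(cfg)
  cons$required_measurements <- cfg$response
  qr <- query_store(store, ontologies, cfg$feature_class, cons)
  if (length(qr$samples) == 0L || length(qr$terms) == 0L) {
    empty_result_error("query matched no samples/terms")
  }
  rel <- relativize_result(qr, store)
  filt <- drop_empty_samples(variance_filter(rel, cfg$variance_drop))
  clr <- clr_transform(filt)
  y <- qr$measurements[[cfg$response]][match(clr$samples, qr$samples)]
  fit <- elastic_net_select(clr$values, y, family = "gaussian",
                            alpha = cfg$alpha, n_folds = cfg$n_folds,
                            rule = cfg$rule, seed = cfg$seed)
  list(query = qr, result = fit, matrix = clr)
}

recipe_species_vs_species <- function(store, ontologies, cfg) {
  cons <- base_constraints(cfg)
  qr <- query_store(store, ontologies, cfg$feature_class, cons)
  if (length(qr$samples) == 0L) empty_result_error("query matched no samples")
  tab <- filter_species_level(result_table(qr), ontologies$taxa)
  tab <- prevalence_filter(tab, cfg$min_cpm, cfg$min_fraction)$table
  if (!cfg$response_term %in% table_terms(tab)) {
    empty_result_error(sprintf("response term %s not retained after filtering",
                               cfg$response_term))
  }
  rel <- relativize_taxa(tab, store$stats)
  clr <- clr_transform(rel)
  y <- clr$values[, cfg$response_term]
  X <- clr$values[, setdiff(clr$terms, cfg$response_term), drop = FALSE]
  X <- variance_filter(X, cfg$variance_drop)
  fit <- elastic_net_select(X, y, family = "gaussian", alpha = cfg$alpha,
                            n_folds = cfg$n_folds, rule = cfg$rule,
                            seed = cfg$seed)
  list(query = qr, result = fit, matrix = clr)
}

recipe_omz_species <- function(store, ontologies, cfg) {
  cons <- base_constraints(cfg)
  cons$required_measurements <- cfg$response
  qr <- query_store(store, ontologies, cfg$feature_class, cons)
  if (length(qr$samples) == 0L || length(qr$terms) == 0L) {
    empty_result_error("query matched no samples/terms")
  }
  tab <- filter_species_level(result_table(qr), ontologies$taxa)
  tab <- prevalence_filter(tab, cfg$min_cpm, cfg$min_fraction)$table
  if (length(table_terms(tab)) == 0L) {
    empty_result_error("no species-level terms retained")
  }
  rel <- relativize_taxa(tab, store$stats)
  filt <- drop_empty_samples(variance_filter(rel, cfg$variance_drop))
  clr <- clr_transform(filt)
  y <- qr$measurements[[cfg$response]][match(clr$samples, qr$samples)]
  fit <- elastic_net_select(clr$values, y, family = "gaussian",
                            alpha = cfg$alpha, n_folds = cfg$n_folds,
                            rule = cfg$rule, seed = cfg$seed)
  z <- if (length(fit$selected) >= 2L) zscale_coefficients(fit) else NULL
  list(query = qr, result = fit, zscores = z, matrix = clr)
}

recipe_indicators <- function(store, ontologies, cfg) {
  cons <- base_constraints(cfg)
  cons$required_measurements <- cfg$bin_measurement
  qr <- query_store(store, ontologies, cfg$feature_class, cons)
  if (length(qr$samples) == 0L || length(qr$terms) == 0L) {
    empty_result_error("query matched no samples/terms")
  }
  vals <- stats::setNames(qr$measurements[[cfg$bin_measurement]], qr$samples)
  bins <- bin_values(vals, cfg$thresholds, cfg$labels)
  groups <- bins$bins[qr$samples]
  if (length(unique(groups)) < 2L) {
    empty_result_error("binning produced fewer than 2 groups")
  }
  # indicator analysis runs on the raw (unnormalized) counts
  res <- indval(qr$counts, groups, n_perm = cfg$n_perm, seed = cfg$seed)
  list(query = qr, result = res, bins = bins)
}

recipe_binned_enet <- function(store, ontologies, cfg, kind) {
  cons <- base_constraints(cfg)
  cons$required_measurements <- cfg$bin_measurement
  qr <- query_store(store, ontologies, cfg$feature_class, cons)
  if (length(qr$samples) == 0L || length(qr$terms) == 0L) {
    empty_result_error("query matched no samples/terms")
  }
  vals <- stats::setNames(qr$measurements[[cfg$bin_measurement]], qr$samples)
  bins <- bin_values(vals, cfg$thresholds, cfg$labels)
  y <- bins$bins[qr$samples]
  if (length(unique(y)) < 2L) {
    empty_result_error("binning produced fewer than 2 groups")
  }
  tab <- result_table(qr)
  if (kind == "taxon") {
    tab <- filter_species_level(tab, ontologies$taxa)
    tab <- prevalence_filter(tab, cfg$min_cpm, cfg$min_fraction)$table
    if (length(table_terms(tab)) == 0L) {
      empty_result_error("no species-level terms retained")
    }
  }
  rel <- if (kind == "taxon") relativize_taxa(tab, store$stats)
  else relativize_functions(tab, store$stats)
  filt <- drop_empty_samples(variance_filter(rel, cfg$variance_drop))
  clr <- clr_transform(filt)
  fit <- elastic_net_select(clr$values, y[clr$samples], family = "binomial",
                            alpha = cfg$alpha, n_folds = cfg$n_folds,
                            rule = cfg$rule, seed = cfg$seed)
  list(query = qr, result = fit, bins = bins, matrix = clr)
}

write_recipe_output <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- out$result
  if (inherits(res, "enet_result")) {
    df <- data.frame(term = names(res$coefficients),
                     coefficient = unname(res$coefficients),
                     selected = names(res$coefficients) %in% res$selected,
                     stringsAsFactors = FALSE)
    df <- df[order(-abs(df$coefficient), df$term), ]
    df$coefficient <- sprintf("%.12g", df$coefficient)
    write_tsv_plain(df, file.path(out_dir, "coefficients.tsv"))
    if (!is.null(out$zscores)) {
      zdf <- data.frame(term = names(out$zscores$z),
                        z = sprintf("%.12g", out$zscores$z),
                        stringsAsFactors = FALSE)
      write_tsv_plain(zdf, file.path(out_dir, "zscores.tsv"))
    }
  } else if (inherits(res, "indicator_result")) {
    tab <- res$table
    for (col in c("A", "B", "stat", "p")) tab[[col]] <- sprintf("%.12g", tab[[col]])
    write_tsv_plain(tab, file.path(out_dir, "indicators.tsv"))
  }
  manifest <- list(recipe = out$recipe, config = out$config,
                   n_samples = length(out$query$samples),
                   n_terms = length(out$query$terms),
                   package_version = as.character(utils::packageVersion("ontomarine")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
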