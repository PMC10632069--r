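# Seeded synthetic data: ontologies, taxonomies and sample cohorts with
# planted structure emulating an ocean time-series corpus (depth
# gradients, oxygen-defined groups, multinomial count tables), so the
# whole engine is testable without external downloads.
#
# Every generator is a pure function of its seed: the same (design,
# seed) yields byte-identical outputs.

# Fixed fragment embedded in every GO-like ontology: a metabolic-process
# chain and a binding family, so worked subclass-query examples hold on
# every generated graph.
go_fixed_terms <- function() {
  list(
    list("GO:0003673", "gene ontology root", character()),
    list("GO:0008150", "biological process", "GO:0003673"),
    list("GO:0003674", "molecular function", "GO:0003673"),
    list("GO:0008152", "metabolic process", "GO:0008150"),
    list("GO:0044237", "cellular metabolic process", "GO:0008152"),
    list("GO:0015979", "photosynthesis", "GO:0044237"),
    list("GO:0006730", "one-carbon metabolic process", "GO:0044237"),
    list("GO:0015947", "methane metabolic process", "GO:0006730"),
    list("GO:0015948", "methanogenesis", "GO:0015947"),
    list("GO:0009061", "anaerobic respiration", "GO:0044237"),
    list("GO:0005488", "binding", "GO:0003674"),
    list("GO:0043169", "cation binding", "GO:0005488"),
    list("GO:0046872", "metal ion binding", "GO:0043169"),
    list("GO:0042301", "phosphate ion binding", "GO:0005488"),
    list("GO:0034618", "arginine binding", "GO:0005488"),
    list("GO:0016491", "oxidoreductase activity", "GO:0003674"),
    list("GO:0018492", "carbon-monoxide dehydrogenase (acceptor) activity",
         "GO:0016491"),
    list("GO:0042279", "nitrite reductase (cytochrome, ammonia-forming) activity",
         "GO:0016491"))
}

#' Generate a GO-like ontology
#'
#' A random DAG of `n_terms` synthetic terms grafted onto a fixed
#' metabolic-process / binding fragment (so e.g. photosynthesis and
#' methanogenesis are always recursive subclasses of cellular metabolic
#' process). Random terms take 1-3 parents among earlier terms, which
#' guarantees acyclicity; roughly a quarter are steered under the cation
#' binding subtree so function queries always find a populated family.
#'
#' @param seed RNG seed.
#' @param n_terms number of random terms to add (>= 20).
#' @return an `onto_graph` rooted at a single term.
#' @export
make_go_like_ontology <- function(seed, n_terms = 80L) {
  stopifnot(n_terms >= 20L)
  set.seed(seed)
  fixed <- go_fixed_terms()
  ids <- vapply(fixed, `[[`, character(1L), 1L)
  labels <- vapply(fixed, `[[`, character(1L), 2L)
  parents <- lapply(fixed, `[[`, 3L)

  cation_pool <- c("GO:0043169", "GO:0046872")
  for (k in seq_len(n_terms)) {
    id <- sprintf("GO:9%06d", k)
    n_par <- 1L + stats::rbinom(1L, 2L, 0.15)
    if (k %% 4L == 0L) {
      first <- sample(cation_pool, 1L)
      cation_pool <- c(cation_pool, id)
    } else {
      first <- sample(ids, 1L)
    }
    extra <- if (n_par > 1L) sample(setdiff(ids, first),
                                    min(n_par - 1L, length(ids) - 1L)) else character()
    ids <- c(ids, id)
    labels <- c(labels, sprintf("synthetic process %d", k))
    parents <- c(parents, list(c(first, extra)))
  }
  onto_graph(ids = ids, labels = labels, parents = parents)
}

taxon_rank_order <- c("no rank", "domain", "phylum", "class", "order",
                      "family", "genus", "species", "strain")

taxon_fixed_terms <- function() {
  list(
    list("NCBITaxon:1", "root", character(), "no rank"),
    list("NCBITaxon:131567", "cellular organisms", "NCBITaxon:1", "no rank"),
    list("NCBITaxon:2", "Bacteria", "NCBITaxon:131567", "domain"),
    list("NCBITaxon:1117", "Cyanobacteria", "NCBITaxon:2", "phylum"),
    list("NCBITaxon:1218", "Prochlorococcus", "NCBITaxon:1117", "genus"),
    list("NCBITaxon:1129", "Synechococcus", "NCBITaxon:1117", "genus"),
    list("NCBITaxon:1219", "Prochlorococcus marinus", "NCBITaxon:1218", "species"),
    list("NCBITaxon:167555", "Prochlorococcus marinus str. NATL1A",
         "NCBITaxon:1219", "strain"),
    list("NCBITaxon:59920", "Prochlorococcus marinus str. NATL2A",
         "NCBITaxon:1219", "strain"),
    list("NCBITaxon:93059", "Prochlorococcus marinus str. MIT 9211",
         "NCBITaxon:1219", "strain"),
    list("NCBITaxon:167539", "Prochlorococcus marinus subsp. marinus str. CCMP1375",
         "NCBITaxon:1219", "strain"),
    list("NCBITaxon:1501269", "Prochlorococcus sp. MIT 0801",
         "NCBITaxon:1218", "species"),
    list("NCBITaxon:32046", "Synechococcus elongatus", "NCBITaxon:1129", "species"),
    list("NCBITaxon:1140", "Synechococcus elongatus PCC 7942",
         "NCBITaxon:32046", "strain"),
    list("NCBITaxon:1224", "Proteobacteria", "NCBITaxon:2", "phylum"),
    list("NCBITaxon:28211", "Alphaproteobacteria", "NCBITaxon:1224", "class"),
    list("NCBITaxon:1236", "Gammaproteobacteria", "NCBITaxon:1224", "class"),
    list("NCBITaxon:976", "Bacteroidetes", "NCBITaxon:2", "phylum"))
}

#' Generate a ranked taxonomy tree
#'
#' A single-rooted tree embedding a fixed cyanobacterial backbone (the
#' Prochlorococcus genus with its named low-light strains, Synechococcus,
#' and a few other phyla/classes) plus `n_terms` random taxa. Every node
#' has exactly one parent and a rank strictly finer than its parent's
#' ranked ancestors; random taxa are steered in thirds toward the
#' Cyanobacteria and Alphaproteobacteria subtrees so the focal clades
#' carry enough species for regression designs.
#'
#' @param seed RNG seed.
#' @param n_terms number of random taxa to add (>= 30).
#' @return an `onto_graph` with `rank` filled.
#' @export
make_taxonomy <- function(seed, n_terms = 120L) {
  stopifnot(n_terms >= 30L)
  set.seed(seed)
  fixed <- taxon_fixed_terms()
  ids <- vapply(fixed, `[[`, character(1L), 1L)
  labels <- vapply(fixed, `[[`, character(1L), 2L)
  parents <- lapply(fixed, function(x) as.character(x[[3L]]))
  ranks <- vapply(fixed, `[[`, character(1L), 4L)

  next_rank <- function(r) {
    i <- match(r, taxon_rank_order)
    if (is.na(i) || r == "no rank") return("phylum")
    taxon_rank_order[[min(i + 1L, length(taxon_rank_order))]]
  }
  subtree_pool <- function(root) {
    pool <- c(root, ids[vapply(seq_along(ids), function(i)
      root %in% path_to_root(i), logical(1L))])
    pool[ranks[match(pool, ids)] != "strain"]
  }
  path_to_root <- function(i) {
    p <- parents[[i]]; out <- character()
    while (length(p) > 0L) {
      out <- c(out, p)
      j <- match(p, ids)
      p <- if (is.na(j)) character() else parents[[j]]
    }
    out
  }

  for (k in seq_len(n_terms)) {
    pool <- if (k %% 3L == 0L) subtree_pool("NCBITaxon:1117")
    else if (k %% 3L == 1L) subtree_pool("NCBITaxon:28211")
    else ids[ranks != "strain"]
    par <- sample(pool, 1L)
    id <- sprintf("NCBITaxon:9%06d", k)
    r <- next_rank(ranks[[match(par, ids)]])
    ids <- c(ids, id)
    labels <- c(labels, sprintf("synthetic taxon %d", k))
    parents <- c(parents, list(par))
    ranks <- c(ranks, r)
  }
  onto_graph(ids = ids, labels = labels, parents = parents, rank = ranks)
}

#' The fixed environment/parameter ontology
#'
#' A small ENVO-like vocabulary: water-body and zone classes for sample
#' context plus the physicochemical parameter terms (water depth,
#' dissolved oxygen, phosphate, dissolved inorganic carbon, cell counts)
#' used as measurement keys. Deterministic: no random part.
#'
#' @return an `onto_graph`.
#' @export
make_env_ontology <- function() {
  terms <- list(
    list("ENVO:01000254", "environmental system", character()),
    list("ENVO:00001999", "marine water body", "ENVO:01000254"),
    list("ENVO:00000015", "ocean", "ENVO:00001999"),
    list("ENVO:02000049", "coastal water body", "ENVO:00001999"),
    list("ENVO:00000213", "marine mesopelagic zone", "ENVO:00001999"),
    list("ENVO:01000061", "marine wind mixed layer", "ENVO:00001999"),
    list("ENVO:00000022", "river", "ENVO:01000254"),
    list("PMO:00000001", "measurement parameter", "ENVO:01000254"),
    list("ENVO:3100031", "depth of water", "PMO:00000001"),
    list("ENVO:3100011", "concentration of dioxygen in liquid water",
         "PMO:00000001"),
    list("ENVO:3100026", "concentration of phosphate in liquid water",
         "PMO:00000001"),
    list("PMO:00000142", "dissolved inorganic carbon", "PMO:00000001"),
    list("PMO:00000159", "Prochlorococcus cell count", "PMO:00000001"),
    list("PMO:00000160", "Synechococcus cell count", "PMO:00000001"))
  onto_graph(ids = vapply(terms, `[[`, character(1L), 1L),
             labels = vapply(terms, `[[`, character(1L), 2L),
             parents = lapply(terms, `[[`, 3L))
}

#' Simulation design for a synthetic cohort
#'
#' Defaults describe the emulated corpus: a vertical profile cohort with
#' post-QC read totals on the 10-million scale and ORF totals on the
#' 1-million scale, depth spanning the upper kilometer, an exponentially
#' declining oxygen profile, and planted monotone depth effects on terms
#' from the cation binding family and the Prochlorococcus strains. Pass
#' smaller `totals` for quick experiments.
#'
#' @param seed mandatory RNG seed.
#' @param n_samples cohort size (default 40).
#' @param depth_range depth span in meters, sampled on an even grid.
#' @param n_function_terms,n_taxon_terms random-term counts for the
#'   generated ontologies.
#' @param totals list: `n_reads_qc_mean`, `n_orfs_mean`, `raw_over_qc`
#'   (raw reads = qc reads x this factor).
#' @param planted_effects data.frame with columns `term`, `table`
#'   (`"function"`/`"taxon"`), `covariate` (`"depth"` or `"group"`),
#'   `strength` (log-scale slope per SD of depth; ignored for `"group"`
#'   terms, which become exclusive indicators of the anoxic group).
#'   `NULL` installs the default gradient plants.
#' @param group list defining the binary oxygen grouping: `threshold`
#'   (umol/kg, default 20) and `labels` (low then high, default
#'   `c("anoxic", "oxic")`).
#' @param dispersion Dirichlet overdispersion concentration applied on
#'   top of the per-term noise; `Inf` (default) draws exact multinomials.
#' @param noise_sd mean of the exponential distribution the per-term
#'   lognormal noise SDs are drawn from (default 1): most background
#'   terms wobble mildly between samples, a heavy tail of patchy terms
#'   fluctuates strongly, as taxa and gene families do across a water
#'   column.
#' @param planted_noise_sd lognormal noise SD of planted gradient terms
#'   (default 0.3: clean monotone profiles with individual variation).
#' @param qc_failures number of samples planted to fail quality control.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(seed, n_samples = 40L, depth_range = c(5, 1000),
                       n_function_terms = 80L, n_taxon_terms = 120L,
                       totals = list(), planted_effects = NULL,
                       group = list(), dispersion = Inf, noise_sd = 1.0,
                       planted_noise_sd = 0.3, qc_failures = 0L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  totals <- utils::modifyList(
    list(n_reads_qc_mean = 1e7, n_orfs_mean = 1e6, raw_over_qc = 1.1), totals)
  group <- utils::modifyList(
    list(threshold = 20, labels = c("anoxic", "oxic")), group)
  if (n_samples > 0 && qc_failures > n_samples) {
    stop("more planted failures than samples", call. = FALSE)
  }
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("term", "table", "covariate", "strength") %in%
                    names(planted_effects)),
              all(planted_effects$table %in% c("function", "taxon")),
              all(planted_effects$covariate %in% c("depth", "group")),
              all(is.finite(planted_effects$strength)))
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 depth_range = depth_range,
                 n_function_terms = as.integer(n_function_terms),
                 n_taxon_terms = as.integer(n_taxon_terms),
                 totals = totals, planted_effects = planted_effects,
                 group = group, dispersion = dispersion,
                 noise_sd = noise_sd, planted_noise_sd = planted_noise_sd,
                 qc_failures = as.integer(qc_failures)),
            class = "sim_design")
}

default_plants <- function(go, taxonomy) {
  # gradient terms: count-bearing cation binding descendants (functions)
  # and the named low-light strains (taxa), mostly declining with depth
  cation <- intersect(descendants(go, "GO:0043169"),
                      count_bearing_terms(go, "function"))
  cation <- utils::head(sort(cation), 5L)
  strains <- c("NCBITaxon:167555", "NCBITaxon:59920", "NCBITaxon:93059",
               "NCBITaxon:167539", "NCBITaxon:1501269")
  rbind(
    data.frame(term = cation, table = "function", covariate = "depth",
               strength = c(-1, -1, -1, 1, 1)[seq_along(cation)],
               stringsAsFactors = FALSE),
    data.frame(term = strains, table = "taxon", covariate = "depth",
               strength = -1, stringsAsFactors = FALSE))
}

count_bearing_terms <- function(g, kind) {
  live <- g$ids[!g$obsolete]
  if (kind == "function") {
    leaves <- live[vapply(g$children[live], length, integer(1L)) == 0L]
    sort(leaves)
  } else {
    ranked <- g$rank[live]
    sort(live[ranked %in% c("species", "strain", "genus")])
  }
}

o2_profile <- function(depth) 230 * exp(-depth / 250)

simulate_counts <- function(terms, total_by_sample, a, b, z, mask,
                            dispersion, tau) {
  # weight matrix: samples x terms on the log scale, with per-term
  # lognormal environmental noise of sd tau (patchy taxa wobble a lot,
  # gradient followers very little)
  W <- outer(z, b) + matrix(a, nrow = length(z), ncol = length(terms),
                            byrow = TRUE)
  W <- W + matrix(stats::rnorm(length(W)), nrow = nrow(W)) *
    rep(tau, each = nrow(W))
  W[mask] <- -Inf
  counts <- matrix(0L, nrow = length(z), ncol = length(terms),
                   dimnames = list(names(total_by_sample), terms))
  expected <- matrix(0, nrow = length(z), ncol = length(terms),
                     dimnames = list(names(total_by_sample), terms))
  for (j in seq_along(z)) {
    w <- W[j, ]
    p <- exp(w - max(w[is.finite(w)]))
    p[!is.finite(w)] <- 0
    p <- p / sum(p)
    expected[j, ] <- p
    if (is.finite(dispersion)) {
      alpha <- dispersion * p
      gam <- stats::rgamma(length(p), shape = alpha)
      gam[alpha == 0] <- 0
      p <- gam / sum(gam)
    }
    counts[j, ] <- stats::rmultinom(1L, size = total_by_sample[[j]], prob = p)
  }
  list(counts = counts, expected = expected)
}

#' Simulate a synthetic cohort
#'
#' Generates ontologies, sample metadata with a depth/oxygen/phosphate
#' gradient, per-sample pipeline totals, and multinomial function and
#' taxon count tables with the design's planted effects. The returned
#' ledger records everything a test oracle needs: planted terms and
#' strengths, per-sample totals and covariates, expected relative
#' abundances, group labels and planted QC failures.
#'
#' @param design a `sim_design`.
#' @return list with `metadata` (a `sample_metadata`), `stats`
#'   (`sample_stats`), `functions` and `taxa` (`feature_table`s),
#'   `ontologies` (list `functions`, `taxa`, `env`), `store` (assembled
#'   `sample_store`), `ledger`.
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  go <- make_go_like_ontology(design$seed, design$n_function_terms)
  tax <- make_taxonomy(design$seed + 1L, design$n_taxon_terms)
  env <- make_env_ontology()
  plants <- design$planted_effects %||% default_plants(go, tax)
  for (tbl in c("function", "taxon")) {
    g <- if (tbl == "function") go else tax
    missing <- setdiff(plants$term[plants$table == tbl], g$ids)
    if (length(missing) > 0L) {
      stop("planted terms absent from the generated ontology: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  n <- design$n_samples
  set.seed(design$seed + 2L)
  if (n == 0L) {
    empty_md <- structure(list(
      samples = data.frame(sample_id = character(), project_id = character(),
                           depth_m = numeric(), latitude = numeric(),
                           longitude = numeric(), collected_at = character()),
      env = data.frame(sample_id = character(), term_id = character()),
      measurements = data.frame(sample_id = character(), term_id = character(),
                                value = numeric(), unit = character())),
      class = "sample_metadata")
    stats <- sample_stats(data.frame(sample_id = character(),
                                     n_reads_raw = integer(),
                                     n_reads_qc = integer(),
                                     n_orfs = integer()))
    store <- build_store(stats = stats, metadata = empty_md)
    return(list(metadata = empty_md, stats = stats,
                functions = store$functions, taxa = store$taxa,
                ontologies = list(functions = go, taxa = tax, env = env),
                store = store,
                ledger = list(design = unclass(design), samples = character())))
  }

  sample_ids <- sprintf("S%03d", seq_len(n))
  depth <- seq(design$depth_range[[1L]], design$depth_range[[2L]],
               length.out = n)
  z <- as.numeric(scale(depth))
  oxygen <- pmax(0, o2_profile(depth) + stats::rnorm(n, 0, 3))
  phosphate <- pmax(0, 0.1 + 2.8 * depth / 1000 + stats::rnorm(n, 0, 0.05))
  dic <- 1900 + 150 * depth / 1000 + stats::rnorm(n, 0, 10)
  groups <- ifelse(oxygen < design$group$threshold,
                   design$group$labels[[1L]], design$group$labels[[2L]])

  tot <- design$totals
  n_reads_qc <- round(tot$n_reads_qc_mean * exp(stats::rnorm(n, 0, 0.05)))
  n_orfs <- round(tot$n_orfs_mean * exp(stats::rnorm(n, 0, 0.05)))
  n_reads_raw <- round(n_reads_qc * tot$raw_over_qc)

  # planted QC failures: first half low raw reads, second half low richness
  fail_ids <- character(); fail_reason <- character()
  restricted <- rep(FALSE, n)
  if (design$qc_failures > 0L) {
    fail_idx <- sample.int(n, design$qc_failures)
    n_low_reads <- ceiling(design$qc_failures / 2)
    low_read_idx <- fail_idx[seq_len(n_low_reads)]
    low_rich_idx <- setdiff(fail_idx, low_read_idx)
    n_reads_raw[low_read_idx] <- round(0.25 * tot$n_reads_qc_mean *
                                         tot$raw_over_qc)
    n_reads_qc[low_read_idx] <- pmin(n_reads_qc[low_read_idx],
                                     n_reads_raw[low_read_idx])
    restricted[low_rich_idx] <- TRUE
    fail_ids <- sample_ids[fail_idx]
    fail_reason <- ifelse(fail_idx %in% low_read_idx,
                          "min_raw_reads", "min_unique_taxa")
  }

  build_table <- function(kind, ontology, totals_vec) {
    terms <- count_bearing_terms(ontology, kind)
    a <- stats::rnorm(length(terms), 0, 1.2)
    names(a) <- terms
    # capped exponential: a heavy but bounded tail of patchy terms, so no
    # single term can swallow a whole sample
    tau <- stats::setNames(
      pmin(stats::rexp(length(terms), 1 / design$noise_sd),
           2.5 * design$noise_sd), terms)
    b <- stats::setNames(rep(0, length(terms)), terms)
    pl <- plants[plants$table == kind, , drop = FALSE]
    depth_pl <- pl[pl$covariate == "depth", , drop = FALSE]
    b[depth_pl$term] <- depth_pl$strength
    # gradient plants follow the covariate cleanly at moderate base
    # abundance: the emulated corpus has gradient-following genes of
    # middling share whose variance does not dominate the patchy,
    # strongly fluctuating background families
    a[depth_pl$term] <- -0.5
    tau[depth_pl$term] <- design$planted_noise_sd
    ind_terms <- pl$term[pl$covariate == "group"]
    mask <- matrix(FALSE, nrow = n, ncol = length(terms),
                   dimnames = list(sample_ids, terms))
    if (length(ind_terms) > 0L) {
      a[ind_terms] <- max(a) + 1  # high base abundance: full occupancy
      tau[ind_terms] <- design$planted_noise_sd
      mask[groups != design$group$labels[[1L]], ind_terms] <- TRUE
    }
    if (any(restricted)) {
      # richness-failure samples only ever see a handful of terms
      keep <- utils::head(terms, 5L)
      mask[restricted, setdiff(terms, keep)] <- TRUE
    }
    names(totals_vec) <- sample_ids
    sim <- simulate_counts(terms, totals_vec, a, b, z, mask,
                           design$dispersion, tau)
    e <- sim$counts
    long <- data.frame(
      sample_id = rep(rownames(e), times = ncol(e)),
      term_id = rep(colnames(e), each = nrow(e)),
      count = as.vector(e), stringsAsFactors = FALSE)
    long <- long[long$count > 0, ]
    list(table = feature_table(long, kind = kind),
         expected = sim$expected, base = a, slope = b)
  }

  fun <- build_table("function", go, n_orfs)
  txn <- build_table("taxon", tax, n_reads_qc)

  env_class <- ifelse(depth >= 200 & depth < 1000, "ENVO:00000213",
                      "ENVO:01000061")
  md_samples <- data.frame(
    sample_id = sample_ids, project_id = "HOT_SYN",
    depth_m = depth, latitude = 22.75, longitude = -158,
    collected_at = format(as.Date("2020-01-01") + seq_len(n),
                          "%Y-%m-%dT00:00:00Z"),
    stringsAsFactors = FALSE)
  md_env <- data.frame(sample_id = sample_ids, term_id = env_class,
                       stringsAsFactors = FALSE)
  md_meas <- rbind(
    data.frame(sample_id = sample_ids, term_id = "ENVO:3100031",
               value = depth, unit = "m", stringsAsFactors = FALSE),
    data.frame(sample_id = sample_ids, term_id = "ENVO:3100011",
               value = oxygen, unit = "umol/kg", stringsAsFactors = FALSE),
    data.frame(sample_id = sample_ids, term_id = "ENVO:3100026",
               value = phosphate, unit = "umol/kg", stringsAsFactors = FALSE),
    data.frame(sample_id = sample_ids, term_id = "PMO:00000142",
               value = dic, unit = "umol/kg", stringsAsFactors = FALSE))
  metadata <- structure(list(samples = md_samples, env = md_env,
                             measurements = md_meas),
                        class = "sample_metadata")
  stats <- sample_stats(data.frame(
    sample_id = sample_ids, n_reads_raw = n_reads_raw,
    n_reads_qc = n_reads_qc, n_orfs = n_orfs, stringsAsFactors = FALSE))
  store <- build_store(functions = fun$table, taxa = txn$table,
                       stats = stats, metadata = metadata)

  ledger <- list(
    design = unclass(design),
    samples = sample_ids,
    depth = stats::setNames(depth, sample_ids),
    z = stats::setNames(z, sample_ids),
    oxygen = stats::setNames(oxygen, sample_ids),
    groups = stats::setNames(groups, sample_ids),
    totals = data.frame(sample_id = sample_ids, n_reads_raw = n_reads_raw,
                        n_reads_qc = n_reads_qc, n_orfs = n_orfs,
                        stringsAsFactors = FALSE),
    planted = plants,
    qc_failures = data.frame(sample_id = fail_ids, reason = fail_reason,
                             stringsAsFactors = FALSE),
    qc_thresholds = list(
      min_raw_reads = round(0.5 * tot$n_reads_qc_mean * tot$raw_over_qc),
      min_unique_taxa = 20),
    expected_function = fun$expected[, plants$term[plants$table == "function"],
                                     drop = FALSE],
    expected_taxon = txn$expected[, plants$term[plants$table == "taxon"],
                                  drop = FALSE])

  list(metadata = metadata, stats = stats, functions = fun$table,
       taxa = txn$table,
       ontologies = list(functions = go, taxa = tax, env = env),
       store = store, ledger = ledger)
}

#' Write a loadable fixture bundle to disk
#'
#' Serializes a simulated cohort as the plain-text formats the store
#' readers consume (OBO ontologies, TSV count/stats/metadata tables), a
#' JSON ledger of the planted structure, and a manifest of MD5 file
#' hashes. The bundle round-trips through [read_count_table()],
#' [read_sample_stats()], [read_sample_metadata()] and [parse_obo()].
#'
#' @param dir output directory (created if needed).
#' @param design a `sim_design`.
#' @return the manifest (named MD5 strings), invisibly; also written as
#'   `manifest.json`.
#' @export
write_fixture_bundle <- function(dir, design) {
  sim <- simulate_dataset(design)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_obo(sim$ontologies$functions, p("go.obo"))
  write_obo(sim$ontologies$taxa, p("taxonomy.obo"))
  write_obo(sim$ontologies$env, p("env.obo"))
  write_count_table(sim$functions, p("functions.tsv"))
  write_count_table(sim$taxa, p("taxa.tsv"))
  write_tsv_plain(as.data.frame(sim$stats), p("stats.tsv"))
  write_metadata_tsv(sim$metadata, p("metadata.tsv"))
  ledger <- sim$ledger
  ledger$depth <- as.list(ledger$depth)
  ledger$z <- as.list(ledger$z)
  ledger$oxygen <- as.list(ledger$oxygen)
  ledger$groups <- as.list(ledger$groups)
  ledger$expected_function <- NULL  # matrices stay in-memory only
  ledger$expected_taxon <- NULL
  jsonlite::write_json(ledger, p("ledger.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("go.obo", "taxonomy.obo", "env.obo", "functions.tsv",
             "taxa.tsv", "stats.tsv", "metadata.tsv", "ledger.json")
  manifest <- tools::md5sum(file.path(dir, files))
  names(manifest) <- files
  jsonlite::write_json(as.list(manifest), p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

write_metadata_tsv <- function(metadata, path) {
  s <- metadata$samples
  env_col <- vapply(s$sample_id, function(id) {
    paste(sort(metadata$env$term_id[metadata$env$sample_id == id]),
          collapse = "|")
  }, character(1L))
  df <- data.frame(sample_id = s$sample_id, project_id = s$project_id,
                   env_classes = env_col, depth_m = s$depth_m,
                   latitude = s$latitude, longitude = s$longitude,
                   collected_at = s$collected_at,
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- metadata$measurements
  for (term in sort(unique(m$term_id))) {
    rows <- m[m$term_id == term, ]
    col <- sprintf("%s[%s]", term, rows$unit[[1L]])
    df[[col]] <- rows$value[match(s$sample_id, rows$sample_id)]
  }
  write_tsv_plain(df, path)
}

#' Load a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir bundle directory.
#' @return list with `store`, `ontologies` and the parsed `ledger`.
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  ontologies <- list(functions = parse_obo(p("go.obo")),
                     taxa = parse_obo(p("taxonomy.obo")),
                     env = parse_obo(p("env.obo")))
  metadata <- read_sample_metadata(p("metadata.tsv"),
                                   env_ontology = ontologies$env)
  store <- build_store(
    functions = read_count_table(p("functions.tsv"), "function"),
    taxa = read_count_table(p("taxa.tsv"), "taxon"),
    stats = read_sample_stats(p("stats.tsv")),
    metadata = metadata)
  ledger <- jsonlite::read_json(p("ledger.json"), simplifyVector = TRUE)
  list(store = store, ontologies = ontologies, ledger = ledger)
}
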