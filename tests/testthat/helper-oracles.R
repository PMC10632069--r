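# Shared fixtures and independent oracles. The oracles deliberately use
# naive algorithms (repeated-scan BFS, double loops) so they share no
# code path with the package.

# Small hand-written OBO fixture: the metabolic chain and binding family.
go_fixture_obo <- function() {
  c("format-version: 1.2",
    "",
    "[Term]", "id: GO:0003673", "name: gene ontology root",
    "",
    "[Term]", "id: GO:0008150", "name: biological process",
    "is_a: GO:0003673 ! gene ontology root",
    "",
    "[Term]", "id: GO:0008152", "name: metabolic process",
    "is_a: GO:0008150",
    "",
    "[Term]", "id: GO:0044237", "name: cellular metabolic process",
    "is_a: GO:0008152",
    "",
    "[Term]", "id: GO:0015979", "name: photosynthesis",
    "is_a: GO:0044237",
    "",
    "[Term]", "id: GO:0006730", "name: one-carbon metabolic process",
    "is_a: GO:0044237",
    "",
    "[Term]", "id: GO:0015947", "name: methane metabolic process",
    "is_a: GO:0006730",
    "",
    "[Term]", "id: GO:0015948", "name: methanogenesis",
    "is_a: GO:0015947",
    "",
    "[Term]", "id: GO:0003674", "name: molecular function",
    "is_a: GO:0003673",
    "",
    "[Term]", "id: GO:0005488", "name: binding",
    "is_a: GO:0003674",
    "",
    "[Term]", "id: GO:0043169", "name: cation binding",
    "is_a: GO:0005488")
}

go_fixture <- function() parse_obo(text = go_fixture_obo())

# Independent random-DAG generator: node k picks parents among nodes
# 1..k-1, so acyclicity holds by construction. Returns plain adjacency.
oracle_random_dag <- function(seed, n) {
  set.seed(seed * 7919L)
  ids <- sprintf("T:%04d", seq_len(n))
  parents <- vector("list", n)
  parents[[1L]] <- character()
  for (k in seq_len(n)[-1L]) {
    np <- sample(1:min(3L, k - 1L), 1L)
    parents[[k]] <- sort(sample(ids[seq_len(k - 1L)], np))
  }
  names(parents) <- ids
  list(ids = ids, parents = parents)
}

# Naive reachability: repeatedly expand a frontier by scanning the full
# parent map each round.
oracle_ancestor_set <- function(parents, start) {
  out <- character(); frontier <- parents[[start]]
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- unique(unlist(parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  sort(out)
}

oracle_descendant_set <- function(parents, start) {
  ids <- names(parents)
  sort(Filter(function(x) start %in% oracle_ancestor_set(parents, x), ids))
}

dag_as_graph <- function(dag) {
  onto_graph(ids = dag$ids, parents = dag$parents)
}

# Brute-force intersection query: double loop over metadata samples and
# all table entries applying each predicate literally.
oracle_query <- function(store, ontologies, feature_class, constraints) {
  g <- if (startsWith(feature_class, "GO")) ontologies$functions else ontologies$taxa
  table <- if (startsWith(feature_class, "GO")) store$functions else store$taxa
  terms_all <- sort(union(feature_class,
                          oracle_descendant_set_graph(g, feature_class)))
  md <- store$metadata
  keep <- character()
  for (s in md$samples$sample_id) {
    row <- md$samples[md$samples$sample_id == s, ]
    ok <- TRUE
    if (!is.null(constraints$project_id) &&
        row$project_id != constraints$project_id) ok <- FALSE
    if (ok && !is.null(constraints$env_class)) {
      cls <- union(constraints$env_class,
                   oracle_descendant_set_graph(ontologies$env,
                                               constraints$env_class))
      mine <- md$env$term_id[md$env$sample_id == s]
      if (!any(mine %in% cls)) ok <- FALSE
    }
    if (ok) for (m in constraints$required_measurements) {
      v <- md$measurements$value[md$measurements$sample_id == s &
                                   md$measurements$term_id == m]
      if (length(v) == 0L || all(is.na(v))) ok <- FALSE
    }
    if (ok && !is.null(constraints$depth_range)) {
      d <- row$depth_m
      r <- constraints$depth_range
      if (is.na(d) || d < r[1] || d >= r[2]) ok <- FALSE
    }
    if (ok) {
      hit <- any(table$entries$sample_id == s &
                   table$entries$term_id %in% terms_all &
                   table$entries$count > 0)
      if (hit) keep <- c(keep, s)
    }
  }
  present <- sort(unique(table$entries$term_id[
    table$entries$sample_id %in% keep &
      table$entries$term_id %in% terms_all & table$entries$count > 0]))
  list(samples = keep, terms = present)
}

# descendant set via the naive scan, but over an onto_graph's parent map
oracle_descendant_set_graph <- function(g, start) {
  live <- g$ids[!g$obsolete]
  parents <- g$parents[live]
  out <- Filter(function(x) {
    start %in% oracle_ancestor_set_graph(g, x)
  }, setdiff(live, start))
  sort(unlist(out, use.names = FALSE) %||% character())
}

oracle_ancestor_set_graph <- function(g, start) {
  out <- character(); frontier <- g$parents[[start]]
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(g$parents[frontier], use.names = FALSE)),
                        out)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# standard small synthetic cohort used by several test files
small_sim <- function(seed = 11L, n_samples = 30L, ...) {
  simulate_dataset(sim_design(
    seed = seed, n_samples = n_samples,
    totals = list(n_reads_qc_mean = 5e4, n_orfs_mean = 5e4), ...))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
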