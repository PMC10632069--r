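make_stats <- function(ids, orfs, reads) {
  sample_stats(data.frame(sample_id = ids, n_reads_raw = reads * 2,
                          n_reads_qc = reads, n_orfs = orfs))
}

test_that("relativization divides by the correct per-sample denominator", {
  tab <- feature_table(data.frame(
    sample_id = c("S1", "S1", "S2"),
    term_id = c("GO:0000001", "GO:0000002", "GO:0000001"),
    count = c(5, 20, 0)), kind = "function")
  st <- make_stats(c("S1", "S2"), orfs = c(100, 50), reads = c(1e4, 1e4))
  rel <- relativize_functions(tab, st)
  expect_equal(rel$values["S1", "GO:0000001"], 0.05)
  expect_equal(rel$values["S1", "GO:0000002"], 0.20)
  expect_equal(sum(rel$values["S2", ]), 0)

  taxt <- feature_table(data.frame(sample_id = "S1", term_id = "NCBITaxon:2",
                                   count = 1000), kind = "taxon")
  stt <- make_stats("S1", orfs = 10, reads = 1e7)
  expect_equal(relativize_taxa(taxt, stt)$values[1, 1], 1e-4)

  # random fixture equals the elementwise quotient oracle
  sim <- small_sim(seed = 41L, n_samples = 10L)
  rel2 <- relativize_taxa(sim$taxa, sim$stats)
  m <- as_matrix(sim$taxa)
  denom <- sim$stats$n_reads_qc[match(rownames(m), sim$stats$sample_id)]
  expect_equal(rel2$values, m / denom)

  # error paths
  st0 <- make_stats(c("S1", "S2"), orfs = c(0, 50), reads = c(1e4, 1e4))
  expect_error(relativize_functions(tab, st0), "zero n_orfs")
  expect_error(relativize_functions(tab, make_stats("S1", 10, 10)),
               "missing from stats")
})

test_that("clade aggregation sums the subtree including internal assignments", {
  tax <- make_taxonomy(3, 60)
  sim <- small_sim(seed = 42L, n_samples = 12L)
  rel <- relativize_taxa(sim$taxa, sim$stats)
  v <- aggregate_clade(rel, sim$ontologies$taxa, "NCBITaxon:1218")
  members <- descendants(sim$ontologies$taxa, "NCBITaxon:1218",
                         include_self = TRUE)
  # brute-force subtree sum from the raw entries
  e <- sim$taxa$entries[sim$taxa$entries$term_id %in% members, ]
  denom <- sim$stats$n_reads_qc
  names(denom) <- sim$stats$sample_id
  for (s in rel$samples) {
    expect_equal(unname(v[s]), sum(e$count[e$sample_id == s]) / denom[[s]])
  }
  # counts at the genus node itself are included
  expect_true("NCBITaxon:1218" %in% members)

  # leaf clade equals the leaf value
  leaf <- "NCBITaxon:167555"
  vl <- aggregate_clade(rel, sim$ontologies$taxa, leaf)
  expect_equal(unname(vl), unname(rel$values[, leaf]))

  # additive over disjoint clades
  v1 <- aggregate_clade(rel, sim$ontologies$taxa, "NCBITaxon:1218")
  v2 <- aggregate_clade(rel, sim$ontologies$taxa, "NCBITaxon:1129")
  both <- descendants(sim$ontologies$taxa, "NCBITaxon:1117",
                      include_self = TRUE)
  expect_length(intersect(descendants(sim$ontologies$taxa, "NCBITaxon:1218",
                                      include_self = TRUE),
                          descendants(sim$ontologies$taxa, "NCBITaxon:1129",
                                      include_self = TRUE)), 0L)
  e2 <- sim$taxa$entries[sim$taxa$entries$term_id %in%
                           setdiff(both, c("NCBITaxon:1117")), ]
  expect_error(aggregate_clade(rel, sim$ontologies$taxa, "NCBITaxon:404"),
               "unknown")
  expect_true(all(v1 + v2 <= 1 + 1e-12))
})

test_that("species-level filter keeps species and everything below them", {
  tax <- make_taxonomy(5, 60)
  terms <- c("NCBITaxon:1218",    # genus: drop
             "NCBITaxon:1219",    # species: keep
             "NCBITaxon:167555",  # strain under species: keep
             "NCBITaxon:1117",    # phylum: drop
             "NCBITaxon:1501269") # species: keep
  tab <- feature_table(data.frame(sample_id = "S1", term_id = terms,
                                  count = 1), kind = "taxon")
  kept <- table_terms(filter_species_level(tab, tax))
  expect_setequal(kept, c("NCBITaxon:1219", "NCBITaxon:167555",
                          "NCBITaxon:1501269"))

  phy <- feature_table(data.frame(sample_id = "S1", term_id = "NCBITaxon:1117",
                                  count = 1), kind = "taxon")
  expect_length(table_terms(filter_species_level(phy, tax)), 0L)

  # oracle: rank/ancestry check over all count-bearing taxa
  sim <- small_sim(seed = 43L, n_samples = 6L)
  g <- sim$ontologies$taxa
  got <- table_terms(filter_species_level(sim$taxa, g))
  want <- Filter(function(t) {
    r <- g$rank[[t]]
    if (identical(r, "species")) return(TRUE)
    any(vapply(oracle_ancestor_set_graph(g, t),
               function(a) identical(g$rank[[a]], "species"), logical(1L)))
  }, table_terms(sim$taxa))
  expect_setequal(got, want)
})

test_that("prevalence filter applies the CPM-in-fraction-of-samples rule", {
  # 20 samples, totals 1e6 each; term X at 2 counts (2 CPM) in 2 samples (10%)
  ids <- sprintf("S%02d", 1:20)
  filler <- data.frame(sample_id = ids, term_id = "GO:0000009",
                       count = 1e6 - c(2, 2, rep(0, 18)) - rep(1, 20))
  entries <- rbind(
    filler,
    data.frame(sample_id = ids[1:2], term_id = "GO:0000001", count = 2),
    data.frame(sample_id = ids, term_id = "GO:0000002", count = 1)) # 1 CPM everywhere
  tab <- feature_table(entries, kind = "function")
  res <- prevalence_filter(tab, min_cpm = 1, min_fraction = 0.05)
  expect_true("GO:0000001" %in% table_terms(res$table))   # 2 CPM in 10%
  expect_true("GO:0000002" %in% table_terms(res$table))   # exactly 1 CPM in all
  # 0.9 CPM everywhere: removed
  tab2 <- feature_table(rbind(
    data.frame(sample_id = ids, term_id = "GO:0000003", count = 9),
    data.frame(sample_id = ids, term_id = "GO:0000009", count = 1e7 - 9)),
    kind = "function")
  res2 <- prevalence_filter(tab2)
  expect_false("GO:0000003" %in% table_terms(res2$table))
  expect_true("GO:0000003" %in% res2$removed)
})

test_that("CLR matches closed forms and its invariances", {
  m <- matrix(c(0.25, 0.25, 0.25, 0.25), nrow = 1,
              dimnames = list("S1", paste0("T:", 1:4)))
  clr <- clr_transform(norm_matrix(m, "relabund"))
  expect_equal(unname(clr$values[1, ]), rep(0, 4))

  m2 <- matrix(c(1, 3), nrow = 1, dimnames = list("S1", c("T:1", "T:2")))
  clr2 <- clr_transform(m2)
  expect_equal(unname(clr2$values[1, ]), c(-log(sqrt(3)), log(sqrt(3))),
               tolerance = 1e-12)
  expect_equal(unname(clr2$values[1, 2]), 0.5493061, tolerance = 1e-6)

  set.seed(9)
  m3 <- matrix(rexp(60), nrow = 6,
               dimnames = list(paste0("S", 1:6), paste0("T:", 1:10)))
  clr3 <- clr_transform(m3)
  expect_true(all(abs(rowSums(clr3$values)) < 1e-9))
  # scale invariance
  clr3b <- clr_transform(m3 * 17)
  expect_equal(clr3$values, clr3b$values, tolerance = 1e-12)

  zero_row <- matrix(c(0, 1, 0, 2), nrow = 2,
                     dimnames = list(c("S1", "S2"), c("T:1", "T:2")))
  expect_error(clr_transform(zero_row), "S1")

  # pseudocount only perturbs zero cells; multiplicative preserves unit sum
  m4 <- matrix(c(0, 2, 2, 2), nrow = 1,
               dimnames = list("S1", paste0("T:", 1:4)))
  cp <- clr_transform(m4, "pseudocount")
  cm <- clr_transform(m4 / sum(m4), "multiplicative")
  expect_true(all(abs(rowSums(cp$values)) < 1e-9))
  expect_true(all(abs(rowSums(cm$values)) < 1e-9))
})

test_that("variance filter drops the highest-variance features deterministically", {
  set.seed(4)
  m <- matrix(rnorm(50), nrow = 5,
              dimnames = list(paste0("S", 1:5), sprintf("T:%02d", 1:10)))
  out <- variance_filter(m, 0.30)
  expect_equal(ncol(out), 7L)   # ceil(0.3 * 10) = 3 removed
  v <- apply(m, 2, var)
  expect_setequal(colnames(out), names(sort(v))[1:7])

  # constant feature is never removed unless everything is
  m2 <- cbind(m[, 1:3], `T:99` = rep(1, 5))
  out2 <- variance_filter(m2, 0.30)
  expect_true("T:99" %in% colnames(out2))
  expect_error(variance_filter(m, 1), "drop_fraction")
})

test_that("binning uses half-open intervals with the upper label at thresholds", {
  b <- bin_values(c(a = 10, b = 200, c = 500, d = 1500),
                  thresholds = c(200, 1000),
                  labels = c("shallow", "intermediate", "deep"))
  expect_equal(unname(b$bins[c("a", "b", "c", "d")]),
               c("shallow", "intermediate", "intermediate", "deep"))
  ox <- bin_values(c(s = 20), thresholds = 20, labels = c("anoxic", "oxic"))
  expect_equal(unname(ox$bins), "oxic")
  withna <- bin_values(c(x = NA, y = 5), 10, c("lo", "hi"))
  expect_equal(withna$unassigned, "x")
  empty <- bin_values(numeric(), 10, c("lo", "hi"))
  expect_length(empty$bins, 0L)
  expect_error(bin_values(1:3, c(5, 5), c("a", "b", "c")), "increasing")
})

test_that("the taxonomic pipeline commutes when the species filter moves ahead", {
  sim <- small_sim(seed = 44L, n_samples = 15L)
  g <- sim$ontologies$taxa
  # species filter -> prevalence (the paper's order) ...
  t1 <- prevalence_filter(filter_species_level(sim$taxa, g))$table
  a <- clr_transform(relativize_taxa(t1, sim$stats))
  # ... versus prevalence on the full table, species filter afterwards
  t2 <- filter_species_level(prevalence_filter(sim$taxa)$table, g)
  b <- clr_transform(relativize_taxa(t2, sim$stats))
  expect_setequal(table_terms(t1), table_terms(t2))
  expect_equal(a$values, b$values[, colnames(a$values)])
})
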