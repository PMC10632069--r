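test_that("count tables read from TSV with validation and duplicate summing", {
  path <- write_lines_tmp(c("sample_id\tterm_id\tcount",
                            "S1\tGO:0000001\t5",
                            "S1\tGO:0000002\t2",
                            "S2\tGO:0000001\t7"))
  tab <- read_count_table(path, "function")
  expect_equal(nrow(tab$entries), 3L)
  expect_equal(annotation_richness(tab, "S1"), 2L)
  expect_equal(annotation_richness(tab, "S2"), 1L)

  dup <- write_lines_tmp(c("sample_id\tterm_id\tcount",
                           "S1\tGO:0000001\t5",
                           "S1\tGO:0000001\t3"))
  expect_warning(tab2 <- read_count_table(dup, "function"), "duplicate")
  expect_equal(tab2$entries$count, 8)

  hdr <- write_lines_tmp("sample_id\tterm_id\tcount")
  expect_equal(nrow(read_count_table(hdr, "taxon")$entries), 0L)

  bad <- write_lines_tmp(c("sample_id\tterm_id\tcount",
                           "S1\tGO:0000001\t2.5"))
  expect_error(read_count_table(bad, "function"), "line 2")
  badc <- write_lines_tmp(c("sample_id\tterm_id\tcount",
                            "S1\tnot_a_curie\t2"))
  expect_error(read_count_table(badc, "function"), "CURIE")
})

test_that("metadata reading types fields, parses measurement columns, validates ranges", {
  env <- make_env_ontology()
  path <- write_lines_tmp(c(
    paste("sample_id", "project_id", "env_classes", "depth_m", "latitude",
          "longitude", "collected_at", "ENVO:3100011[umol/kg]", sep = "\t"),
    paste("S1", "P", "ENVO:00000213|ENVO:00001999", "450", "22.75", "-158",
          "2020-06-01T00:00:00Z", "2.5", sep = "\t"),
    paste("S2", "P", "", "", "", "", "", "", sep = "\t")))
  md <- read_sample_metadata(path, env_ontology = env)
  expect_equal(md$samples$depth_m, c(450, NA))
  expect_setequal(md$env$term_id[md$env$sample_id == "S1"],
                  c("ENVO:00000213", "ENVO:00001999"))
  expect_equal(md$measurements$value, 2.5)
  expect_equal(md$measurements$unit, "umol/kg")
  expect_equal(nrow(md$env[md$env$sample_id == "S2", ]), 0L)

  bad <- write_lines_tmp(c(
    paste("sample_id", "project_id", "env_classes", "depth_m", "latitude",
          "longitude", "collected_at", sep = "\t"),
    paste("S1", "P", "", "10", "95", "0", "", sep = "\t")))
  expect_error(read_sample_metadata(bad), "out-of-range")

  unresolved <- write_lines_tmp(c(
    paste("sample_id", "project_id", "env_classes", "depth_m", "latitude",
          "longitude", "collected_at", sep = "\t"),
    paste("S1", "P", "ENVO:99999999", "10", "0", "0", "", sep = "\t")))
  expect_error(read_sample_metadata(unresolved, env_ontology = env),
               "ENVO:99999999")
})

test_that("sample stats validate totals and the raw >= qc invariant", {
  expect_error(sample_stats(data.frame(sample_id = "S1", n_reads_raw = 10,
                                       n_reads_qc = 20, n_orfs = 5)),
               "exceeds")
  st <- sample_stats(data.frame(sample_id = "S1", n_reads_raw = 20,
                                n_reads_qc = 10, n_orfs = 5))
  expect_true(is.na(st$n_unique_taxa))
})

test_that("QC removes below-threshold samples and keeps boundary values", {
  st <- sample_stats(data.frame(
    sample_id = c("A", "B", "C", "D"),
    n_reads_raw = c(4999999, 5000000, 8e6, 8e6),
    n_reads_qc = c(4e6, 5e6, 7e6, 7e6),
    n_orfs = rep(1e5, 4),
    n_unique_taxa = c(50000, 10000, 9999, 10001),
    n_unique_go = rep(NA, 4)))
  store <- build_store(stats = st)
  res <- qc_filter_samples(store)
  expect_setequal(res$store$stats$sample_id, c("B", "D"))
  expect_equal(res$report$reason[res$report$sample_id == "A"],
               "min_raw_reads")
  expect_equal(res$report$reason[res$report$sample_id == "C"],
               "min_unique_taxa")
})

test_that("QC on a planted cohort removes exactly the planted failures", {
  sim <- small_sim(seed = 21L, n_samples = 20L, qc_failures = 6L)
  thr <- sim$ledger$qc_thresholds
  res <- qc_filter_samples(sim$store, thr$min_raw_reads, thr$min_unique_taxa)
  expect_setequal(res$report$sample_id, sim$ledger$qc_failures$sample_id)
  got <- res$report[order(res$report$sample_id), ]
  want <- sim$ledger$qc_failures[order(sim$ledger$qc_failures$sample_id), ]
  expect_equal(got$reason, want$reason)
  # retained order is preserved
  expect_equal(res$store$stats$sample_id,
               setdiff(sim$stats$sample_id, res$report$sample_id))
})

test_that("QC errors when a table sample has no statistics", {
  tab <- feature_table(data.frame(sample_id = "S9", term_id = "NCBITaxon:1",
                                  count = 3), kind = "taxon")
  st <- sample_stats(data.frame(sample_id = "S1", n_reads_raw = 6e6,
                                n_reads_qc = 5e6, n_orfs = 1e5))
  store <- suppressWarnings(build_store(taxa = tab, stats = st))
  expect_error(qc_filter_samples(store), "missing statistics")
})

test_that("intersection query equals the brute-force oracle", {
  sim <- small_sim(seed = 31L, n_samples = 25L)
  cases <- list(
    list(fc = "GO:0043169", cons = list(required_measurements = "ENVO:3100031")),
    list(fc = "GO:0044237", cons = list(depth_range = c(200, 700))),
    list(fc = "NCBITaxon:1218",
         cons = list(env_class = "ENVO:00000213", project_id = "HOT_SYN")),
    list(fc = "NCBITaxon:1117",
         cons = list(required_measurements = c("ENVO:3100011", "ENVO:3100026"),
                     depth_range = c(0, 400))))
  for (cs in cases) {
    got <- query_store(sim$store, sim$ontologies, cs$fc, cs$cons)
    want <- oracle_query(sim$store, sim$ontologies, cs$fc, cs$cons)
    expect_equal(got$samples, want$samples)
    expect_equal(got$terms, want$terms)
    # counts agree with the store entry by entry
    for (j in seq_along(got$terms)) {
      e <- sim$store[[if (got$kind == "function") "functions" else "taxa"]]$entries
      for (i in seq_along(got$samples)) {
        v <- e$count[e$sample_id == got$samples[i] & e$term_id == got$terms[j]]
        expect_equal(got$counts[i, j], if (length(v)) v else 0)
      }
      break # one column checked densely is enough per case
    }
  }
})

test_that("query is monotone in constraints and total at the ontology root", {
  sim <- small_sim(seed = 32L, n_samples = 20L)
  base <- query_store(sim$store, sim$ontologies, "GO:0003673", list())
  narrowed <- query_store(sim$store, sim$ontologies, "GO:0003673",
                          list(depth_range = c(100, 600)))
  expect_true(all(narrowed$samples %in% base$samples))
  # root query returns every function term present for matched samples
  present <- sort(unique(sim$functions$entries$term_id[
    sim$functions$entries$sample_id %in% base$samples]))
  expect_equal(base$terms, present)
  # unknown classes error
  expect_error(query_store(sim$store, sim$ontologies, "GO:1111111"), "not found")
  expect_error(query_store(sim$store, sim$ontologies, "GO:0043169",
                           list(env_class = "ENVO:12345678")), "unknown")
})

test_that("environment matching expands over subclasses unless disabled", {
  sim <- small_sim(seed = 33L, n_samples = 16L)
  # every sample is tagged with a subclass of marine water body
  expanded <- query_store(sim$store, sim$ontologies, "GO:0003673",
                          list(env_class = "ENVO:00001999"))
  exact <- query_store(sim$store, sim$ontologies, "GO:0003673",
                       list(env_class = "ENVO:00001999", expand_env = FALSE))
  expect_gt(length(expanded$samples), 0L)
  expect_length(exact$samples, 0L)
})

test_that("QC-then-query commutes with query-then-drop", {
  sim <- small_sim(seed = 34L, n_samples = 20L, qc_failures = 4L)
  thr <- sim$ledger$qc_thresholds
  qc <- qc_filter_samples(sim$store, thr$min_raw_reads, thr$min_unique_taxa)
  a <- query_store(qc$store, sim$ontologies, "GO:0044237",
                   list(required_measurements = "ENVO:3100031"))
  b <- query_store(sim$store, sim$ontologies, "GO:0044237",
                   list(required_measurements = "ENVO:3100031"))
  survivors <- setdiff(b$samples, qc$report$sample_id)
  expect_equal(a$samples, survivors)
})

test_that("N-Triples export matches the closed-form count and reparses exactly", {
  env <- make_env_ontology()
  md_path <- write_lines_tmp(c(
    paste("sample_id", "project_id", "env_classes", "depth_m", "latitude",
          "longitude", "collected_at", "ENVO:3100011[umol/kg]", sep = "\t"),
    paste("S1", "P", "ENVO:00000213", "450", "10", "10", "", "2.5", sep = "\t")))
  md <- read_sample_metadata(md_path, env_ontology = env)
  tab <- feature_table(data.frame(sample_id = c("S1", "S1"),
                                  term_id = c("GO:0000001", "GO:0000002"),
                                  count = c(4, 9)), kind = "function")
  st <- sample_stats(data.frame(sample_id = "S1", n_reads_raw = 6e6,
                                n_reads_qc = 5e6, n_orfs = 100))
  store <- build_store(functions = tab, stats = st, metadata = md)
  path <- tempfile(fileext = ".nt")
  n <- export_ntriples(store, path)
  # 3 per count entry + 3 per measurement + (type + project + env) per sample
  expect_equal(n, 3 * 2 + 3 * 1 + (1 + 1 + 1))

  parsed <- read_ntriples(path)
  expect_equal(nrow(parsed), n)
  counts <- parsed[parsed$predicate ==
                     "http://purl.example.org/ontomarine/count", ]
  expect_setequal(as.numeric(counts$value), c(4, 9))
  vals <- parsed[parsed$predicate ==
                   "http://purl.example.org/ontomarine/value", ]
  expect_equal(as.numeric(vals$value), 2.5)
  types <- parsed[parsed$predicate ==
                    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
                    grepl("GO_000000", parsed$object), ]
  expect_equal(nrow(types), 2L)

  # byte-identical re-export
  path2 <- tempfile(fileext = ".nt")
  export_ntriples(store, path2)
  expect_identical(readLines(path), readLines(path2))

  # empty store
  empty <- build_store()
  p3 <- tempfile(fileext = ".nt")
  expect_equal(export_ntriples(empty, p3), 0L)
})

test_that("export round-trips the full (sample, term, count) and measurement sets", {
  sim <- small_sim(seed = 35L, n_samples = 8L)
  path <- tempfile(fileext = ".nt")
  export_ntriples(sim$store, path)
  parsed <- read_ntriples(path)
  ns <- "http://purl.example.org/ontomarine/"
  cnt <- parsed[parsed$predicate == paste0(ns, "count"), ]
  node <- sub(paste0(ns, "sample/"), "", cnt$subject)
  got <- data.frame(
    sample_id = sub("/count/.*$", "", node),
    term_id = sub("_", ":", sub("^.*/count/", "", node)),
    count = as.numeric(cnt$value), stringsAsFactors = FALSE)
  got <- got[order(got$sample_id, got$term_id), ]
  want <- rbind(sim$functions$entries, sim$taxa$entries)
  want <- want[order(want$sample_id, want$term_id), ]
  expect_equal(got$sample_id, want$sample_id)
  expect_equal(got$term_id, want$term_id)
  expect_equal(got$count, want$count)

  mv <- parsed[parsed$predicate == paste0(ns, "value"), ]
  expect_equal(nrow(mv), nrow(sim$metadata$measurements))
  expect_setequal(round(as.numeric(mv$value), 9),
                  round(sim$metadata$measurements$value, 9))
})
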