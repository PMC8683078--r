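test_that("label normalization folds case, punctuation and Greek glyphs", {
  expect_equal(normalize_label("NF-κB"), c("nf", "kappab"))
  expect_equal(normalize_label("p53"), "p53")
  expect_equal(normalize_label("SIRT3"), normalize_label("sirt3"))
  expect_equal(normalize_label("TNF-α/beta (soluble)"),
               c("tnf", "alpha", "beta", "soluble"))
  expect_equal(normalize_label(""), character())
})

test_that("normalization is idempotent and matches the character-level oracle", {
  labels <- c("NF-κB", "Interleukin-6", "PI3K/AKT", "TGF β1",
              "p53 (tumor suppressor)", "SENP1", "ubiquitin--protein ligase")
  for (lab in labels) {
    toks <- normalize_label(lab)
    expect_identical(normalize_label(paste(toks, collapse = " ")), toks)
    expect_identical(paste(toks, collapse = " "), oracle_norm(lab))
  }
})

test_that("similarity scoring: exact normalized match scores 1, tie-break picks the shorter name", {
  rec <- grounding_record("ncbi-gene", "7157", "tumor protein p53",
                          c("TP53", "p53"), organism = "9606")
  hit <- score_label("p53", rec)
  expect_equal(hit$score, 1)
  expect_equal(hit$matched_name, "p53")
  expect_equal(score_label("P53", rec)$score, 1)
  expect_lt(score_label("zzzzqq", rec)$score, 0.3)
  # symmetry of the underlying measure
  r1 <- grounding_record("ncbi-gene", "1", "abcdef")
  r2 <- grounding_record("ncbi-gene", "2", "abcxyz")
  expect_equal(score_label("abcxyz", r1)$score, score_label("abcdef", r2)$score)
})

test_that("organism context steers ranking of equally scored homologs", {
  idx <- synonym_index(p53_records())
  human_first <- search_records(idx, "p53", "protein",
                                organism_context = "9606", k = 2)
  expect_equal(human_first$record_id[1], "7157")
  mouse_first <- search_records(idx, "p53", "protein",
                                organism_context = "10090", k = 2)
  expect_equal(mouse_first$record_id[1], "22059")
  # empty context falls back to the default order (human first)
  default <- search_records(idx, "p53", "protein", k = 2)
  expect_equal(default$record_id[1], "7157")
  # chemicals search the chebi namespace only
  chem <- search_records(idx, "ATP", "chemical", k = 5)
  expect_equal(chem$namespace, "chebi")
  expect_equal(chem$record_id[1], "15422")
})

test_that("k = 1 result is the prefix of the k = 10 result and search is deterministic", {
  idx <- synonym_index(p53_records())
  top10 <- search_records(idx, "p53", "protein", k = 10)
  top1 <- search_records(idx, "p53", "protein", k = 1)
  expect_equal(top1, top10[1, ])
  expect_identical(search_records(idx, "sirtuin", "protein", k = 5),
                   search_records(idx, "sirtuin", "protein", k = 5))
  expect_equal(nrow(search_records(idx, "", "protein", k = 5)), 0)
})

test_that("search ranking equals the brute-force oracle on random dictionaries", {
  set.seed(101)
  for (trial in 1:12) {
    spec <- benchmark_spec(n_records = sample(20:120, 1), n_queries = 8,
                           seed = 5000 + trial)
    dict <- generate_dictionary(spec)
    idx <- synonym_index(dict)
    oidx <- oracle_index(dict)
    bench <- generate_benchmark(dict, spec)
    for (q in seq_len(nrow(bench))) {
      ctx <- if (nzchar(bench$organism_context[q]))
        strsplit(bench$organism_context[q], "|", fixed = TRUE)[[1]]
        else character()
      got <- search_records(idx, bench$query_label[q], bench$entity_class[q],
                            organism_context = ctx, k = length(dict))
      want <- oracle_search(dict, bench$query_label[q],
                            bench$entity_class[q], ctx, length(dict),
                            oidx = oidx)
      expect_equal(got$record_id, want$record_id)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("organism-priority dominance: equal scores, earlier-context organism wins", {
  recs <- list(
    grounding_record("ncbi-gene", "20", "ABC1", organism = "10090"),
    grounding_record("ncbi-gene", "10", "ABC1", organism = "9606")
  )
  idx <- synonym_index(recs)
  for (ctx in list(c("10090", "9606"), c("9606", "10090"))) {
    hits <- search_records(idx, "ABC1", "protein", organism_context = ctx,
                           k = 2)
    expect_equal(hits$score, c(1, 1))
    expect_equal(hits$organism, ctx)
  }
})

test_that("ground_document assigns top hits in insertion order and earlier organisms steer later ones", {
  idx <- synonym_index(p53_records())
  doc <- pathway_document()
  doc <- add_entity(doc, "Trp53", "protein")
  doc <- add_entity(doc, "p53", "protein")   # ambiguous homolog
  doc <- add_entity(doc, "", "protein")      # empty label stays ungrounded
  doc <- add_entity(doc, "xyzzyplugh", "protein") # below min score
  doc <- ground_document(doc, idx)
  g1 <- doc$entities[["e1"]]$grounding
  g2 <- doc$entities[["e2"]]$grounding
  expect_equal(g1$record_id, "22059")
  # mouse history from e1 steers the ambiguous e2 to the mouse record
  expect_equal(g2$record_id, "22059")
  expect_null(doc$entities[["e3"]]$grounding)
  expect_null(doc$entities[["e4"]]$grounding)
  # without history the same ambiguous label grounds human-first
  doc2 <- pathway_document()
  doc2 <- add_entity(doc2, "p53", "protein")
  doc2 <- ground_document(doc2, idx)
  expect_equal(doc2$entities[["e1"]]$grounding$record_id, "7157")
  expect_equal(doc2$entities[["e1"]]$grounding$canonical_name, "TP53")
})

test_that("top-k accuracy is exact on all-exact benchmarks and monotone in k", {
  # no homolog collisions: exact names are unambiguous, so the top hit must
  # be the truth regardless of organism context
  spec <- benchmark_spec(
    n_records = 60, n_queries = 40, seed = 7, collision_rate = 0,
    perturbation_rates = c(exact = 1, case_change = 0, punct_variant = 0,
                           greek_spelling = 0, truncation = 0,
                           distractor = 0))
  dict <- generate_dictionary(spec)
  idx <- synonym_index(dict)
  bench <- generate_benchmark(dict, spec)
  acc <- evaluate_topk(idx, bench, ks = c(1, 3, 10))
  expect_equal(acc$accuracy[1], 1.0)
  expect_true(all(diff(acc$accuracy) >= 0))
  # truth absent from the index -> zero accuracy at every k
  ghost <- data.frame(query_label = "ABC1", entity_class = "protein",
                      truth_namespace = "ncbi-gene", truth_id = "absent",
                      organism_context = "", stringsAsFactors = FALSE)
  acc0 <- evaluate_topk(idx, ghost, ks = c(1, 10))
  expect_equal(acc0$accuracy, c(0, 0))
  # monotonicity on a noisy benchmark
  spec2 <- benchmark_spec(n_records = 60, n_queries = 60, seed = 8)
  dict2 <- generate_dictionary(spec2)
  acc2 <- evaluate_topk(synonym_index(dict2),
                        generate_benchmark(dict2, spec2), ks = 1:10)
  expect_true(all(diff(acc2$accuracy) >= 0))
})

test_that("dictionary TSV round-trips through write/read", {
  recs <- p53_records()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(recs, path)
  back <- read_dictionary(path)
  expect_equal(length(back), length(recs))
  for (j in seq_along(recs)) {
    expect_equal(back[[j]]$record_id, recs[[j]]$record_id)
    expect_equal(back[[j]]$canonical_name, recs[[j]]$canonical_name)
    expect_equal(back[[j]]$synonyms, recs[[j]]$synonyms)
    expect_equal(back[[j]]$organism, recs[[j]]$organism)
  }
  writeLines("ncbi-gene\tonly-two", path)
  expect_error(read_dictionary(path), class = "malformed-document")
})
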