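# Synthetic fixtures: synonym dictionaries, grounding benchmarks, pathway
# documents and schematic SIF networks. Everything is a pure function of its
# spec + seed, so the whole package is testable with no external download.
# The benchmark emulates how authors type entity names (exact symbols, case
# and punctuation variants, Greek spellings, truncations, and deliberately
# confusable near-miss labels); it does not reproduce any published test set.

#' Specification of the synthetic dictionary + benchmark
#'
#' Defaults define the standard benchmark used throughout: a 500-record
#' dictionary over two organisms and 1000 queries drawn with the documented
#' perturbation mix. `perturbation_rates` must sum to 1.
#'
#' @param n_records Total records in the dictionary.
#' @param synonyms_per_record Integer range `c(min, max)` of synonyms.
#' @param n_organisms Number of gene organisms used (taken from the head of
#'   [pf_organisms()]).
#' @param n_queries Number of benchmark queries.
#' @param perturbation_rates Named probabilities over
#'   `exact`, `case_change`, `punct_variant`, `greek_spelling`,
#'   `truncation`, `distractor`.
#' @param collision_rate Fraction of gene records whose symbol also exists
#'   under another organism (homolog ambiguity, the human/mouse p53 case).
#' @param near_miss_rate Fraction of gene records paired with another record
#'   whose name lies at edit distance 1-2 (confusable symbols).
#' @param chemical_fraction Fraction of records drawn from the chemical
#'   (chebi) namespace.
#' @param context_match_prob Probability that a gene query's organism context
#'   names the truth record's organism.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_records = 500,
                           synonyms_per_record = c(2, 4),
                           n_organisms = 2,
                           n_queries = 1000,
                           perturbation_rates = c(exact = 0.55,
                                                  case_change = 0.15,
                                                  punct_variant = 0.12,
                                                  greek_spelling = 0.05,
                                                  truncation = 0.08,
                                                  distractor = 0.05),
                           collision_rate = 0.3,
                           near_miss_rate = 0.1,
                           chemical_fraction = 0.1,
                           context_match_prob = 0.9,
                           seed = 42) {
  kinds <- c("exact", "case_change", "punct_variant", "greek_spelling",
             "truncation", "distractor")
  stopifnot(n_records >= 1, n_queries >= 1, n_organisms >= 1,
            length(synonyms_per_record) == 2,
            all(kinds %in% names(perturbation_rates)),
            abs(sum(perturbation_rates) - 1) < 1e-9)
  structure(list(n_records = as.integer(n_records),
                 synonyms_per_record = as.integer(synonyms_per_record),
                 n_organisms = as.integer(n_organisms),
                 n_queries = as.integer(n_queries),
                 perturbation_rates = perturbation_rates[kinds],
                 collision_rate = collision_rate,
                 near_miss_rate = near_miss_rate,
                 chemical_fraction = chemical_fraction,
                 context_match_prob = context_match_prob,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

# alpha, beta, gamma, delta, kappa
greek_glyphs <- c("\u03b1", "\u03b2", "\u03b3", "\u03b4", "\u03ba")

rand_symbol <- function() {
  paste0(paste(sample(LETTERS, sample(3:4, 1), replace = TRUE),
               collapse = ""),
         sample(1:9, 1))
}

unique_symbols <- function(n) {
  out <- character(0)
  while (length(out) < n) out <- unique(c(out, replicate(n, rand_symbol())))
  out[seq_len(n)]
}

mutate_symbol <- function(sym) {
  # one character substitution, yielding an edit-distance-1 neighbour
  pos <- nchar(sym)
  ch <- substr(sym, pos, pos)
  repl <- if (grepl("[0-9]", ch)) sample(setdiff(as.character(0:9), ch), 1)
          else sample(setdiff(LETTERS, ch), 1)
  paste0(substr(sym, 1, pos - 1), repl)
}

make_synonyms <- function(sym, n, idx) {
  pool <- c(
    tolower(sym),
    sub("([A-Za-z])([0-9])", "\\1-\\2", sym),
    paste(tolower(sym), "associated protein", idx %% 7 + 1),
    paste0(sym, sample(greek_glyphs, 1)),
    paste("putative", tolower(sym), "homolog")
  )
  unique(pool[seq_len(min(n, length(pool)))])
}

#' Generate a synthetic grounding dictionary
#'
#' Gene records are distributed over `n_organisms` taxa with homologous
#' symbol collisions across organisms at `collision_rate` (same symbol,
#' different taxon — the ambiguity organism priority must resolve) and
#' near-miss symbol pairs at `near_miss_rate` (edit distance 1). Each record
#' carries a synonym set mixing case, hyphenation, descriptive and
#' Greek-glyph variants. Deterministic given `spec$seed`.
#'
#' @param spec A [benchmark_spec()].
#' @return List of [grounding_record()]s.
#' @export
generate_dictionary <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  taxa <- pf_default_organism_order()[seq_len(spec$n_organisms)]
  n_chem <- round(spec$n_records * spec$chemical_fraction)
  n_gene <- spec$n_records - n_chem
  n_coll_pairs <- floor(spec$collision_rate * n_gene / 2)
  n_nm_pairs <- floor(spec$near_miss_rate * n_gene / 2)
  n_free <- n_gene - 2L * n_coll_pairs - 2L * n_nm_pairs
  base_syms <- unique_symbols(n_coll_pairs + n_nm_pairs + n_free)
  records <- vector("list", spec$n_records)
  ri <- 0L
  add_gene <- function(sym, organism) {
    ri <<- ri + 1L
    nsyn <- sample(seq(spec$synonyms_per_record[1],
                       spec$synonyms_per_record[2]), 1)
    records[[ri]] <<- grounding_record(
      "ncbi-gene", sprintf("g%05d", ri), sym,
      synonyms = setdiff(make_synonyms(sym, nsyn, ri), sym),
      organism = organism
    )
  }
  si <- 0L
  if (spec$n_organisms >= 2) {
    for (p in seq_len(n_coll_pairs)) {
      si <- si + 1L
      orgs <- sample(taxa, 2)
      add_gene(base_syms[si], orgs[1])
      add_gene(base_syms[si], orgs[2])
    }
  } else {
    n_free <- n_free + 2L * n_coll_pairs
    n_coll_pairs <- 0L
  }
  for (p in seq_len(n_nm_pairs)) {
    si <- si + 1L
    add_gene(base_syms[si], sample(taxa, 1))
    add_gene(mutate_symbol(base_syms[si]), sample(taxa, 1))
  }
  for (p in seq_len(n_free)) {
    si <- si + 1L
    add_gene(base_syms[si], sample(taxa, 1))
  }
  chem_names <- unique(replicate(n_chem * 2, paste0(
    paste(sample(letters, sample(5:8, 1), replace = TRUE), collapse = ""),
    sample(c("ol", "ine", "ate", "ic acid"), 1))))
  for (p in seq_len(n_chem)) {
    ri <- ri + 1L
    nm <- chem_names[p]
    records[[ri]] <- grounding_record(
      "chebi", sprintf("c%05d", ri), nm,
      synonyms = c(toupper(substr(nm, 1, 4)),
                   sub("([a-z]{3})", "\\1-", nm)),
      organism = NA_character_
    )
  }
  records[seq_len(ri)]
}

flip_case <- function(x) {
  ch <- strsplit(x, "")[[1]]
  alpha <- grepl("[A-Za-z]", ch)
  flip <- alpha & stats::runif(length(ch)) < 0.5
  ch[flip] <- ifelse(ch[flip] %in% letters, toupper(ch[flip]),
                     tolower(ch[flip]))
  paste(ch, collapse = "")
}

punct_variant <- function(x) {
  if (grepl("-", x, fixed = TRUE)) return(sub("-", " ", x))
  if (grepl(" ", x, fixed = TRUE)) return(sub(" ", "-", x))
  if (grepl("[A-Za-z][0-9]", x)) return(sub("([A-Za-z])([0-9])", "\\1-\\2", x))
  x
}

greek_swap <- function(x) {
  for (g in names(greek_map))
    if (grepl(g, x, fixed = TRUE))
      return(sub(g, greek_map[[g]], x, fixed = TRUE))
  for (g in names(greek_map))
    if (grepl(paste0("\\b", greek_map[[g]], "\\b"), x))
      return(sub(paste0("\\b", greek_map[[g]], "\\b"), g, x))
  x
}

truncate_name <- function(x) {
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  if (length(toks) < 2) return(x)
  paste(toks[-length(toks)], collapse = " ")
}

one_edit <- function(x) {
  pos <- sample(nchar(x), 1)
  ch <- substr(x, pos, pos)
  repl <- if (grepl("[0-9]", ch)) sample(setdiff(as.character(0:9), ch), 1)
          else sample(setdiff(letters, tolower(ch)), 1)
  paste0(substr(x, 1, pos - 1), repl, substr(x, pos + 1, nchar(x)))
}

#' Generate a synthetic grounding benchmark
#'
#' Each query samples a truth record, one of its names, and a perturbation
#' from `spec$perturbation_rates`: `exact` keeps the name verbatim;
#' `case_change` flips letter cases; `punct_variant` toggles a hyphen/space
#' at a token boundary; `greek_spelling` swaps a Greek glyph with its
#' spelled-out name (either direction); `truncation` drops the trailing token
#' of a multi-token name; `distractor` applies a one-character edit to the
#' truth's name, which — given the dictionary's near-miss pairs — places the
#' label within edit distance 2 of a *different* record's name, the
#' deliberately confusable case. The organism context names the truth's
#' organism with probability `spec$context_match_prob` (genes only).
#'
#' @param dictionary Output of [generate_dictionary()].
#' @param spec A [benchmark_spec()].
#' @return Data frame with columns `query_label`, `entity_class`,
#'   `truth_namespace`, `truth_id`, `organism_context` (pipe-separated, may
#'   be empty), `perturbation`.
#' @export
generate_benchmark <- function(dictionary, spec = benchmark_spec()) {
  stopifnot(length(dictionary) > 0, inherits(spec, "benchmark_spec"))
  set.seed(spec$seed + 1L)
  taxa <- pf_default_organism_order()[seq_len(spec$n_organisms)]
  kinds <- names(spec$perturbation_rates)
  rows <- vector("list", spec$n_queries)
  for (q in seq_len(spec$n_queries)) {
    rec <- dictionary[[sample(length(dictionary), 1)]]
    name <- sample(record_names(rec), 1)
    kind <- sample(kinds, 1, prob = spec$perturbation_rates)
    label <- switch(kind,
      exact = name,
      case_change = flip_case(name),
      punct_variant = punct_variant(name),
      greek_spelling = greek_swap(name),
      truncation = truncate_name(name),
      distractor = one_edit(rec$canonical_name)
    )
    if (rec$namespace == "ncbi-gene") {
      ctx <- if (stats::runif(1) < spec$context_match_prob) {
        rec$organism
      } else if (length(taxa) > 1 && stats::runif(1) < 0.5) {
        sample(setdiff(taxa, rec$organism), 1)
      } else {
        ""
      }
    } else {
      ctx <- ""
    }
    rows[[q]] <- data.frame(
      query_label = label,
      entity_class = if (rec$namespace == "chebi") "chemical" else "protein",
      truth_namespace = rec$namespace,
      truth_id = rec$record_id,
      organism_context = ctx,
      perturbation = kind,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a random valid pathway document
#'
#' Produces a document exercising every entity class, sign and mechanism with
#' configured frequency. By default every entity is grounded within a single
#' organism and connected (via an interaction or a complex) whenever
#' `n_interactions` allows, so standard generator output validates cleanly.
#'
#' @param n_entities,n_interactions,n_complexes Element counts;
#'   `n_interactions` must not exceed the number of unordered entity pairs
#'   and complexes use two entities each.
#' @param seed Integer seed.
#' @param ground Assign synthetic groundings to every entity.
#' @return A `pathway_document`.
#' @export
generate_document <- function(n_entities, n_interactions = 0,
                              n_complexes = 0, seed = 1, ground = TRUE) {
  if (n_interactions > n_entities * (n_entities - 1) / 2 ||
      2 * n_complexes > n_entities)
    pf_error("invalid-spec",
             "requested counts exceed what the entity set can support")
  set.seed(seed)
  doc <- pathway_document(article_ref(
    title = sprintf("Synthetic pathway %d", seed),
    external_id = sprintf("10.0000/synthetic.%d", seed),
    id_namespace = "doi"
  ))
  doc <- add_context(doc, c("synthetic benchmark", "fixture"))
  if (n_entities == 0) return(doc)
  syms <- unique_symbols(n_entities)
  classes <- sample(pf_entity_classes(), n_entities, replace = TRUE,
                    prob = c(0.6, 0.12, 0.08, 0.2))
  organism <- sample(pf_default_organism_order()[1:2], 1)
  ids <- character(n_entities)
  for (j in seq_len(n_entities)) {
    doc <- add_entity(doc, syms[j], classes[j])
    ids[j] <- last_id(doc)
    if (ground) {
      if (classes[j] == "chemical") {
        doc <- set_grounding(doc, ids[j], "chebi", sprintf("c%04d", j),
                             canonical_name = syms[j])
      } else {
        doc <- set_grounding(doc, ids[j], "ncbi-gene", sprintf("g%04d", j),
                             organism = organism, canonical_name = syms[j])
      }
    }
  }
  shuffled <- sample(ids)
  cx_members <- list()
  if (n_complexes > 0) {
    for (c_i in seq_len(n_complexes)) {
      members <- shuffled[(2 * c_i - 1):(2 * c_i)]
      doc <- add_complex(doc, members, sprintf("complex %d", c_i))
      cx_members[[c_i]] <- members
    }
  }
  # connect uncovered entities first, then add random extra interactions
  free <- setdiff(shuffled, unlist(cx_members))
  used_pairs <- character()
  pick_sign_mech <- function() {
    mech <- sample(pf_mechanisms(), 1,
                   prob = c(0.2, 0.1, 0.2, 0.05, 0.05, 0.05,
                            0.05, 0.03, 0.07, 0.2))
    sign <- if (mech == "binding") "unsigned"
            else sample(pf_signs(), 1, prob = c(0.5, 0.3, 0.2))
    list(sign = sign, mech = mech)
  }
  add_pair <- function(a, b) {
    sm <- pick_sign_mech()
    doc <<- add_interaction(doc, a, b, sm$sign, sm$mech)
    used_pairs <<- c(used_pairs, paste(sort(c(a, b)), collapse = "\r"))
  }
  n_left <- n_interactions
  j <- 1L
  while (n_left > 0 && j < length(free)) {
    add_pair(free[j], free[j + 1])
    n_left <- n_left - 1L
    j <- j + 2L
  }
  if (n_left > 0 && j == length(free) && length(ids) > 1) {
    other <- sample(setdiff(ids, free[j]), 1)
    add_pair(free[j], other)
    n_left <- n_left - 1L
  }
  guard <- 0L
  while (n_left > 0 && guard < 10000L) {
    pair <- sample(ids, 2)
    key <- paste(sort(pair), collapse = "\r")
    guard <- guard + 1L
    if (key %in% used_pairs) next
    add_pair(pair[1], pair[2])
    n_left <- n_left - 1L
  }
  doc
}

#' Schematic SIF fixtures for the network-integration analysis
#'
#' Small hand-written networks mirroring the topology of the published
#' integration example without copying any real pathway content: two
#' disconnected pathway components (a SUMO-processing schematic containing
#' SENP1 and SIRT5, and a mitochondrial-biogenesis schematic containing
#' SIRT3 and UCP1), the two curated interactions that bridge them
#' (`SENP1 controls-state-change-of SIRT3`,
#' `SIRT5 controls-state-change-of UCP1`), and a directed SENP1-to-SOD2
#' chain of three regulatory edges.
#'
#' @return Named list: `sumo_processing`, `mito_biogenesis`,
#'   `senp1_sod2_chain` (each an `interaction_network`) and `curated_edges`
#'   (a data frame of the two new edges).
#' @export
schematic_networks <- function() {
  sumo <- read_sif(c(
    "SENP1\tcontrols-state-change-of\tSUMO1",
    "SUMO1\tinteracts-with\tRANGAP1",
    "SENP1\tinteracts-with\tSIRT5"
  ), source_tag = "sumo_processing")
  mito <- read_sif(c(
    "SIRT3\tcontrols-state-change-of\tPGC1A",
    "PGC1A\tcontrols-expression-of\tTFAM",
    "PGC1A\tcontrols-expression-of\tNRF1",
    "UCP1\tinteracts-with\tPGC1A"
  ), source_tag = "mito_biogenesis")
  chain <- read_sif(c(
    "SENP1\tcontrols-state-change-of\tSIRT3",
    "SIRT3\tcontrols-state-change-of\tFOXO3",
    "FOXO3\tcontrols-expression-of\tSOD2"
  ), source_tag = "senp1_sod2_chain")
  curated <- data.frame(
    source = c("SENP1", "SIRT5"),
    relation = c("controls-state-change-of", "controls-state-change-of"),
    target = c("SIRT3", "UCP1"),
    stringsAsFactors = FALSE
  )
  list(sumo_processing = sumo, mito_biogenesis = mito,
       senp1_sod2_chain = chain, curated_edges = curated)
}
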