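# Entity grounding: ranked synonym search with organism prioritization.
# Free-text labels are matched against gene (ncbi-gene) or chemical (chebi)
# records; similarity is a normalized edit-distance ratio over the record's
# full name set, with an exact-normalized-match fast path scoring 1.

greek_letter_names <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
  "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
  "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"
)

# glyph -> spelled-out Latin name; uppercase block skips U+03A2, lowercase
# includes final sigma (U+03C2)
greek_map <- local({
  upper <- setdiff(0x0391:0x03A9, 0x03A2)
  lower <- 0x03B1:0x03C9
  glyphs <- vapply(c(upper, lower), intToUtf8, "")
  nms <- c(greek_letter_names,
           c(greek_letter_names[1:17], "sigma", greek_letter_names[18:24]))
  stats::setNames(nms, glyphs)
})

#' Normalize a free-text entity label
#'
#' Deterministic normalization used on both sides of the similarity
#' comparison: Greek glyphs are spelled out in Latin (\eqn{\alpha} becomes
#' `alpha`), the label is case-folded, and punctuation (hyphen, slash,
#' parentheses and any other non-alphanumeric run) becomes a token boundary.
#' The function is idempotent on its own joined output.
#'
#' @param label Character scalar (an author-typed entity label).
#' @return Character vector of normalized tokens; empty for an empty label.
#' @export
#' @examples
#' normalize_label("NF-κB")   # "nf" "kappab"
normalize_label <- function(label) {
  if (length(label) == 0 || is.na(label)) return(character())
  x <- as.character(label)
  if (!nzchar(x)) return(character())
  if (grepl("[^\x01-\x7f]", x, useBytes = TRUE)) {
    for (g in names(greek_map))
      if (grepl(g, x, fixed = TRUE))
        x <- gsub(g, greek_map[[g]], x, fixed = TRUE)
  }
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks[nzchar(toks)]
}

norm_key <- function(label) paste(normalize_label(label), collapse = " ")

# similarity between two already-normalized key strings
sim_ratio <- function(qkey, keys) {
  n <- pmax(nchar(qkey), nchar(keys))
  d <- as.vector(utils::adist(qkey, keys))
  s <- ifelse(n == 0, 0, 1 - d / n)
  s[keys == qkey] <- 1
  pmin(pmax(s, 0), 1)
}

#' Create a grounding record
#'
#' A namespaced database record an entity label can be grounded to:
#' NCBI Gene for genes and their products (with an organism taxon), ChEBI for
#' small molecules (no organism).
#'
#' @param namespace `"ncbi-gene"` or `"chebi"`.
#' @param record_id Identifier string; `(namespace, record_id)` must be unique
#'   within a dictionary.
#' @param canonical_name Primary name.
#' @param synonyms Character vector of alternative names.
#' @param organism Taxon identifier, or `NA` for chemicals.
#' @return A `grounding_record` list whose effective name set is the
#'   canonical name plus synonyms.
#' @export
grounding_record <- function(namespace, record_id, canonical_name,
                             synonyms = character(), organism = NA_character_) {
  namespace <- match.arg(namespace, c("ncbi-gene", "chebi"))
  if (any(grepl("|", c(canonical_name, synonyms), fixed = TRUE)))
    pf_error("malformed-document", "'|' is forbidden inside record names")
  structure(list(
    namespace = namespace,
    record_id = as.character(record_id),
    canonical_name = as.character(canonical_name),
    synonyms = unique(as.character(synonyms)),
    organism = if (is.null(organism) || is.na(organism)) NA_character_
               else as.character(organism)
  ), class = "grounding_record")
}

record_names <- function(rec) unique(c(rec$canonical_name, rec$synonyms))

#' Build a synonym index over grounding records
#'
#' Precomputes the normalized name table the ranked search scores against.
#' The index is an optimization detail only: ranking is defined as brute-force
#' scoring of every record.
#'
#' @param records List of [grounding_record()]s with unique
#'   `(namespace, record_id)` pairs.
#' @return A `synonym_index` object.
#' @export
synonym_index <- function(records) {
  stopifnot(all(vapply(records, inherits, TRUE, "grounding_record")))
  key <- vapply(records, function(r) paste(r$namespace, r$record_id), "")
  if (anyDuplicated(key))
    pf_error("malformed-document",
             "duplicate (namespace, record_id) in dictionary")
  rows <- lapply(seq_along(records), function(i) {
    nms <- record_names(records[[i]])
    data.frame(rec = i, name = nms,
               nkey = vapply(nms, norm_key, "", USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(
    records = records,
    namespace = vapply(records, `[[`, "", "namespace"),
    record_id = vapply(records, `[[`, "", "record_id"),
    organism = vapply(records, `[[`, "", "organism"),
    names = tab
  ), class = "synonym_index")
}

#' @export
print.synonym_index <- function(x, ...) {
  cat(sprintf("<synonym_index> %d records (%d ncbi-gene, %d chebi), %d names\n",
              length(x$records), sum(x$namespace == "ncbi-gene"),
              sum(x$namespace == "chebi"), nrow(x$names)))
  invisible(x)
}

#' Score a query label against one record's name set
#'
#' The score is the maximum over the record's canonical name and synonyms of
#' a normalized edit-distance ratio between the normalized strings; exact
#' normalized equality scores 1. Symmetric and deterministic. When several
#' names tie, the shorter (then lexicographically smaller) name is reported.
#'
#' @param query Free-text label.
#' @param record A [grounding_record()].
#' @return List with `score` in `[0, 1]` and `matched_name`.
#' @export
score_label <- function(query, record) {
  nms <- record_names(record)
  s <- sim_ratio(norm_key(query), vapply(nms, norm_key, "", USE.NAMES = FALSE))
  best <- which(s == max(s))
  best <- best[order(nchar(nms[best]), nms[best])][1]
  list(score = unname(max(s)), matched_name = nms[best])
}

org_priority <- function(organisms, organism_context, organism_order) {
  p <- match(organisms, organism_context)
  fb <- length(organism_context) + match(organisms, organism_order)
  p[is.na(p)] <- fb[is.na(p)]
  p[is.na(p)] <- length(organism_context) + length(organism_order) + 1L
  p
}

#' Ranked entity search with organism prioritization
#'
#' Scores the query against every record in the namespace implied by the
#' entity class (chemicals search ChEBI; protein, RNA and DNA all search NCBI
#' Gene — the product type is metadata, not a filter) and returns the top `k`
#' hits. Ranking is by descending similarity score, then organism priority
#' (records whose organism appears earlier in `organism_context` win, then
#' the configured default organism order), then shorter matched name, then
#' lexicographic record identifier — fully deterministic.
#'
#' @param index A [synonym_index()].
#' @param query Free-text label; an empty query returns no hits.
#' @param entity_class One of [pf_entity_classes()].
#' @param organism_context Taxon identifiers, highest priority first
#'   (typically [organism_history()] of the document being curated).
#' @param k Maximum number of hits (`k >= 1`).
#' @param organism_order Default organism priority used after the context.
#' @return Data frame of hits: `namespace`, `record_id`, `canonical_name`,
#'   `organism`, `score`, `matched_name`, best first.
#' @export
search_records <- function(index, query, entity_class = "protein",
                           organism_context = character(), k = 10,
                           organism_order = pf_default_organism_order()) {
  stopifnot(inherits(index, "synonym_index"), k >= 1)
  entity_class <- match.arg(entity_class, pf_entity_classes())
  ns <- if (entity_class == "chemical") "chebi" else "ncbi-gene"
  empty <- data.frame(namespace = character(), record_id = character(),
                      canonical_name = character(), organism = character(),
                      score = numeric(), matched_name = character(),
                      stringsAsFactors = FALSE)
  qk <- norm_key(query)
  if (!nzchar(qk)) return(empty)
  cand <- which(index$namespace == ns)
  if (length(cand) == 0) return(empty)
  tab <- index$names[index$names$rec %in% cand, ]
  tab$sim <- sim_ratio(qk, tab$nkey)
  # best name per record: max similarity, ties to shorter then smaller name
  tab <- tab[order(tab$rec, -tab$sim, nchar(tab$name), tab$name), ]
  tab <- tab[!duplicated(tab$rec), ]
  pri <- org_priority(index$organism[tab$rec], organism_context,
                      organism_order)
  ord <- order(-tab$sim, pri, nchar(tab$name), index$record_id[tab$rec])
  tab <- tab[ord, ]
  tab <- tab[seq_len(min(k, nrow(tab))), , drop = FALSE]
  data.frame(
    namespace = index$namespace[tab$rec],
    record_id = index$record_id[tab$rec],
    canonical_name = vapply(index$records[tab$rec], `[[`, "",
                            "canonical_name"),
    organism = index$organism[tab$rec],
    score = tab$sim,
    matched_name = tab$name,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Ground every entity of a document against a dictionary
#'
#' Entities are processed in insertion order. Each ungrounded entity with a
#' non-empty label receives the top search hit computed with the organism
#' history of the document *at that point*, so earlier groundings steer the
#' organism priority of later ones. Entities whose best hit scores below
#' `min_score` stay ungrounded (they surface later as `ungrounded-entity`
#' validation warnings).
#'
#' @param doc A `pathway_document`.
#' @param index A [synonym_index()].
#' @param min_score Minimum acceptance score in `[0, 1]`; default 0.5.
#' @param organism_order Default organism priority when the history is empty.
#' @return The document with groundings assigned.
#' @export
ground_document <- function(doc, index, min_score = 0.5,
                            organism_order = pf_default_organism_order()) {
  stopifnot(inherits(doc, "pathway_document"))
  for (id in names(doc$entities)) {
    ent <- doc$entities[[id]]
    if (!is.null(ent$grounding) || !nzchar(trimws(ent$label))) next
    hits <- search_records(index, ent$label, ent$entity_class,
                           organism_context = organism_history(doc), k = 1,
                           organism_order = organism_order)
    if (nrow(hits) == 0 || hits$score[1] < min_score) next
    doc <- set_grounding(doc, id, hits$namespace[1], hits$record_id[1],
                         organism = if (is.na(hits$organism[1])) NULL
                                    else hits$organism[1],
                         canonical_name = hits$canonical_name[1])
  }
  doc
}

#' Top-k retrieval accuracy of the grounding search
#'
#' For each benchmark query, runs [search_records()] with the query's own
#' organism context and records the rank of the true record; `accuracy(k)` is
#' the fraction of queries whose truth appears within the first `k` hits.
#' Accuracy is non-decreasing in `k`.
#'
#' @param index A [synonym_index()].
#' @param benchmark Data frame as produced by [generate_benchmark()]:
#'   columns `query_label`, `entity_class`, `truth_namespace`, `truth_id`,
#'   `organism_context` (pipe-separated taxa, may be empty).
#' @param ks Integer vector of cutoffs.
#' @param organism_order Default organism priority order.
#' @return Data frame with columns `k` and `accuracy`.
#' @export
evaluate_topk <- function(index, benchmark, ks = c(1, 5, 10),
                          organism_order = pf_default_organism_order()) {
  stopifnot(inherits(index, "synonym_index"), nrow(benchmark) > 0)
  ks <- sort(unique(as.integer(ks)))
  if (length(ks) == 0)
    return(data.frame(k = integer(), accuracy = numeric()))
  kmax <- max(ks)
  ranks <- vapply(seq_len(nrow(benchmark)), function(i) {
    q <- benchmark[i, ]
    ctx <- if (nzchar(q$organism_context))
      strsplit(q$organism_context, "|", fixed = TRUE)[[1]] else character()
    hits <- search_records(index, q$query_label, q$entity_class,
                           organism_context = ctx, k = kmax,
                           organism_order = organism_order)
    pos <- which(hits$namespace == q$truth_namespace &
                 hits$record_id == q$truth_id)
    if (length(pos) == 0) Inf else as.numeric(pos[1])
  }, numeric(1))
  data.frame(k = ks,
             accuracy = vapply(ks, function(k) mean(ranks <= k), numeric(1)))
}

# ---- dictionary TSV I/O -------------------------------------------------

#' Read and write dictionary files
#'
#' Tab-separated, one record per line:
#' `namespace<TAB>record_id<TAB>organism_taxon<TAB>canonical_name<TAB>syn1|syn2|...`
#' with an empty taxon field for chemicals; UTF-8; `|` forbidden inside names.
#'
#' @param path File path.
#' @return `read_dictionary` returns a list of [grounding_record()]s;
#'   `write_dictionary` returns `path` invisibly.
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4 || length(f) > 5)
      pf_error("malformed-document",
               sprintf("dictionary line %d: expected 4-5 tab-separated fields",
                       i))
    syns <- if (length(f) == 5 && nzchar(f[5]))
      strsplit(f[5], "|", fixed = TRUE)[[1]] else character()
    grounding_record(f[1], f[2], f[4], syns,
                     organism = if (nzchar(f[3])) f[3] else NA_character_)
  })
}

#' @rdname read_dictionary
#' @param records List of [grounding_record()]s.
#' @export
write_dictionary <- function(records, path) {
  lines <- vapply(records, function(r) {
    paste(r$namespace, r$record_id,
          if (is.na(r$organism)) "" else r$organism,
          r$canonical_name, paste(r$synonyms, collapse = "|"),
          sep = "\t")
  }, "")
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}
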