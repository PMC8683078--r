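# Independent oracles and tiny hand-built fixtures used across the suite.
# The oracles re-derive the specified behaviour from scratch (their own
# normalization, scoring aggregation, ordering, and exhaustive enumeration)
# so they share no code path with the implementation they check.

# glyph -> spelled name, entered by hand (lowercase Greek incl. final sigma)
oracle_greek <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta", "θ" = "theta", "ι" = "iota",
  "κ" = "kappa", "λ" = "lambda", "μ" = "mu",
  "ν" = "nu", "ξ" = "xi", "ο" = "omicron",
  "π" = "pi", "ρ" = "rho", "ς" = "sigma",
  "σ" = "sigma", "τ" = "tau", "υ" = "upsilon",
  "φ" = "phi", "χ" = "chi", "ψ" = "psi",
  "ω" = "omega"
)

# character-by-character normalization, mechanically unlike the package's
# regex pipeline
oracle_norm <- function(x) {
  if (is.na(x) || !nzchar(x)) return("")
  chars <- strsplit(x, "")[[1]]
  out <- vapply(chars, function(ch) {
    if (ch %in% names(oracle_greek)) return(oracle_greek[[ch]])
    if (grepl("^[A-Z]$", ch)) return(tolower(ch))
    if (grepl("^[a-z0-9]$", ch)) return(ch)
    " "
  }, "", USE.NAMES = FALSE)
  joined <- paste(out, collapse = "")
  paste(strsplit(trimws(joined), " +")[[1]], collapse = " ")
}

# precomputed flat name table for a dictionary, so the brute-force oracle
# normalizes each name exactly once
oracle_index <- function(records) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    nms <- unique(c(r$canonical_name, r$synonyms))
    data.frame(i = i, namespace = r$namespace, record_id = r$record_id,
               organism = r$organism, name = nms,
               nname = vapply(nms, oracle_norm, "", USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# full brute-force ranked search: score every record, then sort by the
# documented keys (score desc, organism priority, shorter matched name,
# record id)
oracle_search <- function(records, query, entity_class, ctx, k,
                          default_order = pf_default_organism_order(),
                          oidx = NULL) {
  ns <- if (entity_class == "chemical") "chebi" else "ncbi-gene"
  qn <- oracle_norm(query)
  if (!nzchar(qn)) return(data.frame(record_id = character(),
                                     score = numeric()))
  if (is.null(oidx)) oidx <- oracle_index(records)
  tab <- oidx[oidx$namespace == ns, , drop = FALSE]
  if (nrow(tab) == 0) return(data.frame(record_id = character(),
                                        score = numeric()))
  d <- as.vector(utils::adist(qn, tab$nname))
  len <- pmax(nchar(qn), nchar(tab$nname))
  tab$score <- ifelse(tab$nname == qn, 1,
                      pmin(1, pmax(0, ifelse(len == 0, 0, 1 - d / len))))
  per_rec <- lapply(split(tab, tab$i), function(g) {
    best <- g[g$score == max(g$score), , drop = FALSE]
    best <- best[order(nchar(best$name), best$name), , drop = FALSE][1, ]
    best
  })
  tab <- do.call(rbind, per_rec)
  pri <- match(tab$organism, ctx)
  fb <- length(ctx) + match(tab$organism, default_order)
  pri[is.na(pri)] <- fb[is.na(pri)]
  pri[is.na(pri)] <- length(ctx) + length(default_order) + 1
  tab <- tab[order(-tab$score, pri, nchar(tab$name), tab$record_id), ]
  utils::head(tab[, c("record_id", "score")], k)
}

# exhaustive simple-path enumeration by generating every candidate node
# tuple up to the edge limit and filtering on adjacency
oracle_paths <- function(net, source, target, limit, directed_only = TRUE) {
  edges <- net$edges
  if (directed_only)
    edges <- edges[startsWith(edges$relation, "controls-"), , drop = FALSE]
  has_edge <- function(a, b) {
    any(edges$source == a & edges$target == b) ||
      any(!startsWith(edges$relation, "controls-") &
            edges$source == b & edges$target == a)
  }
  nodes <- sort(unique(c(net$edges$source, net$edges$target)))
  if (identical(source, target)) return(list(source))
  found <- list()
  for (n_edges in seq_len(limit)) {
    n_mid <- n_edges - 1L
    mids <- if (n_mid == 0) list(character(0)) else {
      grid <- do.call(expand.grid,
                      c(rep(list(nodes), n_mid),
                        list(stringsAsFactors = FALSE)))
      lapply(seq_len(nrow(grid)), function(r) as.character(grid[r, ]))
    }
    for (mid in mids) {
      path <- c(source, mid, target)
      if (anyDuplicated(path)) next
      ok <- all(vapply(seq_len(length(path) - 1L),
                       function(j) has_edge(path[j], path[j + 1L]),
                       logical(1)))
      if (ok) found[[length(found) + 1L]] <- path
    }
  }
  if (length(found) == 0) return(list())
  keys <- vapply(found, paste, "", collapse = "\r")
  found[order(lengths(found), keys)]
}

random_network <- function(n_nodes, n_edges,
                           relations = c("controls-state-change-of",
                                         "controls-expression-of",
                                         "interacts-with",
                                         "in-complex-with")) {
  nodes <- paste0("N", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  keep <- src != tgt
  interaction_network(data.frame(
    source = src[keep],
    relation = sample(relations, sum(keep), replace = TRUE),
    target = tgt[keep],
    stringsAsFactors = FALSE
  ))
}

# hand-built dictionary around the human/mouse p53 ambiguity
p53_records <- function() {
  list(
    grounding_record("ncbi-gene", "7157", "TP53",
                     c("p53", "tumor protein p53"), organism = "9606"),
    grounding_record("ncbi-gene", "22059", "Trp53",
                     c("p53", "transformation related protein 53"),
                     organism = "10090"),
    grounding_record("ncbi-gene", "6715", "SIRT3",
                     c("sirtuin 3", "SIR2L3"), organism = "9606"),
    grounding_record("chebi", "15422", "ATP",
                     c("adenosine triphosphate"), organism = NA_character_)
  )
}

doc_fields <- function(doc) {
  attributes(doc) <- attributes(doc)[c("names", "class")]
  doc
}
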