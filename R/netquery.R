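# SIF network integration: read/merge multi-source interaction networks,
# enumerate bounded-length regulatory paths, and measure the connectivity
# contributed by newly curated edges.

directed_relation <- function(relation) startsWith(relation, "controls-")

canonical_edges <- function(edges) {
  if (nrow(edges) == 0) {
    return(data.frame(source = character(), relation = character(),
                      target = character(), sources = character(),
                      stringsAsFactors = FALSE))
  }
  undir <- !directed_relation(edges$relation)
  flip <- undir & edges$source > edges$target
  tmp <- edges$source[flip]
  edges$source[flip] <- edges$target[flip]
  edges$target[flip] <- tmp
  key <- paste(edges$source, edges$relation, edges$target, sep = "\r")
  tags <- split(edges$sources, key)
  tags <- vapply(tags, function(x) {
    u <- sort(unique(unlist(strsplit(x, "|", fixed = TRUE))))
    paste(u[nzchar(u)], collapse = "|")
  }, "")
  edges <- edges[!duplicated(key), c("source", "relation", "target")]
  edges$sources <- unname(tags[paste(edges$source, edges$relation,
                                     edges$target, sep = "\r")])
  edges <- edges[order(edges$source, edges$relation, edges$target), ]
  rownames(edges) <- NULL
  edges
}

#' Construct an interaction network from SIF-style edges
#'
#' Relations starting with `controls-` are directed; `interacts-with`,
#' `in-complex-with` and any unknown relation token are undirected (and
#' stored with lexicographic participant order). Duplicate
#' `(source, relation, target)` triples collapse to one edge whose source
#' tags accumulate.
#'
#' @param edges Data frame with columns `source`, `relation`, `target` and
#'   optionally `sources` (a `|`-separated provenance tag set).
#' @param source_tag Tag recorded on every edge lacking one.
#' @return An `interaction_network`.
#' @export
interaction_network <- function(edges = NULL, source_tag = "") {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), relation = character(),
                        target = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "relation", "target") %in% names(edges)))
  if (is.null(edges$sources))
    edges$sources <- rep(source_tag, nrow(edges))
  structure(list(edges = canonical_edges(edges)),
            class = "interaction_network")
}

#' Nodes of an interaction network
#' @param net An `interaction_network`.
#' @return Sorted character vector of node names.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  sort(unique(c(net$edges$source, net$edges$target)))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(network_nodes(x)), nrow(x$edges)))
  invisible(x)
}

#' Read a Simple Interaction Format file
#'
#' One edge per non-empty line, three tab-separated columns
#' `source<TAB>relation<TAB>target`. Unknown relation tokens are preserved
#' verbatim and treated as undirected. Duplicate lines collapse to a single
#' edge (set semantics).
#'
#' @param text A file path, or a character vector of SIF lines.
#' @param source_tag Provenance tag attached to every edge (defaults to the
#'   file name when reading from a path).
#' @return An `interaction_network`.
#' @export
read_sif <- function(text, source_tag = NULL) {
  if (length(text) == 1 && !grepl("\t|\n", text) && file.exists(text)) {
    if (is.null(source_tag)) source_tag <- basename(text)
    lines <- readLines(text, encoding = "UTF-8", warn = FALSE)
  } else {
    if (is.null(source_tag)) source_tag <- ""
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    pf_error("malformed-sif",
             sprintf("line %d: expected 3 tab-separated columns, got %d",
                     keep[bad[1]], lengths(parts)[bad[1]]))
  edges <- data.frame(
    source = vapply(parts, `[`, "", 1),
    relation = vapply(parts, `[`, "", 2),
    target = vapply(parts, `[`, "", 3),
    stringsAsFactors = FALSE
  )
  interaction_network(edges, source_tag = source_tag)
}

#' Merge interaction networks from multiple sources
#'
#' Node set and edge set are unions; source tags accumulate on shared edges
#' rather than duplicating them. The operation is idempotent, commutative and
#' associative up to edge-set equality.
#'
#' @param networks A list of `interaction_network` objects (or several passed
#'   via `...`).
#' @param ... Additional networks.
#' @return The merged `interaction_network`.
#' @export
merge_networks <- function(networks, ...) {
  if (inherits(networks, "interaction_network")) networks <- list(networks)
  networks <- c(networks, list(...))
  stopifnot(all(vapply(networks, inherits, TRUE, "interaction_network")))
  all_edges <- do.call(rbind, lapply(networks, `[[`, "edges"))
  if (is.null(all_edges))
    return(interaction_network())
  structure(list(edges = canonical_edges(all_edges)),
            class = "interaction_network")
}

adjacency_list <- function(net, directed_only) {
  edges <- net$edges
  if (directed_only) edges <- edges[directed_relation(edges$relation), ]
  adj <- list()
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
  }
  for (j in seq_len(nrow(edges))) {
    add(edges$source[j], edges$target[j])
    if (!directed_relation(edges$relation[j]))
      add(edges$target[j], edges$source[j])
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' Enumerate bounded-length paths between two nodes
#'
#' All simple paths (no repeated node) from `source` to `target` with at most
#' `limit` edges. By default only directed `controls-*` relations are
#' traversed — the regulatory-path semantics of SIF graph queries; setting
#' `directed_only = FALSE` admits undirected relations in either orientation.
#' Paths are returned sorted by length, then lexicographic node sequence.
#'
#' @param net An `interaction_network`.
#' @param source,target Node names present in the network.
#' @param limit Maximum number of edges separating the two nodes
#'   (`limit >= 1`).
#' @param directed_only Restrict traversal to directed regulatory relations.
#' @return List of paths, each a character vector of node names. Querying a
#'   node against itself yields the single zero-length path.
#' @export
paths_between <- function(net, source, target, limit = 3,
                          directed_only = TRUE) {
  stopifnot(inherits(net, "interaction_network"), limit >= 1)
  nodes <- network_nodes(net)
  for (n in c(source, target))
    if (!n %in% nodes)
      pf_error("unknown-node", sprintf("node '%s' not in network", n), n)
  if (identical(source, target)) return(list(source))
  adj <- adjacency_list(net, directed_only)
  found <- list()
  walk <- function(path) {
    head <- path[length(path)]
    if (length(path) - 1L >= limit) return()
    for (nxt in adj[[head]]) {
      if (nxt %in% path) next
      if (nxt == target) {
        found[[length(found) + 1L]] <<- c(path, nxt)
      } else {
        walk(c(path, nxt))
      }
    }
  }
  walk(source)
  if (length(found) == 0) return(list())
  keys <- vapply(found, paste, "", collapse = "\r")
  found <- found[order(lengths(found), keys)]
  found
}

as_igraph_skeleton <- function(net, extra_nodes = character()) {
  nodes <- unique(c(network_nodes(net), extra_nodes))
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target")],
    directed = FALSE, vertices = nodes
  )
}

#' Connectivity contributed by newly curated edges
#'
#' Computes connected components on the undirected skeleton of `net` before
#' and after adding `new_edges`, and reports which new edges are *bridging*:
#' their endpoints lay in different components of the existing network,
#' meaning the curated interaction unifies previously disconnected pathway
#' knowledge.
#'
#' @param net An `interaction_network` (the existing knowledge).
#' @param new_edges Data frame with columns `source`, `relation`, `target`
#'   (or an `interaction_network`).
#' @return List with `components_before`, `components_after` (integers) and
#'   `bridging_edges` (the bridging subset of `new_edges`).
#' @export
connectivity_delta <- function(net, new_edges) {
  stopifnot(inherits(net, "interaction_network"))
  if (inherits(new_edges, "interaction_network")) new_edges <- new_edges$edges
  if (is.null(new_edges$sources))
    new_edges$sources <- rep("", nrow(new_edges))
  g0 <- as_igraph_skeleton(net)
  comp <- igraph::components(g0)
  before <- comp$no
  membership <- comp$membership
  nodes <- network_nodes(net)
  bridging <- logical(nrow(new_edges))
  for (j in seq_len(nrow(new_edges))) {
    a <- new_edges$source[j]; b <- new_edges$target[j]
    bridging[j] <- a %in% nodes && b %in% nodes &&
      membership[[a]] != membership[[b]]
  }
  merged <- merge_networks(list(net, interaction_network(new_edges)))
  after <- igraph::components(as_igraph_skeleton(merged))$no
  out_cols <- intersect(c("source", "relation", "target"), names(new_edges))
  list(components_before = as.integer(before),
       components_after = as.integer(after),
       bridging_edges = {
         b <- new_edges[bridging, out_cols, drop = FALSE]
         rownames(b) <- NULL
         b
       })
}
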