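# ---- controlled vocabularies --------------------------------------------

#' Controlled vocabularies of the pathway-document model
#'
#' Entity classes, interaction signs and interaction mechanisms accepted by
#' the document model. `binding` is the undirected relation and may only be
#' combined with the `unsigned` sign.
#'
#' @return A character vector of allowed tokens.
#' @export
pf_entity_classes <- function() c("protein", "rna", "dna", "chemical")

#' @rdname pf_entity_classes
#' @export
pf_signs <- function() c("activates", "inhibits", "unsigned")

#' @rdname pf_entity_classes
#' @export
pf_mechanisms <- function() {
  c("binding", "transcription-translation",
    "phosphorylation", "dephosphorylation",
    "methylation", "demethylation",
    "ubiquitination", "deubiquitination",
    "other-modification", "unspecified")
}

#' Supported organisms
#'
#' The default organism table covers human plus the model organisms the
#' curation system supports, keyed by NCBI taxonomy identifier. The vector is
#' ordered by default search priority: human first, then the model organisms.
#' Extra taxa (e.g. viral genomes) can be appended via `extra`, a named
#' character vector of `name = taxon`.
#'
#' @param extra Named character vector of additional `name = taxon` entries.
#' @return Named character vector mapping organism name to taxon identifier.
#' @export
#' @examples
#' pf_organisms()[["human"]]
pf_organisms <- function(extra = NULL) {
  base <- c(
    human       = "9606",
    mouse       = "10090",
    rat         = "10116",
    yeast       = "4932",
    fly         = "7227",
    ecoli       = "562",
    worm        = "6239",
    zebrafish   = "7955",
    arabidopsis = "3702"
  )
  if (!is.null(extra)) {
    stopifnot(!is.null(names(extra)), all(nzchar(names(extra))))
    base <- c(base, extra[!extra %in% base])
  }
  base
}

#' Default organism priority order (taxon identifiers)
#' @param extra passed to [pf_organisms()]
#' @return Character vector of taxon identifiers, highest priority first.
#' @export
pf_default_organism_order <- function(extra = NULL) unname(pf_organisms(extra))

# ---- structured error conditions ----------------------------------------

pf_error <- function(code, message, subject = NULL) {
  stop(structure(
    class = c(code, "pathfactoid_error", "error", "condition"),
    list(message = message, call = sys.call(-1), code = code,
         subject = subject)
  ))
}

# ---- constructors -------------------------------------------------------

#' Create an article reference
#'
#' @param title Free-text article title.
#' @param external_id Identifier string (PubMed identifier, DOI, ...), opaque
#'   to the package.
#' @param id_namespace One of `"pubmed"`, `"doi"`, `"none"`. When it is not
#'   `"none"`, `external_id` must be non-empty.
#' @return An `article_ref` list.
#' @export
article_ref <- function(title = "", external_id = "", id_namespace = "none") {
  id_namespace <- match.arg(id_namespace, c("pubmed", "doi", "none"))
  if (id_namespace != "none" && !nzchar(external_id))
    pf_error("malformed-document",
             "external_id must be non-empty when id_namespace is not 'none'")
  structure(list(title = as.character(title),
                 external_id = as.character(external_id),
                 id_namespace = id_namespace),
            class = "article_ref")
}

#' Create an empty pathway document
#'
#' A pathway document is the article-linked container of molecular entities,
#' complexes, interactions and free-text context terms that an author curates
#' and submits. All `add_*` functions are pure: they return the updated
#' document, and the identifier of the newly created element is stored in the
#' `"last_id"` attribute (see [last_id()]).
#'
#' @param article An [article_ref()].
#' @param context_terms Character vector of free-text context terms, stored
#'   verbatim.
#' @return A `pathway_document` object.
#' @export
#' @examples
#' doc <- pathway_document()
#' doc <- add_entity(doc, "p53", "protein")
#' last_id(doc)
pathway_document <- function(article = article_ref(),
                             context_terms = character()) {
  stopifnot(inherits(article, "article_ref"))
  structure(list(
    article = article,
    entities = list(),
    complexes = list(),
    interactions = list(),
    context_terms = as.character(context_terms),
    counters = list(entity = 0L, complex = 0L, interaction = 0L),
    order_counter = 0L
  ), class = "pathway_document")
}

#' Identifier of the most recently added element
#' @param doc A `pathway_document`.
#' @return Character identifier, or `NULL` for a fresh document.
#' @export
last_id <- function(doc) attr(doc, "last_id")

with_last_id <- function(doc, id) {
  attr(doc, "last_id") <- id
  doc
}

resolve_element <- function(doc, id) {
  if (!is.null(doc$entities[[id]])) return(doc$entities[[id]])
  if (!is.null(doc$complexes[[id]])) return(doc$complexes[[id]])
  NULL
}

# ---- add operations -----------------------------------------------------

#' Add a gene, gene product or chemical node
#'
#' Creates an ungrounded entity. Empty labels are allowed at creation time and
#' flagged later by [validate_document()] as `unlabelled-node`.
#'
#' @param doc A `pathway_document`.
#' @param label Free-text label, as the author typed it.
#' @param entity_class One of [pf_entity_classes()].
#' @return The updated document; the fresh entity identifier is available via
#'   [last_id()]. Insertion order is recorded (it drives organism priority in
#'   grounding).
#' @export
add_entity <- function(doc, label, entity_class) {
  stopifnot(inherits(doc, "pathway_document"))
  entity_class <- match.arg(entity_class, pf_entity_classes())
  doc$counters$entity <- doc$counters$entity + 1L
  doc$order_counter <- doc$order_counter + 1L
  id <- paste0("e", doc$counters$entity)
  doc$entities[[id]] <- list(
    entity_id = id,
    label = as.character(label),
    entity_class = entity_class,
    grounding = NULL,
    order = doc$order_counter
  )
  with_last_id(doc, id)
}

#' Assign a database grounding to an entity
#'
#' @param doc A `pathway_document`.
#' @param entity_id Identifier of a plain entity in `doc`.
#' @param namespace `"ncbi-gene"` for genes and their products, `"chebi"` for
#'   chemicals.
#' @param record_id Record identifier inside the namespace.
#' @param organism Taxon identifier, or `NULL` (chemicals carry no organism).
#' @param canonical_name Canonical name of the database record, used as node
#'   name by exporters when present.
#' @return The updated document.
#' @export
set_grounding <- function(doc, entity_id, namespace, record_id,
                          organism = NULL, canonical_name = NULL) {
  stopifnot(inherits(doc, "pathway_document"))
  namespace <- match.arg(namespace, c("ncbi-gene", "chebi"))
  ent <- doc$entities[[entity_id]]
  if (is.null(ent))
    pf_error("unknown-element",
             sprintf("no entity '%s' in document", entity_id), entity_id)
  if (ent$entity_class == "chemical" && namespace != "chebi")
    pf_error("malformed-document",
             "chemical entities ground to the chebi namespace", entity_id)
  if (ent$entity_class != "chemical" && namespace != "ncbi-gene")
    pf_error("malformed-document",
             "gene-product entities ground to the ncbi-gene namespace",
             entity_id)
  doc$entities[[entity_id]]$grounding <- list(
    namespace = namespace,
    record_id = as.character(record_id),
    organism = if (is.null(organism)) NULL else as.character(organism),
    canonical_name = if (is.null(canonical_name)) NULL
                     else as.character(canonical_name)
  )
  with_last_id(doc, entity_id)
}

#' Link two nodes by a signed, mechanism-tagged interaction
#'
#' Directed signs (`activates`, `inhibits`) make the participant order
#' meaningful: the first participant is the controller, the second the
#' target. `binding` is undirected and must be `unsigned`.
#'
#' @param doc A `pathway_document`.
#' @param source_id,target_id Identifiers of entities or complexes in `doc`;
#'   must differ.
#' @param sign One of [pf_signs()].
#' @param mechanism One of [pf_mechanisms()].
#' @return The updated document; interaction identifier via [last_id()].
#' @export
add_interaction <- function(doc, source_id, target_id,
                            sign = "unsigned", mechanism = "unspecified") {
  stopifnot(inherits(doc, "pathway_document"))
  sign <- match.arg(sign, pf_signs())
  mechanism <- match.arg(mechanism, pf_mechanisms())
  if (identical(source_id, target_id))
    pf_error("self-interaction",
             sprintf("participants must differ (got '%s' twice)", source_id),
             source_id)
  for (id in c(source_id, target_id))
    if (is.null(resolve_element(doc, id)))
      pf_error("unknown-element",
               sprintf("participant '%s' not in document", id), id)
  if (mechanism == "binding" && sign != "unsigned")
    pf_error("sign-mechanism-conflict",
             "binding is the undirected relation and cannot carry a sign")
  doc$counters$interaction <- doc$counters$interaction + 1L
  doc$order_counter <- doc$order_counter + 1L
  id <- paste0("i", doc$counters$interaction)
  doc$interactions[[id]] <- list(
    interaction_id = id,
    participants = c(source_id, target_id),
    sign = sign,
    mechanism = mechanism,
    order = doc$order_counter
  )
  with_last_id(doc, id)
}

#' Group entities into a labelled molecular complex
#'
#' Members must be plain entities already in the document; complexes do not
#' nest. A blank label is allowed at creation and flagged by validation.
#'
#' @param doc A `pathway_document`.
#' @param member_ids Identifiers of at least two plain entities.
#' @param label Complex label (may be empty).
#' @return The updated document; complex identifier via [last_id()].
#' @export
add_complex <- function(doc, member_ids, label = "") {
  stopifnot(inherits(doc, "pathway_document"))
  member_ids <- unique(as.character(member_ids))
  if (length(member_ids) < 2)
    pf_error("malformed-document", "a complex needs at least two members")
  for (id in member_ids) {
    if (!is.null(doc$complexes[[id]]))
      pf_error("nested-complex-unsupported",
               sprintf("member '%s' is itself a complex; complexes do not nest",
                       id), id)
    if (is.null(doc$entities[[id]]))
      pf_error("unknown-element",
               sprintf("member '%s' not in document", id), id)
  }
  doc$counters$complex <- doc$counters$complex + 1L
  doc$order_counter <- doc$order_counter + 1L
  id <- paste0("x", doc$counters$complex)
  doc$complexes[[id]] <- list(
    entity_id = id,
    label = as.character(label),
    member_ids = member_ids,
    order = doc$order_counter
  )
  with_last_id(doc, id)
}

#' Add free-text context terms
#' @param doc A `pathway_document`.
#' @param terms Character vector, stored verbatim and uninterpreted.
#' @return The updated document.
#' @export
add_context <- function(doc, terms) {
  stopifnot(inherits(doc, "pathway_document"))
  doc$context_terms <- c(doc$context_terms, as.character(terms))
  doc
}

# ---- validation ---------------------------------------------------------

issue_row <- function(severity, code, subject_id, message, order) {
  data.frame(severity = severity, code = code,
             subject_id = if (is.null(subject_id)) NA_character_ else subject_id,
             message = message, order = order,
             stringsAsFactors = FALSE)
}

#' Validate a pathway document for submission
#'
#' Deterministically checks the submission-time quality rules and returns all
#' findings as a table rather than raising. Codes:
#' \describe{
#'   \item{`empty-document`}{error; no entities and no interactions.}
#'   \item{`unlabelled-node`}{error; an entity or complex has a blank label.}
#'   \item{`ungrounded-entity`}{warning; an entity has no database grounding.}
#'   \item{`isolated-entity`}{warning; an entity participates in no
#'     interaction and no complex.}
#'   \item{`mixed-organisms`}{warning; grounded gene entities span more than
#'     one organism.}
#' }
#' Issues are ordered by severity (errors first), then element insertion
#' order. An empty table means the document is submittable.
#'
#' @param doc A `pathway_document`.
#' @return A data frame with columns `severity`, `code`, `subject_id`,
#'   `message`.
#' @export
#' @examples
#' validate_document(pathway_document())$code
validate_document <- function(doc) {
  stopifnot(inherits(doc, "pathway_document"))
  issues <- list()
  if (length(doc$entities) == 0 && length(doc$interactions) == 0) {
    issues[[length(issues) + 1L]] <-
      issue_row("error", "empty-document", NULL,
                "document contains no entities and no interactions", 0L)
  }
  used <- character()
  for (x in doc$interactions) used <- c(used, x$participants)
  for (x in doc$complexes) used <- c(used, x$member_ids)
  organisms <- character()
  for (ent in doc$entities) {
    if (!nzchar(trimws(ent$label)))
      issues[[length(issues) + 1L]] <-
        issue_row("error", "unlabelled-node", ent$entity_id,
                  sprintf("entity '%s' has no label", ent$entity_id),
                  ent$order)
    if (is.null(ent$grounding))
      issues[[length(issues) + 1L]] <-
        issue_row("warning", "ungrounded-entity", ent$entity_id,
                  sprintf("entity '%s' (%s) is not matched to a database record",
                          ent$entity_id, ent$label), ent$order)
    if (!ent$entity_id %in% used)
      issues[[length(issues) + 1L]] <-
        issue_row("warning", "isolated-entity", ent$entity_id,
                  sprintf("entity '%s' is in no interaction and no complex",
                          ent$entity_id), ent$order)
    if (!is.null(ent$grounding) &&
        identical(ent$grounding$namespace, "ncbi-gene") &&
        !is.null(ent$grounding$organism))
      organisms <- c(organisms, ent$grounding$organism)
  }
  for (cx in doc$complexes) {
    if (!nzchar(trimws(cx$label)))
      issues[[length(issues) + 1L]] <-
        issue_row("error", "unlabelled-node", cx$entity_id,
                  sprintf("complex '%s' has no label", cx$entity_id),
                  cx$order)
  }
  if (length(unique(organisms)) > 1)
    issues[[length(issues) + 1L]] <-
      issue_row("warning", "mixed-organisms", NULL,
                sprintf("grounded genes span %d organisms (%s)",
                        length(unique(organisms)),
                        paste(sort(unique(organisms)), collapse = ", ")), 0L)
  if (length(issues) == 0) {
    return(data.frame(severity = character(), code = character(),
                      subject_id = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  out <- out[order(match(out$severity, c("error", "warning")), out$order), ]
  rownames(out) <- NULL
  out$order <- NULL
  out
}

#' Organisms of previously grounded genes, most recent first
#'
#' Returns the taxon identifiers of grounded gene entities in
#' most-recently-added-first order, deduplicated preserving recency. This is
#' the organism context that steers the priority of subsequent grounding
#' searches.
#'
#' @param doc A `pathway_document`.
#' @return Character vector of taxon identifiers (possibly empty).
#' @export
organism_history <- function(doc) {
  stopifnot(inherits(doc, "pathway_document"))
  ord <- integer(); tax <- character()
  for (ent in doc$entities) {
    g <- ent$grounding
    if (!is.null(g) && identical(g$namespace, "ncbi-gene") &&
        !is.null(g$organism)) {
      ord <- c(ord, ent$order); tax <- c(tax, g$organism)
    }
  }
  if (length(tax) == 0) return(character())
  tax <- tax[order(ord, decreasing = TRUE)]
  unique(tax)
}

#' @export
print.pathway_document <- function(x, ...) {
  cat(sprintf("<pathway_document> %d entities, %d complexes, %d interactions\n",
              length(x$entities), length(x$complexes), length(x$interactions)))
  if (nzchar(x$article$title))
    cat("  article:", x$article$title, "\n")
  if (length(x$context_terms))
    cat("  context:", paste(x$context_terms, collapse = ", "), "\n")
  invisible(x)
}
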