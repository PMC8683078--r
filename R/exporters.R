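# Serialization of pathway documents to community standards: canonical JSON
# (the native round-trip format), SIF (Pathway Commons token set), SBGN-ML
# Process Description, and a minimal BioPAX Level 3 mapping. All exporters
# are deterministic: equal documents yield byte-identical output.

PF_SCHEMA_VERSION <- "1.0"

display_name <- function(el) {
  if (!is.null(el$grounding) && !is.null(el$grounding$canonical_name) &&
      nzchar(el$grounding$canonical_name))
    return(el$grounding$canonical_name)
  if (nzchar(trimws(el$label))) return(el$label)
  el$entity_id
}

# ---- native JSON --------------------------------------------------------

#' Serialize a pathway document to canonical JSON
#'
#' The native raw-data format: fixed key order, element order by insertion,
#' UTF-8. [from_json()] applied to the output reproduces a document equal to
#' the input in every field, and two serializations of equal documents are
#' byte-identical.
#'
#' @param doc A `pathway_document`.
#' @return A JSON string (class `json`).
#' @export
to_json <- function(doc) {
  stopifnot(inherits(doc, "pathway_document"))
  ent_list <- lapply(unname(doc$entities), function(e) {
    out <- list(id = e$entity_id, label = e$label, class = e$entity_class,
                order = e$order)
    if (!is.null(e$grounding)) {
      g <- e$grounding
      out$grounding <- list(namespace = g$namespace, record_id = g$record_id)
      if (!is.null(g$organism)) out$grounding$organism <- g$organism
      if (!is.null(g$canonical_name))
        out$grounding$canonical_name <- g$canonical_name
    }
    out
  })
  cx_list <- lapply(unname(doc$complexes), function(x) {
    list(id = x$entity_id, label = x$label,
         members = as.list(x$member_ids), order = x$order)
  })
  in_list <- lapply(unname(doc$interactions), function(i) {
    list(id = i$interaction_id, source = i$participants[1],
         target = i$participants[2], sign = i$sign,
         mechanism = i$mechanism, order = i$order)
  })
  payload <- list(
    schema_version = PF_SCHEMA_VERSION,
    article = list(title = doc$article$title,
                   external_id = doc$article$external_id,
                   id_namespace = doc$article$id_namespace),
    context_terms = as.list(doc$context_terms),
    entities = ent_list,
    complexes = cx_list,
    interactions = in_list
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

need_field <- function(x, field, path) {
  if (is.null(x[[field]]))
    pf_error("malformed-document",
             sprintf("missing '%s' at %s", field, path))
  x[[field]]
}

#' Parse a pathway document from its native JSON form
#'
#' Validates the schema and the model invariants while parsing. Schema
#' violations raise `malformed-document` naming the offending path; dangling
#' references raise `unknown-element`.
#'
#' @param txt JSON text (string) or a file path to read it from.
#' @return A `pathway_document`.
#' @export
from_json <- function(txt) {
  if (length(txt) == 1 && !grepl("[{]", txt) && file.exists(txt))
    txt <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
  dat <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    pf_error("malformed-document",
                             paste("invalid JSON:", conditionMessage(e))))
  art <- need_field(dat, "article", "$")
  doc <- pathway_document(article_ref(
    title = art$title %||% "",
    external_id = art$external_id %||% "",
    id_namespace = art$id_namespace %||% "none"
  ))
  doc$context_terms <- vapply(dat$context_terms %||% list(),
                              as.character, "")
  for (j in seq_along(dat$entities %||% list())) {
    e <- dat$entities[[j]]
    path <- sprintf("$.entities[%d]", j)
    id <- need_field(e, "id", path)
    cls <- need_field(e, "class", path)
    if (!cls %in% pf_entity_classes())
      pf_error("malformed-document",
               sprintf("unknown entity class '%s' at %s", cls, path))
    if (!is.null(doc$entities[[id]]))
      pf_error("malformed-document", sprintf("duplicate id '%s' at %s",
                                             id, path))
    g <- e$grounding
    doc$entities[[id]] <- list(
      entity_id = id, label = as.character(e$label %||% ""),
      entity_class = cls,
      grounding = if (is.null(g)) NULL else list(
        namespace = need_field(g, "namespace", path),
        record_id = need_field(g, "record_id", path),
        organism = if (is.null(g$organism)) NULL
                   else as.character(g$organism),
        canonical_name = if (is.null(g$canonical_name)) NULL
                         else as.character(g$canonical_name)
      ),
      order = as.integer(e$order %||% j)
    )
  }
  for (j in seq_along(dat$complexes %||% list())) {
    x <- dat$complexes[[j]]
    path <- sprintf("$.complexes[%d]", j)
    id <- need_field(x, "id", path)
    members <- vapply(need_field(x, "members", path), as.character, "")
    if (length(members) < 2)
      pf_error("malformed-document",
               sprintf("complex with < 2 members at %s", path))
    for (m in members)
      if (is.null(doc$entities[[m]]))
        pf_error("unknown-element",
                 sprintf("complex member '%s' at %s not in document",
                         m, path), m)
    doc$complexes[[id]] <- list(
      entity_id = id, label = as.character(x$label %||% ""),
      member_ids = members,
      order = as.integer(x$order %||% j)
    )
  }
  for (j in seq_along(dat$interactions %||% list())) {
    i <- dat$interactions[[j]]
    path <- sprintf("$.interactions[%d]", j)
    id <- need_field(i, "id", path)
    src <- need_field(i, "source", path)
    tgt <- need_field(i, "target", path)
    sign <- need_field(i, "sign", path)
    mech <- need_field(i, "mechanism", path)
    if (!sign %in% pf_signs() || !mech %in% pf_mechanisms())
      pf_error("malformed-document",
               sprintf("invalid sign/mechanism at %s", path))
    if (mech == "binding" && sign != "unsigned")
      pf_error("sign-mechanism-conflict",
               sprintf("binding with a directed sign at %s", path))
    for (p in c(src, tgt))
      if (is.null(doc$entities[[p]]) && is.null(doc$complexes[[p]]))
        pf_error("unknown-element",
                 sprintf("participant '%s' at %s not in document", p, path), p)
    doc$interactions[[id]] <- list(
      interaction_id = id, participants = c(src, tgt),
      sign = sign, mechanism = mech,
      order = as.integer(i$order %||% j)
    )
  }
  suffix_max <- function(ids, prefix) {
    n <- suppressWarnings(as.integer(sub(paste0("^", prefix), "", ids)))
    if (length(n) == 0 || all(is.na(n))) 0L else max(n, na.rm = TRUE)
  }
  doc$counters <- list(
    entity = suffix_max(names(doc$entities), "e"),
    complex = suffix_max(names(doc$complexes), "x"),
    interaction = suffix_max(names(doc$interactions), "i")
  )
  orders <- c(vapply(doc$entities, `[[`, 0L, "order"),
              vapply(doc$complexes, `[[`, 0L, "order"),
              vapply(doc$interactions, `[[`, 0L, "order"), 0L)
  doc$order_counter <- max(orders)
  doc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SIF ----------------------------------------------------------------

sif_relation <- function(interaction) {
  if (interaction$mechanism == "binding") return("interacts-with")
  if (interaction$sign %in% c("activates", "inhibits")) {
    if (interaction$mechanism == "transcription-translation")
      "controls-expression-of" else "controls-state-change-of"
  } else {
    "interacts-with"
  }
}

#' Export a document to Simple Interaction Format edges
#'
#' Mapping onto the Pathway Commons SIF vocabulary: directed interactions
#' with mechanism transcription-translation become `controls-expression-of`,
#' other directed interactions `controls-state-change-of`, binding and
#' unsigned interactions `interacts-with`, and a complex of *n* members
#' expands to the *n(n-1)/2* `in-complex-with` member pairs. Node names are
#' the grounded canonical name when available, else the raw label, else the
#' element identifier. Undirected relations are emitted with lexicographic
#' participant order; edge order is deterministic.
#'
#' @param doc A `pathway_document`.
#' @param sign_column If `TRUE`, append a 4th column carrying the sign of
#'   directed interactions (a documented extension; plain SIF cannot express
#'   it). Off by default.
#' @return Data frame with columns `source`, `relation`, `target` (and
#'   optionally `sign`).
#' @export
to_sif <- function(doc, sign_column = FALSE) {
  stopifnot(inherits(doc, "pathway_document"))
  rows <- list()
  for (i in doc$interactions) {
    rel <- sif_relation(i)
    a <- display_name(resolve_element(doc, i$participants[1]))
    b <- display_name(resolve_element(doc, i$participants[2]))
    if (rel == "interacts-with") {
      pair <- sort(c(a, b)); a <- pair[1]; b <- pair[2]
    }
    rows[[length(rows) + 1L]] <-
      data.frame(source = a, relation = rel, target = b, sign = i$sign,
                 stringsAsFactors = FALSE)
  }
  for (x in doc$complexes) {
    nms <- sort(vapply(x$member_ids,
                       function(m) display_name(doc$entities[[m]]), ""))
    if (length(nms) >= 2) {
      pairs <- utils::combn(nms, 2)
      for (j in seq_len(ncol(pairs)))
        rows[[length(rows) + 1L]] <-
          data.frame(source = pairs[1, j], relation = "in-complex-with",
                     target = pairs[2, j], sign = "unsigned",
                     stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), relation = character(),
               target = character(), sign = character(),
               stringsAsFactors = FALSE)
  if (!sign_column) out$sign <- NULL
  rownames(out) <- NULL
  out
}

#' Write SIF edges to a file
#' @param edges Data frame from [to_sif()] (3 or 4 columns).
#' @param path Output path; tab-separated UTF-8, one edge per line,
#'   newline-terminated.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  lines <- do.call(paste, c(unname(as.list(edges)), sep = "\t"))
  writeLines(enc2utf8(as.character(lines)), path, useBytes = TRUE)
  invisible(path)
}

# ---- SBGN-ML Process Description ----------------------------------------

sbgn_entity_class <- function(entity_class) {
  switch(entity_class,
         protein = "macromolecule",
         rna = "nucleic acid feature",
         dna = "nucleic acid feature",
         chemical = "simple chemical")
}

grid_bbox <- function(node, slot, w = 80, h = 40) {
  xml2::xml_add_child(node, "bbox",
                      x = sprintf("%d", ((slot - 1) %% 8) * 140 + 20),
                      y = sprintf("%d", ((slot - 1) %/% 8) * 100 + 20),
                      w = sprintf("%d", w), h = sprintf("%d", h))
}

add_glyph <- function(parent, id, class, label, slot, w = 80, h = 40) {
  g <- xml2::xml_add_child(parent, "glyph", id = id, class = class)
  if (nzchar(label)) xml2::xml_add_child(g, "label", text = label)
  grid_bbox(g, slot, w, h)
  g
}

#' Export a document to SBGN-ML (Process Description)
#'
#' Entities become `macromolecule`, `nucleic acid feature` or
#' `simple chemical` glyphs; a complex becomes a `complex` glyph containing
#' its member glyphs (members therefore appear once, nested). Each directed
#' interaction is rendered as a `process` glyph with a `stimulation` or
#' `inhibition` arc from the controller and a `production` arc to the target;
#' binding becomes an `association` glyph with `consumption` arcs from both
#' participants; other unsigned interactions a `process` with consumption and
#' production arcs. Every glyph carries a bounding box from a deterministic
#' grid layout (no layout algorithm is implied by the data).
#'
#' @param doc A `pathway_document`.
#' @return SBGN-ML XML text (character scalar).
#' @export
to_sbgnml <- function(doc) {
  stopifnot(inherits(doc, "pathway_document"))
  root <- xml2::xml_new_root("sbgn", xmlns = "http://sbgn.org/libsbgn/0.2")
  map <- xml2::xml_add_child(root, "map", language = "process description")
  in_complex <- unlist(lapply(doc$complexes, `[[`, "member_ids"))
  slot <- 0L
  for (ent in doc$entities) {
    if (ent$entity_id %in% in_complex) next
    slot <- slot + 1L
    add_glyph(map, ent$entity_id, sbgn_entity_class(ent$entity_class),
              display_name(ent), slot)
  }
  for (cx in doc$complexes) {
    slot <- slot + 1L
    g <- add_glyph(map, cx$entity_id, "complex", cx$label, slot,
                   w = 160, h = 100)
    for (m in cx$member_ids) {
      slot <- slot + 1L
      add_glyph(g, doc$entities[[m]]$entity_id,
                sbgn_entity_class(doc$entities[[m]]$entity_class),
                display_name(doc$entities[[m]]), slot)
    }
  }
  arc_n <- 0L
  add_arc <- function(class, source, target) {
    arc_n <<- arc_n + 1L
    a <- xml2::xml_add_child(map, "arc", id = sprintf("arc%d", arc_n),
                             class = class, source = source, target = target)
    xml2::xml_add_child(a, "start", x = "0", y = "0")
    xml2::xml_add_child(a, "end", x = "0", y = "0")
    a
  }
  for (i in doc$interactions) {
    slot <- slot + 1L
    pid <- paste0("proc_", i$interaction_id)
    src <- i$participants[1]; tgt <- i$participants[2]
    if (i$mechanism == "binding") {
      add_glyph(map, pid, "association", "", slot, w = 20, h = 20)
      add_arc("consumption", src, pid)
      add_arc("consumption", tgt, pid)
    } else if (i$sign == "activates") {
      add_glyph(map, pid, "process", "", slot, w = 20, h = 20)
      add_arc("stimulation", src, pid)
      add_arc("production", pid, tgt)
    } else if (i$sign == "inhibits") {
      add_glyph(map, pid, "process", "", slot, w = 20, h = 20)
      add_arc("inhibition", src, pid)
      add_arc("production", pid, tgt)
    } else {
      add_glyph(map, pid, "process", "", slot, w = 20, h = 20)
      add_arc("consumption", src, pid)
      add_arc("production", pid, tgt)
    }
  }
  as.character(root)
}

# ---- BioPAX Level 3 -----------------------------------------------------

BP_NS <- "http://www.biopax.org/release/biopax-level3.owl#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

biopax_entity_class <- function(entity_class) {
  switch(entity_class,
         protein = "bp:Protein", rna = "bp:Rna", dna = "bp:Dna",
         chemical = "bp:SmallMolecule")
}

bp_text <- function(parent, tag, value) {
  xml2::xml_add_child(parent, tag, value,
                      "rdf:datatype" = "http://www.w3.org/2001/XMLSchema#string")
}

bp_ref <- function(parent, tag, id) {
  xml2::xml_add_child(parent, tag, "rdf:resource" = paste0("#", id))
}

#' Export a document to BioPAX Level 3 (RDF/XML)
#'
#' A minimal faithful mapping: entities become `Protein`, `Rna`, `Dna` or
#' `SmallMolecule` with a `UnificationXref` from their grounding; complexes
#' become `Complex` with `component` links; a directed interaction becomes a
#' `Control` (controlType `ACTIVATION` or `INHIBITION`) over a
#' `BiochemicalReaction` on the target — or, for transcription-translation, a
#' `TemplateReactionRegulation` over a `TemplateReaction` producing the
#' target; binding becomes a `ComplexAssembly`; other unsigned interactions a
#' `MolecularInteraction`. Context terms are attached as comments on a
#' `Pathway` element that lists every interaction as a component. Resource
#' identifiers derive deterministically from element identifiers.
#' Modification-site detail (amino-acid positions, mutations) is outside the
#' model and never synthesized.
#'
#' @param doc A `pathway_document`.
#' @return RDF/XML text (character scalar).
#' @export
to_biopax <- function(doc) {
  stopifnot(inherits(doc, "pathway_document"))
  root <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = RDF_NS,
    "xmlns:bp" = BP_NS,
    "xmlns:xsd" = "http://www.w3.org/2001/XMLSchema#",
    "xml:base" = "http://pathfactoid.local/"
  )
  xml2::xml_add_child(root, "bp:Ontology", "rdf:ID" = "ontology")
  for (ent in doc$entities) {
    e <- xml2::xml_add_child(root, biopax_entity_class(ent$entity_class),
                             "rdf:ID" = ent$entity_id)
    bp_text(e, "bp:displayName", display_name(ent))
    if (!is.null(ent$grounding)) {
      xid <- paste0("xref_", ent$entity_id)
      bp_ref(e, "bp:xref", xid)
      x <- xml2::xml_add_child(root, "bp:UnificationXref", "rdf:ID" = xid)
      bp_text(x, "bp:db",
              if (ent$grounding$namespace == "chebi") "ChEBI" else "NCBI Gene")
      bp_text(x, "bp:id", ent$grounding$record_id)
    }
  }
  for (cx in doc$complexes) {
    c_el <- xml2::xml_add_child(root, "bp:Complex", "rdf:ID" = cx$entity_id)
    if (nzchar(cx$label)) bp_text(c_el, "bp:displayName", cx$label)
    for (m in cx$member_ids) bp_ref(c_el, "bp:component", m)
  }
  for (i in doc$interactions) {
    id <- i$interaction_id
    src <- i$participants[1]; tgt <- i$participants[2]
    if (i$mechanism == "binding") {
      a <- xml2::xml_add_child(root, "bp:ComplexAssembly", "rdf:ID" = id)
      bp_ref(a, "bp:left", src)
      bp_ref(a, "bp:left", tgt)
    } else if (i$sign %in% c("activates", "inhibits")) {
      ctype <- if (i$sign == "activates") "ACTIVATION" else "INHIBITION"
      rid <- paste0("rxn_", id)
      if (i$mechanism == "transcription-translation") {
        r <- xml2::xml_add_child(root, "bp:TemplateReaction", "rdf:ID" = rid)
        bp_ref(r, "bp:product", tgt)
        ctl <- xml2::xml_add_child(root, "bp:TemplateReactionRegulation",
                                   "rdf:ID" = id)
      } else {
        r <- xml2::xml_add_child(root, "bp:BiochemicalReaction",
                                 "rdf:ID" = rid)
        bp_ref(r, "bp:left", tgt)
        bp_ref(r, "bp:right", tgt)
        ctl <- xml2::xml_add_child(root, "bp:Control", "rdf:ID" = id)
      }
      bp_text(ctl, "bp:controlType", ctype)
      bp_ref(ctl, "bp:controller", src)
      bp_ref(ctl, "bp:controlled", rid)
    } else {
      m <- xml2::xml_add_child(root, "bp:MolecularInteraction", "rdf:ID" = id)
      bp_ref(m, "bp:participant", src)
      bp_ref(m, "bp:participant", tgt)
    }
  }
  pw <- xml2::xml_add_child(root, "bp:Pathway", "rdf:ID" = "pathway")
  if (nzchar(doc$article$title))
    bp_text(pw, "bp:displayName", doc$article$title)
  for (term in doc$context_terms) bp_text(pw, "bp:comment", term)
  for (id in names(doc$interactions)) bp_ref(pw, "bp:pathwayComponent", id)
  as.character(root)
}
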