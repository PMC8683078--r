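fig1b_doc <- function() {
  # small curated document: a labelled complex of two grounded entities
  # activating a third via phosphorylation, plus one binding interaction
  doc <- pathway_document(article_ref("Ras story", "10.1/x", "doi"))
  doc <- add_context(doc, c("cancer", "signalling"))
  doc <- add_entity(doc, "HRAS", "protein"); a <- last_id(doc)
  doc <- set_grounding(doc, a, "ncbi-gene", "3265", organism = "9606",
                       canonical_name = "HRAS")
  doc <- add_entity(doc, "GTP", "chemical"); b <- last_id(doc)
  doc <- set_grounding(doc, b, "chebi", "15996", canonical_name = "GTP")
  doc <- add_entity(doc, "RAF1", "protein"); c_ent <- last_id(doc)
  doc <- add_entity(doc, "MEK1", "rna"); d_ent <- last_id(doc)
  doc <- add_complex(doc, c(a, b), "Activated ras"); cx <- last_id(doc)
  doc <- add_interaction(doc, cx, c_ent, "activates", "phosphorylation")
  doc <- add_interaction(doc, c_ent, d_ent, "unsigned", "binding")
  doc
}

test_that("JSON serialization is canonical and round-trips the document", {
  doc <- fig1b_doc()
  txt <- to_json(doc)
  expect_identical(as.character(txt), as.character(to_json(doc)))
  back <- from_json(as.character(txt))
  expect_equal(doc_fields(back), doc_fields(doc))
  expect_identical(validate_document(back), validate_document(doc))
  # empty document round-trips too
  empty <- pathway_document()
  expect_equal(doc_fields(from_json(as.character(to_json(empty)))),
               doc_fields(empty))
})

test_that("JSON round-trip is the identity on generated documents", {
  for (seed in 1:25) {
    doc <- generate_document(n_entities = sample(4:10, 1),
                             n_interactions = sample(1:4, 1),
                             n_complexes = sample(0:1, 1), seed = seed)
    back <- from_json(as.character(to_json(doc)))
    expect_equal(doc_fields(back), doc_fields(doc))
  }
})

test_that("malformed JSON inputs raise structured errors", {
  expect_error(from_json("{ not json"), class = "malformed-document")
  expect_error(from_json('{"article": {"id_namespace": "none"}, "entities": [],
    "interactions": [{"id": "i1", "source": "e9", "target": "e8",
    "sign": "activates", "mechanism": "unspecified"}]}'),
    class = "unknown-element")
  expect_error(from_json('{"entities": []}'), class = "malformed-document")
})

test_that("SIF export follows the Pathway Commons relation mapping", {
  doc <- pathway_document()
  doc <- add_entity(doc, "SENP1", "protein"); a <- last_id(doc)
  doc <- add_entity(doc, "SIRT3", "protein"); b <- last_id(doc)
  doc <- add_interaction(doc, a, b, "activates", "unspecified")
  edges <- to_sif(doc)
  expect_equal(unname(unlist(edges[1, ])),
               c("SENP1", "controls-state-change-of", "SIRT3"))
  # transcription-translation is expression control
  doc <- add_entity(doc, "TFAM", "dna"); d <- last_id(doc)
  doc <- add_interaction(doc, b, d, "activates", "transcription-translation")
  expect_true(any(to_sif(doc)$relation == "controls-expression-of"))
  # binding is undirected with canonical (lexicographic) order
  doc2 <- pathway_document()
  doc2 <- add_entity(doc2, "ZZZ3", "protein"); z <- last_id(doc2)
  doc2 <- add_entity(doc2, "AAA1", "protein"); a2 <- last_id(doc2)
  doc2 <- add_interaction(doc2, z, a2, "unsigned", "binding")
  e2 <- to_sif(doc2)
  expect_equal(e2$source, "AAA1")
  expect_equal(e2$relation, "interacts-with")
  expect_equal(e2$target, "ZZZ3")
  # a 3-member complex expands into 3 member pairs
  doc3 <- pathway_document()
  for (nm in c("A", "B", "C")) doc3 <- add_entity(doc3, nm, "protein")
  doc3 <- add_complex(doc3, names(doc3$entities), "trimer")
  e3 <- to_sif(doc3)
  expect_equal(nrow(e3), 3)
  expect_true(all(e3$relation == "in-complex-with"))
  # optional 4th column carries the sign
  expect_equal(to_sif(doc)$sign, NULL)
  expect_equal(to_sif(doc, sign_column = TRUE)$sign[1], "activates")
})

test_that("SIF edge count matches the closed-form formula on generated documents", {
  for (seed in 1:15) {
    n_cx <- sample(0:2, 1)
    doc <- generate_document(n_entities = 8, n_interactions = sample(2:6, 1),
                             n_complexes = n_cx, seed = 100 + seed)
    edges <- to_sif(doc)
    expected <- length(doc$interactions) +
      sum(vapply(doc$complexes,
                 function(x) choose(length(x$member_ids), 2), numeric(1)))
    expect_equal(nrow(edges), expected)
  }
})

test_that("SBGN-ML output is well-formed with one glyph per element", {
  doc <- fig1b_doc()
  xml <- to_sbgnml(doc)
  parsed <- xml2::read_xml(xml)
  glyphs <- xml2::xml_find_all(parsed, "//*[local-name()='glyph']")
  classes <- xml2::xml_attr(glyphs, "class")
  entity_classes <- c("macromolecule", "nucleic acid feature",
                      "simple chemical")
  expect_equal(sum(classes %in% entity_classes), length(doc$entities))
  expect_equal(sum(classes == "complex"), length(doc$complexes))
  expect_equal(sum(classes %in% c("process", "association")),
               length(doc$interactions))
  # complex glyph contains its member glyphs
  cx <- glyphs[classes == "complex"]
  inner <- xml2::xml_find_all(cx, ".//*[local-name()='glyph']")
  expect_equal(length(inner), 2)
  # every glyph has a bounding box
  expect_equal(
    length(xml2::xml_find_all(parsed,
      "//*[local-name()='glyph']/*[local-name()='bbox']")),
    length(glyphs))
  # arcs: one pair per interaction
  arcs <- xml2::xml_find_all(parsed, "//*[local-name()='arc']")
  expect_equal(length(arcs), 2 * length(doc$interactions))
  expect_true("stimulation" %in% xml2::xml_attr(arcs, "class"))
  # a single chemical makes a single simple-chemical glyph
  doc1 <- add_entity(pathway_document(), "ATP", "chemical")
  p1 <- xml2::read_xml(to_sbgnml(doc1))
  g1 <- xml2::xml_find_all(p1, "//*[local-name()='glyph']")
  expect_equal(xml2::xml_attr(g1, "class"), "simple chemical")
})

test_that("BioPAX export maps entities, controls, template reactions and bindings", {
  doc <- pathway_document()
  doc <- add_entity(doc, "SENP1", "protein"); a <- last_id(doc)
  doc <- set_grounding(doc, a, "ncbi-gene", "29843", organism = "9606",
                       canonical_name = "SENP1")
  doc <- add_entity(doc, "SIRT3", "protein"); b <- last_id(doc)
  doc <- add_interaction(doc, a, b, "activates", "unspecified")
  parsed <- xml2::read_xml(to_biopax(doc))
  ln <- function(tag) xml2::xml_find_all(parsed,
    sprintf("//*[local-name()='%s']", tag))
  expect_equal(length(ln("Protein")), 2)
  expect_equal(length(ln("UnificationXref")), 1)
  ctl <- ln("Control")
  expect_equal(length(ctl), 1)
  expect_equal(xml2::xml_text(xml2::xml_find_first(
    ctl[[1]], ".//*[local-name()='controlType']")), "ACTIVATION")
  # transcription-translation becomes a template reaction regulation
  doc <- add_entity(doc, "SOD2", "protein"); d <- last_id(doc)
  doc <- add_interaction(doc, b, d, "activates", "transcription-translation")
  p2 <- xml2::read_xml(to_biopax(doc))
  ln2 <- function(tag) xml2::xml_find_all(p2,
    sprintf("//*[local-name()='%s']", tag))
  expect_equal(length(ln2("TemplateReaction")), 1)
  expect_equal(length(ln2("TemplateReactionRegulation")), 1)
  # binding becomes a complex assembly
  doc <- add_interaction(doc, a, d, "unsigned", "binding")
  p3 <- xml2::read_xml(to_biopax(doc))
  expect_equal(length(xml2::xml_find_all(p3,
    "//*[local-name()='ComplexAssembly']")), 1)
  # context terms ride along as pathway comments; empty document still valid
  doc <- add_context(doc, "oxidative stress")
  p4 <- xml2::read_xml(to_biopax(doc))
  expect_true("oxidative stress" %in% xml2::xml_text(
    xml2::xml_find_all(p4, "//*[local-name()='comment']")))
  expect_silent(xml2::read_xml(to_biopax(pathway_document())))
})

test_that("exporters are deterministic: equal documents give byte-identical output", {
  d1 <- generate_document(6, 4, 1, seed = 99)
  d2 <- generate_document(6, 4, 1, seed = 99)
  expect_identical(as.character(to_json(d1)), as.character(to_json(d2)))
  expect_identical(to_sbgnml(d1), to_sbgnml(d2))
  expect_identical(to_biopax(d1), to_biopax(d2))
  expect_identical(to_sif(d1), to_sif(d2))
})

test_that("SIF files written to disk re-read as the same network", {
  doc <- fig1b_doc()
  path <- tempfile(fileext = ".sif")
  write_sif(to_sif(doc), path)
  net <- read_sif(path)
  expect_equal(nrow(net$edges), nrow(to_sif(doc)))
})
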