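# pathfactoid

Computational core for **author-driven pathway curation**: the structured
data model, entity-grounding search, validation, standard-format exporters
and network-integration queries that let working biologists turn a described
molecular interaction (e.g. *"SENP1 activates SIRT3"*) into computable
pathway knowledge.

It is aimed at people building or studying curation pipelines: it has no
drawing UI — the document is built and inspected programmatically or through
a small command-line tool.

## What it does

* **Document model** — typed entities (protein / RNA / DNA / chemical),
  labelled complexes (flat, ≥ 2 members), signed mechanism-tagged pairwise
  interactions (activates / inhibits / unsigned × binding,
  transcription-translation, phosphorylation, ...), free-text context terms,
  all linked to an article reference. Submission-time validation returns a
  deterministic issue table (`empty-document`, `unlabelled-node`,
  `ungrounded-entity`, `isolated-entity`, `mixed-organisms`).
* **Entity grounding** — maps a free-text label to an NCBI Gene or ChEBI
  record by ranked synonym similarity. Similarity is a normalized
  edit-distance ratio, `s(q,n) = 1 − d(q,n)/max(|q|,|n|)`, taken as the
  maximum over a record's name set after case folding, punctuation removal
  and Greek-glyph spelling (`NF-κB` ≡ `nf kappab`). Ties are resolved by
  *organism priority*: organisms of genes already in the document outrank
  the default order (human first). `evaluate_topk()` measures top-k
  retrieval accuracy against a benchmark.
* **Exporters** — canonical JSON (lossless round-trip), SIF with the
  Pathway Commons relation tokens, SBGN-ML Process Description, and a
  minimal BioPAX Level 3.
* **Network queries** — read and merge multi-source SIF networks, enumerate
  simple regulatory paths with a bounded number of edges, and report which
  newly curated edges *bridge* previously disconnected components.
* **Fixtures** — seeded generators for synonym dictionaries, grounding
  benchmarks, pathway documents and schematic networks, so everything above
  is testable offline.

## Worked example

```r
library(pathfactoid)

## curate a two-interaction document
doc <- pathway_document(article_ref("SENP1 desumoylates SIRT3", "10.0/x", "doi"))
doc <- add_entity(doc, "SENP1", "protein"); senp1 <- last_id(doc)
doc <- add_entity(doc, "SIRT3", "protein"); sirt3 <- last_id(doc)
doc <- add_interaction(doc, senp1, sirt3, "activates", "unspecified")

## ground labels against a dictionary (shipped example, TSV)
dict <- read_dictionary(system.file("extdata", "example_dictionary.tsv",
                                    package = "pathfactoid"))
doc <- ground_document(doc, synonym_index(dict))
doc$entities[[senp1]]$grounding$record_id
#> [1] "29843"
validate_document(doc)        # 0 rows: submittable
#> [1] severity   code       subject_id message   
#> <0 rows> (or 0-length row.names)

## export and integrate
to_sif(doc)
#>   source                 relation target
#> 1  SENP1 controls-state-change-of  SIRT3
fx <- schematic_networks()
base <- merge_networks(list(fx$sumo_processing, fx$mito_biogenesis))
connectivity_delta(base, to_sif(doc))[c("components_before", "components_after")]
#> $components_before
#> [1] 2
#> $components_after
#> [1] 1
paths_between(fx$senp1_sod2_chain, "SENP1", "SOD2", limit = 3)
#> [[1]]
#> [1] "SENP1" "SIRT3" "FOXO3" "SOD2"
```

The grounding assigns SENP1 its human gene record; the single curated edge
joins the two previously disconnected schematic pathways (2 components → 1);
and a three-edge regulatory route links SENP1 to SOD2 within the standard
path limit of 3.

A command-line wrapper with the same functionality ships in
`inst/scripts/pathfactoid`:

```sh
pathfactoid validate doc.json
pathfactoid ground doc.json --dict dict.tsv -o grounded.json
pathfactoid export grounded.json --format biopax -o doc.owl
pathfactoid paths merged.sif --from SENP1 --to SOD2 --limit 3
```

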