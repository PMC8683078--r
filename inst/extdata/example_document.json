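{
  "schema_version": "1.0",
  "article": {
    "title": "SENP1-mediated desumoylation activates SIRT3",
    "external_id": "10.0000/example",
    "id_namespace": "doi"
  },
  "context_terms": [
    "mitochondria",
    "oxidative stress"
  ],
  "entities": [
    {
      "id": "e1",
      "label": "SENP1",
      "class": "protein",
      "order": 1,
      "grounding": {
        "namespace": "ncbi-gene",
        "record_id": "29843",
        "organism": "9606",
        "canonical_name": "SENP1"
      }
    },
    {
      "id": "e2",
      "label": "SIRT3",
      "class": "protein",
      "order": 2,
      "grounding": {
        "namespace": "ncbi-gene",
        "record_id": "23410",
        "organism": "9606",
        "canonical_name": "SIRT3"
      }
    },
    {
      "id": "e3",
      "label": "SOD2",
      "class": "protein",
      "order": 3,
      "grounding": {
        "namespace": "ncbi-gene",
        "record_id": "6648",
        "organism": "9606",
        "canonical_name": "SOD2"
      }
    }
  ],
  "complexes": [],
  "interactions": [
    {
      "id": "i1",
      "source": "e1",
      "target": "e2",
      "sign": "activates",
      "mechanism": "unspecified",
      "order": 4
    },
    {
      "id": "i2",
      "source": "e2",
      "target": "e3",
      "sign": "activates",
      "mechanism": "other-modification",
      "order": 5
    }
  ]
}
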