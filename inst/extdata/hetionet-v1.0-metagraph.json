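{
  "metanodes": [
    {"identifier": "Anatomy", "abbreviation": "A"},
    {"identifier": "Biological Process", "abbreviation": "BP"},
    {"identifier": "Cellular Component", "abbreviation": "CC"},
    {"identifier": "Compound", "abbreviation": "C"},
    {"identifier": "Disease", "abbreviation": "D"},
    {"identifier": "Gene", "abbreviation": "G"},
    {"identifier": "Molecular Function", "abbreviation": "MF"},
    {"identifier": "Pathway", "abbreviation": "PW"},
    {"identifier": "Pharmacologic Class", "abbreviation": "PC"},
    {"identifier": "Side Effect", "abbreviation": "SE"},
    {"identifier": "Symptom", "abbreviation": "S"}
  ],
  "metaedges": [
    {"source": "A", "target": "G", "kind": "downregulates", "abbreviation": "d", "directed": false},
    {"source": "A", "target": "G", "kind": "expresses", "abbreviation": "e", "directed": false},
    {"source": "A", "target": "G", "kind": "upregulates", "abbreviation": "u", "directed": false},
    {"source": "C", "target": "G", "kind": "binds", "abbreviation": "b", "directed": false},
    {"source": "C", "target": "SE", "kind": "causes", "abbreviation": "c", "directed": false},
    {"source": "C", "target": "G", "kind": "downregulates", "abbreviation": "d", "directed": false},
    {"source": "C", "target": "D", "kind": "palliates", "abbreviation": "p", "directed": false},
    {"source": "C", "target": "C", "kind": "resembles", "abbreviation": "r", "directed": false},
    {"source": "C", "target": "D", "kind": "treats", "abbreviation": "t", "directed": false},
    {"source": "C", "target": "G", "kind": "upregulates", "abbreviation": "u", "directed": false},
    {"source": "D", "target": "G", "kind": "associates", "abbreviation": "a", "directed": false},
    {"source": "D", "target": "G", "kind": "downregulates", "abbreviation": "d", "directed": false},
    {"source": "D", "target": "A", "kind": "localizes", "abbreviation": "l", "directed": false},
    {"source": "D", "target": "S", "kind": "presents", "abbreviation": "p", "directed": false},
    {"source": "D", "target": "D", "kind": "resembles", "abbreviation": "r", "directed": false},
    {"source": "D", "target": "G", "kind": "upregulates", "abbreviation": "u", "directed": false},
    {"source": "G", "target": "G", "kind": "covaries", "abbreviation": "c", "directed": false},
    {"source": "G", "target": "G", "kind": "interacts", "abbreviation": "i", "directed": false},
    {"source": "G", "target": "BP", "kind": "participates", "abbreviation": "p", "directed": false},
    {"source": "G", "target": "CC", "kind": "participates", "abbreviation": "p", "directed": false},
    {"source": "G", "target": "MF", "kind": "participates", "abbreviation": "p", "directed": false},
    {"source": "G", "target": "PW", "kind": "participates", "abbreviation": "p", "directed": false},
    {"source": "G", "target": "G", "kind": "regulates", "abbreviation": "r", "directed": true},
    {"source": "PC", "target": "C", "kind": "includes", "abbreviation": "i", "directed": false}
  ]
}
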