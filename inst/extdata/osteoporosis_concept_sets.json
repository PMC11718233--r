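[
  {
    "name": "osteoporosis diagnosis",
    "expression": {
      "items": [
        {
          "concept": {
            "CONCEPT_ID": 1000
          },
          "includeDescendants": true,
          "isExcluded": false
        }
      ]
    }
  },
  {
    "name": "osteoporosis treatments",
    "expression": {
      "items": [
        {
          "concept": {
            "CONCEPT_ID": 3001
          },
          "includeDescendants": false,
          "isExcluded": false
        },
        {
          "concept": {
            "CONCEPT_ID": 3002
          },
          "includeDescendants": false,
          "isExcluded": false
        }
      ]
    }
  }
]
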