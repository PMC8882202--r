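{
  "recurrence_threshold": 10,
  "version": "1",
  "root": {
    "label": "freq_standalone",
    "kind": "test",
    "factor": "af",
    "op": "ge",
    "value": 0.005,
    "yes": {
      "label": "common_benign",
      "kind": "leaf",
      "class": 1,
      "adjust": []
    },
    "no": {
      "label": "freq_benign",
      "kind": "test",
      "factor": "af",
      "op": "ge",
      "value": 0.0005,
      "yes": {
        "label": "frequent_likely_benign",
        "kind": "leaf",
        "class": 2,
        "adjust": []
      },
      "no": {
        "label": "truncating",
        "kind": "test",
        "factor": "null_type",
        "op": "eq",
        "value": true,
        "yes": {
          "label": "rare_truncating",
          "kind": "leaf",
          "class": 4,
          "adjust": ["assay", "recurrence"]
        },
        "no": {
          "label": "insilico_pathogenic",
          "kind": "test",
          "factor": "insilico",
          "op": "eq",
          "value": "supports_pathogenic",
          "yes": {
            "label": "predicted_deleterious",
            "kind": "leaf",
            "class": 4,
            "adjust": "assay"
          },
          "no": {
            "label": "insilico_benign",
            "kind": "test",
            "factor": "insilico",
            "op": "eq",
            "value": "supports_benign",
            "yes": {
              "label": "predicted_neutral",
              "kind": "leaf",
              "class": 2,
              "adjust": "assay"
            },
            "no": {
              "label": "segregation",
              "kind": "test",
              "factor": "segregation",
              "op": "eq",
              "value": "segregates",
              "yes": {
                "label": "cosegregating",
                "kind": "leaf",
                "class": 4,
                "adjust": "assay"
              },
              "no": {
                "label": "non_segregation",
                "kind": "test",
                "factor": "segregation",
                "op": "eq",
                "value": "non_segregating",
                "yes": {
                  "label": "non_segregating",
                  "kind": "leaf",
                  "class": 2,
                  "adjust": "assay"
                },
                "no": {
                  "label": "default_vus",
                  "kind": "leaf",
                  "class": 3,
                  "adjust": "assay"
                }
              }
            }
          }
        }
      }
    }
  }
}
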