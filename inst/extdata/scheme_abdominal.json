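{
  "id": "onset",
  "type": "router",
  "question": "Is the abdominal complaint of acute onset?",
  "finding": "acute_onset",
  "children": {
    "present": { "action": "acute abdominal pain work-up" },
    "absent": {
      "id": "organic_history",
      "type": "reviser",
      "question": "Do history findings support an organic cause?",
      "category": "organic",
      "table": "abdominal",
      "modalities": ["history"],
      "threshold": 0.1,
      "prior": "diseases",
      "children": {
        "above": { "action": "pursue organic work-up" },
        "below": {
          "id": "organic_labs",
          "type": "reviser",
          "question": "Do laboratory findings support an organic cause?",
          "category": "organic",
          "table": "abdominal",
          "modalities": ["laboratory"],
          "threshold": 0.1,
          "prior": "carry",
          "children": {
            "above": { "action": "pursue organic work-up" },
            "below": {
              "id": "neoplasm",
              "type": "reviser",
              "question": "Could a neoplasm still explain the complaint?",
              "category": "organic/neoplasm",
              "table": "abdominal",
              "threshold": 0.05,
              "prior": "diseases",
              "children": {
                "above": { "action": "refer to a specialist" },
                "below": { "action": "symptomatic treatment & follow-up" }
              }
            }
          }
        }
      }
    }
  }
}
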