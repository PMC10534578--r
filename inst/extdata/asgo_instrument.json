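{
  "instrument": "ASGO",
  "description": "General Assessment of the Hospitalised Patient: 10 non-medical functions weighted by commitment to support needs. Each modality's ranking value equals variable weight x level rank. Four variables allow more than one modality to be selected.",
  "version": "1.0",
  "variables": [
    {
      "name": "mental_status",
      "label": "Mental status",
      "weight": 1.6,
      "multi_select": false,
      "modalities": [
        {"level": 1, "label": "Awake and lucid", "ranking_value": 1.6},
        {"level": 2, "label": "Non-responsive", "ranking_value": 3.2},
        {"level": 3, "label": "Comatose", "ranking_value": 4.8},
        {"level": 4, "label": "Disoriented behaviour", "ranking_value": 6.4},
        {"level": 5, "label": "Slowed thinking", "ranking_value": 8.0},
        {"level": 6, "label": "Memory loss", "ranking_value": 9.6},
        {"level": 7, "label": "Forgetfulness and confusion", "ranking_value": 11.2}
      ]
    },
    {
      "name": "movement",
      "label": "Movement/ambulation",
      "weight": 1.3,
      "multi_select": false,
      "modalities": [
        {"level": 1, "label": "Full movement", "ranking_value": 1.3},
        {"level": 2, "label": "Walking aids", "ranking_value": 2.6},
        {"level": 3, "label": "Autonomous wheelchair user", "ranking_value": 3.9},
        {"level": 4, "label": "Bedridden", "ranking_value": 5.2},
        {"level": 5, "label": "Bedridden with risk of falling", "ranking_value": 6.5},
        {"level": 7, "label": "Supported by someone", "ranking_value": 9.1}
      ]
    },
    {
      "name": "circulation",
      "label": "Circulation",
      "weight": 0.4,
      "multi_select": true,
      "modalities": [
        {"level": 1, "label": "Adequate", "ranking_value": 0.4},
        {"level": 2, "label": "Oedemas", "ranking_value": 0.8},
        {"level": 3, "label": "Cold", "ranking_value": 1.2},
        {"level": 4, "label": "Hypotension", "ranking_value": 1.6},
        {"level": 5, "label": "Fatigue", "ranking_value": 2.0},
        {"level": 6, "label": "Erythema", "ranking_value": 2.4},
        {"level": 7, "label": "Skin ulcers", "ranking_value": 2.8}
      ]
    },
    {
      "name": "breathing",
      "label": "Breathing",
      "weight": 0.4,
      "multi_select": false,
      "modalities": [
        {"level": 1, "label": "Adequate", "ranking_value": 0.4},
        {"level": 2, "label": "Tracheostomy", "ranking_value": 0.8},
        {"level": 3, "label": "Mechanical ventilation", "ranking_value": 1.2},
        {"level": 4, "label": "Body position required", "ranking_value": 1.6},
        {"level": 5, "label": "Self-management of respiratory therapy", "ranking_value": 2.0},
        {"level": 6, "label": "Fatigue", "ranking_value": 2.4},
        {"level": 7, "label": "Impaired, with O2 support", "ranking_value": 2.8}
      ]
    },
    {
      "name": "elimination",
      "label": "Elimination/sphincters control",
      "weight": 1.2,
      "multi_select": true,
      "modalities": [
        {"level": 1, "label": "Normal", "ranking_value": 1.2},
        {"level": 2, "label": "Urinary catheter", "ranking_value": 2.4},
        {"level": 3, "label": "Faecal incontinence", "ranking_value": 3.6},
        {"level": 4, "label": "Urinary incontinence", "ranking_value": 4.8},
        {"level": 5, "label": "Partial urinary control", "ranking_value": 6.0},
        {"level": 6, "label": "Faecal partial control", "ranking_value": 7.2},
        {"level": 7, "label": "Enterostomy", "ranking_value": 8.4}
      ]
    },
    {
      "name": "feeding",
      "label": "Feeding",
      "weight": 0.6,
      "multi_select": true,
      "modalities": [
        {"level": 1, "label": "Free", "ranking_value": 0.6},
        {"level": 2, "label": "Enteral nutrition", "ranking_value": 1.2},
        {"level": 3, "label": "Parenteral nutrition", "ranking_value": 1.8},
        {"level": 4, "label": "Mouth ulcers/infections", "ranking_value": 2.4},
        {"level": 5, "label": "Difficult/painful swallowing", "ranking_value": 3.0},
        {"level": 6, "label": "Limited/absent chewing", "ranking_value": 3.6},
        {"level": 7, "label": "Spoon-fed/direct eating help", "ranking_value": 4.2}
      ]
    },
    {
      "name": "sleep_wake",
      "label": "Sleep/wake",
      "weight": 1.2,
      "multi_select": false,
      "modalities": [
        {"level": 1, "label": "Regular", "ranking_value": 1.2},
        {"level": 2, "label": "Sleep medicine", "ranking_value": 2.4},
        {"level": 3, "label": "Regular bedtime routine", "ranking_value": 3.6},
        {"level": 4, "label": "Tiredness", "ranking_value": 4.8},
        {"level": 5, "label": "Frequent awakenings", "ranking_value": 6.0},
        {"level": 6, "label": "Unrefreshing sleep", "ranking_value": 7.2},
        {"level": 7, "label": "Disturbed sleep, apnoea", "ranking_value": 8.4}
      ]
    },
    {
      "name": "sensory",
      "label": "Sensory system",
      "weight": 0.6,
      "multi_select": true,
      "modalities": [
        {"level": 1, "label": "Normal", "ranking_value": 0.6},
        {"level": 2, "label": "Hearing impaired", "ranking_value": 1.2},
        {"level": 3, "label": "Visually impaired", "ranking_value": 1.8},
        {"level": 4, "label": "Deaf", "ranking_value": 2.4},
        {"level": 5, "label": "Blind", "ranking_value": 3.0},
        {"level": 6, "label": "Environmental perception impaired", "ranking_value": 3.6},
        {"level": 7, "label": "Pain", "ranking_value": 4.2}
      ]
    },
    {
      "name": "self_care",
      "label": "Self-care ability",
      "weight": 1.3,
      "multi_select": false,
      "modalities": [
        {"level": 1, "label": "Complete", "ranking_value": 1.3},
        {"level": 2, "label": "Minimal bathing assistance", "ranking_value": 2.6},
        {"level": 3, "label": "Major bathing assistance", "ranking_value": 3.9},
        {"level": 4, "label": "Unable to dress", "ranking_value": 5.2},
        {"level": 5, "label": "Passive movement", "ranking_value": 6.5},
        {"level": 6, "label": "Following movements", "ranking_value": 7.8},
        {"level": 7, "label": "Basic moves", "ranking_value": 9.1}
      ]
    },
    {
      "name": "mood",
      "label": "Prevailing mood",
      "weight": 1.4,
      "multi_select": false,
      "modalities": [
        {"level": 1, "label": "Stable", "ranking_value": 1.4},
        {"level": 2, "label": "Needs to be encouraged", "ranking_value": 2.8},
        {"level": 3, "label": "Social withdrawal", "ranking_value": 4.2},
        {"level": 4, "label": "Emotional stress", "ranking_value": 5.6},
        {"level": 5, "label": "Anxiety", "ranking_value": 7.0},
        {"level": 6, "label": "Apathy", "ranking_value": 8.4},
        {"level": 7, "label": "Depression, suicidal ideation", "ranking_value": 9.8}
      ]
    }
  ],
  "profile_bands": {
    "note": "Bands apply to the FD index (raw score / 10); left-closed, right-open intervals.",
    "minimum": [1.0, 2.6],
    "medium": [2.6, 3.7],
    "high": [3.7, 4.8],
    "maximum": [4.8, null]
  }
}
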