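{
  "findings": [
    {
      "finding_id": "ana_positive",
      "name": "ANA positive",
      "kind": "lab",
      "cost": 5,
      "is_core": false,
      "bundle_id": "b_serology"
    },
    {
      "finding_id": "arthritis_knee",
      "name": "Knee arthritis",
      "kind": "clinical",
      "cost": 0.5,
      "is_core": true
    },
    {
      "finding_id": "conjunctivitis",
      "name": "Conjunctivitis",
      "kind": "clinical",
      "cost": 0.2,
      "is_core": true
    },
    {
      "finding_id": "esr_high",
      "name": "Elevated ESR",
      "kind": "lab",
      "cost": 2,
      "is_core": true,
      "bundle_id": "b_serology"
    },
    {
      "finding_id": "fever",
      "name": "Fever",
      "kind": "clinical",
      "cost": 0.1,
      "is_core": true
    },
    {
      "finding_id": "rash",
      "name": "Rash",
      "kind": "clinical",
      "cost": 0.1,
      "is_core": true
    },
    {
      "finding_id": "tick_exposure",
      "name": "Tick exposure",
      "kind": "clinical",
      "cost": 0.1,
      "is_core": false
    }
  ],
  "diseases": [
    {
      "disease_id": "d_lyme",
      "name": "Tick-borne arthritis",
      "category_ids": "arthritis",
      "incidence": {
        "age_bins": [
          [0, 5],
          [5, 18],
          [18, 120]
        ],
        "incidence_per_bin": [1, 3, 2],
        "gender_multiplier": {
          "male": 1,
          "female": 1
        }
      },
      "treatability": 0.95,
      "severity": 0.4,
      "heritable": false,
      "acuity_class": "weeks"
    },
    {
      "disease_id": "d_sja",
      "name": "Systemic juvenile arthritis",
      "category_ids": "arthritis",
      "incidence": {
        "age_bins": [
          [0, 5],
          [5, 18],
          [18, 120]
        ],
        "incidence_per_bin": [2, 3, 0.5],
        "gender_multiplier": {
          "male": 1,
          "female": 1
        }
      },
      "treatability": 0.8,
      "severity": 0.6,
      "heritable": false,
      "acuity_class": "weeks"
    },
    {
      "disease_id": "d_vasc",
      "name": "Acute febrile vasculitis",
      "category_ids": "vasculitis",
      "incidence": {
        "age_bins": [
          [0, 5],
          [5, 18],
          [18, 120]
        ],
        "incidence_per_bin": [5, 1, 0.1],
        "gender_multiplier": {
          "male": 1.4,
          "female": 0.6
        }
      },
      "treatability": 0.9,
      "severity": 0.8,
      "heritable": false,
      "acuity_class": "days"
    }
  ],
  "associations": [
    {
      "disease_id": "d_lyme",
      "finding_id": "arthritis_knee",
      "frequency": 0.9,
      "onset": [2, 18]
    },
    {
      "disease_id": "d_lyme",
      "finding_id": "esr_high",
      "frequency": 0.6,
      "onset": [2, 18]
    },
    {
      "disease_id": "d_lyme",
      "finding_id": "tick_exposure",
      "frequency": 0.7,
      "onset": [2, 18]
    },
    {
      "disease_id": "d_sja",
      "finding_id": "arthritis_knee",
      "frequency": 0.7,
      "onset": [1, 16]
    },
    {
      "disease_id": "d_sja",
      "finding_id": "esr_high",
      "frequency": 0.9,
      "onset": [0.5, 16]
    },
    {
      "disease_id": "d_sja",
      "finding_id": "fever",
      "frequency": 0.95,
      "onset": [0.5, 16]
    },
    {
      "disease_id": "d_sja",
      "finding_id": "rash",
      "frequency": 0.8,
      "onset": [0.5, 16]
    },
    {
      "disease_id": "d_vasc",
      "finding_id": "conjunctivitis",
      "frequency": 0.85,
      "onset": [0, 5],
      "disappearance": [1, 8]
    },
    {
      "disease_id": "d_vasc",
      "finding_id": "fever",
      "frequency": 1,
      "onset": [0, 5]
    },
    {
      "disease_id": "d_vasc",
      "finding_id": "rash",
      "frequency": 0.9,
      "onset": [0, 5],
      "disappearance": [1, 8]
    }
  ],
  "categories": {
    "arthritis": "Arthritis",
    "vasculitis": "Vasculitis"
  },
  "core_checklist": ["arthritis_knee", "conjunctivitis", "esr_high", "fever", "rash"]
}
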