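{
  "description": "Column codebook for respondent-level cohort CSVs.",
  "columns": {
    "respondent_id": {"type": "identifier"},
    "gender_raw": {"type": "categorical",
                   "codes": ["girl", "boy", "other", "unsure"]},
    "grade": {"type": "integer", "range": [7, 12]},
    "birth_country_raw": {"type": "categorical",
                          "codes": ["sweden", "europe", "world"]},
    "guardian_a_occupation": {"type": "categorical",
      "codes": ["working", "studying", "unemployed", "longterm_sick",
                "sick_short", "other", "unknown"]},
    "guardian_b_occupation": {"type": "categorical",
      "codes": ["working", "studying", "unemployed", "longterm_sick",
                "sick_short", "other", "unknown", "no_second_guardian"]},
    "grade_f_raw": {"type": "categorical",
                    "codes": ["none", "1-2", "3-4", "5_plus"]},
    "truancy_raw": {"type": "categorical",
      "codes": ["no", "per_semester", "per_month", "2-3_per_month",
                "per_week", "several_per_week"]},
    "stress_raw": {"type": "categorical",
      "codes": ["no", "some_extent", "fairly_much", "very_much"]},
    "mhc_1..mhc_14": {"type": "integer", "range": [0, 5],
      "note": "MHC-SF items; 1-3 emotional well-being, 4-8 social, 9-14 psychological functioning"},
    "sdq_1..sdq_25": {"type": "integer", "range": [0, 2],
      "note": "SDQ self-report items in the standard published order"},
    "cyrm_1..cyrm_12": {"type": "integer", "range": [1, 5]},
    "sss": {"type": "integer", "range": [1, 10],
            "note": "MacArthur subjective social status ladder, school version"},
    "height": {"type": "numeric", "unit": "cm"},
    "weight": {"type": "numeric", "unit": "kg"}
  }
}
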