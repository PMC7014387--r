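{
  "comment": "Calibration targets for the synthetic ground truth: published posterior marginals, posteriors given ambulance=yes, and posteriors given claim=compensation. Where the source text and its tables disagree (handrail 0.23 text vs 0.20 table; movement 0.20 text vs 0.23 table; claim-for-compensation 0.03 vs 0.04), the table values are used.",
  "marginals": {
    "age": {"age_0_6": 0.07, "age_7_17": 0.01, "age_18_40": 0.21, "age_41_65": 0.23, "age_66_plus": 0.48},
    "gender": {"male": 0.36, "female": 0.64},
    "accident_time": {"before_0730": 0.03, "t0730_0929": 0.08, "t0930_1729": 0.65, "t1730_1959": 0.10, "after_1930": 0.13},
    "escalator_type": {"long": 0.22, "conventional": 0.78},
    "travel_direction": {"upward": 0.86, "downward": 0.14},
    "company": {"with_company": 0.63, "without_company": 0.37},
    "other_tasks": {"yes": 0.32, "no": 0.68},
    "stand_firm_fail": {"yes": 0.48, "no": 0.52},
    "handrail_not_held": {"yes": 0.20, "no": 0.80},
    "other_passenger_movement": {"yes": 0.23, "no": 0.77},
    "hazard_pattern": {"fall": 0.90, "entrapment": 0.05, "falling_object": 0.04, "other_unknown": 0.01},
    "injured_region": {"multiple": 0.29, "head_neck": 0.27, "lower_extremity": 0.17, "upper_extremity": 0.14, "trunk": 0.10, "unknown": 0.03},
    "claim": {"compensation": 0.03, "tendency": 0.13, "reserve_right": 0.11, "no_claim": 0.69, "unknown": 0.03},
    "ambulance": {"yes": 0.33, "no": 0.67}
  },
  "ambulance_conditionals": {
    "age": {"age_0_6": 0.07, "age_7_17": 0.01, "age_18_40": 0.20, "age_41_65": 0.22, "age_66_plus": 0.50},
    "gender": {"male": 0.33, "female": 0.67},
    "escalator_type": {"long": 0.20, "conventional": 0.80},
    "travel_direction": {"upward": 0.87, "downward": 0.13},
    "other_tasks": {"yes": 0.36, "no": 0.64},
    "stand_firm_fail": {"yes": 0.54, "no": 0.46},
    "other_passenger_movement": {"yes": 0.21, "no": 0.79},
    "injured_region": {"multiple": 0.24, "head_neck": 0.38, "lower_extremity": 0.12, "upper_extremity": 0.08, "trunk": 0.15, "unknown": 0.02}
  },
  "claim_conditionals": {
    "age": {"age_0_6": 0.07, "age_7_17": 0.01, "age_18_40": 0.20, "age_41_65": 0.22, "age_66_plus": 0.50},
    "gender": {"male": 0.35, "female": 0.65},
    "escalator_type": {"long": 0.21, "conventional": 0.79},
    "other_tasks": {"yes": 0.36, "no": 0.64},
    "stand_firm_fail": {"yes": 0.51, "no": 0.49},
    "handrail_not_held": {"yes": 0.22, "no": 0.78},
    "other_passenger_movement": {"yes": 0.20, "no": 0.80},
    "injured_region": {"multiple": 0.26, "head_neck": 0.34, "lower_extremity": 0.15, "upper_extremity": 0.10, "trunk": 0.13, "unknown": 0.02},
    "hazard_pattern": {"fall": 0.83, "entrapment": 0.09, "falling_object": 0.05, "other_unknown": 0.03},
    "ambulance": {"yes": 0.73, "no": 0.27}
  }
}
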