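[
  {
    "node_id": "age",
    "label": "Passenger age band",
    "tier": 1,
    "states": ["age_0_6", "age_7_17", "age_18_40", "age_41_65", "age_66_plus"]
  },
  {
    "node_id": "gender",
    "label": "Passenger gender",
    "tier": 1,
    "states": ["male", "female"]
  },
  {
    "node_id": "accident_time",
    "label": "Time of incident",
    "tier": 1,
    "states": ["before_0730", "t0730_0929", "t0930_1729", "t1730_1959", "after_1930"]
  },
  {
    "node_id": "escalator_type",
    "label": "Escalator type",
    "tier": 1,
    "states": ["long", "conventional"]
  },
  {
    "node_id": "travel_direction",
    "label": "Escalator travel direction",
    "tier": 1,
    "states": ["upward", "downward"]
  },
  {
    "node_id": "company",
    "label": "Riding with company",
    "tier": 1,
    "states": ["with_company", "without_company"]
  },
  {
    "node_id": "other_tasks",
    "label": "Carrying out other tasks",
    "tier": 2,
    "states": ["yes", "no"]
  },
  {
    "node_id": "stand_firm_fail",
    "label": "Failing to stand firm",
    "tier": 2,
    "states": ["yes", "no"]
  },
  {
    "node_id": "handrail_not_held",
    "label": "Not holding the handrail",
    "tier": 2,
    "states": ["yes", "no"]
  },
  {
    "node_id": "other_passenger_movement",
    "label": "Another passenger's movement",
    "tier": 2,
    "states": ["yes", "no"]
  },
  {
    "node_id": "hazard_pattern",
    "label": "Hazard pattern",
    "tier": 3,
    "states": ["fall", "entrapment", "falling_object", "other_unknown"]
  },
  {
    "node_id": "injured_region",
    "label": "Injured body region",
    "tier": 4,
    "states": ["multiple", "head_neck", "lower_extremity", "upper_extremity", "trunk", "unknown"]
  },
  {
    "node_id": "claim",
    "label": "Claim against the operator",
    "tier": 5,
    "states": ["compensation", "tendency", "reserve_right", "no_claim", "unknown"]
  },
  {
    "node_id": "ambulance",
    "label": "Ambulance called",
    "tier": 5,
    "states": ["yes", "no"]
  }
]
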