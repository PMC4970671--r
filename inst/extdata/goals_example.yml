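# Example goal-model configuration: one composite goal with two subgoals
# and one simple goal whose status is the equal-weight mean of two layers.
goals:
  - goal_code: FP
    goal_weight: 1
    subgoals:
      - goal_code: FIS
        weight: 2
        layers:
          status: {fis_b_bmsy: 1}
          pressure: {fishing_pressure: 1}
          resilience: {fisheries_mgmt: 1}
      - goal_code: MAR
        weight: 1
        layers:
          status: {mar_yield: 1}
          pressure: {mar_disease: 1}
          resilience: {mar_regulation: 1}
  - goal_code: AO
    goal_weight: 1
    beta: 0.67
    layers:
      status: {ao_need: 1, ao_access: 1}
      pressure: {artisanal_pressure: 1}
      resilience: {coastal_governance: 1}
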