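# Survey instrument definitions. Each item lists its ordered response
# levels; "favorable" marks the single most favorable level (the top box),
# "values" give numeric scoring values (default: position), and screen-type
# instruments mark the "at_risk" levels that endorse the screen. Item
# wordings and level sets are simplified stand-ins for the source program's
# items; the schema (not the exact wording) is what the pipeline depends on.
instruments:
  hunger_vital_sign:
    scoring: screen
    items:
      hvs_food_run_out:
        levels: ["Often true", "Sometimes true", "Never true"]
        favorable: "Never true"
        at_risk: ["Often true", "Sometimes true"]
      hvs_food_not_last:
        levels: ["Often true", "Sometimes true", "Never true"]
        favorable: "Never true"
        at_risk: ["Often true", "Sometimes true"]
  brief_health_literacy_screen:
    scoring: sum
    items:
      bhls_help_reading:
        levels: ["1", "2", "3", "4", "5"]
        values: [1, 2, 3, 4, 5]
        favorable: "5"
      bhls_confident_forms:
        levels: ["1", "2", "3", "4", "5"]
        values: [1, 2, 3, 4, 5]
        favorable: "5"
      bhls_difficulty_understanding:
        levels: ["1", "2", "3", "4", "5"]
        values: [1, 2, 3, 4, 5]
        favorable: "5"
  neighborhood_disorder:
    scoring: mean
    items:
      nds_graffiti: &nds_item
        levels: ["1", "2", "3", "4", "5"]
        values: [1, 2, 3, 4, 5]
        favorable: "1"
      nds_vandalism: *nds_item
      nds_vacant: *nds_item
      nds_trash: *nds_item
      nds_noise: *nds_item
      nds_crime: *nds_item
  mos_social_support:
    scoring: mean
    items:
      mos_help_sick: &mos_item
        levels: ["1", "2", "3", "4", "5"]
        values: [1, 2, 3, 4, 5]
        favorable: "5"
      mos_confide: *mos_item
      mos_advice: *mos_item
      mos_love: *mos_item
      mos_good_time: *mos_item
      mos_understand: *mos_item
      mos_chores: *mos_item
      mos_distract: *mos_item
  housing_instability:
    scoring: categorical
    barrier_levels: ["Yes"]
    items:
      housing_worried_losing:
        levels: ["Yes", "No"]
        favorable: "No"
  housing_quality:
    scoring: categorical
    barrier_levels: ["Yes"]
    items:
      housing_quality_concern:
        levels: ["Yes", "No"]
        favorable: "No"
  delayed_or_cant_afford_care:
    scoring: categorical
    barrier_levels: ["Yes"]
    items:
      care_delayed:
        levels: ["Yes", "No"]
        favorable: "No"
      care_cant_afford:
        levels: ["Yes", "No"]
        favorable: "No"
  insurance:
    scoring: categorical
    barrier_levels: ["None or not accepted"]
    items:
      insurance_status:
        levels: ["Insured", "None or not accepted"]
        favorable: "Insured"
  income:
    scoring: categorical
    barrier_levels: ["Less than 50k"]
    items:
      annual_income:
        levels: ["Less than 50k", "50-100k", "More than 100k"]
        favorable: "More than 100k"
  education:
    scoring: categorical
    barrier_levels: ["Less than high school degree or equivalent"]
    items:
      highest_education:
        levels:
          - "Less than high school degree or equivalent"
          - "High school degree or equivalent"
          - "Some college, college degree, or advanced degree"
        favorable: "Some college, college degree, or advanced degree"
  english_proficiency:
    scoring: categorical
    barrier_levels: ["Not well"]
    items:
      english_spoken:
        levels: ["Well", "Not well"]
        favorable: "Well"
  employment:
    scoring: categorical
    barrier_levels: ["Out of work"]
    items:
      employment_status:
        levels: ["Employed", "Out of work", "Other"]
        favorable: "Employed"
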