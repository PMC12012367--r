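# Demo code-set registry for diverticular disease severity phenotyping.
# Entries are "VOCAB:pattern" strings; a trailing "*" makes the pattern a
# prefix. Matching is case- and dot-insensitive. These lists are
# illustrative: institutional users should review and replace them with
# their local diagnosis/procedure/imaging code lists.
codesets:
  diverticulosis_dx:
    - "ICD10CM:K57.30"
    - "ICD10CM:K57.31"
    - "ICD10CM:K57.90"
    - "ICD10CM:K57.91"
    - "ICD9CM:562.10"
    - "ICD9CM:562.12"
  diverticulitis_dx:
    - "ICD10CM:K57.2*"
    - "ICD10CM:K57.32"
    - "ICD10CM:K57.33"
    - "ICD10CM:K57.92"
    - "ICD10CM:K57.93"
    - "ICD9CM:562.11"
    - "ICD9CM:562.13"
  diverticular_any_dx:
    - "ICD10CM:K57.30"
    - "ICD10CM:K57.31"
    - "ICD10CM:K57.90"
    - "ICD10CM:K57.91"
    - "ICD10CM:K57.2*"
    - "ICD10CM:K57.32"
    - "ICD10CM:K57.33"
    - "ICD10CM:K57.92"
    - "ICD10CM:K57.93"
    - "ICD9CM:562.1*"
  abdominal_ct:
    - "CPT:74150"
    - "CPT:74160"
    - "CPT:74170"
    - "CPT:74176"
    - "CPT:74177"
    - "CPT:74178"
  lower_gi_endoscopy:
    - "CPT:45330"
    - "CPT:45331"
    - "CPT:45378"
    - "CPT:45380"
    - "CPT:45385"
  colectomy:
    - "CPT:44140"
    - "CPT:44141"
    - "CPT:44143"
    - "CPT:44145"
    - "CPT:44160"
    - "CPT:44204"
    - "CPT:44205"
    - "CPT:44207"
    - "CPT:44208"
  percutaneous_drain:
    - "CPT:49405"
    - "CPT:49406"
  fistula_repair:
    - "CPT:44650"
    - "CPT:44660"
    - "CPT:44661"
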