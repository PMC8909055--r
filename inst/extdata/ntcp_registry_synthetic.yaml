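# Default 16-model NTCP registry for nasopharyngeal-carcinoma plan comparison.
#
# Structure (organ, endpoint, CTS weight, MBS membership, MBS thresholds in
# percentage points) follows the published model set. The dose-response
# PARAMETERS below are SYNTHETIC representative values chosen to produce
# complication probabilities of realistic magnitude for head-and-neck dose
# levels; they are stand-ins, not transcriptions of the cited publications.
# Replace each `parameters:` block with the published values (see the
# `reference` keys) before any clinical use.
#
# Schema per model block:
#   id                  unique model identifier
#   organ               structure_id whose DVH the model reads
#   endpoint            toxicity endpoint, grade and time horizon
#   form                lkb_probit | logistic_linear | loglogistic_d50_gamma
#   dose_summary        {type: mean} | {type: geud, a: <num>} | {type: dx, x: <percent>}
#   parameters          lkb_probit: td50 [Gy(RBE)], m
#                       logistic_linear: intercept, coefficients (named; "dose"
#                         multiplies the dose summary, other names are patient
#                         covariates)
#                       loglogistic_d50_gamma: d50 [Gy(RBE)], gamma50
#   evidence_level      3 or 4
#   mbs                 member of the 7-model selection set
#   threshold_standard / threshold_young   MBS thresholds [percentage points]
#   weight              CTS weight (all 16 weights sum to unity)
composite_threshold: 35
models:
  - id: brain_necrosis_niyazi
    organ: brain
    endpoint: "Necrosis > grade II (2 years)"
    form: logistic_linear
    dose_summary: {type: geud, a: 8}
    parameters:
      intercept: -7.1
      coefficients: {dose: 0.15}
    evidence_level: 3
    mbs: true
    threshold_standard: 10
    threshold_young: 5
    weight: 0.1
    reference: "Niyazi 2020 (proton-derived)"
  - id: temporal_lobe_infarction_kong
    organ: temporal_lobe
    endpoint: "Temporal lobe infarction (>3 months)"
    form: lkb_probit
    dose_summary: {type: geud, a: 10}
    parameters: {td50: 92, m: 0.25}
    evidence_level: 4
    mbs: false
    weight: 0.1
    reference: "Kong 2016"
  - id: rion_palorini
    organ: optic_pathways
    endpoint: "Radiation-induced ocular toxicity RION (>3 months)"
    form: loglogistic_d50_gamma
    dose_summary: {type: dx, x: 1}
    parameters: {d50: 70, gamma50: 2.5}
    evidence_level: 4
    mbs: true
    threshold_standard: 5
    threshold_young: 3
    weight: 0.07
    reference: "Palorini 2019 (photon-derived)"
  - id: visual_loss_palorini
    organ: optic_pathways
    endpoint: "Grade IV visual acuity loss (>3 months)"
    form: loglogistic_d50_gamma
    dose_summary: {type: dx, x: 1}
    parameters: {d50: 76, gamma50: 2.5}
    evidence_level: 4
    mbs: true
    threshold_standard: 5
    threshold_young: 3
    weight: 0.07
    reference: "Palorini 2019 (photon-derived)"
  - id: larynx_edema_rancati
    organ: glottic
    endpoint: "Edema grade II (15 months)"
    form: lkb_probit
    dose_summary: {type: geud, a: 1}
    parameters: {td50: 47, m: 0.2}
    evidence_level: 4
    mbs: false
    weight: 0.005
    reference: "Rancati 2009"
  - id: aspiration_glottic_eisbruch
    organ: glottic
    endpoint: "Aspiration (12 months)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -5.0
      coefficients: {dose: 0.08}
    evidence_level: 4
    mbs: false
    weight: 0.005
    reference: "Eisbruch 2011"
  - id: mucositis_bhide
    organ: oral_cavity
    endpoint: "Mucositis (8 weeks)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -2.8
      coefficients: {dose: 0.03}
    evidence_level: 3
    mbs: true
    threshold_standard: 10
    threshold_young: 10
    weight: 0.05
    reference: "Bhide 2012 (photon-derived, validated for protons)"
  - id: aspiration_pcm_eisbruch
    organ: pcm_superior
    endpoint: "Aspiration (12 months)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -4.5
      coefficients: {dose: 0.05}
    evidence_level: 4
    mbs: false
    weight: 0.005
    reference: "Eisbruch 2011"
  - id: dysphagia_loizeau
    organ: pcm_superior
    endpoint: "Grade II-IV dysphagia (6 months)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -3.2
      coefficients: {dose: 0.025, age: 0.012}
    evidence_level: 3
    mbs: true
    threshold_standard: 5
    threshold_young: 3
    weight: 0.2
    reference: "Loizeau 2021 (Dutch national selection model)"
  - id: swallow_solids_christianen
    organ: pcm_superior
    endpoint: "Problems swallowing solids (6 months)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -6.7
      coefficients: {dose: 0.08}
    evidence_level: 3
    mbs: false
    weight: 0.005
    reference: "Christianen 2012"
  - id: swallow_liquids_christianen
    organ: pcm_superior
    endpoint: "Problems swallowing liquids (6 months)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -7.5
      coefficients: {dose: 0.08}
    evidence_level: 3
    mbs: false
    weight: 0.005
    reference: "Christianen 2012"
  - id: xerostomia_loizeau
    organ: parotid
    endpoint: "Moderate to severe xerostomia (6 months)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -2.2
      coefficients: {dose: 0.06}
    evidence_level: 3
    mbs: true
    threshold_standard: 15
    threshold_young: 15
    weight: 0.2
    reference: "Loizeau 2021 (Dutch national selection model)"
  - id: parotid_flow_roesink
    organ: parotid
    endpoint: "Stimulated flow ratio < 25% (1 year)"
    form: lkb_probit
    dose_summary: {type: geud, a: 1}
    parameters: {td50: 39, m: 0.45}
    evidence_level: 3
    mbs: false
    weight: 0.005
    reference: "Roesink 2001"
  - id: tinnitus_lee
    organ: cochlea
    endpoint: "Tinnitus (2 years)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -3.4
      coefficients: {dose: 0.05}
    evidence_level: 4
    mbs: false
    weight: 0.01
    reference: "Lee 2015"
  - id: trismus_lindblom
    organ: tmj
    endpoint: "Trismus, jaw opening < 35 mm (>3 months)"
    form: loglogistic_d50_gamma
    dose_summary: {type: mean}
    parameters: {d50: 55, gamma50: 1.0}
    evidence_level: 4
    mbs: true
    threshold_standard: 10
    threshold_young: 7.5
    weight: 0.15
    reference: "Lindblom 2014 (photon-derived)"
  - id: hypothyroidism_vogelius
    organ: thyroid
    endpoint: "Hypothyroidism (2 years)"
    form: logistic_linear
    dose_summary: {type: mean}
    parameters:
      intercept: -2.6
      coefficients: {dose: 0.03}
    evidence_level: 3
    mbs: false
    weight: 0.02
    reference: "Vogelius 2011"
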