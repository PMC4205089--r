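{
  "version": "criteria-templates/1.0",
  "comment": "Synthetic eligibility-criterion template bank. Templates are written against the category definitions (not against the detector rule pack, which lives in barrier_rules.json) so that generator/detector agreement is a real drift test. Each category template is constructed to trip exactly its own category; distractors trip none. Slots in {BRACES} are filled from the lexicons below.",
  "temporal": [
    "At least {NSMALL} weeks since therapy with {DRUG}",
    "No more than {NSMALL} months since prior {DRUG} treatment",
    "Diagnosis of {DISEASE} ≤ {NSMALL} years prior to enrollment",
    "More than {NMED} days since the last dose of {DRUG}",
    "Stable dose of {DRUG} for at least {NSMALL} weeks before randomization",
    "Completion of radiotherapy at least {NSMALL} months before study entry"
  ],
  "lab": [
    "Absolute neutrophil count ≥ {NANC}/µL",
    "Serum creatinine ≤ {NDEC} mg/dL",
    "Hemoglobin ≥ {NHGB} g/dL",
    "Platelet count ≥ {NPLT}/µL",
    "Total bilirubin ≤ 1.5 times the upper limit of normal",
    "ECOG performance status {NRANGE}",
    "Karnofsky performance status ≥ {NKPS}%"
  ],
  "subpopulation": [
    "If patients are receiving oral corticosteroids, the dose must be stable",
    "Unless contraindicated, standard premedication is required for all enrolled patients",
    "For patients with diabetes, documented glycemic control is required",
    "Only applies to participants enrolled in the expansion cohort",
    "In case of bilateral disease, the more severely affected eye is designated the study eye"
  ],
  "subpopulation_nested": {
    "parent": "Patients with {CONDITION}:",
    "children": [
      "Documented stable disease on the most recent imaging assessment",
      "Review of the case by the coordinating center is required",
      "Enrollment requires approval by the medical monitor"
    ]
  },
  "patient": [
    "Patient must be willing to comply with radiation safety procedures",
    "Able to walk on a treadmill or cycle on a stationary bike",
    "Willing to {ACTIVITY}",
    "Capable of understanding the study procedures and requirements",
    "Must agree to {ACTIVITY}"
  ],
  "distractor": [
    "Histologically confirmed diagnosis of {DISEASE}",
    "Written documentation of the diagnosis in the medical record",
    "Currently enrolled at a participating study center",
    "Not pregnant and not breastfeeding",
    "Receiving standard of care treatment for {DISEASE}",
    "Diagnosis of {DISEASE} confirmed by biopsy",
    "Good general health in the opinion of the investigator",
    "Negative pregnancy test at screening",
    "Adequate organ function as judged by the treating physician",
    "Resident of the catchment area of a participating center"
  ],
  "distractor_negated": [
    "No active uncontrolled infection",
    "No known allergy to the study medication",
    "No concurrent enrollment in another interventional study",
    "No history of poorly controlled hypertension"
  ],
  "prose": [
    "Patients are eligible when the treating physician considers study participation appropriate and the diagnosis of {DISEASE} has been confirmed by the local site. Further details on eligibility are available from the coordinating center upon request. Enrollment decisions rest with the principal investigator at each site.",
    "Eligibility for this study of {DISEASE} is determined at the discretion of the investigator following a screening interview. The protocol describes the full set of requirements, which are reviewed with each candidate during the consenting visit."
  ],
  "lexicons": {
    "DISEASE": ["chronic myeloid leukemia", "gastrointestinal stromal tumor", "cataract", "neuroblastoma", "rheumatoid arthritis"],
    "DRUG": ["imatinib", "methotrexate", "prednisone", "cyclophosphamide", "etanercept", "rituximab"],
    "CONDITION": ["hepatic involvement", "renal impairment", "central nervous system involvement", "documented cardiac comorbidity"],
    "ACTIVITY": ["attend all scheduled study visits", "complete quality of life questionnaires", "use adequate contraception during the study", "maintain a daily symptom diary"],
    "NSMALL": ["2", "3", "4", "6"],
    "NMED": ["14", "28", "30", "90"],
    "NANC": ["1,000", "1,500"],
    "NDEC": ["1.5", "2.0"],
    "NHGB": ["8", "9", "10"],
    "NPLT": ["75,000", "100,000"],
    "NRANGE": ["0-1", "0-2"],
    "NKPS": ["50", "60", "70"]
  }
}
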