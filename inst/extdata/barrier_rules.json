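{
  "version": "barrier-rules/1.0",
  "comment": "Detector knowledge for the four machine-readability barrier categories. Patterns are PCRE, matched case-insensitively against text with unicode comparators normalized to ASCII. Age/gender criteria are excluded from temporal and lab detection because the registry carries them as structured fields.",
  "temporal": {
    "quantity": "(?:\\d+(?:\\.\\d+)?|one|two|three|four|five|six|seven|eight|nine|ten|twelve)",
    "units": "(?:day|week|month|year|hour)s?\\b",
    "anchors": [
      "\\bsince\\b", "\\bwithin\\b", "\\bprior\\b", "\\bbefore\\b",
      "\\bafter\\b", "\\bat least\\b", "\\bno more than\\b",
      "\\bno less than\\b", "\\bmore than\\b", "\\bless than\\b",
      "\\bpast\\b", "\\bprevious\\b", "\\bfollowing\\b", "[<>]=?"
    ],
    "exclusions": [
      "^\\s*ages?\\b",
      "years?\\s+(?:of\\s+age|or\\s+older|or\\s+younger|and\\s+older|and\\s+younger)",
      "\\baged\\s+\\d"
    ]
  },
  "lab": {
    "analytes": [
      "anc", "absolute neutrophil count", "neutrophil count",
      "white blood cell count", "wbc", "platelet count", "platelets",
      "hemoglobin", "haemoglobin", "bilirubin", "creatinine clearance",
      "creatinine", "ast", "alt", "sgot", "sgpt", "alkaline phosphatase",
      "albumin", "inr", "hba1c", "c-reactive protein", "crp",
      "erythrocyte sedimentation rate", "esr", "egfr", "ejection fraction"
    ],
    "scores": [
      "ecog", "karnofsky", "lansky", "nyha", "das28", "das 28",
      "performance status", "mmse", "rankin", "apgar", "glasgow coma"
    ],
    "numeric_contexts": [
      "[<>]=?\\s*\\d",
      "\\d[\\d.,]*\\s*(?:x\\s*10\\^?9?)?\\s*/\\s*(?:ul|mm3|l\\b)",
      "\\d[\\d.,]*\\s*(?:mg/dl|g/dl|g/l|iu/l|u/l|mmol/l|umol/l|ml/min|%)",
      "\\b\\d+(?:\\.\\d+)?(?:\\s*-\\s*\\d+(?:\\.\\d+)?)?\\b"
    ]
  },
  "subpopulation": {
    "markers": [
      "\\bif\\b", "\\bunless\\b", "\\bin case of\\b",
      "\\bonly (?:applies|applicable|if|for)\\b",
      "\\bfor (?:patients|subjects|participants) with\\b",
      "\\bdepending on\\b"
    ],
    "subgroup_header": "\\b(?:patients|subjects|participants|women|men|children|those)\\s+with\\b.*:\\s*$|\\b(?:cohort|arm|stratum)\\b.*:\\s*$"
  },
  "patient": {
    "phrases": [
      "\\bwilling(?:ness)?\\s+to\\b", "\\bable\\s+to\\b",
      "\\bability\\s+to\\b", "\\bunable\\s+to\\b", "\\bmust\\s+agree\\b",
      "\\bagrees?\\s+to\\b", "\\bcapable\\s+of\\b",
      "\\bcompliance\\s+with\\b", "\\bcomply\\s+with\\b",
      "\\bconsents?\\s+to\\b", "\\bcommits?\\s+to\\b"
    ]
  }
}
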