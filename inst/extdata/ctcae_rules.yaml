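# Default CTCAE treatment-toxicity detection rules, one block per category.
# These definitions are reconstructions built on public CTCAE grade boundaries,
# the WHO ATC index and ICD-10; every list is user-editable and the file can be
# replaced wholesale via load_toxicity_rules().
#
# Channels per category:
#   labs            -> laboratory indicator (analyte matched on LOINC code;
#                      relative_to_baseline: true compares against the most
#                      recent pre-window value, within baseline_lookback_days)
#   drugs           -> indicator drug orders; each inner list is one trigger
#                      set, all member ATC codes must start within 3 days
#   keywords        -> case-insensitive whole-word match in imaging reports
#                      (deliberately negation-blind)
#   admission_codes -> ICD-10 main or secondary admission diagnoses (prefix match)
#   icu_flag        -> fires on any ICU admission overlapping the window
acute_renal_failure:
  labs:
    - analyte: creatinine
      loinc: "2160-0"
      unit: umol/L
      comparator: ">"
      threshold: 1.5
      relative_to_baseline: true
hemorrhage:
  keywords: [hemorrhage, bleeding, hematoma]
  admission_codes: [R58, K92.2, I61.9]
hepatic_toxicity:
  labs:
    - analyte: total bilirubin
      loinc: "1975-2"
      unit: umol/L
      comparator: ">"
      threshold: 51.3
      relative_to_baseline: false
    - analyte: alanine aminotransferase
      loinc: "1742-6"
      unit: U/L
      comparator: ">"
      threshold: 250
      relative_to_baseline: false
icu_admission:
  icu_flag: true
invasive_aspergillosis:
  drugs: [["J02AC03"]]
  keywords: [aspergillosis, aspergillus]
  admission_codes: [B44.0, B44.1, B44.7]
invasive_candidiasis:
  drugs: [["J02AX04"], ["J02AX06"]]
  admission_codes: [B37.1, B37.7]
pulmonary_toxicity:
  keywords: [pneumonitis, ground-glass]
  admission_codes: [J70.4, J84.9]
sepsis:
  drugs: [["J01DH02"], ["J01CR05"]]
  admission_codes: [A41.9, R57.2]
typhlitis:
  drugs: [["J01XD01"]]
  admission_codes: [K52.9]
venous_thrombosis:
  drugs: [["B01AB05"], ["B01AF01"]]
baseline_lookback_days: 90
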