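# Frequency scales of the dietary screener, with the occasions-per-day weight
# assigned to each option by the frequency-to-nutrient conversion.
#
# Anchored weights (fixed by the conversion protocol): "Rarely or Never" = 0,
# "Once per week" = 1/7, "1-2 times a day" = 1.5, and the top of the standard
# scale "5+ a day" = 5. All other weights follow a midpoint-occasions-per-day
# convention (e.g. "2-3 times per week" = 2.5/7) and are implementation
# choices: edit here, never in code. Weights may be arithmetic expressions.
standard8:
  - {label: "Rarely or Never", weight: "0"}
  - {label: "1-3 times last month", weight: "2/30"}
  - {label: "Once per week", weight: "1/7"}
  - {label: "2-3 times per week", weight: "2.5/7"}
  - {label: "4-6 times per week", weight: "5/7"}
  - {label: "1-2 times a day", weight: "1.5"}
  - {label: "3-4 times a day", weight: "3.5"}
  - {label: "5+ a day", weight: "5"}
# 6-option scale used by the seven meat and fish categories; the top option
# "At least everyday" maps to 1.0 occasions/day.
meat6:
  - {label: "Rarely or Never", weight: "0"}
  - {label: "1-3 times last month", weight: "2/30"}
  - {label: "Once per week", weight: "1/7"}
  - {label: "2-3 times per week", weight: "2.5/7"}
  - {label: "4-6 times per week", weight: "5/7"}
  - {label: "At least everyday", weight: "1"}
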