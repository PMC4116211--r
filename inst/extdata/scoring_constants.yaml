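# Phenotype scoring constants for the caffeine questionnaire pipeline.
# caffeine_mg_per_drink: approximate caffeine content per drink (mg)
# outlier_max_per_day:   daily consumption above this is coded missing (strict >)
# closed_recode:         closed-format frequency label -> drinks per week
caffeine_mg_per_drink:
  coffee: 75
  tea: 40
  cola: 34.5
outlier_max_per_day:
  coffee: 10
  tea: 15
  cola: 21
closed_recode:
  "never or rarely": 0
  "once in 2 weeks": 0.5
  "1 to 3 times a week": 2
  "4 to 7 times a week": 5.5
  "once a day or more": 7
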