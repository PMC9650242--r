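# SOFA component cut-offs (1996 consensus score), in AmsterdamUMCdb units.
#
# respiration: PaO2/FiO2 ratio in kPa; score k (k = 1..4) when the ratio falls
#   below cutoffs[k]; scores >= ventilation_required_from additionally require
#   a ventilation event in the window (capped below it otherwise).
#   For mmHg data set cutoffs to [400, 300, 200, 100].
# coagulation: platelets x10^9/L, score k when below cutoffs[k].
# liver: bilirubin umol/L, score k when at or above cutoffs[k].
# cardiovascular: MAP mmHg (score 1 when below map_cutoff); vasopressor /
#   inotrope doses in ug/kg/min.
# cns: Glasgow Coma Scale; bands 15 / 13-14 / 10-12 / 6-9 / <6.
# renal: creatinine umol/L, score k when at or above cutoffs[k]; urine output
#   overrides in mL per 24h window.

respiration:
  cutoffs: [53.3, 40.0, 26.7, 13.3]
  ventilation_required_from: 3
coagulation:
  cutoffs: [150, 100, 50, 20]
liver:
  cutoffs: [20, 33, 102, 204]
cardiovascular:
  map_cutoff: 70
  dopamine_low: 5.0
  dopamine_high: 15.0
  norepinephrine: 0.1
  epinephrine: 0.1
cns:
  cutoffs: [15, 13, 10, 6]
renal:
  creatinine_cutoffs: [110, 171, 300, 440]
  urine_score3_below: 500
  urine_score4_below: 200
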