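# Antibiotic rank map used by escalation detection.
#
# Higher rank = broader-spectrum / more "escalated" agent. The escalation
# algebra (rise in maximum rank, or in the count of agents at the maximum
# rank, with >= 1 intravenous agent) is the method; this particular ranking is
# ILLUSTRATIVE data and should be replaced by the site's own classification.
#
# sdd: drugs given routinely for selective digestive decontamination, ignored
# by escalation detection within the listed post-admission windows.

ranks:
  benzylpenicillin: 1
  flucloxacillin: 1
  amoxicillin: 1
  cefazolin: 1
  metronidazole: 1
  amoxicillin-clavulanate: 2
  cefuroxime: 2
  ciprofloxacin: 2
  gentamicin: 2
  clindamycin: 2
  cefotaxime: 3
  ceftriaxone: 3
  ceftazidime: 3
  piperacillin-tazobactam: 3
  vancomycin: 3
  meropenem: 4
  imipenem: 4
  linezolid: 4
  colistin: 4

synonyms:
  augmentin: amoxicillin-clavulanate
  tazocin: piperacillin-tazobactam
  penicillin g: benzylpenicillin
  kefzol: cefazolin

sdd:
  drugs: [cefotaxime]
  days: [0, 1, 2, 3]
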