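# Concept map: raw item labels -> clinical concepts.
#
# The real AmsterdamUMCdb item identifiers cannot be shipped (the database is
# access-restricted), so these defaults cover the synthetic vocabulary emitted
# by the cohort generator. Users with real data access replace the item keys
# with their own item labels/ids; the concepts on the right are fixed.
#
# Optional per-item fields:
#   factor: multiplier applied to the numeric value (unit conversion)
#   name:   canonical drug name (antibiotics only), resolved by the rank map

numericitems:
  "PaO2": {concept: pao2, unit: kPa}
  "FiO2": {concept: fio2, unit: fraction}
  "Platelets": {concept: platelets, unit: "10^9/L"}
  "Bilirubin (total)": {concept: bilirubin, unit: umol/L}
  "ABP mean": {concept: map, unit: mmHg}
  "GCS total": {concept: gcs, unit: points}
  "Creatinine": {concept: creatinine, unit: umol/L}
  "Urine output": {concept: urine_output, unit: mL}
  "Lactate": {concept: lactate, unit: mmol/L}

drugitems:
  "Noradrenaline": {concept: norepinephrine_dose, unit: ug/kg/min}
  "Adrenaline": {concept: epinephrine_dose, unit: ug/kg/min}
  "Dopamine": {concept: dopamine_dose, unit: ug/kg/min}
  "Dobutamine": {concept: dobutamine_dose, unit: ug/kg/min}
  "Benzylpenicillin": {concept: antibiotic, name: benzylpenicillin}
  "Flucloxacillin": {concept: antibiotic, name: flucloxacillin}
  "Amoxicillin": {concept: antibiotic, name: amoxicillin}
  "Cefazolin": {concept: antibiotic, name: cefazolin}
  "Metronidazole": {concept: antibiotic, name: metronidazole}
  "Amoxicillin/clavulanate": {concept: antibiotic, name: amoxicillin-clavulanate}
  "Cefuroxime": {concept: antibiotic, name: cefuroxime}
  "Ciprofloxacin": {concept: antibiotic, name: ciprofloxacin}
  "Gentamicin": {concept: antibiotic, name: gentamicin}
  "Clindamycin": {concept: antibiotic, name: clindamycin}
  "Cefotaxime": {concept: antibiotic, name: cefotaxime}
  "Ceftriaxone": {concept: antibiotic, name: ceftriaxone}
  "Ceftazidime": {concept: antibiotic, name: ceftazidime}
  "Piperacillin/tazobactam": {concept: antibiotic, name: piperacillin-tazobactam}
  "Vancomycin": {concept: antibiotic, name: vancomycin}
  "Meropenem": {concept: antibiotic, name: meropenem}
  "Imipenem": {concept: antibiotic, name: imipenem}
  "Linezolid": {concept: antibiotic, name: linezolid}
  "Colistin": {concept: antibiotic, name: colistin}

listitems:
  "Mechanical ventilation": {concept: ventilated}
  "Blood culture": {concept: culture_drawn}
  "Sepsis at admission": {concept: admission_sepsis_flag}
  "Admission diagnosis": {concept: admission_diagnosis}
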