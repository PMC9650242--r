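# sepsis3icu

Sepsis-3 phenotyping on long-format ICU event tables.

Robust identification of septic patients in large ICU databases is a
prerequisite for reproducible observational research, but "sepsis" is not a
recorded field: it has to be operationalised from raw events. `sepsis3icu`
implements the Sepsis-3 clinical criteria — an acute rise in the Sequential
Organ Failure Assessment (SOFA) score of at least 2 points, accompanied by a
suspected infection, with septic shock requiring vasopressors and lactate ≥
2 mmol/L — as a configurable, tested rule engine over CSV tables shaped like
the AmsterdamUMCdb exports (admissions, drug administrations, numeric
measurements, list observations). It is written for critical-care
researchers who need an auditable cohort definition rather than a black box.

The pipeline, per admission and per 24-hour window *d* (the interval
[*d*·24h, (*d*+1)·24h) relative to admission; *d* may be negative):

1. **Daily SOFA**: the six component scores (respiration, coagulation,
   liver, cardiovascular, CNS, renal) from worst-in-window values, totalled
   as the sum of non-missing components (unmeasured pre-admission components
   are assumed zero).
2. **Suspected infection** via antibiotic escalation: a rise in the maximum
   antibiotic rank, or in the number of distinct agents at that rank, with
   at least one intravenous agent — after discarding routine prophylaxis
   (selective digestive decontamination cefotaxime in days 0–3, and
   perioperative antibiotics after elective surgery).
3. **Sepsis episode** at *d*: escalation at *d*, plus
   SOFA(*d*)−SOFA(*d*−1) ≥ 2 or SOFA(*d*+1)−SOFA(*d*−1) ≥ 2 or
   SOFA(*d*+1)−SOFA(*d*) ≥ 2; post-admission windows with ≥ 3 missing
   components yield no verdict.
4. **Septic shock**: sepsis with cardiovascular SOFA ≥ 3 and worst lactate
   ≥ 2 mmol/L.

All cut-offs, the antibiotic rank map and the item-to-concept mapping are
YAML configuration (`inst/extdata/`), not code. Because the target database
is access-restricted, the package includes a synthetic cohort generator with
planted, independently derived ground truth, so the entire pipeline is
verifiable without any data access.

## Worked example

The packaged fixture generates a four-admission cohort — two elective
surgical admissions with perioperative prophylaxis, two urgent admissions
that deteriorate with a fresh intravenous antibiotic course before admission:

```r
library(sepsis3icu)
gen   <- generate_cohort(tables23_fixture(), tempfile())
store <- read_tables(gen$paths)
out   <- run_pipeline(store, day_range = c(-3L, 1L), out_dir = "out")
```

`out/sofa.csv`:

```
admissionid,time,sofa_respiration_score,sofa_coagulation_score,sofa_liver_score,sofa_cardiovascular_score,sofa_cns_score,sofa_renal_score,sofa_total_score
0,-1,NaN,0,NaN,NaN,NaN,0,0
0,0,3,0,NaN,1,0,0,4
0,1,2,1,NaN,2,NaN,0,5
1,-1,NaN,1,NaN,NaN,NaN,0,1
1,0,2,0,NaN,2,0,0,4
1,1,NaN,NaN,NaN,0,NaN,0,0
2,-2,NaN,0,0,NaN,NaN,0,0
2,-1,NaN,1,NaN,NaN,NaN,NaN,1
2,0,2,0,NaN,4,0,0,6
3,-3,NaN,0,NaN,NaN,NaN,1,1
3,0,2,0,NaN,0,NaN,1,3
```

`out/sepsis.csv`:

```
admissionid,time,sofa_total_score,antibiotic_escalation,prophylaxis,infection,sepsis_episode,septic_shock
0,-1,0,True,True,False,False,False
0,0,4,False,False,False,False,False
0,1,5,NaN,False,False,False,False
1,-1,1,True,True,False,False,False
1,0,4,False,False,False,False,False
1,1,0,NaN,False,False,False,False
2,-2,0,NaN,False,False,False,False
2,-1,1,True,False,True,True,False
2,0,6,False,False,False,False,False
3,-3,1,NaN,False,False,False,False
3,-1,0,True,False,True,True,False
3,0,3,False,False,False,False,False
```

Reading the rows: `NaN` in a SOFA cell means the component was unmeasured in
that window (it contributes 0 to the total); `NaN` in
`antibiotic_escalation` means no antibiotics were given that day, so no
determination is made. Admission 2 escalates (first intravenous ceftriaxone)
at day −1 while its total SOFA rises 0 → 1 → 6 across days −2..0, so day −1
is a sepsis episode; its cardiovascular score is unmeasured that window, so
no septic shock. Admissions 0 and 1 get the same kind of new intravenous
course at day −1, but they are elective surgical admissions, so the
administration is classified perioperative prophylaxis and no infection is
called.

A thin command-line wrapper with subcommands `sofa | sepsis | synth |
compare` is installed at `inst/cli/sepsis3.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sepsis3.R",package="sepsis3icu"))')" \
    synth --n 100 --seed 7 --out cohort/
```

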