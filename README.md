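# owascreen

Open-world pre-screening of clinical-trial eligibility with partially known
patient data.

## The problem

Pre-screening matches patients against trial eligibility criteria using
retrospective record data, long before informed consent. At that point much of
the information needed to decide each criterion is simply not recorded: in
routine oncology case-review data, well over half of the form fields can be
unspecified. A trial is modeled as a pair of criterion lists, and a patient
`p` is eligible when all inclusion criteria and none of the exclusion criteria
hold:

    eligible(p)  <=>  I_0(p) ∧ … ∧ I_n(p) ∧ ¬E_0(p) ∧ … ∧ ¬E_m(p)

Under the classic closed-world reading (negation as failure), any conjunct
that cannot be *proven* fails, so every patient with a single unknown status
is rejected — indistinguishable from a patient who provably fails a
criterion. That systematically under-estimates recruitment.

`owascreen` evaluates the same conjunction in three-valued strong Kleene logic
under the open world assumption. Each criterion status is `TRUE`, `FALSE` or
unknown (`NA`), and the conjunction is false as soon as one conjunct is known
false, unknown if none is false but some are unknown, and true otherwise.
Patients therefore fall into three classes:

* **eligible** — every criterion decided favourably;
* **not eligible** — at least one criterion decided against the patient, with
  the causing criteria reported;
* **potentially eligible** — nothing decides against the patient, but some
  statuses are unknown; the exact missing criteria are reported so they can
  be sought.

The package also compiles trials and patients into an OWL 2 ontology design
pattern (per criterion `x` a class `C_x` and `Not_C_x ≡ Criterion ⊓ ¬C_x`;
per trial a defined `Ct_k_include` intersection class and two `Ct_k_exclude`
cause classes defined as unions), and cross-checks the engine against a
built-in instance classifier for that Boolean fragment of OWL 2 DL — two
independent routes to the same decisions.

## Worked example

The fictitious validation trial has two inclusion criteria (`I0`, `I1`) and
two exclusion criteria (`E0`, `E1`); nine patients cover every
true/false/unknown combination of `I1` and `E1` (unknown statuses are simply
omitted from the record):

```r
library(owascreen)

trial <- validate_trial(trial_definition("ct", c("I0", "I1"), c("E0", "E1")))
patients <- list(
  patient_record("p0", c(I0 = TRUE, I1 = TRUE,  E0 = FALSE, E1 = TRUE)),
  patient_record("p1", c(I0 = TRUE, I1 = TRUE,  E0 = FALSE, E1 = FALSE)),
  patient_record("p2", c(I0 = TRUE, I1 = TRUE,  E0 = FALSE)),
  patient_record("p3", c(I0 = TRUE, I1 = FALSE, E0 = FALSE, E1 = TRUE)),
  patient_record("p4", c(I0 = TRUE, I1 = FALSE, E0 = FALSE, E1 = FALSE)),
  patient_record("p5", c(I0 = TRUE, I1 = FALSE, E0 = FALSE)),
  patient_record("p6", c(I0 = TRUE, E0 = FALSE, E1 = TRUE)),
  patient_record("p7", c(I0 = TRUE, E0 = FALSE, E1 = FALSE)),
  patient_record("p8", c(I0 = TRUE, E0 = FALSE))
)

screening_report(classify_cohort(trial, patients),
                 compare_policies(trial, patients))
```

prints

```
Screening report for trial 'ct' (9 patients)
  eligible:             1 (11.11%)
  not eligible:         5 (55.56%)
  potentially eligible: 3 (33.33%)
Potentially eligible patients (criteria to seek):
  p2: missing E1
  p7: missing I1
  p8: missing I1, E1
Not eligible patients (cause):
  p0: matched exclusion E1
  p3: failed inclusion I1; matched exclusion E1
  p4: failed inclusion I1
  p5: failed inclusion I1
  p6: matched exclusion E1
Patients a closed-world policy would over-reject: p2, p7, p8
```

Only `p1` is provably eligible. Five patients are provably not eligible —
note `p5` and `p6` are rejected *despite* an unknown status, because one known
criterion already decides them. The closed-world baseline
(`evaluate_closed_world()`) would reject eight of the nine patients; the three
potentially-eligible ones (`p2`, `p7`, `p8`) are exactly the over-rejections,
and the report lists the criteria that must be sought to settle them.

The OWL route gives the same answer:

```r
model <- build_ontology(trial, patients = patients)
cat(serialize_ontology(model, "turtle"))           # or "rdfxml", "ofn"
crosscheck_engine_vs_reasoner(trial, patients = patients)
#> [1] trial_id          patient_id        engine_decision   reasoner_decision
#> <0 rows> (or 0-length row.names)
```

A command-line interface (`classify`, `export-owl`, `crosscheck`, `simulate`,
`stats`, `report`) is installed at
`system.file("cli", "owascreen", package = "owascreen")`.

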