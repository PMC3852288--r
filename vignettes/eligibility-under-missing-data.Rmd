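---
title: "Eligibility determination under missing data: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eligibility determination under missing data: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owascreen)
```

## The model

A trial is a pair of criterion lists, inclusion `(I_i)` and exclusion
`(E_j)`; a patient is eligible iff every inclusion criterion holds and no
exclusion criterion does, i.e. the uniform conjunction

\[
\text{eligible}(p) \iff \bigwedge_i I_i(p) \wedge \bigwedge_j \neg E_j(p).
\]

Each criterion is an independent unary predicate of the patient's data: the
status of one criterion is never inferred from the others (a weak-independence
assumption; correlated criteria must be modeled as a single decomposed
criterion by the user). At pre-screening, the available record often cannot
decide a criterion at all, so a status is one of three values: true, false or
unknown.

`owascreen` evaluates the conjunction in strong Kleene logic: conjunction is
false as soon as one conjunct is false, unknown if no conjunct is false but at
least one is unknown, and true otherwise; negation swaps true and false and
fixes unknown. The three outcomes map onto the screening vocabulary *eligible*
/ *not eligible* / *potentially eligible*. Two consequences matter clinically:

* a single criterion known to fail decides the patient regardless of any
  other unknowns — rejections are confident rejections;
* unknowns alone never reject; they leave the patient potentially eligible,
  and the engine reports exactly which criteria must be sought.

The closed-world baseline (`evaluate_closed_world()`) treats a conjunct as
satisfied only when provable, so any unknown rejects. We deliberately do
**not** implement the naive negation-as-failure reading in which `¬E_j`
*succeeds* when `E_j` is unprovable: that reading silently converts ignorance
about an exclusion criterion into inclusion, and symmetric *ad hoc*
conversions between inclusion and exclusion criteria break down as soon as
the same criterion appears on different sides of two trials. In our baseline,
unknown fails both a positive and a negated conjunct ("cannot assert"), which
is the behaviour an eligibility conjunction compiled to a rule engine
exhibits. The over-rejection relation is then a theorem: closed-world
`INCLUDE` coincides with open-world `ELIGIBLE`, so the closed-world `EXCLUDE`
set is the union of the open-world not-eligible and potentially-eligible
sets; `compare_policies()` returns the difference.

Three-valued statuses are represented as R logicals with `NA` for unknown —
base R's `NA` semantics for `&`, `|`, `!` *are* the strong Kleene tables, and
`kleene_and()` / `kleene_not()` document that contract. The representation is
checked against two independent routes rather than against itself: the
completion oracle and the OWL classifier, below.

### The completion oracle

`completion_oracle()` implements the semantics by brute force: every unknown
status is completed to true/false in all `2^u` ways, each completion is
evaluated classically, and the answers are aggregated (eligible in all
completions / in none / in some). The test suite proves the Kleene engine
equal to the oracle on *every* trial shape with up to six criteria and every
status vector in `{T, F, U}^k` — 7,108 cases — and the same property underlies
knowledge monotonicity: resolving an unknown can only settle an undetermined
patient, never flip a decided one.

## The OWL design pattern

`build_ontology()` compiles trials and patients into the pattern:

* a root class `Criterion`;
* per criterion `x`: a class `C_x` and `Not_C_x ≡ Criterion ⊓ ¬C_x`. Under
  the open world assumption an individual asserted into neither class is
  simply *unknown* — exactly the third truth value;
* per trial `k`: `Ct_k` (placeholder), `Ct_k_include ≡ ⊓_i C_{I_i} ⊓ ⊓_j
  Not_C_{E_j}`, a placeholder `Ct_k_exclude ⊑ Ct_k`, and its two cause
  subclasses `Ct_k_exclude_at_least_one_exclusion_criterion ≡ ⊔_j C_{E_j}`
  and `Ct_k_exclude_at_least_one_failed_inclusion_criterion ≡ ⊔_i
  Not_C_{I_i}`;
* per patient: a named individual asserted an instance of `C_x` for each
  criterion known true and `Not_C_x` for each known false — and of nothing
  for unknowns. Asserting patients as instances of criterion classes is
  ontologically loose but keeps the pattern free of properties, which is what
  makes the classification decidable by enumeration.

Patient individuals are additionally asserted instances of the `Criterion`
root. The `Not_C_x` definition requires root membership before it can
classify an individual, and nothing else in the pattern supplies it; without
this assertion a patient asserted only `Not_C_x` types would never reach the
failed-inclusion union. The choice is validated by the agreement property
below. No disjointness axioms are added: the complement equivalence already
makes `C_x` and `Not_C_x` disjoint. Criterion definitions over raw data are
not emitted either — statuses are precomputed by the binding module, keeping
the ontology purely propositional.

A model with `c` criteria and `t` trials declares `1 + 2c + 5t` classes. IRIs
are `base_iri#fragment` with prefixes `C_`, `Not_C_`, `Ct_` and
non-alphanumerics replaced by underscores, so output is deterministic and
diff-stable. Serializations: RDF/XML (default), Turtle (the two denote the
same RDF graph; the suite checks isomorphism with an external RDF library)
and OWL functional syntax.

### The built-in instance classifier

The pattern lives in the *role-free Boolean fragment* of OWL 2 DL: every
axiom is an equivalence or subclass statement between Boolean combinations of
named classes, and the ABox contains only named-class assertions. On this
fragment every axiom constrains class memberships pointwise, individuals do
not interact, and instance checking reduces to propositional entailment: `a`
is an inferred instance of `X` iff `X` is true in every interpretation of the
named classes satisfying the axioms and `a`'s asserted types.
`classify_with_reasoner()` decides this exactly: it parses the serialized
RDF/XML back into axioms, treats acyclically-defined equivalences as
definitions evaluated by substitution, enumerates all `2^f` interpretations of
the remaining free classes (refusing ontologies with more than 20 — the
pattern has `1 + c + 2t`), filters by the subclass axioms, and reads off
consistency (an individual with no satisfying interpretation raises an error
naming it) and entailed memberships. It is a genuine, if small, reasoner for
this fragment — sound and complete on it, and deliberately *not* a re-run of
the Kleene engine: the two routes share no code beyond the model types.

`crosscheck_engine_vs_reasoner()` maps memberships to decisions
(`Ct_k_include` entailed → eligible; `Ct_k_exclude` or either cause subclass
entailed → not eligible; neither → potentially eligible) and diffs against
the engine. The suite verifies zero deviations exhaustively on the 81
tri-valued records over the four-criterion validation trial and by sampling
on larger trials; that agreement is also the empirical justification for
using strong Kleene connectives in the engine — on this propositional
fragment they coincide with open-world OWL classification of the pattern.

## Binding raw fields to criteria

`binding_rule()` is a deliberately small declarative language: one rule per
atomic criterion, referencing one column of a patient field table with a
comparator (`eq`, `ne`, `lt`, `le`, `gt`, `ge`, `in`, `not_in`, `present`,
`absent`). A missing cell (encoded `NA`, empty, or `"not specified"`, as on
case-report forms) yields an unknown status for every comparator except
`present`/`absent`, which test availability itself. There is no unit
conversion — operands must be in the table's units — and no temporal or
cross-field logic: complex criteria are decomposed by the user into atomic
rules combined at trial level. Missingness is conserved: the number of
unknown statuses among bound criteria equals the number of missing cells in
the bound columns.

## The synthetic cohort generator

`generate_cohort()` and `generate_field_table()` exist so that every module is
testable at arbitrary scale without any patient data. Each status/cell is
observed independently with per-id probability `p_known` (always, for the
`always_known` ids) and, if observed, true with probability `p_true`;
unobserved statuses are *absent* from the record, mirroring the
representation of unknowns by omission. Draws use R's Mersenne–Twister
generator (recorded in the config for provenance) and are fully reproducible
from the seed.

The `mdm_like_config()` preset emulates the missingness structure of a
retrospective urology case-review dataset: 286 cases on a 65-field form, 6
administrative fields never blank (identifier, meeting date, birth date,
gender, tumor site, histological type), and the observation probability of
the remaining 59 fields solved from the target expected unknown fraction
0.609 (`p = 1 − 0.609·65/59 ≈ 0.329`). `p_true = 0.5` is an uninformative
default — the preset emulates the *missingness* structure, not clinical value
distributions. What the generator does **not** emulate: informative
(non-random) missingness, correlation between fields, per-field missingness
profiles, and repeated examinations of one patient. Tests passing on this
generator therefore validate the logic and calibration of the machinery, not
the clinical realism of any particular cohort.

## Reporting

`missingness_stats()` quantifies unspecified values overall, per field and
per record; `trial_field_report()` restricts to the fields bound by a trial's
rules and counts, per trial, inclusion/exclusion/common fields and the
patients with all inclusion, all exclusion, and all fields known. "Common
fields" means fields referenced by both an inclusion-bound and an
exclusion-bound rule of the same trial — the report's own, explicit
definition. `screening_report()` renders decision counts (percentages to two
decimals), the missing criteria of every potentially-eligible patient, the
causes of every rejection, and the closed-world over-rejection set, as plain
text and as JSON that round-trips losslessly.

## Numerical and design choices

* **Problem sizes in the suite.** Exhaustive checks are run where the space
  is small enough to enumerate completely: all 7,108 engine-vs-oracle cases
  up to six criteria, all 81 reasoner-vs-engine records over four criteria;
  beyond that, sampled cohorts under fixed seeds (50–300 records) and a
  single n = 10,000 law-of-large-numbers check of the generator (tolerance
  ±2%, comfortably above the binomial standard error at 650,000 cells).
* **Validation requirement.** The engine refuses unvalidated trials rather
  than validating implicitly: validation errors (duplicate ids, a criterion
  on both sides — an unsatisfiable trial — unknown ids) should surface at
  configuration time, not mid-cohort.
* **Unknown sets of decided patients.** A rejected patient's unknown criteria
  are still reported — they explain what else could not be verified — but
  never affect the decision.
* **Degenerate inputs.** Empty criterion lists are legal (the empty
  conjunction is true, the empty union is nothing: a trial with no criteria
  accepts everyone); empty cohorts and empty status maps are legal;
  missingness statistics on an empty table are an error rather than `NaN`.
* **Ties and ordering.** Results preserve cohort input order; criterion
  order within a list never affects decisions (checked by a permutation
  property).

## Known limitations

The engine assumes criterion independence; it performs no probabilistic
imputation of unknown statuses (deliberately — assuming values conflates
"assumed" with "known" and the assumption direction would depend on which
side of a trial a criterion sits), no ranking of potentially-eligible
patients, and no temporal reasoning. The built-in classifier covers exactly
the role-free Boolean fragment the pattern emits; ontologies using
properties, nominals or datatypes are out of scope. The binding language is
atomic per criterion: derived quantities and terminology-coded matching are
the user's preprocessing.
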