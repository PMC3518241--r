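---
title: "Switching medications to a hospital formulary: the model behind rxswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching medications to a hospital formulary: the model behind rxswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxswitch)
```

## The problem

Hospitals prescribe from a restricted list, the hospital drug formulary
(HDF). On admission, a patient's home medication must be translated into
HDF products — a task that involves matching active ingredients, strengths
and dosage forms, recomputing dose regimens when only a different strength
is stocked, and, when the ingredient itself is not available, substituting
a therapeutically equivalent drug of the same class at an equipotent dose.
Done by hand this is slow and error-prone; `rxswitch` implements the
rule-based decision support that automates the routine majority of these
switches and flags the rest for a pharmacist.

## The five-step algorithm

Every prescription receives exactly one outcome group:

1. **HDF drug** — the product itself is on the formulary; no switch.
2. **Pharmaceutical equivalent** — an HDF product with the same active
   moiety (the *drug parent*), the same strength and a comparable
   application form. The regimen carries over unchanged.
3. **Pharmaceutical alternative** — same parent, comparable form, but a
   different strength. The regimen is recomputed to preserve the total
   daily dose (TDD).
4. **Therapeutic equivalent** — a different parent within the same
   interchange class. The target daily dose is `TDD × f`, where the
   conversion factor `f` is the ratio of equipotent daily doses
   (target/source) for the matched indication.
5. **No automatic switch** — everything else is routed to manual handling:
   excluded classes, non-oral forms in step 4, infeasible dose
   recomputations, unresolvable free-text lines, and drugs with no
   formulary relative.

Steps are tried strictly in order, so the result group is the first step
that succeeds; if a step-*k* match exists the group is never worse than
*k*.

### What "comparable form" means here

The literature rarely operationalizes "comparable dosage forms". We ship a
config-overridable mapping from dosage-form codes to comparability groups:
plain, coated and film-coated tablets and capsules form one oral-solid
group; oral liquids, injectables, inhalations and topicals are each their
own group. Release characteristics are matched separately and exactly: a
modified-release product is never comparable to an immediate-release one,
because converting between release forms changes exposure profiles and is
out of scope for automatic switching.

### Strength matching and the tolerance knob

Pharmaceutical equivalence compares per-parent strengths after unit
normalization (micrograms are converted to mg; IU compares only to IU,
since IU-to-mass conversion is drug-specific). The default relative
tolerance is `rel_tol = 0` — exact identity. That strictness has a known
failure mode: two brands of the same moiety can differ by a fraction of a
percent because strengths are declared for different salt forms (e.g.
78.09 vs 77.82 mg metoprolol). Setting `rel_tol = 0.01` in
`engine_config()` absorbs such salt-rounding differences; the match is
then annotated with a `dose-deviation` warning. Salt descriptors
themselves are stripped during parent normalization but retained, and a
`salt-difference` warning is attached when they differ. A guard list of
mineral cations (ferrous, calcium, magnesium, ...) prevents stripping
where the anion is part of the active moiety ("ferrous sulfate" stays
whole while "metoprolol tartrate" becomes metoprolol).

## Regimen arithmetic

A regimen is four slot doses (morning–noon–evening–night) in dose units;
`"1-0-1"` and `"1-0-1-1"` dialects are parsed, with fractions as `1/2` or
`0.5`. Anything unparseable is carried as flagged free text and ends in
group 5 — never silently dropped. The TDD of an ingredient is the slot sum
times its strength.

`redistribute()` lays a target daily dose onto a candidate's grid: slot
doses must be multiples of `1/divisibility` (1, 2 or 4 — whole tablets,
halves, quarters) and are capped at 4 units per slot. Since the achieved
dose depends only on the total daily units, the search picks the best
total and then the simplest layout. Preference order:

1. smallest relative deviation `|achieved − target| / target`;
2. fewest administrations per day (regimen simplicity is a known
   adherence factor, so once daily is preferred when deviations tie);
3. fewest split (fractional) dose units;
4. the smaller total — when an underdose and an overdose are equidistant
   we prefer the underdose;
5. doses placed in earlier slots.

Any fractional slot attaches a `tablet-splitting` warning. A result whose
best deviation exceeds `max_dose_deviation` (default 0.10) is reported
infeasible and the prescription demotes to group 5: emitting a silently
wrong dose is worse than asking a human. The 10% default is a documented
choice — published evaluations do not state the deviation their
pharmacists tolerated — and it is exposed in `engine_config()`. The
4-units-per-slot cap covers realistic oral regimens and keeps the scheme
space small enough that the test suite can check the search against
exhaustive enumeration.

## The interchange knowledge base

Therapeutic substitution is driven by 21 ATC-scoped drug classes (antacids
through benzodiazepine-related hypnotics). Factors are never stored
pairwise: each member carries an equipotent daily dose per indication, and
`f(a→b, i) = dose(b, i) / dose(a, i)`. This makes reciprocity
(`f(a→b)·f(b→a) = 1`) and within-class transitivity hold by construction
rather than by curation discipline.

Indications are a flat controlled vocabulary; a candidate qualifies only
if its labelled indications intersect the source's (a calcium-channel
blocker labelled for hypertension is never replaced by one labelled only
for cerebral-vasospasm prevention). If a pair shares several indications
with different factors, the lexicographically first shared indication is
used and a `differing-indications` warning is attached for the prescriber.

Four ATC prefixes are excluded from automatic substitution — insulins
(A10A), alpha-adrenoceptor blockers (C02CA), hyperkalemia/hyperphosphatemia
agents (V03AE) and other antianemics (B03XA) — because their switches need
individualised monitoring, release-form changes or expert judgment.
Therapeutic substitution is additionally restricted to single-ingredient
oral solid forms. Exclusions are enforced twice: a knowledge base that
claims an excluded class fails validation, and the candidate query filters
both source and candidate.

The shipped default KB transcribes the 21 classes with their ATC codes;
its equipotent doses are curator-editable placeholders derived from
approved maintenance doses (the standard fallback when no head-to-head
comparison exists). Only the simvastatin 20 / pravastatin 40 mg/day pair
is load-bearing in examples; no test depends on the other placeholder
values, and a deployment should review them against local policy
(`lint_kb()` validates third-party files).

## Combination products

A multi-ingredient product that fails steps 1–3 as a whole may be split:
each component is projected onto a virtual single-agent prescription
(component strength, original scheme) and resolved through the
equivalent/alternative steps only — combinations are never substituted
therapeutically. The split is all-or-nothing (one unmatched component
voids it), products with more than `max_combination_components` (default
3) ingredients are never split, and the recorded group is the worst
component's step — a deliberate choice where published figures show split
combinations without naming the recorded group.

## The synthetic-data generator

No public drug catalogue or patient data ships with the package, so
`generator_spec()` / `generate_catalogue()` / `generate_consultations()`
build study-shaped synthetic worlds with constructed ground truth. Each
drug family is engineered for exactly one resolution path, families share
no parents, ATC codes or indications, and the manifest records the
intended group, suggestion ids and dose for every prescription — the
suite's central property is that the engine recovers 100% of them.

Defaults emulate a routine admission-switching service: consultations of
7.5 ± 3.9 drugs (normal, truncated at 1, since a zero-drug consultation is
meaningless), 12.2% incomplete prescriptions (scheme blanked or brand
rendered unidentifiable), and an outcome mix of
31.7/40.7/12.2/7.0/8.4% across groups 1–5. The spec exposes both
`hdf_fraction` and the group mix; we define the group-1 share to *be*
`hdf_fraction` and renormalize the remaining mix over `1 − hdf_fraction`,
which the default numbers satisfy exactly and which makes
`hdf_fraction = 1` degenerate cleanly to an all-formulary world. Catalogue
and consultation sampling use separate RNG streams (`seed`, `seed + 1`),
so adding consultations never perturbs the catalogue.

What the generator does **not** emulate: correlated drug classes within a
patient (draws are independent), market-share-weighted brands, realistic
brand names, price/package data, and catalogue-scale ambiguity (multiple
near-matches per family). Passing the recovery property therefore shows
the engine implements its contracts, not that 91%-style automatic-switch
rates would be achieved on real consultations against a commercial
catalogue.

## Numerical and degenerate-input choices

* Dose comparisons use a `1e-12` relative guard; scheme slots live on a
  quarter grid so all arithmetic is exact in doubles.
* Percentages in performance reports are rounded half away from zero to
  one decimal (`round_half_up()`), so a printed column can sum to 100.1;
  the automatic-switch total is reported both as the sum of rounded cells
  (matching how such tables are printed) and unrounded.
* Candidate ranking is deterministic everywhere: queries order by mean
  relative strength deviation then product id; the engine refines step-3/4
  choices by achieved deviation, implied daily units, then product id.
  Results are invariant under catalogue row permutation, and identical
  inputs give byte-identical serialized outputs.
* Empty consultations, empty knowledge bases, unresolvable lines and
  infeasible conversions are all in-band results, never errors; file
  loaders distinguish strict (abort on first bad row, with row numbers)
  from permissive (skip and count) modes.

## Problem sizes in the test suite

Property tests run brute-force oracle comparisons on catalogues of up to
100 products, exhaustive-search verification of dose redistribution on
the full scheme grid, and ground-truth recovery on a 500-product world
with ~70 consultations (≥500 prescriptions); these sizes give full
predicate coverage while keeping the default suite under a minute.

## Known limitations

Release-form conversion (modified ↔ immediate), parenteral and inhaled
switching, oral↔IV conversion at ICU admission, discharge back-switching,
PRN and non-daily regimens, renal/hepatic adjustment and pediatric dosing
are out of scope; prescriptions needing them end in group 5 by design.
The expert adjudication of "equivalent / better / worse" between two
switches is an input (`apply_adjudications()`), never computed — the
package only does the bookkeeping.
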