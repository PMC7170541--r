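---
title: "Methods: census-based ascertainment of antipsychotic use in dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census-based ascertainment of antipsychotic use in dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The surveillance problem

Mental-health services that prescribe antipsychotics to people with dementia
are expected to document a risk–benefit review on a structured monitoring
form, at initiation and periodically thereafter. Traditional audits sample
case notes every few years; `apmonitor` implements the alternative: a
monthly, fully automated census. On the 28th of each month the pipeline
asks, for every patient: is this person on the active caseload, do they have
a dementia diagnosis, is there evidence of *recent* antipsychotic use, and
has a monitoring form been completed recently? Team-level completion
percentages are then fed back to clinicians.

Most of the evidence lives in free text, so the pipeline pairs structured
ICD-10 diagnosis fields with a deterministic lexicon extractor for diagnosis
assertions and medication references. This extractor is an explicit,
simpler stand-in for the NLP applications that production EHR research
platforms run; it is exactly analysable, which is what the test suite
needs, and it is *not* a clinical NLP system.

## Ascertainment model

At census $c$ with lookback window $w$ days (closed interval $[c-w,\,c]$):

1. **Active caseload** — at least one care episode whose interval contains
   $c$; an open end date means care is ongoing.
2. **Dementia** — earliest diagnosis event in the F00–F03 block dated
   $\le c$, from either source. The earliest-event rule makes the index
   date stable as more text is processed.
3. **Recent use v1** — any medication reference in the window, stop
   references included (a stop reference is still evidence the drug was
   recently in the picture).
4. **Recent use v2** — the refined filter: the pooled in-window reference
   count must be $\ge 2$ (patients with a single passing mention are
   usually not on continuing treatment), and any drug with an in-window
   stop reference is discarded; the patient remains only if a surviving
   drug retains a reference. Exclusion reasons are recorded as
   `single_reference` and `stopped` respectively.
5. **Sensitivity output** — excludes patients who may legitimately need an
   antipsychotic or whose dementia label was superseded: any F20–F29 event
   ever recorded up to $c$ (rule applied first), then any other-F event
   strictly after the index dementia date and $\le c$.

Completion at a census is one or more forms of either type dated within the
form-validity window; the reverse check reports forms completed for active
dementia patients the algorithm did *not* flag, which is how algorithm
false negatives were surfaced during service feedback.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `window_days` | 183 | "recent" is not fixed by the published account; six months matches the community review cadence (every 3–6 months) and is surfaced in every report header. |
| `min_references_v2` | 2 | the refinement rule is "exclude patients with only one reference". |
| `rule1_scope` | `pooled` | "patients with only one antipsychotic drug reference" reads most naturally as a patient-level count; the per-drug alternative is implemented and toggleable because the phrasing is genuinely ambiguous. |
| `form_validity_days` | = `window_days` | how recently a form must have been completed to count is not specified anywhere; tying it to the exposure window keeps one notion of "recent". A setting-specific mode (28 days for inpatients, matching the 2–4-week inpatient review cadence) is available. |
| rounding | half away from zero, 1 dp | matches clinical-audit reporting style (44.9, 48.5, 60.2, 3.9). |

Boundary conventions: every interval is closed on both ends ("ever" means
up to and including the census; a reference exactly $w$ days before the
census is in-window), and "after the index diagnosis" is strict, so a
same-day other-F diagnosis does not exclude.

## What the synthetic generator emulates

The generator states a world and the tests measure it; its defaults were
chosen once and are not tuned against test outcomes.

* **Population**: 660 patients, all with dementia (the unit being modelled
  is the dementia caseload), 32.1% truly exposed to one antipsychotic,
  19% with an ever-psychosis diagnosis, 15% acquiring a different
  psychiatric diagnosis after the index date. 30% of dementia diagnoses
  exist *only* in text, forcing the NLP pathway.
* **Timeline**: 16 monthly censuses (October 2017 – January 2019 analogue)
  inside a record running January 2017 – January 2019.
* **Documentation**: notes are single templated sentences drawn from the
  shipped lexicons, so extraction is exactly invertible when noise is off.
  A non-sparse exposure is documented by a same-day pair of notes at the
  start (a start-phrase note plus a plain mention) and a 28-day mention
  cadence. The pair-at-start is deliberate: it guarantees that any census
  window overlapping the exposure contains at least two references, which
  makes "v2 inclusion $\equiv$ ground-truth window overlap" an exact
  identity when `mention_noise = 0` and `stop_rate = 0` — the recovery
  test needs an identity, not an approximation.
* **Noise knobs**: `mention_noise` (default 0.1) makes a patient a sparse
  documenter (one mention per ~150 days, typically a single in-window
  reference, so v2 misses them); `stop_rate` (default 0.1) ends the
  exposure inside the record with a documented stop note. Both create the
  kinds of false negatives the refined algorithm trades against; measured
  v2 sensitivity against ground truth at these defaults is ~0.92.
* **Forms**: a latent adoption-threshold model. Each exposed patient draws
  $u_i \sim U(0,1)$ and starts completing monthly forms at the first
  census where the linear ramp $p_t$ (0.22 → 0.58) reaches $u_i$. A
  per-month independent Bernoulli draw would *not* reproduce the ramp
  endpoints under a 183-day validity window, because earlier months' forms
  persist; under the adoption model the measured per-census completion
  fraction tracks $p_t$ for any validity window of at least one month,
  and it is also a reasonable mechanism for a quality-improvement ramp
  (teams adopt and then keep using the form). Non-exposed patients carry a
  stray form with probability 0.04, feeding the reverse check.

What it does **not** emulate: realistic prose (templates only), dosage,
polypharmacy, team transfers, demographic structure beyond birth year, or
seasonal caseload dynamics. A green test therefore establishes algorithmic
correctness against a stated world, not clinical performance of the
extractor on real notes.

## Numerical and design choices

* **Attribution** — a start/stop/negation cue binds to a drug or diagnosis
  term in the same sentence (split at `.;!?`) within 5 tokens; the nearest
  cue wins, with stop outranking start at equal distance (conservative for
  exposure). References are deduplicated per (drug, note) — the refined
  rule counts "references", and document-level counting is the least
  ambiguous reading — with stop > start > mention on conflict.
* **Empty denominators** — a completion percentage with no eligible
  patients is reported absent (NA), never 0.
* **Determinism** — one seed drives the whole bundle; serialization is
  byte-stable, and the monthly pipeline is a pure function of the bundle.
* **Stage composition** — exclusion reasons record the *first* failing
  rule (not-active → no-dementia → recent-use → sensitivity), which is
  what the variant-comparison tallies report.

## Known limitations

* The extractor has no syntax: a cue more than five tokens away, or across
  a sentence boundary, is ignored; real clinical negation and temporality
  are far messier.
* Exposure is reference-based; there is no prescription-duration or dose
  model, and no carry-forward of exposure between windows.
* One published reference pair (122 of 638 printed as 19.0%) is
  arithmetically inconsistent (it computes to 19.1%); the acceptance suite
  keeps a deliberately failing test documenting this rather than adjusting
  either the arithmetic or the expectation.
* Team-level and Trust-wide figures are pooled counts, not team-weighted
  means; a patient active in several teams counts once in pooled figures
  and once per team in team figures.
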