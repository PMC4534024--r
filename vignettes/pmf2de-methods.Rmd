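---
title: "Methods: peptide mass fingerprinting and 2-D gel differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide mass fingerprinting and 2-D gel differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmf2de)
```

## Overview

`pmf2de` implements the classical gel-based proteomic biomarker workflow as
it was practised for saliva profiling in oral squamous cell carcinoma
(OSCC): proteins separated on 2-D gels, spots excised and digested with
trypsin, identified by MALDI-TOF peptide mass fingerprinting (PMF) against
a protein sequence database, quantified as percent volume, filtered by
fold change and tumour specificity, and finally validated as a binary
marker with sensitivity and specificity. The package exposes each stage as
ordinary R functions and ships seeded generators that emulate the raw
inputs (peak lists and spot tables) so the whole pipeline can be exercised
end to end with known ground truth.

## Peptide chemistry

Peptide masses are sums of residue masses plus one water. The element
masses are pinned in a single table (`export_mass_constants()` writes it
to JSON for audit): monoisotopic values from the CODATA/NIST compilation,
average masses from the IUPAC 2005 standard atomic weights. Monoisotopic
masses are the working scale throughout, because reflector MALDI resolves
the monoisotopic peak in the 500–4000 Da range; average masses are
available for completeness.

Residues are unmodified by default. The digestion protocol this package
models reports no cysteine alkylation step, so no fixed Cys modification
is applied; `peptide_mass(..., fixed_modification = c(C = 57.02146))`
accepts one when a workflow needs it.

MALDI produces predominantly singly protonated ions, so `[M+H]+` with the
proton at 1.00727646677 Da is the default ion view (`mz_from_mass()`), and
only charge 1 is used by the pipeline. Fragment confirmation uses the b
and y ladders (prefix sums + proton; suffix sums + water + proton), the
series produced by LIFT TOF/TOF laser-induced dissociation. a/c/x/z
series, neutral losses and isotope envelopes are out of scope.

## In-silico digestion

The default cleavage rule is trypsin: cut C-terminal to K or R unless the
next residue is P. Peptides are enumerated between cleavage boundaries
with at most `max_missed` retained internal sites. Defaults, chosen where
the modelled study is silent:

* `max_missed = 1` — the conventional PMF setting; the synthetic spectrum
  generator uses the same value so search and simulation are symmetric.
* mass window 500–4000 Da — the usable reflector range of the instrument
  class; peptides outside it are rarely observed.
* no N-terminal Met stripping — a documented switch was considered and
  rejected as speculative; the digest operates on the sequence as given.

`digest_database()` concatenates per-protein digests into a mass-sorted
index; `query_index()` and the search use binary search (`findInterval`),
so a tolerance window costs O(log N) rather than a linear scan. Tests
verify the index against a linear-scan oracle.

## Internal calibration

The modelled protocol spikes two standard peptides into every sample:
des-Arg1-bradykinin (PPGFSPFR) and an ACTH fragment. The fragment is not
named in the protocol; the package defaults to ACTH 18–39
(RPVKVYPNGAEDESAEAFPLEF), the conventional MALDI calibrant in this mass
region, and the standard set is plain configuration
(`reference_standards()`). Reference m/z values are computed from the
sequences through the package's own mass tables rather than hard-coded, so
they stay consistent with everything else.

Two standards determine an affine map exactly, which motivates the
calibration family: `reference = a × observed + b`, least-squares fitted
when more than two standards match. Standards are matched to the nearest
peak within a 1 Da coarse window — far above pre-calibration MALDI error
(hundreds of ppm at most, i.e. < 1 Da below m/z 4000) and far below
inter-peptide spacing; equidistant ties break to the lower m/z so the
procedure is deterministic. Fewer than two matched standards is a
calibration-impossible condition: the pipeline then searches uncalibrated
and records a warning in the run report. A fitted slope outside (0.9, 1.1)
triggers a sanity warning, since real instrument drift is orders of
magnitude smaller.

## PMF search and scoring

A peak matches a theoretical peptide when
`|m(obs) − m(theo)| ≤ tol × m(theo)` with the default `tol = 2.5e-5`
(0.0025 %), the tolerance of the modelled search. The window is relative,
so its absolute half-width doubles when the peptide mass doubles. The mass
convention for `m(theo)` is a search parameter: `"protonated"` (default —
a MALDI peak list reports `[M+H]+`) or `"neutral"`, because the modelled
protocol does not state which convention its matching used. All
peak–peptide matches are retained; no greedy one-to-one assignment is
made, since PMF scoring operates on candidate-level tallies.

Candidates are ranked by a chance score defined in full so ranking is
reproducible: with n observed peaks and k of them matching the candidate
(distinct peaks — duplicate peptide masses from sequence repeats cannot
inflate k), the score is `−log10 P(X ≥ k)`, `X ~ Binomial(n, p̂)`, where
`p̂` is the candidate's expected per-peak match probability: the number of
its peptides inside the observed mass range times the mean tolerance
window width, divided by that range. This binomial-tail construction is
MOWSE-like in spirit but self-contained; published per-spot score
annotations in the fixture tables are opaque strings and are never
recomputed or compared. Ties break by matched count, then coverage, then
accession, giving a total deterministic order. `p̂` is clamped to
`[1e-12, 1 − 1e-12]`, and for degenerate single-peak spectra (zero mass
range) it falls back to one window width; both choices only avoid
0/Inf pathologies and do not affect ordinary spectra.

Fragment confirmation (`fragment_confirm()`) checks a named candidate
peptide, as in the modelled workflow where MS/MS was a confirmation step
for spots not identified in MS mode: it counts b/y ladder ions with a
fragment peak within a relative tolerance (default 2.5e-4, looser than
MS mode because LIFT fragment masses are less accurate) and reports the
matched fraction of the 2(n−1) ions. Full tandem-MS database search and
target–decoy FDR are out of scope.

## Percent volume and differential filters

Each spot's volume is normalised to the summed volume of its gel
(×100), making gels comparable regardless of loading; per-gel percent
volumes sum to 100 within 1e-9 by construction, and tests enforce it.
Whether the original 1.5-fold rule was applied to raw or percent volumes
is unstated in the modelled study; when the same spot set is measured in
every gel the two are proportional per gel, and the package applies the
rule to percent volumes, the unit it reports.

Two filters run per fraction (A: epithelial cell debris, B: supernatant —
analysed separately, as the fractions were run on separate gels):

* **Fold change**: ratio of arithmetic group means of percent volume
  (case/control), flagged when ≥ 1.5 or ≤ 1/1.5. The 1.5-fold default is
  the threshold the modelled study chose as the limit of reproducible
  detection on Coomassie-stained gels. Means are arithmetic; the study
  does not state its aggregation and medians would be undefined for the
  2 + 2 and smaller designs the tests also exercise.
* **Specificity**: a protein present (percent volume above the presence
  threshold, default 0) in *all* case gels and *no* control gel. A group
  mean of exactly zero yields no finite fold change; such spots carry
  `case_specific`/`control_specific` flags instead, mutually exclusive
  with `differential`.

A spot absent from a gel's table is treated as volume 0 in that gel —
the convention the dropout model of the generator produces.

## Diagnostics

`validate_marker()` normalises marker band intensity to the beta-actin
loading control lane by lane, calls samples positive when the ratio
strictly exceeds a threshold (ties negative, so threshold sweeps are
deterministic and monotone), and summarises TP/FP/TN/FN with
sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`. Metrics with a
zero denominator are reported as `NA`, never as 0. The positivity
threshold is a required user parameter: the modelled study reports 80 %
sensitivity and ~90 % specificity for its galectin-7 Western blot at
n = 10 but not the per-sample intensities or its thresholding rule, so
those figures are context, not a reproduction target; correctness of the
summary is instead established by exhaustive enumeration of all call
patterns at small n.

## Synthetic data: what it emulates, and what not

The generators are pure functions of their parameters and a mandatory
seed (the session RNG state is saved and restored, and identical calls
are byte-identical).

* `simulate_protein_db()`: uniform random sequences over the 20 residues.
  Real proteomes have biased composition and homologous families; uniform
  sequences make the identification task neither artificially easy nor
  adversarial, and the tests' recovery rates should be read with that in
  mind.
* `simulate_pmf_spectrum()`: tryptic peptides of one source protein
  retained i.i.d. (default detection probability 0.8), multiplicative
  Gaussian mass error (default 10 ppm sd — matching the relative-error
  regime of the 0.0025 % search tolerance), uniform noise peaks (default
  5 per spectrum over 500–4000 Da), optional spiked standards, and an
  affine drift applied last, mimicking an uncalibrated axis. Peak
  intensities are uninformative uniforms: PMF matching and scoring use
  only m/z, so simulating intensity structure would suggest fidelity the
  pipeline does not consume. Isotope envelopes, peak shapes, detector
  saturation and chemical (non-uniform) noise are not modelled.
* `simulate_spot_tables()`: per-spot log-normal baselines
  (meanlog log 1000, sdlog 1 — a right-skewed abundance distribution
  spanning ~3 orders of magnitude, as on a stained gel), per-measurement
  log-normal noise (default sd 0.2 on the log scale, a typical gel CV),
  planted fold effects in case gels, and i.i.d. dropout. Defaults are the
  study's conditions: 5 case and 5 control gels, 800 spots per gel.
  Spot matching across gels is assumed perfect (shared IDs); mis-matching
  and image-processing artefacts are out of scope, so passing tests show
  the *filters* are correct, not that gel image analysis is solved.

The packaged tables (`table1_fixture()`, `table2_fixture()`) are verbatim
transcriptions of the published spot-identification lists, including
duplicate gene-product rows; deduplication is left explicit so the
transcription stays auditable. The published headline count of distinct
gene products cannot be reconciled row-by-row with the printed lists and
is asserted nowhere. `table2_presence_matrix()` expands the
all-cases/no-controls counts into the presence matrix that the
specificity filter consumes.

## Numerical choices and problem sizes

* Masses are written with 5 decimals (1e-5 Da, well below every tolerance
  used); JSON reports use full precision and stable field order, so
  rerunning an identical configuration is byte-identical.
* Digest coordinates are 1-based inclusive residue positions.
* The implementation is single-threaded; determinism outranks speed at
  this scale (a 50-protein search takes milliseconds).
* Test and validation problem sizes: 1000 random peptides against the
  elemental-composition oracle; 1000 random proteins for digest
  reconstruction; 100 corrupted spectra against a 50-protein database for
  recovery (observed rank-1 recovery is ≥ 95 %); 800-spot, 5 + 5 gel
  tables for the differential filters. The null fold-change exceedance
  band used in tests ([0, 0.0075] at sd 0.2) was frozen from a
  400-replicate simulation of the same model.

## Known limitations

* PMF against large databases is inherently ambiguous for short or
  poorly covered proteins; the chance score mitigates but cannot remove
  this, and real searches confirm borderline spots by fragment ions, as
  the `fragment_confirm()` step does here for a *named* candidate only.
* The binomial score assumes peaks match candidates independently and
  peptide masses are locally uniform; both are approximations, adequate
  for ranking but not calibrated as p-values.
* The affine calibration family cannot capture higher-order TOF
  nonlinearity; with the two-standard protocol modelled here nothing
  beyond affine is identifiable anyway.
* Presence/absence specificity at threshold 0 is fragile to faint
  staining in real gels; the threshold parameter exists precisely so
  users can demand a minimum percent volume.
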