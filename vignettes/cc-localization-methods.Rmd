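---
title: "Methods: C=C localization from PB tandem MS and isomer-ratio statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C=C localization from PB tandem MS and isomer-ratio statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pblipidr)
```

This vignette documents the models, rules and numerical choices behind
`pblipidr`, in the order the three-stage workflow applies them, and states
what the simulator does and does not emulate.

## Mass arithmetic and identification levels

All m/z prediction rests on five monoisotopic element masses (C, H, N, O, P)
and the proton mass 1.007276 Da as the charge carrier. Using the proton mass
for both cationization and deprotonation absorbs the electron mass
consistently and reproduces reference neutral masses to four decimals (e.g.
PE 39:4, C₄₄H₈₀NO₈P, 781.5622 Da). Diacyl glycerophospholipid formulas are
closed-form templates in the summed chain composition (c carbons, D double
bonds); each template equals the building-block assembly glycerol + H₃PO₄ +
headgroup alcohol + two free acids − 4 H₂O, which the test suite verifies for
200 random species. O-alkyl ether chains modify a template by −O +2H.
PA and PS templates are included for completeness but no profiling scan is
defined for them, matching the acquisition scheme; C=C assignment on ether
chains is gated behind `pb_config(ether_cc = TRUE)` because ether lipids are
low-abundance and their PB behaviour is less established.

A lipid is carried through three identification levels — subclass
("PE 34:1"), fatty acyl ("PE 16:0_18:1"), C=C location
("PE 16:0_18:1(Δ9)") — and sn-position is never assigned (the `_` separator
encodes this); the acquisition cannot distinguish sn-1 from sn-2.

## Stage 1: subclass profiling

Each subclass is profiled by its headgroup-linked scan: neutral-loss 141.0191
(PE, positive), precursor-ion 184.0733 (PC, positive), 152.9958 (PG,
negative), 241.0119 (PI, negative). Profile scans are represented as
centroided pseudo-spectra whose peaks are (precursor m/z, RT-window-summed
intensity). Peaks above a relative-intensity floor (default 0.1% of the
subclass base peak — a peak-picking threshold the acquisition literature
leaves open, so it is a config value) are converted to neutral mass by
undoing the profiling adduct and matched against a (c, D) grid, default
c = 24–48 and D = 0–8 with odd carbon totals allowed, since odd chains
(15:0, 17:0, 19:0) occur in mammalian tissue. Matching tolerance defaults to
0.3 Da, appropriate for a unit-resolution triple quadrupole; a ppm mode
exists for high-resolution reuse. Unmatched peaks are retained and flagged
rather than dropped.

Isobars that collide in m/z — the canonical case is PE 39:4 vs PC 36:4, the
*same* molecular formula — are separated by two orthogonal keys: the scan
type (an NLS-141 peak can only be a PE) and the subclass retention-time
window (defaults PE 5.1–6.5 min, PC 13.8–15.1 min, PG/PI 0–5 min, from the
HILIC separation this workflow assumes; fully configurable). Within one
subclass window, species sharing a total composition (PE 18:0_18:2 vs
PE 18:1_18:1, both "PE 36:2") are kept apart by retention time: every
downstream stage selects the scan closest in RT to its own profile hit.

## Stage 2: chain assignment

Each annotated hit is targeted in negative mode under the subclass adduct
([M−H]⁻ for PE/PG/PI, [M+CH₃COO]⁻ for PC). Candidate two-chain compositions
summing to the hit's (c, D) are enumerated over per-chain carbons 2–26, and
each is scored by the summed intensity of its two matched carboxylate anions;
*both* anions must be present. The top composition is called dominant when it
out-scores the runner-up by a factor of 3 (config `dominance_ratio`; the
underlying acquisition papers state "one dominant composition" without a
number, so the threshold is exposed and echoed into outputs). Hits with no
matched composition are flagged `chains unresolved` and excluded from the C=C
stage.

## Stage 3: PB targets and de novo C=C assignment

Unsaturated dominant compositions generate PB targets at +58.0419 Da
(one acetone across a C=C): intact [M+H]⁺ basis for PE/PC filtered to the
acquisition m/z ranges (PE 350–1000, PC 500–1000), fatty-acyl-anion basis for
PG/PI (second precursor = carboxylate anion + 58, the MS³-style route), and
[M−H]⁻ + 58 for free acids. Saturated species never enter the list.

For each PB spectrum, candidate positions are enumerated: all Δ2..Δ(c−2) for
monounsaturated chains; for polyunsaturated chains the default constraint is
the methylene-interrupted pattern (n, n+3, n+6, …), which covers essentially
all mammalian PUFA, with an unconstrained escape hatch
(`pb_config(constraint = "unconstrained")`) for unusual structures. A
candidate is accepted only if

* **pair-complete** — both F_A and F_O match for *every* position of the set;
* **S/N-adequate** — each ion at signal-to-noise ≥ 3 (`s_min`);
* **intensity-symmetric** — F_A and F_O within a factor 5 of each other
  (`fa_fo_ratio_limit`); a true pair appears at similar intensities, but no
  quantitative bound is established in the literature, so both knobs are
  config values surfaced in every report.

Pair-completeness is what makes the method specific: wrong candidate sets of
a PUFA chain typically share *some* ions with the true set (the collision
report quantifies this; e.g. for PE 17:0_22:4 a Δ9-candidate F_O and a
Δ10-candidate F_A both fall at 493.39) but essentially never all of them.

Surviving single-bond candidates beyond the chain's declared double-bond
count are interpreted as **coexisting location isomers**, not extra bonds —
stage 2's chain composition fixes how many bonds one molecule carries. For
polyunsaturated chains all pair-complete sets are reported ranked by summed
evidence. Assignments below 10% of the chain's top assignment are flagged
low-confidence (alternative structures such as branched chains may explain
them) but never suppressed. Ions colliding within tolerance with ions of
another accepted assignment are flagged, and collision-tainted assignments
are excluded from ratios; minor (non-dominant) compositions are assigned
only when collision-free against every candidate ion of the dominant
composition — otherwise they are "not reported", the conservative choice for
overlapped minor species. Chains with no surviving candidate are returned
flagged `unassigned` and count against the pipeline's localization rate.

### Signal-to-noise on centroided spectra

S/N for a matched peak is its intensity over a local noise level: the median
intensity of low peaks (below 5% of the window maximum) within ±50 Da,
excluding the matched peak itself. When a window holds fewer than 4 such low
peaks — the normal situation for a centroided spectrum whose noise has
already been removed, and for the package's noise-free fixtures — the noise
floor falls back to 1, so S/N reduces to raw intensity. A plain window median
would count the diagnostic ions themselves as noise in ion-dense PUFA
spectra and reject true calls; restricting the noise estimate to the low
population avoids that failure mode while still penalizing peaks that sit in
genuine chemical noise.

## Isomer relative quantitation

For two coexisting isomers A (lower Δ set) and B, the ratio is the
summed-diagnostic-ion quotient R = Σ(F_A + F_O of A) / Σ(F_A + F_O of B) —
for the Δ9/Δ11 pair of PE 16:0_18:1 this is (I₄₆₇ + I₄₉₃)/(I₄₉₅ + I₅₂₁).
Diagnostic-ion abundance ratios correlate linearly with concentration
ratios, so R is reported as a *relative* ratio; absolute isomer
concentrations would need authentic standards and are out of scope. All
pairwise ratios are emitted when more than two isomers coexist. A zero
denominator yields an explicit `undefined` flag, never infinity. Replicate
ratios aggregate to mean ± s.d. and RSD; swapping labels inverts R exactly.

## Statistics layer

Group comparison is an equal-variance two-tailed Student's t-test by default
(the convention in this assay's literature) with a Welch switch; technical
repeats are averaged within individual first, so n is the number of
biological individuals. Multiple testing defaults to Benjamini–Hochberg
(`stats::p.adjust`), pluggable. RSD decomposition reports technical RSD (mean
per-individual RSD across repeats) and inter-individual RSD (RSD of
individual means) per measurement kind — the quantity of interest is the
contrast between isomer-ratio measurements (small inter-individual RSD) and
subclass-level I/I_IS quantitation (large).

Hierarchical clustering standardizes each lipid (z-score of log2 values — a
preprocessing choice this package makes and records in the result object;
raw and plain-z options exist), then Euclidean distance and average linkage
(Ward/complete available). The flat cut at k groups is scored against known
labels with the Rand index. Constant lipid columns standardize to NaN and are
dropped as informationless.

## The simulator: what it emulates, what it does not

`generate_lipidome()` + `simulate_run()` produce the three scan layers for a
ground-truth lipidome. The built-in template carries the canonical mammalian
isomer structure: C18:1 as Δ9 (major)/Δ11 (minor) in every C18:1-containing
species, C16:1 as Δ9/Δ7, PUFA ω-6/ω-9 and ω-3/ω-6 mixtures, a low-abundance
Δ10 18:1 isomer, the PE 39:4/PC 36:4 isobar pair, odd-carbon chains and a
free FA 18:1 at a ~9:1 isomer ratio. Simulation parameters default to the
study conditions of the assay: PB conversion yield 0.25 (the moderate 20–30%
regime), single-acetone addition fraction 0.93 (> 0.9, the remainder emitted
as a +116 double-addition satellite), m/z jitter σ = 0.01 Da, multiplicative
intensity noise CV 5%, uniform background peaks (standing in for Norrish-type
side products) at ~2 per 100 Da and 0.2% of the base intensity, and Gaussian
RT jitter σ = 0.1 min. Chromatography is reduced to per-species RT values:
the pipeline consumes centroided scans, so simulating profile-mode peak
shapes would add nothing testable. Not emulated: isotope envelopes, detector
saturation, ion suppression beyond a per-subclass scale, real chemical-noise
structure, and chimeric spectra from co-isolation. Passing tests on
simulated data therefore demonstrate the correctness of the *computation* —
mass arithmetic, matching rules, ratio recovery, statistical behaviour — not
instrument-level robustness on real extracts.

`simulate_cohort()` generates two-group sample × measurement tables with
technical repeats nested in individuals, log-normal biological variation
(defaults: CV 10% for isomer ratios, 40% for subclass quantitation, matching
the precision contrast observed in plasma) and 8% technical CV. The built-in
effect panel shifts 7 of 19 ratio measurements at plasma-like magnitudes
(5.0 → 3.7, 2.4 → 4.8, ...) and 2 of 20 subclass measurements modestly, so
that ratio-based clustering separates the groups while subclass clustering
does not.

## Problem sizes and reproducibility

The shipped examples and tests run at desk scale by design: lipidomes of
~24 acyl-level species (the full template), duplex ratio recovery over
20 seeds × 3 repeats per true ratio, 10,000 simulated null datasets for the
type-I-error check, and 6-vs-6 cohorts with 3 technical repeats — sizes at
which every property is stable and the whole suite runs in minutes on one
core. Every random draw is governed by an explicit seed; `simulate_run()`
output is byte-identical across runs at a fixed seed, and `run_pipeline()`
is idempotent. Original-study census numbers that depend on a specific
biological extract (counts of identified species, cohort-specific ratios)
are inherently not recomputable from code and are represented by the
simulator-based surrogates above.

## Known limitations

* C=C geometry (cis/trans) and sn-position are outside what the chemistry
  can report.
* The methylene-interrupted default will miss genuinely unusual PUFA
  spacings unless the unconstrained mode is enabled (at a combinatorial
  cost and with more ion collisions).
* Quantitation is relative; absolute isomer concentrations require
  standards.
* Only PC, PE, PG, PI and free fatty acids are profiled; SM and
  glycerolipids need a different derivatization regime and are out of scope.
* The MGF dialect expects `key=value` metadata in TITLE lines as written by
  `write_mgf()`; other producers' files parse but fall back to defaults for
  scan type and polarity.
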