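---
title: "Demultiplexing top-down DIA feature data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing top-down DIA feature data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diademux)
```

## The model

Top-down DIA acquires one MS1 scan plus a fixed sweep of MS/MS scans per
cycle, each MS/MS scan co-fragmenting every precursor inside a narrow
isolation window (4 m/z in the layout emulated here, 20 windows per 80
m/z gas-phase fraction). The consequence is multiplexing: a fragment
feature observed in a window's LC-MS/MS map may originate from any of the
precursors isolated there. `diademux` resolves this by pairing
deconvoluted fragment features with single charge proteoform features
(SCPFs) using chromatographic co-elution, and assembling per-precursor
pseudo MS/MS spectra.

The package assumes deconvolution has already happened: inputs are
feature tables (neutral monoisotopic mass, charge, per-cycle intensity),
not raw or centroided spectra. The only spectrum-level operations are the
noise/S-N utilities, which operate on centroided peak lists.

### The three-round cascade

Within a window, SCPFs are processed in decreasing total-intensity order
(ties by ascending id, for determinism). For each SCPF with cycle count
$c$ the fragment pool is filtered as follows.

**Round 1 (apex gate).** A fragment survives when its apex cycle distance
to the SCPF is at most $\min\{t, \lfloor c/2 \rfloor\}$. The cap $t = 3$
reflects that most genuine precursor–fragment pairs co-apex within a few
cycles; the $\lfloor c/2 \rfloor$ term tightens the gate for
briefly eluting precursors. The distance is an absolute value: a signed
difference would break the threshold semantics.

**Round 2 (logistic score).** Each surviving pair is scored by a logistic
regression over three attributes:

* *normalized intensity rank* — the fragment's rank in the surviving list
  $L$ sorted by decreasing intensity, divided by $|L|$ (ties broken by
  ascending fragment id);
* *normalized cycle number* — fragment support size / SCPF support size,
  deliberately uncapped (the definition is a plain ratio; a long-eluting
  fragment can exceed 1);
* *shared XIC* — both chromatograms are linearly interpolated onto a
  uniform grid spanning the union of their supports, normalized to unit
  area by the trapezoid rule, and the integral of the pointwise minimum
  is taken. This lies in $[0,1]$, equals 1 exactly for proportional
  elution shapes, and 0 when the supports are separated by an empty
  cycle.

Pairs scoring above the cutoff (default 0.55) survive; when fewer than 25
do, the 25 top-scoring members of $L$ are reported without filtering, so
weakly populated precursors still receive a searchable spectrum.

**Round 3 (mass-stratified budget).** Surviving fragments are split at
1500 Da. The proteoform length is estimated as
$l = \max(2, \mathrm{round}(M / 111.1254))$ — the Averagine average
residue mass — and the budget set to $T = 2(l-1)$, the count of
theoretical b/y masses of a length-$l$ chain. Up to 25 top-scoring
low-mass and $T - 25$ top-scoring high-mass fragments are kept (25 is the
expected number of terminal fragment masses below 1500 Da). For tiny
precursors with $T < 25$ the high-mass quota clamps to zero and the
low-mass quota is capped at $T$; the original description never needs
this case, so the clamping is this package's choice.

Fragments consumed by a pseudo spectrum are removed from the pool before
the next SCPF is processed. Only round-3 survivors are consumed: a
fragment that passed rounds 1–2 but fell to the budget stays available to
later SCPFs, since only fragments *used in the pseudo spectrum* are
removed. Empty pseudo spectra are still emitted (downstream search simply
fails on them); `drop_empty` omits them at write time.

This greedy one-to-one consumption means a fragment shared by two
co-eluting proteoforms of the same protein is attributed only to the more
intense one — a known limitation of the approach that this implementation
reproduces rather than fixes.

### Scoring model training

Training pairs are built exactly as the cascade sees them: same-window
SCPF–fragment pairs passing the round-1 gate (a fragment may pair with
several SCPFs). A pair is labeled positive when the fragment's neutral
mass matches a theoretical b/y mass of the SCPF's identified, unmodified
sequence within 10 ppm (relative to the theoretical mass), using the
standard 20-residue monoisotopic table with b$_i$ = prefix sums and
y$_i$ = suffix sums + water. The model is unregularized maximum-likelihood
logistic regression (`stats::glm`); features are used raw, as all three
are already near unit scale. A seed-fixed random 70:30 split provides
held-out balanced accuracy (at probability 0.5) and ROC AUC.

### Noise estimation and peak filtering

The noise level $h$ of a centroided spectrum is the midpoint of the most
populated bin of a histogram of all peak intensities. The binning is
equal-width over the intensity range with $\lceil \sqrt{N} \rceil$ bins
(configurable); this square-root rule is scale-free and deterministic,
and frequency ties break toward the lower-intensity bin. Peaks with
intensity strictly below $r \cdot h$ are removed ($r_1 = 3$ for MS1,
$r_2 = 1$ for MS/MS); a peak exactly at the threshold is retained. $h$ is
not re-estimated after filtering.

### Window assignment and postprocessing

An SCPF is assigned to the isolation window containing strictly more than
50% of its summed isotopic-peak intensity — at most one window can, so no
tie-break is needed — and windows are half-open $[low, high)$ so a
boundary peak counts exactly once. Two identified proteoforms are
duplicates when they share a protein accession and
$\min\{|m_1-m_2|, |m_1-m_2-1.00235|, |m_1-m_2+1.00235|\}$ is at most
10 ppm, the 1.00235 Da shift being the common one-neutron deconvolution
error; the ppm denominator is the smaller mass (the conservative choice —
the rule's source does not specify one). Duplicate removal ranks by
decreasing SCPF intensity and compares each record against *all*
better-ranked records, kept or not; on transitively consistent duplicate
sets this agrees with comparing against survivors only. Multi-run merging
concatenates and deduplicates. Spectral averaging pools sorted peaks and
merges greedy left-to-right at 0.01 m/z, so a chain of close peaks can
merge beyond the tolerance end to end; output peaks sit at the
intensity-weighted mean with summed intensity (total intensity is
conserved).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `r1`, `r2` | 3, 1 | — | MS1/MS2 S/N peak-removal ratios |
| `t` | 3 | cycles | apex-distance cap, round 1 |
| `score_cutoff` | 0.55 | — | logistic threshold, round 2 |
| `min_keep` | 25 | fragments | round-2 fallback and round-3 low-mass quota |
| `low_mass_boundary` | 1500 | Da | round-3 mass split |
| `avg_residue_mass` | 111.1254 | Da | Averagine length estimate |
| `dup_ppm`, `isotope_shift` | 10, 1.00235 | ppm, Da | duplicate matching |
| `proton_mass` | 1.007276 | Da | m/z conversions |
| `merge_mz_tol` | 0.01 | Th | spectral-averaging peak merge |

The proton mass convention is fixed at 1.007276 Da because it reproduces
the worked precursor example (m/z 850.007, charge 14 → 11,885.99 Da)
within 0.01 Da.

## Numerical choices

* Shared-XIC interpolation uses 10 grid points per cycle; finer grids
  change values by well under $10^{-3}$ for smooth elution shapes, and
  the unit-test oracle integrates at 10× density to confirm it.
* Apex ties go to the earliest cycle; intensity-rank and SCPF-order ties
  go to ascending id. All orderings are therefore total, making the
  cascade deterministic given its inputs.
* `estimate_budget` uses R's `round` (half-to-even); the estimate is a
  count, so sub-half-Da differences in precursor mass never matter.
* Degenerate inputs: empty XICs, empty spectra, empty candidate lists and
  single-class training data all raise errors rather than guessing;
  zero-fragment pseudo spectra are legal values, not errors.

## The synthetic-data generator

`simulate_run()` emulates the acquisition geometry the pipeline targets:
a cycle-structured run (default 120 cycles), 20 four-m/z windows tiling
one 80 m/z gas-phase fraction, and per-window multiplexing. For each of
`n_proteoforms` (default 25) it draws a random residue sequence (70–140
residues), places the precursor at an integer charge putting its m/z
inside the fraction, and gives it a Gaussian elution profile (σ = 2
cycles) whose area is lognormal(16, 1) — the minimal smooth unimodal
elution model; elution shape itself is not part of the method being
emulated. True fragments are sampled from the sequence's theoretical b/y
masses at detection probability 0.8, with 2 ppm Gaussian mass error
(inside the 10 ppm labeling tolerance), apex offsets of rounded N(0, 1)
cycles, correlated Gaussian profiles, and intensities proportional to the
precursor times a lognormal(−3, 1) factor, giving realistic rank
structure for the intensity-rank feature.

Decoy fragments (random masses, one per detected true fragment at the
default 1:1 rate) model everything that is not a b/y fragment of the
precursor. Thirty percent of them co-elute near the precursor apex —
interference from co-isolated species — and the rest elute uniformly;
without the co-eluting component the apex gate removes nearly every decoy
and the training negatives carry no information. Precursors sharing a
window are kept at least 8 cycles apart at apex: co-isolated precursors
rarely share an elution apex in practice, and the exact-co-elution
failure mode is a separately documented limitation, not a test condition.

What the generator does **not** emulate: isotopic envelopes and
deconvolution error beyond a scalar mass noise, retention-time
calibration (pseudo-spectrum RT ranges are reported in cycle units),
modified proteoforms, chimeric fragments shared between proteoforms, and
intensity-dependent detection. Passing tests on simulated runs therefore
demonstrate the correctness and internal consistency of the cascade — not
identification performance on instrument data, which depends on upstream
deconvolution quality the simulation idealizes away. For the same reason
the training metrics printed on simulated runs (balanced accuracy ≈ 0.58,
AUC ≈ 0.65 on the default preset) characterize the simulation, not the
method's behavior on real data.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated data:
oracle-equivalence sweeps use 200 random windows of at most 5 SCPFs and
50 fragments; recovery checks use 12–15 proteoform runs over 120 cycles
(about 2,500 true fragments per run), with 20 seeds for the decoy
comparison; model-sanity checks use 2,000–4,000 synthetic pairs per fit.
These sizes give stable statistics (binomial standard errors well inside
the asserted margins) while keeping a full run in tens of seconds.

## Known limitations

* One-to-one fragment consumption cannot split a genuinely shared
  fragment between two co-eluting proteoforms.
* The round-2 fallback always reports up to 25 fragments, even when every
  score is essentially zero; downstream search is expected to reject the
  resulting spectra.
* The Averagine length estimate ignores composition bias; unusual
  sequences get a proportionally misestimated budget.
* Labeling restricts training to unmodified identifications; modified
  proteoforms contribute no positives.
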