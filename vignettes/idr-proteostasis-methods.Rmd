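---
title: "Methods: disorder profiling, degron scanning, FRAP fitting, and spectral-count quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder profiling, degron scanning, FRAP fitting, and spectral-count quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrproteo)
```

# The scientific problem

Intrinsically disordered regions (IDRs) — polypeptide stretches with high
net charge and low hydrophobicity that adopt no stable fold — influence
protein fate in two ways that this package quantifies side by side. First,
long disordered segments act as initiation sites for proteasomal
degradation: a disordered stretch of roughly 30 residues can thread into
the proteasome channel, so proteins carrying many long IDRs (the human
H3K36 methyltransferase SETD2, with its 2564 residues and IDR-rich
N-terminal region, is the motivating example) turn over quickly. Second,
IDRs drive liquid–liquid phase separation: IDR-rich proteins form nuclear
puncta whose material state — liquid droplet, gel, or solid aggregate —
can be read out by fluorescence recovery after photobleaching (FRAP).
Affinity-purification mass spectrometry connects the two, identifying
which ubiquitin–proteasome components associate with which regions of a
substrate, quantified by spectral counting.

The package implements the complete computational chain: disorder
profiling and long-IDR segmentation; PEST and APC/C degron scanning;
two-stage constrained FRAP curve fitting with material-state calls; and
distributed-NSAF spectral-count quantification with target-decoy FDR
control, protein parsimony, and bait-versus-mock enrichment. Seeded
generators emulate each input type so the entire pipeline can be exercised
and validated with no external data.

# Disorder profiling

## The bundled scorer

`score_disorder()` implements a windowed composition-propensity scorer.
Each residue carries a disorder propensity from a TOP-IDP-style scale
(positive for disorder-promoting residues — P, E, K, S, Q, G — negative
for order-promoting ones — W, F, Y, I, L, V). The per-residue propensity
is averaged over a sequence window (half-width `window = 10` residues),
smoothed a second time (half-width `smooth = 5`), and mapped through a
logistic function (`steepness = 4`) onto [0, 1]. A score above 0.5 marks a
residue as more likely disordered; the comparison is strict, and `X`
residues are pinned to exactly 0.5 so unknowns can never create or extend
a segment.

The two window passes reflect the observation that disorder is a property
of local *composition*, not of individual residues: single
order-promoting residues inside a disordered stretch should not break it.
The half-widths are sized so that the effective kernel (~31 residues)
matches the segment length scale of interest. The steepness is a display
calibration: it controls how sharply the propensity mean saturates toward
0/1 but does not move the 0.5 decision boundary, which sits exactly at a
locally neutral composition.

Any external per-residue predictor (IUPred2A and relatives) can replace
the bundled scorer via `read_disorder_profile()`; downstream segmentation
and statistics consume the same `disorder_profile` container either way.
This is the route to use when reproducing published per-protein numbers
computed with a specific third-party predictor, since different
composition scorers place the 0.5 crossing at slightly different places.

## Segmentation and regional statistics

`find_long_idrs()` returns every *maximal* run of consecutive residues
with score strictly above the threshold whose length is at least
`min_length`. The default `min_length = 31` implements the ">30 residues"
rule for proteasome-engagement-competent segments strictly; both the
threshold and the length are plain parameters, so a ≥30 reading costs one
argument. Maximality is part of the contract: flanking residues of every
reported segment are at or below the threshold or sequence ends, and
segments are pairwise disjoint and non-adjacent. The implementation is a
run-length encoding; the test suite holds it equal to an exhaustive
linear-scan oracle on a thousand random profiles.

`classify_segments()` partitions segments around an N/C junction (for the
SETD2-style split, residue 1403): `N` if the segment ends at or before the
junction, `C` if it starts after it, `overlapping` otherwise; the three
counts always sum to the segment count. `summarize_disorder()` aggregates
the overall disordered fraction, the segment table, the N/C partition and
the per-region fractions; the length-weighted mean of the regional
fractions recomposes the overall fraction exactly, which the tests assert.

# Degron scanning

## PEST regions

`pest_scan()` follows the classical PEST-find procedure. Candidate regions
are the maximal stretches between positively charged flanks (K, R, H, or
sequence ends) of at least `min_window = 10` residues that contain at
least one P, one of D/E, and one of S/T. Each candidate is scored

```
score = 0.55 * DEPST_mass_percent - 0.5 * hydrophobicity_index
```

where the DEPST mass percent is corrected by one equivalent each of P, of
D-or-E, and of S-or-T (when both members of a pair occur, the lighter — D,
S — is subtracted; a deterministic convention), and the hydrophobicity
index is the mass-weighted mean of the Kyte–Doolittle hydropathy mapped to
`10*KD + 45`, spanning 0 (Arg) to 90 (Ile). On this scale a long
poly-DEPST stretch scores about +43 and poly-Ile exactly −45, anchoring
both ends. Scores above +5 (strict) are flagged significant, the
conventional "potential PEST" cutoff. Scores are invariant under extension
of the sequence outside a candidate's flanks, which the tests verify, and
the per-window score is held equal to an independently coded hand
evaluation.

## APC/C degrons

`dbox_scan()` matches the canonical four-residue destruction box R-x-x-L
and `kenbox_scan()` the literal tripeptide KEN. All overlapping matches
are reported with 1-based inclusive coordinates; `x` positions match the
twenty standard residues but never `X`. Scans can be restricted to a
`region()` and are guaranteed to agree with the filtered full-sequence
scan — coordinates always refer to the parent sequence.

# FRAP analysis

## Model and two-stage constrained fit

Traces are min–max normalized (`normalize_trace()`: curve minimum to 0,
maximum to 1) and aligned so the first post-bleach frame sits at t = 0
(`align_bleach()`). Only post-bleach frames enter the fit; prebleach
frames serve as the normalization reference. The bleach is treated as
instantaneous.

Full FRAP (whole punctum bleached) is fit with the single exponential

```
F(t) = plateau - (plateau - F0) * exp(-t / tau)
```

giving the exchange time constant tau of protein entering the punctum
from the nucleoplasm, and `percent_recovery = 100 * (plateau - F0) /
(1 - F0)` — recovery relative to the prebleach level, from the fitted
bleach depth F0.

Half FRAP (half the punctum bleached) mixes internal mixing with
nucleoplasmic exchange and is fit with the double exponential

```
F(t) = plateau - amp_fast * exp(-t / tau_fast) - amp_slow * exp(-t / tau_slow)
```

In the two-stage procedure (`fit_half_frap(trace, full_tau)`), the slow
time constant is *fixed exactly* to the tau from the paired full-FRAP
sample; the constraint is structural (the parameter is never free), so
`tau_slow` in the result is bit-equal to the supplied value. The fast
component then isolates internal turnover inside the punctum.
`fit_half_frap(trace, full_tau = NULL)` fits the unconstrained model,
which is used to demonstrate *why* the constraint exists: on replicate
noisy simulations of one truth the constrained estimator's sampling
variance for `tau_fast` is roughly half the unconstrained one's
(`frap_constrained_var_ratio` in the acceptance output), at the price of
a residual norm that can never be lower than the unconstrained fit's
(nested models).

## Numerical choices

Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm` on explicit residual functions). Initialization is
a deterministic multi-start grid: tau is seeded from the time to
half-recovery scaled by {0.25, 0.5, 1, 2, 4}, amplitudes from the
observed recovery depth; the best converged start by residual sum of
squares wins. There is no randomness in the fit, so identical traces give
identical results. Amplitudes are bounded below by 0, `tau_fast` above by
`full_tau`. Noiseless generator output is recovered to better than 1e-6
relative error for both models; degenerate (flat) traces and unconverged
fits raise errors rather than returning numbers.

## Identifiability and the benchmark regime

The double-exponential decomposition is only well posed when the two time
scales are separated. The package's parameter-recovery benchmark (tests
and acceptance script) therefore simulates the regime the two-stage
design targets: internal mixing with `tau_fast` in 0.1–2 s against
nucleoplasmic exchange at `tau_slow = 10` s, amplitudes 0.40/0.35 on a
0.95 plateau, Gaussian noise SD 0.05, 50 ms frames over 10 s of recovery
plus 0.7 s of prebleach — the acquisition geometry of a typical
spinning-disk FRAP experiment. Under these conditions the median relative
error of `tau_fast` over 200 traces is about 11%. When the two time
constants approach each other (within a factor of ~2–4) the components
trade off against each other and per-trace errors grow to 20% and beyond
at this noise level; that is a property of the model, and the constrained
fit is precisely the mitigation: it removes the slow time constant from
the search.

## Material-state classification

`classify_state()` encodes the qualitative FRAP signatures as an explicit
rule with documented, configurable cutoffs: `solid` if percent recovery is
below `solid_cutoff` (default 20%; strict `<`, so a value exactly at the
cutoff is not solid); otherwise `liquid` if the characteristic tau
(`tau_fast` for double-exponential fits, `tau` for single) is at most
`liquid_tau_cutoff` (default 2 s — twice a typical ~1 s
cytoplasmic-control tau; non-strict `<=`); otherwise `gel`. The defaults
are operating points, not measurements; when a cytoplasmic control is
available its fitted tau should set `liquid_tau_cutoff` directly.
Ensemble summaries average *fitted parameters* across cells, not pooled
curves, and exclude (but count) unconverged fits.

# Spectral-count quantification

## FDR filtering

`fdr_filter()` estimates FDR from shuffled-sequence decoys as
`#decoy / #target` among entities at or above a score threshold
(DTASelect-style; the estimator name is recorded in the output). At the
peptide and protein levels, entities aggregate to their best-scoring
member before counting. The returned threshold is the most permissive
observed score meeting the target — the test suite holds it equal to an
exhaustive scan over all candidate thresholds — and when no threshold
attains the target the result is an empty retention with the best
achievable FDR reported, not an exception.

## Parsimony and detection

`parsimony_reduce()` removes proteins whose observed peptide set is a
strict subset of another's and merges proteins with identical peptide
sets into one group; the representative is the lexicographically smallest
accession — a deterministic replacement for an arbitrary choice. The
operation is idempotent, never removes a protein with unique peptide
evidence, and is held equal to an exhaustive pairwise subset analysis on
randomized small instances. `detection_flags()` marks a protein detected
when at least `min_peptides = 2` distinct peptides are observed combining
all replicates (a union over runs, not a per-run requirement); this flag
drives the presence matrix.

## Distributed NSAF

Shared-peptide counts are distributed among their proteins in proportion
to each protein's unique spectral counts in the same run; when no sharing
protein has unique evidence the counts are split equally (configurable to
`drop`). Distribution conserves per-run totals exactly. The distributed
count is divided by the protein length (`SAF = count / L`) and normalized
across proteins per run, so each run's dNSAF column sums to 1 within
1e-12. Deletion-mutant baits must be quantified against their construct
lengths, not the full-length parent — `length_overrides` exists for
exactly this, and `builtin_catalog()` supplies the SETD2 construct
coordinates. Contaminant entries are excluded from the normalization
denominator by default.

## Enrichment versus mock

`enrich_vs_mock()` is deliberately simple and labelled as such in its
output: `log2((mean bait dNSAF + eps) / (mean mock dNSAF + eps))` with a
condition-label permutation p-value (exhaustive over all label
assignments for up to 10 runs, sampled with a seed beyond that). The
default pseudocount is half the smallest nonzero dNSAF in the dataset —
scale-free, since dNSAF values are already normalized. This is not a
reimplementation of Bayesian spectral-count models; it is a transparent
ranking statistic whose planted-truth recovery the acceptance run
measures.

# What the generators emulate — and what they do not

`gen_sequence()` plants blocks of disorder-promoting versus
order-promoting composition; it emulates the compositional contrast that
composition-based predictors detect, not evolved protein sequence — there
is no positional conservation, repeat structure, or real domain grammar.
`gen_idr_architecture()` builds a 2564-residue protein carrying 17 long
disordered blocks partitioned 11/5/1 around residue 1403, a DEPST-rich
PEST stretch inside 504–1403, a D box at 2033 and a KEN box at 2078, so
the sequence stages can be checked end to end against planted truth.

`gen_frap_trace()` produces exponential recovery with additive Gaussian
noise on the acquisition grid described above; it does not model
diffusion during the bleach, acquisition photobleaching, or
reaction–diffusion coupling. `gen_punctum_stack()` renders a Gaussian
punctum whose bleached-region amplitude follows the FRAP model, with
pixel noise — a registered, drift-free stack by construction.

`gen_count_table()` draws negative-binomial background counts
(mean 4, dispersion 2 per peptide per run), multiplies the planted
enriched set's peptides in bait runs by the effect size, shares a stated
fraction of peptides between protein pairs, and samples lengths over
100–2000 residues. Real AP-MS data add correlated contaminant structure,
abundance-dependent dispersion and missingness that this model does not
attempt. `gen_psm_table()` draws target and decoy scores from
location-shifted Gaussians.

Consequently, passing tests demonstrate algorithmic correctness —
segmentation equals exhaustive enumeration, thresholds equal brute-force
optima, fits recover generating parameters — and calibrated behavior
under the stated noise models. They do not certify predictor accuracy on
real proteins or enrichment power on real interactomes.

# Problem sizes

The default validation runs use: 1000 random profiles (length ≤ 200) for
the segmentation oracle; 200 noisy half-FRAP traces for tau recovery plus
60 paired constrained/unconstrained fits; 100 seeded PSM tables for the
FDR oracle; 500 random instances (≤ 8 proteins, ≤ 10 peptides) for the
parsimony oracle; and a 200-protein, 2+2-run AP-MS simulation for
end-to-end enrichment recovery. The full suite completes in well under a
minute on one core.

# Known limitations

* The bundled disorder scorer is a composition-propensity model; it ranks
  ordered against disordered composition reliably (which is what the
  planted-truth tests exercise) but its absolute 0.5 crossings differ
  from energy-based predictors. Published per-protein disorder fractions
  computed with a specific external predictor should be reproduced by
  loading that predictor's profile, not by the bundled scorer.
* PEST scoring uses average residue masses and the stated one-equivalent
  correction; variant conventions in circulation differ in these details,
  which shifts scores by a few points. All constants are exposed.
* Half-FRAP decomposition is ill-conditioned when time scales are close
  (see the identifiability discussion); reported `tau_fast` values near
  the supplied `full_tau` deserve suspicion.
* The enrichment statistic is a ranking tool with permutation
  significance; with duplicate runs the permutation p-value floor is
  coarse (1/6 for 2+2), so ranks, not p-values, carry the signal at that
  design size.
* Punctum stacks are assumed registered; a frame-to-frame correlation
  check warns about drift but performs no correction.
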