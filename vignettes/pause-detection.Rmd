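---
title: "Detecting transcriptional pause sites from RNA and protein number time series"
author: "pauseTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptional pause sites from RNA and protein number time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA polymerases (RNAPs) elongating through a prokaryotic gene do not move
uniformly.  They pause briefly (a few seconds) at essentially random
positions — *ubiquitous* pauses — and, at specific sequences such as the
*his* pause element, for much longer: about 47 s on average, entered with up
to 80% probability when the polymerase reaches the site.  Long pauses alter
the traffic of polymerases on the template, the coupling between
transcription and translation, and ultimately the fluctuations of RNA and
protein numbers.  Because single-molecule tagging can count RNA and protein
molecules in live cells over time, one can ask: **is the presence, location
and kinetics of a long pause site recoverable from such time series alone?**

pauseTrace implements a complete in-silico test bed for that question: a
delayed stochastic simulator of single-gene expression at nucleotide and
codon resolution, and three statistical instruments operating on its output
— a windowed-mean hypothesis test for pause *presence*, a 10-feature
clustering/classification pipeline for pause *kinetics*, and a
density-overlap approximate likelihood for pause *location*.

## The simulation model

### Delayed stochastic simulation

The engine is an exact stochastic simulation algorithm (direct method)
extended with a *waiting list*: any reaction product may be released after a
delay drawn from a point-mass, exponential, or zero-truncated normal
distribution rather than instantaneously.  Delays represent multi-step
processes that are not exponential, such as open-complex formation
(N(40, 4²) s) and protein folding (N(420, 100²) s).  When a reaction firing
and a waiting-list release coincide, the release is processed first (a fixed
convention).  Sampling records the state after all events with event time at
or before each sample time; samples are taken at integer multiples of the
sampling interval (1 s throughout the study).  Zero-truncated normal delays
are implemented by rejection resampling, not clipping: clipping would place
an atom at zero and bias the mean, whereas with the delays used here the
rejection probability is negligible (for N(40, 4²) it is ~10⁻²³).

The generic engine (`simulateReactions()`, `ssaStep()`) supports arbitrary
mass-action networks with guards and is used directly in the test suite
(birth–death moments, exponential-decay dynamics, distributional agreement
with an independently coded direct-method SSA).  The gene model itself runs
in a dedicated kernel sharing the same event loop, because its translation
state (one ribonucleotide lattice *per transcript*) does not fit a flat
species list.

### Transcription

One gene of length 1,000 nt (default) is transcribed as follows.  A free
RNAP binds the promoter (0.0245 s⁻¹ per free RNAP), forms the open complex
after a N(40, 4²) s delay, and clears the promoter at 150 s⁻¹ once the first
Δ_P + 1 template positions are free.  Elongation is stepwise: at each
nucleotide the polymerase activates (150 s⁻¹; 30 s⁻¹ for the first 10
positions) and then translocates (150 s⁻¹) provided the position Δ_P + 1
ahead is unoccupied.  An elongating RNAP occupies 2Δ_P + 1 = 25 template
positions (Δ_P = 12).  Competing with elongation are:

* **ubiquitous pauses** — entry 0.55 s⁻¹ at every nucleotide, exponential
  duration of mean 3 s;
* **sequence-dependent pauses** — at a pause site the entry rate is derived
  from the pause efficiency ε (the probability of pausing rather than
  activating) as k = k_a (1/ε − 1)⁻¹, so that k/(k + k_a) = ε; durations are
  exponential with the site's mean (47 s for the *his*-like default);
* **collisions** — a trailing RNAP activated immediately upstream releases a
  paused leader at 0.8·150 s⁻¹ and pushes an unpaused leader into a pause at
  0.2·150 s⁻¹;
* **arrests** (2.78·10⁻⁴ s⁻¹, mean 100 s), **editing excursions**
  (0.009 s⁻¹, mean 5 s), **premature termination** (1.9·10⁻⁴ s⁻¹) and
  **pyrophosphorolysis** (single-nucleotide backstepping, 0.75 s⁻¹, only
  when the position behind is free on both the template and the nascent
  transcript).

Termination (2 s⁻¹ at the last nucleotide) releases the polymerase and
completes the transcript.

### Translation and the per-transcript lattice

Each transcript — nascent or complete — carries its own ribonucleotide
availability lattice; ribosome footprints and moves are resolved on it
exactly as RNAP footprints are on the DNA.  Ribonucleotide n becomes
available when the transcribing RNAP passes position n + Δ_P + 1, so
translation is co-transcriptional and a ribosome can never overtake the
polymerase: when the RNAP pauses, trailing ribosomes run up to the stall
point and wait, which is how pause kinetics propagate into protein numbers.
Initiation (0.53 s⁻¹ per free ribosome) requires the first Δ_R + 1
ribonucleotides free (Δ_R = 15); each codon is translated by an activation
step at the codon's class rate (35, 8 or 4.5 s⁻¹ for classes A/B/C) followed
by three translocation substeps at 10⁴ s⁻¹.  Back-translocation (1.5 s⁻¹),
drop-off (1.14·10⁻⁴ s⁻¹) and trans-translation compete; completion
(2 s⁻¹ at the last codon) releases the ribosome and, after a N(420, 100²) s
folding delay, a protein.  Proteins degrade at 0.0029 s⁻¹, mRNAs at
0.025 s⁻¹.

Codon sequences are generated randomly per replicate from a bundled
*E. coli* K-12 codon-usage table (stop codons excluded); each codon's rate
class is assigned by abundance terciles of that table, the most frequent
third being fastest.  A user-supplied class map can override this — the true
class assignment of the source model is not published, so the tercile map is
a documented default, as is the constant trans-translation rate
k_tt = 2·10⁻⁵ s⁻¹ ("sequence dependent" in the source, value unpublished;
set it to 0 to disable the pathway).

Three choices deserve emphasis because the printed reaction scheme is
ambiguous about them:

* **mRNA degradation** fires on intact complete transcripts at 0.025 s⁻¹
  regardless of ribosome load; the transcript immediately stops accepting
  new ribosomes and leaves the mRNA count, while already-bound ribosomes run
  to completion.  Gating degradation on a ribosome-free transcript instead
  would inflate the effective mRNA lifetime far beyond the calibrated
  1/0.025 = 40 s, because loaded transcripts are rarely empty.
* **Premature termination** discards the nascent transcript and returns its
  ribosomes to the pool (a trans-translation-like rescue); the event is
  rarer than 1% per passage, so this bookkeeping choice is immaterial.
* **Translocation substeps** are pass-through states: activation, drop-off
  and back-translocation act only at codon-aligned positions.  Letting them
  act mid-step would break codon alignment, and at 10⁴ s⁻¹ the affected
  probability mass is ~0.4%.

### Pool sizes and the induction regime

The reaction table gives rate constants but no copy numbers for free RNAP
and ribosomes.  These pools set the induction regime, and the study's
description constrains it: RNA present at one-to-a-few molecules, induction
strong enough for RNAP collisions, and a pause site whose presence is
measurable in the mean RNA number.  The defaults are **2 free RNAPs** and
**20 free ribosomes**.  With the promoter kinetics above, any large RNAP
pool makes initiation promoter-limited and the pause invisible in the mean;
with a pool of 2, polymerases held longer on a paused template measurably
reduce the initiation flux, and two polymerases can co-occupy the template
so that collision-mediated pause release/induction is exercised.  Mean
counts in this regime: ~1 mRNA molecule, protein in the low hundreds.

### The measurement model

The sampled observables are the quantities a single-molecule experiment
reports at 1 Hz: the number of tagged mRNA molecules — nascent transcripts
under elongation plus completed, undegraded transcripts — the current
protein count, and the cumulative number of proteins produced.  Counting
nascent transcripts matters: a transcript whose polymerase sits in a 47-s
pause is visible for that much longer, so the pause raises the mean tagged-
RNA number (models A vs B: ≈0.95 vs ≈1.40 under the defaults) even though
the completed-mRNA flux is nearly unchanged.  This is precisely the signal
the detection test exploits.

## Detecting a pause site

Given two F×L count matrices (F replicate series, L stationary samples),
the procedure draws S windowed means from each — replicate row
i ~ unif(1:F), window start L_s ~ unif(1:L−ΔL), mean over ΔL + 1
consecutive samples (both endpoint conventions inclusive, window length
exactly ΔL + 1 as printed in the source) — and compares the two S-vectors
with a Welch two-sample t-test.  Repeating N times yields a p-value
population; a median below α = 0.05 indicates separable models.  Degenerate
(zero-variance) repetitions are excluded and counted, never coerced to
p = 1.  Simulations start without RNA or protein; the first 50,000 s are
discarded as burn-in at full scale (`stationarityCheck()` verifies weak
stationarity by a Welch t-test between ensemble means of n = 10 columns
sampled from the first and last thirds of the span — the windows are our
choice, the source does not pin them down).  Both the replicate row and the
window start are redrawn for every window; the source is ambiguous on
whether the row is fixed per profile, and redrawing is the reading that
makes the S draws exchangeable.

## Feature vectors and classification

Ten statistics summarise one (R, P, E) triple of mRNA, protein and
cumulative-protein series: lag-weighted means and standard deviations of
the autocorrelation of R and of P (lags 1..K, K = 300), of the
cross-correlation of (R, P) and of (P, E), and the mean and SD of the mRNA
*decay times* — lengths of maximal runs of consecutive steps in which the
count does not increase.  The lag weighting (r(l)·l rather than r(l)) is
reproduced exactly as printed; an unweighted mean would be equally
plausible, but fidelity wins over correction.  Empty decay vectors yield
(0, 0) by convention, and single-run vectors an SD of 0.

Feature collections are z-transformed per component (sample mean 0,
variance 1, n−1 normalisation), clustered with Manhattan distance and
McQuitty (WPGMA) linkage, and classified with a random forest (5,000 trees
at full scale) whose error is the mean misclassification rate over 100
bootstrap resamples, evaluated on the items left out of each resample (the
source does not state its error protocol; out-of-resample is the standard
unbiased choice).  Forest defaults beyond the tree count are standard
(√V variables per split).  Pairwise feature-correlation p-values
(two-sided Pearson t-test) document that the 10 features carry largely
complementary information.

## Locating the pause site

The location θ of a pause site is estimated by an approximate likelihood
built from the features: for each candidate θ, reference data are simulated
from a model with the site at θ (same efficiency and mean duration as the
default site) and, feature by feature, the overlap coefficient
∫ min(f̂, ĝ) dx between the observed and simulated feature densities is
computed with Gaussian kernel estimates (Silverman bandwidth per sample,
trapezoidal integration on ≥512 points spanning both samples ±3
bandwidths).  Treating the V = 10 features as independent — justified by
the correlation analysis above — and the overlap as the per-sample factor,
the log-likelihood is log L(θ|y) = S Σ_j log p_j(θ).  The inner product of
the printed double-product form runs over samples but its factors do not
depend on the sample index under this reading, hence the S multiplier; S
does not move the argmax and is retained for fidelity.  Overlaps below
10⁻¹² are floored before the log so profiles stay comparable; raw zeros
are reported separately.  The profile is normalised to the logarithmic
relative likelihood LRL(θ) = log L(θ) − log L(θ̂) ≤ 0, ties in the argmax
resolving to the smallest θ.

Uncertainty comes from resampling the *observed* feature rows with
replacement B times (50,000 by default) and recomputing θ̂ against the
cached simulated reference sets, which are fixed — re-simulating per
bootstrap draw would be both intractable and a different estimator.  The SD
of the bootstrap θ̂ distribution and its percentile interval are reported.
The default grid spans every 50 nt from 50 to 950 for a 1,000-nt gene; grid
spacing and per-θ simulation budget are configurable because the source
does not state them.

## Problem sizes, tests and what they show

The full study design — 10 instances of 10⁶ s per model, 50 feature vectors
per model, B = 50,000 — is reproducible with `runConfig()` defaults but
takes hours per model on one CPU.  The package's own test suite runs the
same machinery at reduced sizes chosen as the smallest where each method's
qualitative claim still has comfortable margins:

* detection: 2 replicates × 2·10⁵ s (burn-in 5·10⁴ s), ΔL = 1,000, S = 10,
  N = 50;
* classification: 6 models × 4 replicates × 1.05·10⁵ s (burn-in 5·10³ s);
  full-row feature vectors for clustering, 50,000-sample windows for the
  forest (500 trees, 20 bootstraps);
* location: grid {200, 350, 500, 650, 800}, S′ = 24 reference vectors per
  candidate from 3 runs, 12 observed vectors per repetition, B = 1,000.

Short runs use a 5,000-s burn-in: the slowest relaxation time under the
default kinetics is the protein lifetime (1/0.0029 ≈ 345 s), so 5,000 s is
>14 lifetimes; the 50,000-s full-scale burn-in is kept where the study's
stated conditions apply.

The synthetic generator emulates intrinsic stochasticity of single-gene
expression with known, stationary kinetics and an isolated gene.  It does
not emulate extrinsic noise (cell division, RNAP/ribosome pool fluctuations
shared across genes), measurement noise of real tagging systems, tag
maturation delays, or RNA immortalisation by MS2 arrays.  Passing tests
therefore show that the statistical machinery recovers pause properties
from ideal single-molecule counts of this model class — not that it would
from any real microscopy series.

## Known limitations

* The translation lattice is per transcript, which is the physically
  consistent reading of the printed reaction set, but it means the flat
  reaction-list export (`buildReactionSystem()`) summarises rather than
  enumerates translation channels.
* Pause-site insertion replaces the ubiquitous pause channel at that
  nucleotide rather than adding to it (the site's entry rate already
  dominates by three orders of magnitude).
* The classification error at full scale (11.75% for six models in the
  source) is not asserted by the test suite; reproducing it requires the
  60 × 10⁶ s design.  The suite asserts the scale-appropriate orderings
  instead (six-model error below chance, position-only subset easier than
  all six).
* Estimation of pause *efficiency* or *duration* by the overlap likelihood
  is not implemented; the profile runs over position only.
* The position estimator's resolution is tied to the feature precision and
  hence to the window length.  At the reduced test sizes the point estimate
  lands within one grid step of the truth in most but not all repetitions
  (the bootstrap interval covers the truth more reliably); sharp recovery
  requires window lengths approaching the full study design, where the
  correlation features become strongly informative.
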