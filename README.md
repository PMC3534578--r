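# pauseTrace

Detecting sequence-dependent transcriptional pauses from RNA and protein
number time series.

## What this package is for

RNA polymerases transcribing a prokaryotic gene pause: briefly and anywhere
(ubiquitous pauses, mean ~3 s), and for much longer at specific sequences —
the *his* pause element holds the polymerase for ~47 s with up to 80%
efficiency.  Long pause sites shape polymerase traffic, transcription–
translation coupling, and the stochastic fluctuations of RNA and protein
numbers, but only a handful of pause-prone sequences are known, because
identifying them has required in vitro single-molecule force spectroscopy.
Single-molecule fluorescence tagging, by contrast, can count RNA and
protein molecules in live cells over time, genome-wide.

pauseTrace is for researchers asking whether such counts are enough: it
simulates single-gene expression at nucleotide and codon resolution with a
delayed stochastic simulation algorithm, and provides the statistics to

1. **detect** a pause site — repeated Welch t-tests on randomly windowed
   means of the count series of a candidate gene against a reference;
2. **classify** pause kinetics — a 10-dimensional feature vector
   (lag-weighted autocorrelation and cross-correlation summaries and mRNA
   decay-time statistics), Manhattan/McQuitty hierarchical clustering, and
   a bootstrap-averaged random-forest error;
3. **locate** the pause site — an approximate likelihood
   log L(θ|y) = S Σⱼ log ∫ min(f̂ⱼ, ĝⱼ(θ)) dx built from Gaussian kernel
   density overlaps between observed and simulated feature distributions,
   profiled over candidate positions θ with a bootstrap confidence
   interval.

The simulator implements the full reaction set: promoter binding with a
N(40, 4²) s open-complex delay, stepwise elongation with a 25-nt polymerase
footprint, ubiquitous and sequence-dependent pausing (site entry rate
k = k_a(1/ε − 1)⁻¹ from the pause efficiency ε), collision-mediated pause
release and induction, arrests, editing, premature termination,
pyrophosphorolysis, termination; and codon-resolution translation with
ribosome traffic on a per-transcript lattice, back-translocation, drop-off,
trans-translation, and a N(420, 100²) s folding delay.  Six reference
models A–F (no site; site at nt 500/250/750; durations 23.5/47/94 s)
reproduce the study design.

## A worked example

Simulate the null model A and the his-pause model B and test whether the
pause is detectable from the mRNA numbers alone:

```r
library(pauseTrace)

b <- makeModel("B", seed = 1)
b@template@pauseSites[[1]]
#> PauseSite: nt 500, efficiency 0.80, mean duration 47 s (exponential)

A <- runExperiment(runConfig("A", replicates = 2, tEnd = 55000,
                             burnin = 5000, seed = 11))
B <- runExperiment(runConfig("B", replicates = 2, tEnd = 55000,
                             burnin = 5000, seed = 12))
c(meanA = mean(tsValues(A$rna)), meanB = mean(tsValues(B$rna)))
#>     meanA     meanB
#> 0.9307514 1.4025119

pv <- compareModels(A$rna, B$rna, deltaL = 1000, S = 10, N = 50, seed = 7)
pv
#> PValueSet: A vs B (deltaL=1000, S=10, N=50)
#>   median p = 8.28e-06; fraction below 0.05 = 1.000
```

The pause raises the mean number of tagged mRNA molecules from ~0.93 to
~1.40 — a transcript whose polymerase sits in a 47-s pause stays visible
longer — and the windowed-mean test separates the two models decisively:
all 50 repetitions reject equality of means at α = 0.05.  Comparing two
independent instances of model A instead yields p-values spread over
[0, 1] with a median near 0.5 (no false detection).

Downstream, `featureTable()` turns replicate matrices into feature vectors,
`rfClassify()`/`clusterFeatures()` quantify how well models with different
pause kinetics separate, and `simulateReferenceSets()` +
`locatePauseSite()` profile the approximate likelihood of the pause
position over a nucleotide grid.

A thin command-line front end over these functions is installed at
`inst/scripts/pausetrace.R` (subcommands `simulate`, `detect`, `features`,
`classify`, `locate`, `fixture`).

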