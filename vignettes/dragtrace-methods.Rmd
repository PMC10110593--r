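---
title: "Models and methods behind dragtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dragtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dragtrace)
```

dragtrace analyzes in situ cellular barcoding data from a recombination
cassette: a synthetic V, D and J segment joined by RAG-mediated
recombination, with nucleotide trimming at the joining sites, untemplated
(TdT) N-additions at the two junctions, and occasional incorporation of the
D segment in reverse-complement orientation. Each recombination event yields
a heritable DNA barcode; sequencing barcodes from sorted cell populations
traces clonal output across developmental compartments and over time. This
vignette records the models, the numerical choices, and what the synthetic
benchmarks do and do not demonstrate.

## The generative recombination model

A recombination scenario is described by seven independent components: a
Bernoulli D-inversion indicator (probability `p_inv`), four trim counts
(V 3' end, D 5' and 3' ends in the post-orientation frame, J 5' end), and
two untemplated insertion strings whose lengths follow categorical
distributions and whose bases are i.i.d. from a four-letter composition
distribution. The scenario probability is the product of its component
probabilities; no Markov dependence between inserted bases and no
P-nucleotides (palindromic additions) are modeled, as neither is
identifiable from junction-level count data.

Defaults: trims are supported on 0–32 per site (capped at the segment
length), insertions on 0–15 per junction, covering the largest insertion and
deletion counts observed in the system; `p_inv = 0.12`, the
observed inversion rate. Within those supports the default trim and
insertion length distributions are truncated geometric (decay 0.80 and 0.65
respectively), concentrating mass at small counts as junction profiles do;
the insertion composition is mildly G/C-biased (A/T 0.20, G/C 0.30),
reflecting TdT preference. All of these are re-estimable from data
(`fit_model()`) and replaceable through `generative_model()`.

The default cassette (`default_reference()`) is a fixed synthetic stand-in:
a 60-nt V, a 17-nt D (the length of the natural DSP2.4 segment, with an ATC
in place of the start codon) and a 40-nt J, long enough to support the trim
ranges. Real cassette sequences can be supplied as FASTA
(`read_reference()`).

One structural caveat: with per-site D-trim supports of 0–17 each, the
factorized model places a small amount of probability on infeasible pairs
`del_d5 + del_d3 > |D|`. `sample_recombination()` resamples such pairs
(conditioning on feasibility), so sampled frequencies exceed
`scenario_probability()` values by the factor `1/(1 - eps)` with `eps` the
infeasible mass. Exact unit normalization of `compute_pgen()` over the
sequence space therefore holds when the joint D support is feasible
(e.g. the micro fixtures used in the tests); for the default model the
discrepancy is below Monte-Carlo resolution at the tested sample sizes.

## Generation probability

`Pgen(s)` is the probability that a single recombination event produces
exactly the sequence `s`. Junctions are ambiguous — an inserted base that
coincides with a germline end can be attributed either way — so `Pgen` must
sum over every consistent scenario; no "best annotation" enters the
computation. The consistent scenario set can be combinatorially large
(notably when the D segment is fully deleted, where every split of the
junction between the two insertions and every `(del_d5, del_d3)` partition
of `|D|` is a distinct scenario). `compute_pgen()` therefore evaluates the
sum in factorized form: left-junction choices (del_v, first insertion)
interact with right-junction choices (del_j, second insertion) only through
the D-core placement interval, so the total is a sum over core placements of
a product of two independently aggregated junction sums. This is exact —
the tests verify equality with explicit scenario-space brute force to 1e-12
on micro cassettes, and unit normalization over the full producible
sequence space — and fast enough to score thousands of barcodes.

`enumerate_scenarios()` materializes the explicit set (optionally capped at
a total edit count) and is the basis of parsimony annotation in barcode
calling: among consistent scenarios, the one with maximal germline
retention. Since the sequence length fixes insertions given deletions,
maximal retention coincides with minimal total edits; remaining ties are
broken lexicographically.

## Fitting the model by EM

`fit_model()` estimates all categoricals and `p_inv` from observed barcode
sequences. The E-step weights every consistent scenario of every sequence
by its normalized probability under the current model; the M-step sets each
categorical to the pseudo-count-regularized expected-count distribution
(pseudo-count 0.5 per category). Initialization is uniform with
`p_inv = 0.5`; iteration stops when the largest parameter change falls
below `tol` (default 1e-6) or at `max_iter` (200).

Because the complete scenario set is too large to materialize at scale, the
E-step enumerates per sequence only scenarios within `slack` (default 6)
total edits of that sequence's parsimony minimum. Each reattributed base
costs at least one trim-probability and one insertion-probability factor,
so the truncated mass decays geometrically; at slack 6 it is orders of
magnitude below the estimation error at the tested sample sizes. The
truncation is fixed before iteration begins, so EM is exact on the
truncated space and its monitored data log-likelihood is non-decreasing.
Parameter recovery on 50,000 simulated barcodes keeps the total-variation
distance of every categorical below 0.05 (the acceptance suite runs this
end to end).

## The synthetic data generator

The simulator provides ground truth at three levels.

**Clone populations** (`simulate_clone_population()`): clones carry unique
sampled barcodes, a fate class (one of the seven nonempty subsets of
{HSPC, MP, M}), and per-compartment cell counts. Default class proportions
put 13.7% of clones in the three-compartment class — the observed fraction
of barcodes shared across HSPCs, myeloid progenitors and myeloid cells —
and zero mass on the HSPC–M class, which is not observed in the data; the
remaining mass is spread over single- and two-compartment classes as a
design choice. Clone sizes are log-normal per compartment (myeloid median
1,000 cells, sigma 0.5 log10 units, spanning roughly 100–10,000 cells; the
distributional family is a choice — the data constrain only the range).
GFP labeling is Bernoulli per clone, independent of fate (labeling is
neutral), default efficiency 0.1.

**Reads** (`simulate_reads()`): GFP+ cells are drawn without replacement
proportional to clone sizes (multivariate hypergeometric), split across PCR
duplicates, tagged with 8-nt UMIs (`1 + Poisson(0.3)` per cell), amplified
to `1 + Poisson(2)` reads per UMI, and given independent per-base
substitution errors (default 1e-3). Each read is UMI + 12-nt constant
anchor + the full recombined region; reads are variable-length and span the
whole cassette, emulating junction-spanning merged/long-read data — a
100-nt fixed layout cannot contain the default cassette's recombined region,
so full-span reads were chosen instead; all offsets are configurable. PCR
is modeled only through the reads-per-UMI distribution: no chimeras, no
jackpot amplification, no quality-score structure.

**Timecourses**: `simulate_diversity_observations()` draws per-sample
diversity values directly from the segmented gamma mixed model below — the
correct generator for estimator-recovery studies — while
`simulate_timecourse()` realizes the same trajectory mechanistically
through the number of active clones per mouse and low-capture blood
replicates (default 5% capture), which reproduces the qualitative gap
between blood and bone-marrow replicate overlap.

What passing these benchmarks shows: the pipeline recovers what this
generator encodes — exact barcode identity, Poisson-ish UMI/read counts,
independent substitution errors. Real libraries add PCR chimeras, indel
sequencing errors, jackpot amplification and context-dependent error rates
that the generator deliberately omits; performance on real data is bounded,
not established, by these tests.

## Barcode calling and filtering

UMI extraction requires the constant anchor within 1 mismatch. Per-UMI
consensus takes the per-position majority over reads of the modal insert
length; any tie (modal length or position vote) discards the group —
barcode identity must be exact, so ambiguity codes are never emitted.
Defaults: 2 reads minimum per UMI, 3 UMIs minimum per replicate, detection
required in both PCR duplicates (`filter_matrix()`); the exact thresholds
in the source study are graphical, so these are configuration-first
defaults. Abundances are normalized per sample and arcsinh-transformed
(cofactor 1) for heatmaps and replicate correlations; replicate overlap is
Jaccard (the overlap statistic is not defined in the source, so the choice
is stated here). With default thresholds the synthetic mixture benchmark
detects a 100-cell clone in a 25,000-cell sample (0.4%) with at most one
false positive across 14 samples.

Recurrent-barcode filtering removes rows with `Pgen >= 1e-4` (strict `<`
retained, matching the study's cutoff). `recurrence_probability()` gives
the binomial tail probability that a barcode arises independently at least
twice among `n` induction events; it is evaluated through `pbinom()` for
numerical stability, which is algebraically the stated closed form.

## Diversity estimation

`chao2()` estimates total richness from incidence across sampling units
(default: the two PCR duplicates). The classic form
`S_obs + ((m-1)/m) Q1^2 / (2 Q2)` is used when doubletons exist, the
bias-corrected form otherwise; both are exposed, as is `chao2_stats()` for
precomputed counts. Labeling correction divides the estimate by the GFP+
fraction — labeled clones are an unbiased Bernoulli thinning of all clones
under neutral labeling, so thinning-corrected richness is richness over the
labeling efficiency. Renyi entropies `H_q` and the Simpson family are
computed directly from relative abundances; inverse Simpson
(`exp(H_2)`) is the default response for the dynamics module because it is
positive and continuous, hence compatible with a gamma model.

## Diversity dynamics: segmented gamma GLMM

`fit_breakpoint_glmm()` models diversity `y_itr` (mouse `i`, time `t`,
replicate `r`) as Gamma with log-link mean
`beta0 + u_i + beta1 t + beta2 (t - t_b)+`, `u_i ~ N(0, sigma_u^2)`. The
marginal likelihood integrates each mouse's random intercept by adaptive
Gauss–Hermite quadrature (default 9 nodes, recentred and rescaled at the
Newton-found conditional mode) and is maximized by L-BFGS-B with a
Nelder-Mead fallback; this authored implementation matches glmmTMB to
about 1e-5 on coefficients and log-likelihood in the test suite, and unlike
a quasi-likelihood fit it yields a true log-likelihood, which model
selection requires. The breakpoint is profiled over a monthly grid (5–10
months, step 0.5) rather than jointly optimized — with 4 mice and 9
timepoints a smooth profile is more stable than gradient search, and the
mean is continuous at `t_b` by construction. AIC counts the profiled
breakpoint as one extra parameter. Replicates enter as repeated
observations ("accounting for sampling"); random slopes are not supported
by 4 mice and are deliberately omitted. Predicted trajectories report the
conditional mean of the median mouse (`u_i = 0`), with a delta-method 95%
interval on the log scale from the fixed-effect covariance.

The default simulated dynamics decline at -0.15/month to a breakpoint at 7
months and rise at +0.15/month afterwards, with sigma_u 0.25 and gamma
shape 20. Published diversity trajectories constrain the shape of this
curve but not its effect sizes; the defaults were chosen so that the
programmed breakpoint is identifiable at monthly precision under the
study design (4 mice, months 4–12, duplicates) — the
recovery experiments in the acceptance suite verify breakpoint recovery
within one month and correct model selection in over 90% of replicates,
and that under linear truth the extra breakpoint parameters are usually
(not always: profiling inflates the apparent gain) rejected by AIC.

## Numerical and degenerate-input conventions

* Scenario enumeration and `Pgen` treat sequences with characters outside
  {A,C,G,T} as unproducible; consensus sequences containing N are rejected
  before annotation.
* `fit_model()` excludes (with a warning and a reported count) sequences
  admitting no scenario; it errors only if none remain.
* Zero-count samples are an error in normalization and clone-size
  computation rather than silently producing NaN.
* Noiseless GLMM inputs drive the gamma shape to its optimizer bound
  (1e8); fixed effects remain exactly identified there, which the tests
  exercise.
* All stochastic functions draw from R's global RNG: a single `set.seed()`
  call makes any pipeline run, including FASTQ bytes, reproducible.

## Problem sizes used in the checks

The packaged suites simulate 100,000 recombinations for the indel/inversion
profiles, 50,000 barcodes for EM recovery, 25,000-cell mixtures for
detection benchmarks, and 100 replicates of the 4-mouse longitudinal design
for breakpoint recovery — sizes at which the Monte-Carlo error of each
checked quantity is well below its acceptance margin.

## Known limitations

* The insertion model is i.i.d.; real TdT tracts have modest
  order-1 structure.
* No chimera or jackpot-PCR model; false-positive rates on real libraries
  can exceed the simulated ones.
* UMI collisions are resolved by majority/tie-discard rather than network
  deduplication; at 8-nt UMIs and very deep sampling a directional-network
  method would be preferable.
* The breakpoint model assumes one shared breakpoint across mice and
  intercept-only random effects.
* `Pgen` assumes error-free barcode sequences; scoring uncorrected
  sequencing errors underestimates generation probabilities.
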