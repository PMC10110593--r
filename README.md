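# dragtrace

Analysis of in situ cellular barcoding data from VDJ-recombination
cassettes. A genomic cassette carrying synthetic V, D and J segments is
recombined once per cell upon induction — segments are joined with
nucleotide trimming at four sites, untemplated (TdT) N-additions at both
junctions, and occasional reverse-complement (inverted) incorporation of
the D segment — creating a heritable DNA barcode that marks the cell's
clonal progeny. Sequencing these barcodes from sorted hematopoietic
compartments (HSPC, myeloid progenitors, mature myeloid cells) and from
longitudinal blood samples quantifies how many stem-cell clones drive
myelopoiesis and how that changes over time.

The package is for scientists running or reanalyzing such lineage-tracing
experiments. It provides:

* **Generative recombination model** — categorical distributions over trim
  counts and insertion lengths, i.i.d. insertion composition, D-inversion
  probability. The generation probability of a barcode,
  `Pgen(s) = sum over scenarios sigma with realize(sigma) = s of P(sigma)`,
  is computed exactly by a factorized scenario-space sum
  (`compute_pgen()`), and all model parameters are estimable from observed
  barcodes by expectation-maximization (`fit_model()`).
* **Ground-truthed simulation** — clone populations with compartment fate
  classes and log-normal sizes, UMI-tagged reads with PCR duplicates and
  sequencing errors, and longitudinal diversity trajectories with a
  programmed breakpoint.
* **Barcode calling** — UMI extraction, per-UMI majority consensus,
  parsimony annotation against the cassette, replicate-consistent
  filtering, arcsinh-normalized abundances, replicate concordance.
* **Recurrence filtering** — removal of high-`Pgen` barcodes (default
  cutoff `1e-4`) that arise independently in multiple cells, plus the
  binomial recurrence probability `1 - (1-p)^n - n p (1-p)^(n-1)`.
* **Clonal analysis** — fate classes (subsets of {HSPC, MP, M}), clone
  sizes in cells, chao2 incidence richness with labeling-efficiency
  correction, Renyi/Simpson diversity profiles.
* **Diversity dynamics** — a segmented gamma GLMM,
  `log mu_it = beta0 + u_i + beta1 t + beta2 (t - t_b)+` with
  `u_i ~ N(0, sigma_u^2)`, fitted by adaptive Gauss-Hermite quadrature
  with the breakpoint profiled over a grid, plus null models, AIC
  selection and mean trajectories with 95% ribbons.

## Worked example

```r
library(dragtrace)
set.seed(42)

ref   <- default_reference()
model <- default_model(ref)

## simulate a barcoded population and sequence its myeloid compartment
pop  <- simulate_clone_population(200, labeling_efficiency = 0.5,
                                  model = model, reference = ref)
sim  <- simulate_reads(pop, sample_spec(compartment = "M",
                                        cells_sampled = 2000))

## reads -> UMI consensus -> annotated count matrix -> filtered matrix
res  <- call_reads(sim$reads, ref)
mat  <- build_matrix(res$calls, sim$samples)
fm   <- filter_matrix(mat)               # >=3 UMIs in both PCR duplicates
replicate_concordance(mat)
#>   mouse compartment timepoint   overlap correlation
#> 1    m1           M         0 0.9482759   0.9432791

## score and remove recurrent (high-Pgen) barcodes
fr <- filter_by_pgen(annotate_pgen(fm, model, ref), threshold = 1e-4)
fr$report
#> pgen_report: threshold 0.0001, retained 44 / 45 (97.8%)
#>   mouse-unique among retained: 100.0%
```

The replicate overlap (Jaccard, 0.95 here) and the correlation of
arcsinh-transformed abundances (0.94) say the two PCR duplicates detect
essentially the same barcodes at consistent abundances; 44 of 45 barcodes
fall below the generation-probability cutoff and are kept as reliable
clone markers.

Longitudinal diversity with a breakpoint:

```r
set.seed(7)
obs <- simulate_diversity_observations()    # 4 mice, months 4-12, duplicates
fit <- fit_breakpoint_glmm(obs)
fit
#> Segmented gamma GLMM (log link, mouse random intercept, AGQ 9)
#>   breakpoint t_b = 7.00 months (profiled over 11 candidates)
#>   beta0 = 5.576, slope before = -0.1188, slope after = 0.1471
#>   sigma_u = 0.350, gamma shape = 24.51
#>   logLik = -358.99 (df 6), AIC = 729.98
compare_models(c(list(breakpoint = fit), fit_null_models(obs)))
#>        model k    logLik      AIC     dAIC
#> 1 breakpoint 6 -358.9902 729.9804  0.00000
#> 2     linear 4 -376.5803 761.1606 31.18024
#> 3  intercept 3 -387.9172 781.8344 51.85401
```

The fitted breakpoint sits at month 7: clonal diversity in blood declines
(slope -0.12/month on the log scale) and then rises (+0.15/month), and the
breakpoint model beats both null models by over 30 AIC units.

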