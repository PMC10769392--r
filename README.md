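# enseq

Deep-ensemble consistency analysis for genomic sequence-to-activity models.

Sequence-to-activity models predict molecular readouts — chromatin
accessibility, TF binding, histone marks, transcription initiation — in
128 bp bins directly from DNA sequence. Their predictions on the reference
genome are strong, but their behaviour on *variant* sequences (eQTLs,
personal genomes) is far less reliable. A practical way to see where such a
model is uncertain is a **deep ensemble**: train M replicates that differ
only in their random seeds and ask where the replicates disagree.

`enseq` implements that analysis as a reusable R pipeline for researchers
in regulatory genomics, together with a synthetic ground-truth model and a
family of seed-perturbed replicate predictors, so the whole machinery runs
and is testable on a desk scale without GPUs:

* **Consistency core** — the ensemble sign probability
  `Pr(y_alt − y_ref > 0) ≈ (1/M) Σ_i 1{f_i(x_alt) − f_i(x_ref) > 0}`,
  three-way classification of units into *consistently correct /
  inconsistent / consistently incorrect* against experimental truth,
  Poisson-mixture moments of ensemble-averaged count predictions, pairwise
  replicate correlations, and exact/approximate one-sided rank tests with
  Benjamini–Hochberg correction.
* **Peak calling** — the Poisson-null caller (λ = mean bin activity,
  upper-tail p-values, BH at FDR 0.01) used to binarize experimental and
  predicted tracks, and the consistency breakdown over all bins, peak bins
  and TSS peak bins.
* **Motif perturbation** — PWM entropy and disruptive-mutation design,
  seeded motif sampling, fixed-offset insertion upstream of the TSS, TF
  activity and mutation-activity scores, and per-track inconsistency
  fractions.
* **Variant effects** — SAD (SNP activity difference) scores summed over
  the three bins centered at a variant, eQTL filtering rules, sign
  consistency tables, effect-size/annotation stratification, and
  majority-vote versus single-replicate accuracy.
* **Personal genomes** — phased haplotype construction, per-individual
  expression prediction, cross-individual Spearman correlations, gene
  uncertainty ranking, and driver-variant identification with
  cross-replicate concordance.

The synthetic generator plants PWM matches in background sequence, maps
them to per-bin activity through a saturating, distance-decayed log-odds
model with a softplus link, samples Poisson "experimental" counts, and
perturbs the ground truth into M pure-function replicates whose
disagreement concentrates — as for trained replicates — on weak and distal
signals. See the methods vignette
(`vignettes/ensemble-consistency-methods.Rmd`) for the model, every
parameter, and the reasoning behind the defaults.

## A worked example

```r
library(enseq)

model <- default_ground_truth()                       # 4,096 bp, 32 bins, 4 tracks
ens   <- make_replicate_ensemble(model, M = 5, sigma = 0.25, seeds = 101:105)
sim   <- simulate_regulatory_genome(model, n_windows = 4, seed = 7)
sim$windows[[1]]
#> <genomic_window> w0001  chrS:0-4096 (+)  anchor=2048
#>   CTAAAGTCATAAGATATACTGTCCCAGTCTGAAATCTGCTCTGTCTACCCTGGGGTAATA...

eq  <- simulate_eqtls(model, sim$windows, sim$sites, n_pos = 8, n_neg = 8, seed = 3)
eff <- variant_effect_table(ens, sim$windows, eq)
eff$table[c(1, 3, 9, 14), c("variant_id", "tss_distance", "true_sign",
                            "sign_probability", "mean_abs_sad", "category")]
#> variant_id  tss_distance  true_sign  sign_probability  mean_abs_sad  category
#> v0001       -899          -1         0.0               10.379        CONSISTENT_CORRECT
#> v0003        -30          -1         0.0                4.201        CONSISTENT_CORRECT
#> v0009       1348          NA         0.4                0.053        INCONSISTENT
#> v0014       -209          NA         0.0                0.008        CONSISTENT_NO_TRUTH
```

Reading the table: `sign_probability` is the fraction of the five
replicates predicting that the alternate allele *increases* activity.
Variants v0001 and v0003 sit inside planted motif instances — their effects
are large (`mean_abs_sad`), every replicate agrees on the direction, and
the direction matches the ground truth. v0009 is a background substitution
with a tiny effect: two of five replicates call it positive, so it is
inconsistent — exactly the small-effect regime where ensemble disagreement
concentrates. v0014 is a unanimous call on a variant with no known truth.

The classification primitive itself:

```r
classify_consistency(c(1, 1, 0, 1, 1), truth = 1, unit_id = "binA")
#> <consistency_record> binA  p=0.80 (M=5)  INCONSISTENT

poisson_mixture_moments(c(1, 3), c(0.5, 0.5))
#> <mixture_moments> mean 2, variance 3
```

(the mixture of two Poissons is overdispersed: variance 3 > mean 2).

The full pipeline — simulation, peak calling, reference consistency, motif
insertion, eQTL and personal-genome stages, plus a summary table — runs
from one call and writes TSV/FASTA/VCF/BED outputs and a run log:

```r
res <- run_pipeline(seed = 1, outdir = "enseq_run")
res$report           # metric/value summary across all stages
```

`run_pipeline(sigma = 0, ...)` is the degenerate control: with a zero
perturbation scale every replicate equals the ground truth and every stage
reports exactly zero inconsistent units.

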