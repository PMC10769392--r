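---
title: "Methods: deep-ensemble consistency analysis for sequence-to-activity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-ensemble consistency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`enseq` quantifies the *predictive uncertainty* of genomic
sequence-to-activity models through the consistency of a deep ensemble:
M replicate predictors that share architecture and training conditions and
differ only in their random seeds. Because training real replicate networks
is far outside the scope of an R package, `enseq` pairs the analysis
machinery with a synthetic ground-truth regulatory model and a family of
seed-perturbed replicate predictors, so that every downstream statistic can
be exercised against a known truth.

The analyses cover four sequence regimes: reference windows (binarized by
Poisson peak calling), reference windows perturbed with transcription-factor
motifs, single-nucleotide variants (SAD scores and eQTL-style sign
analysis), and personal diploid genomes (cross-individual expression
correlation and driver variants).

# The consistency machinery

For a unit of analysis (a genomic bin, a variant, a gene) each replicate
produces a binary label: *is this bin a peak*, *does the alternate allele
increase activity*, *is the cross-individual correlation positive*. The
ensemble sign probability is the fraction of replicates whose prediction
difference is strictly positive; a difference of exactly zero counts as
"not increased". The strict inequality is deliberate: with continuous
predictors, exact zeros arise only in degenerate situations (for example a
zero-noise ensemble), and resolving them toward "no increase" keeps the
degenerate case deterministic.

Units where the probability is 0 or 1 are *consistent*; with ground truth
available they split into *consistently correct* and *consistently
incorrect*; everything else is *inconsistent*. The same recipe is applied
to every unit type via a caller-supplied binarization, which is why the
classification lives in one function (`classify_consistency`) rather than
being re-derived per analysis.

The ensemble-averaged predictive distribution of a Poisson-output model is
a Poisson mixture; `poisson_mixture_moments` exposes its mean and variance
(law of total variance), which is overdispersed — variance strictly above
the mean — whenever component means differ. This motivates working with
replicate agreement on *binary* transformations rather than attempting a
distribution over the difference of two Poisson mixtures, for which no
tractable mass function exists.

# Prediction conventions

All analysis-facing predictions are augmentation-averaged
(`robust_predict`): the mean of six predictions over sequence shifts of
-1, 0, +1 bp crossed with forward and reverse-complement strands.
Reverse-complement outputs are returned to forward bin order before
averaging, and shifted windows are padded with N at the vacated edge. Six
augmentations (rather than four) is the standard convention for this model
family; the choice is configurable only by bypassing `robust_predict`.

* SAD (SNP activity difference): alternate minus reference prediction,
  summed over the bin containing the variant and its two neighbours.
  Variants within one bin of a window edge are rejected rather than
  truncated, to avoid silently asymmetric sums. The signed value is the
  primitive; the absolute value is derived from it, since sign analysis
  requires the raw difference.
* TF activity scores: sum of the two bins flanking the TSS junction
  (windows have an even bin count so the TSS sits exactly at a junction);
  motif "insertion" is substitution in place, the standard convention for
  fixed-length models, and the insertion offset measures the gap between
  the motif's TSS-proximal end and the TSS. The default offset grid is
  10, 100 and 1,000 bp: a fourth, 10,000 bp offset is meaningful only for
  full-scale (>= 131 kb) windows and falls outside the desk-scale window,
  where `insert_motif` rejects it.
* Personal genomes: the mean of the ten bins around the TSS junction per
  haplotype, then the mean of the two haplotypes.

The definitional implementations (two full predictions, subtract) are kept
alongside batch implementations that share window scans across variants,
haplotypes and replicates; the test suite asserts their agreement. Only the
definitional SAD path guarantees bit-exact antisymmetry under allele swap,
which is why `sad_score` never takes the incremental shortcut.

# The ground-truth model

The ground truth maps a window to per-bin, per-track rates:

rate(b, t) = softplus( s0_t + sum over PWM matches s of
  W[motif(s), t] * min(score(s), saturation) * exp(-d(s, b) / decay) )

* Matches are scored by log-odds against uniform background and accepted
  when they exceed a per-motif threshold of 60% of the maximum achievable
  log-odds (the usual fractional `min.score` convention of PWM scanning);
  the contribution is the *centered* score (log-odds minus threshold). A
  raw threshold at zero admits thousands of weak chance matches per window
  and makes the baseline rate meaningless; centering keeps "only
  positive-scoring sites contribute" while matches stay rare (about two
  chance matches per 4 kb window with the default library).
* `site_saturation` (default 2, in centered log-odds units) caps each
  site's contribution. This is occupancy saturation: a strong site is
  effectively always bound, so a single-base weakening of a strong site
  changes the prediction only slightly. Without it, every designed motif
  mutation removes a large, agreed-upon score chunk and replicates could
  never disagree on mutation effects.
* Distance decay is exponential with scale 384 bp, and a site contributes
  nothing to bins whose center is farther than half the receptive field
  (2,048 bp total), making every bin's value a local function of sequence —
  edits outside a bin's receptive field cannot change it (this is asserted
  exactly in the tests).
* N bases contribute nothing: any N inside a match window keeps the site
  below threshold.
* The softplus link keeps rates strictly positive; its inverse fixes the
  intercept so that motif-free sequence predicts exactly `baseline_rate`
  (default 0.5 counts per bin).

Desk-scale geometry: 4,096 bp windows, 32 x 128 bp bins, TSS at the central
bin junction. This preserves the geometry the analyses rely on (even bin
count, central-two-bin TSS readout, ten central bins for expression) at a
size where the full pipeline runs in about a minute. All sizes are
parameters.

The default motif library holds eight sharp PWMs (10-12 bp, consensus
probability drawn in 0.88-0.97 per position, two degenerate positions per
motif). Sharp, jittered columns serve two purposes: chance matches are rare
at the 60% threshold while PWM-sampled realizations usually stay above it,
and single-base log-odds drops vary continuously across motifs, so designed
mutations produce a continuum of effect sizes rather than a few discrete
values. Effects are one strong activator (planted upstream of every TSS so
windows carry promoter-like signal) plus activators and repressors with
magnitudes spread over roughly 0.8-6, scaled per track by uniform
multipliers — four tracks by default, one per assay class.

# The replicate ensemble

Member i of the ensemble is the ground truth perturbed by four
independently seeded components, all proportional to a single scale sigma
and all exactly zero at sigma = 0:

1. Weight noise `w * exp(sigma * z1) + sigma * weight_add_amp * z2`.
   Pure multiplicative noise is sign-preserving, and because the link is
   monotone, a sign-preserving perturbation can never flip the sign of a
   prediction *difference*; the additive component is what lets members
   disagree about the direction of weak effects.
2. A gated weak-site response: member-specific per-motif, per-track
   coefficients applied with gate `(1 - score/saturation)` to
   below-saturation sites. Replicates agree on strong (saturated) sites and
   hold idiosyncratic opinions about weak or degraded matches — mutated
   motifs, partial matches, borderline chance sites. This produces the
   structural asymmetry in which mutation activity scores are less
   consistent than canonical ones.
3. A sparse idiosyncratic k-mer response: 12 active 4-mers per track per
   member, centered weights, additive before the link and *not* decayed
   with distance inside the receptive field. Because true signal decays
   with distance while this response does not, the signal-to-noise ratio of
   an insertion or variant effect falls with distance to the TSS — the
   source of the distal inconsistency gradient.
4. A low-amplitude smooth sinusoidal positional bias per track.

The default sigma = 0.25 was chosen by sweeping the generator itself: it is
the largest scale at which the median replicate-pair Pearson correlation on
reference windows stays near 0.9 — the regime in which reference
predictions look reliable — while variant-level sign disagreement remains
substantial. Sigma has no externally prescribed value; it is the dial that
interpolates between a degenerate ensemble (sigma = 0, all analyses
perfectly consistent, which the tests assert exactly) and an ensemble that
agrees on little.

# Synthetic datasets

* `simulate_regulatory_genome`: i.i.d. background at a configurable GC
  fraction (default 0.41), Poisson-planted motif instances (default 0.5
  per kb, sequences sampled from the PWM, random strand), plus the TSS
  activator. The planted-site table is returned and is the source of
  "causal" variant positions.
* `simulate_track_counts`: Poisson counts at the ground-truth rates — the
  experimental readout. Peak calling treats these exactly like predicted
  tracks.
* `simulate_eqtls`: positives are substitutions inside planted sites with
  the true sign recomputed from the ground-truth SAD (zero-effect
  candidates are redrawn, since an eQTL has a direction by definition);
  negatives are background substitutions with unknown truth. TSS distances
  are recorded for the receptive-field filter.
* `simulate_population`: haplotype alleles drawn independently at the
  stated frequencies (no linkage disequilibrium — the analyses do not model
  LD), measured expression = standardized ground-truth prediction scaled to
  variance h2 plus Gaussian noise of variance 1 - h2 (default h2 = 0.3, a
  realistic cis-heritability for a well-powered gene).

What the generator does **not** emulate: trained-network inductive biases,
assay-specific noise structure beyond Poisson, linkage disequilibrium,
multi-gene loci, alignment or mapping artifacts, and the sheer scale of
thousands of tracks. Tests passing on this generator show that the analysis
machinery is correct and that the qualitative phenomena (distance gradients,
effect-size gradients, mutation-vs-canonical asymmetry) follow from the
stated mechanisms — not that any particular quantitative level will be
observed on real models.

# Peak calling

Peaks are called per track against a Poisson null whose rate is the mean
over all bins; the per-bin p-value is the upper tail at the bin's value
rounded half-up (the Poisson pmf being integer-valued; a continuous-tail
variant was considered and rejected as a needless complication), and
Benjamini-Hochberg step-up at FDR 0.01 is applied per track across bins —
not across tracks, since tracks are calibrated separately. An all-zero
track has lambda = 0 and calls nothing. BH on discrete p-values is
conservative, which the null-track test quantifies with a doubled bound
(called fraction at most 0.02 at nominal 0.01).

TSS bins are the two bins flanking the central junction, matching the
central-two-bin readout convention.

# Drivers

The driver definition — the small set of variants explaining most of the
cross-individual variance of a gene's predicted expression — is
reconstructed rather than copied from a published procedure: variants are
ranked by the squared Pearson correlation between dosage and prediction,
then accepted greedily while the regression R-squared grows by at least
`delta` (default 0.05), up to 6 per gene. Both knobs are exposed because
the criterion admits variants. Genes with constant predictions yield no
drivers and are flagged. Gene uncertainty is the variance of the M
cross-individual Spearman correlations, with an eligibility gate of mean
|rho| >= 0.1; ineligible or undefined genes are never classified HIGH or
LOW. The rank-based ensemble predictor averages an individual's
within-replicate prediction rank across replicates.

# Numerical and interface choices

* Internal coordinates are 0-based half-open; VCF positions convert at the
  boundary; BED stays native. One internal convention prevents off-by-one
  drift, and the loader asserts that every retained variant's reference
  allele matches the window sequence at its offset.
* All randomness flows through explicit integer seeds; simulators restore
  the caller's RNG state. Identical configurations produce byte-identical
  output tables.
* Ten-fold downsampling of reference windows is deterministic: sort by
  coordinate, keep every tenth. Reproducibility was preferred over random
  subsampling.
* Rank-test p-values are exact when both groups have at most eight
  untied observations and use the tie-corrected normal approximation
  otherwise; families of such tests are BH-adjusted.
* PWM input uses the MEME probability-matrix subset (plus a 4-column TSV
  converter); no pseudocount is added by default, and zero probabilities
  are preserved (the log-odds floor handles them during scanning).
  Rows must sum to 1 within 10% before renormalization — anything else is
  almost certainly a counts matrix and is rejected.
* The pipeline stages (`simulate`, `peaks`, `consistency`, `motif`,
  `eqtl`, `personal`, `report`) are driven by `run_pipeline` from R; a
  configuration list or YAML file with argument overrides replaces a shell
  entry point, since the package's users drive analyses from R.

# Known limitations

* The mutation-vs-canonical and distance-gradient findings are directional
  properties of the generator's mechanism; their magnitudes depend on
  sigma and the amplitude parameters and should not be read as calibrated
  estimates for any trained model.
* Attribution maps for the synthetic predictors are in-silico substitution
  scores (mean absolute change of the central-ten-bin output over the three
  alternative bases), not gradients; for a linear-additive ground truth
  these coincide in spirit but not in value with gradient saliency.
* The exact-zero prediction differences that drive the strict-inequality
  tie rule are an artifact of the saturating synthetic model; trained
  networks produce ties with probability zero.
* Window-level analyses assume the TSS at the central bin junction; other
  anchorings require re-deriving the central-bin index conventions.
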