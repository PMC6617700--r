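---
title: "Codon employment analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon employment analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Most amino acids are encoded by several synonymous codons that differ at the
third ("wobble") position. A transcript can therefore be GC3-rich (third
bases mostly G/C) or AU3-rich (mostly A/U) without any change to the encoded
protein. This package quantifies how the *employment* of synonymous codons —
which codons sit in the abundant transcripts of a sample — differs between
transcriptomes, and builds on that a disease-versus-control shift statistic
and a per-patient diagnostic score.

## Composition statistics

Sequences are split into non-overlapping frame-0 triplets. For every gene we
keep the full 64-codon count vector and derive:

* the **61-codon percentage profile** (each sense codon's share of the
  gene's sense codons; stop codons have no entry, so the 61 entries close to
  100%);
* **GC3% and AU3%**: the share of codons whose third base is G/C
  (respectively A/T), with stop codons excluded from the numerators but
  *included* in the denominator. This mixed convention is deliberate: it is
  the unique convention under which a 117-codon transcript with 85 G/C-ending
  and 31 A/T-ending sense codons prints as 72.65% / 26.50%, the worked
  reference pair bundled as `inst/extdata/vamp2_like_synthetic.fa` (a
  synthetic stand-in sequence constructed to have exactly that composition).
  A sense-only denominator is exposed via `gc3_denominator = "sense"`; the
  difference is below one percentage point for typical CDS lengths.
* ATG and TGG end in G and count toward GC3; single-codon families are
  excluded only where variance matters (see below).

```{r}
library(codonshift)
cds <- read_cds("genome.fa")
profile <- composition_profile(count_codons(cds))
gc3_distribution_summary(profile)
```

The spread of the per-gene GC3 distribution is summarized as the **full
width at half maximum** of its histogram. Defaults: bin width 1 percentage
point, a centered moving average of window 3 before the half-maximum search,
global maximum as the reference peak, and linear interpolation of the two
crossings. Distributions with fewer than two occupied bins report `NA`
rather than a fabricated width.

**Codon–codon correlations** (`codon_correlation_matrix()`) use
within-family synonymous fractions (e.g. GCC as a share of all alanine
codons) rather than raw percentages, so amino-acid composition cancels; the
59 codons of degenerate families are included by default because Met/Trp
fractions are identically 1. The split-half mode recomputes fractions on the
first and second half of each coding sequence (stop stripped, the extra
codon of odd counts goes to the first half) and correlates across halves — a
control showing the coupling is a gene-level property, not a local repeat
artifact.

## The codon employment coefficient (CEC)

For one sample, the CEC of a codon is the Pearson correlation, across genes,
between the codon's percentage in each transcript and the transcript's
abundance. Abundances are `log2(1 + x)`-transformed by default (`"raw"` is
available): correlation on the raw scale is dominated by the few most
abundant transcripts, which is rarely what a transcriptome-wide statistic
should measure. Cohorts are aggregated by computing the CEC per sample and
averaging (mean ± SEM per codon), not by correlating mean abundances — the
per-sample route is what makes the SEM and the patient-level diagnostics
meaningful.

The **employment shift** between cohorts is the per-codon relative change
`100 · (CEC_disease − CEC_control) / |CEC_control|`, averaged separately
over AU3 and GC3 codons. The absolute-value denominator keeps the sign
readable as "toward AU3" / "toward GC3" regardless of the control
coefficient's sign. Codons with `|CEC_control| < 0.01` (the `epsilon`
default) are excluded from the group means and listed: a relative change
against a near-zero base is noise.

**CorrCEC** correlates each transcript's 61-entry composition with the
control and the disease cohort CEC vectors; the reported score is
`r_disease − r_control`. The two correlations and a single signed value with
"negative = control-like" semantics admit two natural scalarizations; the
difference of correlations is the default and the correlation with the
difference vector is available (`method = "difference_vector"`). Swapping
the cohorts negates the score exactly.

## Ranked enrichment and the GP1/GP2 groups

Genes are ranked by `log2(gc3 / mean gc3)`; genes with zero GC3 are excluded
(log undefined) and ties break lexicographically so ranking is
deterministic. Enrichment uses the standard weighted running-sum statistic
(hits weighted by `|score|^1`, uniform miss decrement), a gene-label
permutation null (1000 permutations by default; exhaustive enumeration when
the number of placements is small, which makes the small-case p-values
exact), a signed two-sided p-value, and Benjamini–Hochberg FDR across sets
via `stats::p.adjust`. The enrichment engine itself is a documented standard
stand-in — the scientific content lies in the ranking input and in the
robustness protocol, not in the engine.

GP1 (AU3-rich, proliferation-like) and GP2 (GC3-rich, differentiation-like)
are derived as the unions of leading-edge genes of significantly negative
and positive sets at FDR < 0.01; genes claimed by both sides are dropped
from both. Full-membership derivation is available behind a flag.

The **perturbation robustness** protocol jitters every gene's GC3 by
additive uniform noise of ± delta percentage points (clipped to (0, 100]),
re-ranks, re-runs the enrichment five times per delta, and counts the sets
significant in at least five replicates. Additive percentage-point jitter is
the plain reading of "changing the percentage by X%"; a multiplicative mode
exists behind a flag.

## Causal versus effect scenarios

Two generative models of a disease cohort are contrasted:

* **causal**: every gene's abundance is multiplied by
  `2^(beta · (AU3 − mean AU3) / 100)` — the shift itself drives expression,
  graded by composition within any subset;
* **effect**: GP1 genes are multiplied by a uniform `fold` (default 2) —
  the apparent shift is a by-product of a gene-group program.

Because the two models share only the all-genes shift, `beta` is calibrated
by root search so both produce the same all-genes AU3 shift
(`calibrate_causal_beta()`); the contrast then rests entirely on the
subset-restricted statistics, which is the only fair comparison. The
discriminating readout: under the effect model the GP1-only shift stays
inside a null band (calibrated from no-effect runs), under the causal model
every subset shifts. `scenario_discrimination()` packages the whole seeded
battery.

## Diagnostics

The per-patient score is the correlation of the patient's (GP1-restricted)
CEC vector with a trained reference direction — the unit-normalized
disease-minus-control mean CEC difference of the training samples. This
unifies the "CEC shift cutoff" and "CorrCEC cutoff" readings of the
training procedure: it is a CorrCEC-style correlation score computed against
the trained shift direction. A per-patient mean-CorrCEC alternative would
require recomputing per-gene scores per patient and offers no advantage on
the synthetic conditions.

Cutoffs default to the midpoint of the training class score means;
Youden-optimal cutoffs are available. Splits are stratified 80/20, repeated
(1000 by default; the validation suite uses 200 to keep runtimes in
seconds), with all split seeds derived from one master seed. Test samples
never enter the reference direction or the cutoff — the suite asserts this
structurally by poisoning held-out columns.

The label-shuffling null re-permutes labels at every repetition
(`shuffle_labels = TRUE`). With one fixed shuffled labeling instead, the
held-out evaluation is systematically *below* chance: conditioned on a
finite patient pool, the high-scoring members of a pseudo-class are
preferentially drawn into training, which pushes the held-out members of the
same pseudo-class below the trained cutoff. Re-shuffling per repetition
removes this finite-pool artifact and yields the expected 0.5/0.5.

Noise robustness multiplies every abundance value independently by a factor
drawn log-uniformly from `[1/f, f]` ("changed up or down by a fold factor")
and reruns the cross-validation.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which the pipeline is validated.

* **Genome** (`genome_spec()`): 2000 genes; per-gene GC3 targets from a
  two-component normal mixture, means 35 and 70 percentage points, SD 6,
  weights 0.4/0.6 — echoing the bimodal human GC3 distribution with peaks
  near 30–40% and 70%. Codon counts are log-normal around 350 (SD 0.35 on
  the log scale, floored at 30), amino acids follow bundled human-like
  proteome frequencies, each codon's third-base class is Bernoulli in the
  gene's target (with the class probability compensated for the forced
  G-ending Met/Trp codons so realized sense-GC3 matches the target), ATG
  starts and a uniform stop ends every sequence. 15% of genes are planted as
  GP1 — drawn from the *outer half* of the low-GC3 component, because the
  groups emulate genes significantly de-/enriched in GC3, not average
  members of a component — and 15% as GP2 from the high tail.
* **Gene sets** (`generate_gene_sets()`): the planted groups are partitioned
  across five sets each (20% random contamination per set) plus ten random
  background sets, so group recovery through enrichment has a defined
  ground truth.
* **Cohort** (`cohort_spec()`): 25 control + 25 disease samples. Per-gene
  baseline log2 abundance N(6, 2); control coupling of +8 log2-fold per 100
  GC3 percentage points (GC3-rich transcripts are favored in the control
  state); the disease adds the causal AU3 term (`beta`, presets: strong = 8,
  weak = 1.5 — bracketing a near-perfect and a ~85% diagnostic regime);
  per-gene per-sample log2 noise SD 0.5; and a per-patient *tissue
  composition factor* (log2 SD 1) applied coherently to the GP2 genes of
  every sample. This last term emulates the biopsy-to-biopsy
  cellular-composition variability of real cohorts (differentiated-tissue
  programs vary with, e.g., tumor purity). It is what makes all-genes
  patient scoring noticeably worse than GP1-restricted scoring, as observed
  on real cohorts: without some disease-independent structured variation
  outside GP1, a homogeneous causal model would make the all-genes score
  strictly more informative (wider AU3 range, more genes) and the
  GP1-restriction advantage could not exist. Set `tissue_factor_sd = 0` for
  a homogeneous cohort.

What the generator does **not** emulate: read-level counting noise,
library-size and GC biases, gene–gene co-expression beyond the planted
programs, multiple tissues or disease stages, and real GO structure. Passing
the validation suite therefore demonstrates the internal correctness and the
qualitative logic of the analysis chain on data with known truth — not
performance on any real cohort.

## Numerical choices and degenerate inputs

* Fixed alphabetical order of the 61 sense codons everywhere (vectors,
  matrices, file columns).
* Undefined statistics are `NA` and are reported, never silently zero:
  zero-variance codons in correlations and CECs, families with zero counts
  in RSCU, near-zero control CECs in the shift, unscorable patients.
* Pearson correlations are delegated to `stats::cor` with pairwise-complete
  observations; the test suite pins them against a naive two-pass oracle at
  1e-10.
* All randomness flows from explicit integer seeds; derived seeds are kept
  below 2^31. Identical seeds reproduce byte-identical artifacts, which the
  pipeline manifest (MD5 per output) makes checkable.
* Problem sizes in the validation suite: 2000-gene genomes, 25+25 cohorts,
  200 cross-validation repetitions, 100-seed scenario batteries, 1000
  enrichment permutations — chosen so the whole suite completes in a few
  minutes on one core while keeping every qualitative regime stable across
  seeds.

## Known limitations

* The enrichment engine is a generic pre-ranked running-sum implementation,
  not a reimplementation of any specific web toolkit; absolute NES/FDR
  values from other tools will differ even on identical inputs.
* The weak-effect diagnostic regime (~85%) has, by design, seed-to-seed
  variability of several percentage points.
* `read_cds()` accepts any organism's CDS FASTA, but all bundled reference
  behavior is validated on synthetic data plus the single worked
  composition anchor.
* CorrCEC's scalarization is one of two defensible readings (both
  implemented); downstream users comparing against other implementations
  should check which convention those use.
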