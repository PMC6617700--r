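# codonshift

Synonymous codons differ at the third (wobble) position without changing the
protein: a transcript can be written mostly with G/C-ending (GC3) or mostly
with A/U-ending (AU3) codons. `codonshift` is an R package for asking which
of those codons a transcriptome actually *employs* — whether the abundant
transcripts of a sample are the GC3-rich or the AU3-rich ones — and for
turning the answer into a disease-versus-control statistic and a
per-patient diagnostic. It is aimed at computational biologists analyzing
bulk expression cohorts (microarray or RNA-seq summaries) together with
coding sequences.

## The statistics at the core

For codon $c$ and one sample, the **codon employment coefficient** is the
Pearson correlation across genes

$$\mathrm{CEC}_c \;=\; \mathrm{cor}\big(p_{gc},\; \log_2(1 + a_g)\big),$$

where $p_{gc}$ is codon $c$'s percentage in gene $g$'s composition and
$a_g$ the gene's abundance. A cohort is summarized by the per-sample CECs
(mean ± SEM per codon). The **employment shift** between cohorts is the
relative CEC change $100\,(\mathrm{CEC}^{dis}_c -
\mathrm{CEC}^{ctl}_c)/|\mathrm{CEC}^{ctl}_c|$, averaged over the AU3 and the
GC3 codon groups. **CorrCEC** scores one transcript by correlating its
61-codon composition with the cohort CEC vectors,
$r_{dis} - r_{ctl}$: positive means the transcript's composition matches
the disease codon employment. Around these sit the supporting machinery:
GC3/AU3 composition profiles and RSCU, the per-gene GC3 distribution and
its FWHM, codon–codon correlation matrices (with a split-half control), a
GC3-ranked pre-ranked enrichment with permutation null and BH FDR that
derives the AU3-rich (GP1) and GC3-rich (GP2) gene groups, causal-vs-effect
scenario modelling, and a resampled sensitivity/specificity classifier. A
seeded synthetic generator produces genomes and cohorts with known ground
truth for every one of these steps.

## Worked example

The `analysis/` directory holds the workflow as numbered drivers
(`Rscript analysis/01_simulate_genome.R 1`, then `02` … `06`; the argument
is the master seed). Step 4, on the default simulated cohort, prints:

```
Control cohort (n = 25): mean CEC +0.36 over GC3 codons, -0.40 over AU3 codons
(GC3 codons are employed in abundant transcripts in the control state).
Disease cohort shifts codon employment: AU3 +96.0%, GC3 -96.0% (in % of control CECs)
-- the disease state favors AU3-ending codons.
CorrCEC: planted GP1 genes score +0.150 on average (favored by the disease employment),
planted GP2 genes -0.169 (favored by the control employment).
```

Reading: in the control state GC3 codons correlate positively with
abundance (mean CEC +0.36) and AU3 codons negatively (−0.40); the disease
cohort, generated under a causal composition-dependent shift, moves the AU3
coefficients up by ~96% of their control values and the GC3 coefficients
down symmetrically; transcript-level CorrCEC then flags the planted
AU3-rich proliferation-like genes (GP1) as favored. The equivalent calls in
code:

```r
library(codonshift)
cds      <- read_cds("results/data/genome.fa")
profile  <- composition_profile(count_codons(cds))
abund    <- read_abundance("results/data/abundance.tsv")
labels   <- read_labels("results/data/labels.tsv")
ctrl     <- cohort_cec(profile, abund, labels, "control")
dis      <- cohort_cec(profile, abund, labels, "disease")
employment_shift(ctrl, dis)
#> employment_shift: AU3 +96.0%, GC3 -96.0% (0 codons excluded)
```

`run_pipeline(pipeline_config(out_dir = "results/run"))` chains the stages
end to end and writes a manifest with per-artifact checksums; identical
configurations reproduce byte-identical outputs.

The methods vignette
(`vignettes/codon-employment-methods.Rmd`) documents the models, the
parameter conventions (including the stop-codon counting convention behind
the worked 72.65%/26.50% composition anchor) and the design choices.

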