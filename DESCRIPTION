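Package: codonshift
Title: Wobble-Position Codon Composition and Codon Employment Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for synonymous codon composition of coding sequences
    and their relation to transcript abundance. Computes per-transcript
    third-position (GC3/AU3) composition, relative synonymous codon usage,
    codon-codon correlation structure, the codon employment coefficient (CEC,
    the per-codon Pearson correlation between codon percentages and transcript
    abundances), disease-versus-control codon employment shifts, per-transcript
    CorrCEC scores, a GC3-ranked pre-ranked gene-set enrichment with a
    permutation null and Benjamini-Hochberg FDR, causal-versus-effect scenario
    modelling, and a resampled sensitivity/specificity diagnostic classifier.
    Includes a synthetic cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
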