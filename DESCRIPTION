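Package: coldhardy
Title: Cold-Hardiness Genomics and Physiology of Walnut Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for analysing cold hardiness in Juglans
    (walnut) species and their interspecific hybrids. Implements per-gene
    population-genetic selection-signature statistics (segregating sites,
    nucleotide diversity, Watterson's theta, Tajima's D, observed
    heterozygosity, multi-population Weir-Cockerham FST) over pooled
    diploid genotype panels; a candidate-vs-background selective-sweep
    screen keyed on cold-response transcription-factor annotations
    (DREB/CBF/ICE1/ZAT families); the electrolyte-leakage frost damage
    index and ordinal winterkill rating with ANOVA and protected Fisher's
    LSD summaries; delta-delta-Ct relative qPCR expression; and
    alignment-free k-mer distance phylogenies with neighbor joining.
    Ships a coalescent-based synthetic-data generator producing VCF/BED
    genotype panels, conductivity and Ct tables, and sequence sets evolved
    along known trees, so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
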