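Package: cladeqpcr
Title: Clade-Resolved qRT-PCR Analysis of Picocyanobacterial Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for clade-specific quantitative RT-PCR analysis of
    photosynthetic gene expression in marine picocyanobacteria. Calls
    crossing points (Cp) from raw amplification curves by the
    second-derivative-maximum method with replicate quality control and
    standard-curve efficiency estimation; analyses melt curves (-dF/dT)
    to call melting temperatures, resolve single versus double peaks and
    classify amplicons as Prochlorococcus- or Synechococcus-like by Tm
    window; computes delta-Cp relative expression, fold changes, the
    rbcL/psbA ratio and high-light/low-light clade fractions; and runs
    the accompanying statistical contrasts (depth ANOVA with Tukey HSD
    letters, paired treatment/control tests, a three-way factorial GLM
    on fold changes, paired Wilcoxon tests). A synthetic qPCR signal
    generator with known ground truth drives simulation-based testing of
    every stage.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    nortest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
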