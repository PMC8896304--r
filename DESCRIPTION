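Package: tumorASE
Title: Allele-Specific Expression and Somatic Copy-Number Inference for
    Tumor/Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genes with allele-specific expression (ASE) in tumor
    cohorts and attributes it to somatic copy-number alterations (SCNAs) or
    nonsense-mediated decay. Models allele-specific read counts at
    heterozygous sites with a beta-binomial likelihood that accounts for
    overdispersion, genotyping errors (from Phred-scaled genotype
    qualities) and sequencing errors, marginalizing over unknown haplotype
    phase with a linear-time dynamic program. DNA allelic imbalance over
    exon bins is contrasted between tumor and matched normal, segmented
    with circular binary segmentation into SCNA scores, and integrated
    with per-gene RNA imbalance, somatic mutation consequences, promoter
    methylation and expression through permutation and correlation tests.
    Includes a synthetic cohort generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
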