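Package: hapXscan
Title: X Chromosome Versus Autosome Differentiation, Demography and Selection Scans
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing X-linked and autosomal population differentiation
    from phased SNP haplotypes. Implements per-SNP delta and Hudson Fst scans with
    high-delta SNP and region calling, ancestral-allele assignment from an outgroup,
    genic/derived enrichment summaries, the island-model TA/EX transformation and
    its (N_f/N, m_f/m) grid scan with Wilcoxon surfaces for inferring female-biased
    demography, haplotypic and diploid AMOVA with locus bootstrap confidence
    intervals, EHH/iHS/XP-EHH selection scans with fixed-width window aggregation,
    empirical percentile tests and haplotype-heterozygosity ratio tracks, and a
    sex-structured island-model simulator with plantable selective sweeps for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
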