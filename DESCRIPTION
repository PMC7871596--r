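Package: aascan
Title: Ancestral Allele Inference and Retention Scans in Bovinae Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cattle ancestral alleles from three Bovinae outgroup
    lineages (yak; American plus European bison; gayal-gaur-banteng) by a
    fixed-allele consensus rule applied to per-group allele frequency
    spectra from multi-sample VCF files. Scores retention of the ancestral
    allele in taurine and zebu cattle with a per-site frequency-difference
    statistic, counts retained sites in non-overlapping 10 kb windows,
    selects extreme windows (chromosome-wise top 0.1 percent and zero-count
    null windows), classifies null windows by cause, and annotates selected
    windows against gene models. Includes a deterministic synthetic-cohort
    generator with planted conserved and mutated windows for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    vcfR,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
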