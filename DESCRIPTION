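Package: chcloh
Title: Cohort Heterozygosity Comparison for Inferring Loss of
    Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers candidate regions of loss of heterozygosity (LOH)
    from SNP-array genotype calls of unmatched case and control cohorts
    by comparing per-SNP cohort heterozygosity frequencies.  Suggestive
    heterozygosity deficits are thresholded by a power analysis keyed to
    the case cohort size, and contiguous runs of suggestive SNPs are
    reported as inferred-LOH regions ranked by an enrichment score.  The
    package also provides a matched tumor/normal per-SNP LOH caller for
    validation, region evaluation metrics (size, distance to validated
    LOH markers, interval-overlap counting), and a Hardy-Weinberg cohort
    simulator with planted copy-neutral LOH segments.
License: MIT + file LICENSE
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
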