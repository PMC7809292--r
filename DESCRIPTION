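Package: ylineage
Title: Y-Chromosome Lineage Inference from Low-Coverage Ancient DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tree-guided Y-chromosome haplogroup placement of low-coverage
    samples from per-site allele observations, discovery of novel haplogroups
    from the sharing patterns of derived SNPs under a perfect-phylogeny model,
    anchored SNP-count coalescence dating inside a callable-region mask,
    read-ratio (Ry) chromosomal sex assignment, and uniparental-marker
    kinship exclusion. Includes a full generative model (dated genealogy,
    Poisson mutations, ancient-DNA deamination damage, heavy missingness) so
    every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
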