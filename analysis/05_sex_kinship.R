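#!/usr/bin/env Rscript
# Chromosomal sex from X/Y coverage ratios and rule-based kinship exclusion
# from uniparental haplogroups, on the nine royal-basilica samples.  The Ry
# statistic nY/(nX+nY) with thresholds 0.075/0.016 must assign two females
# (HUAA, HU109) and seven males; the kinship rules must leave exactly one
# male pair (Béla III and HU52) sharing a paternal lineage while their
# differing mtDNA excludes son/brother relationships.

suppressPackageStartupMessages(library(ylineage))
dir.create("results", showWarnings = FALSE)

cov <- royal_xy_coverage()
sx <- cbind(sample = cov$sample, assign_sex(cov$nX, cov$nY))
utils::write.table(sx, "results/royal_sex_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("sex calls: ", sum(sx$classification == "XY"), " XY, ",
        sum(sx$classification == "XX"), " XX (",
        paste(sx$sample[sx$classification == "XX"], collapse = ", "), ")")

kin <- cohort_kinship_report(royal_profiles())
utils::write.table(kin, "results/royal_kinship.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
shared <- kin[kin$shared_paternal, ]
message("pairs sharing a paternal lineage: ",
        paste(shared$sample_a, shared$sample_b, sep = "-", collapse = "; "))
message("pairs sharing a maternal lineage: ", sum(kin$shared_maternal))

bela_hu52 <- kin[kin$sample_a == "HU3B" & kin$sample_b == "HU52", ]
message("HU3B vs HU52: father_son ", bela_hu52$father_son,
        ", full_sibling ", bela_hu52$full_sibling,
        " (differing mtDNA excludes son or brother; the shared Y lineage ",
        "leaves father, grandfather or a more distant paternal ancestor)")
message("tables written to results/royal_sex_calls.tsv, results/royal_kinship.tsv")
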