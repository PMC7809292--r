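#!/usr/bin/env Rscript
# Simulate an ancient-DNA Y-chromosome cohort under study-like conditions:
# a dated male genealogy, Poisson mutations inside a callable mask, per-site
# observations with sequencing error / deamination damage / heavy
# missingness spanning sub-1x to high coverage, X/Y read counts for both
# sexes — and a reference haplotree from which the two youngest SNP-defined
# clades have been withheld, setting up the novel-haplogroup discovery
# scenario.  All pipeline inputs are written as plain text under
# results/simulated/.

suppressPackageStartupMessages(library(ylineage))

out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# coverage spread mirroring the sequenced cohort (0.17x .. 7x)
depths <- c(7.0, 9.6, 6.5, 4.3, 1.0, 1.2, 1.8, 3.8, 0.17, 30, 5, 2.5)
cfg <- sim_config(n_tips = 12, root_age = 5000, snp_interval_mu = 120,
                  mean_depth = stats::setNames(depths, paste0("S", 1:12)),
                  seq_error_rate = 0.001, damage_rate = 0.1,
                  missing_rate = 0.05, n_females = 2, seed = 20240901)

# find the two youngest SNP-defined internal nodes and hide them
probe <- simulate_cohort(cfg)
g <- probe$genealogy
defined <- g[g$age > 0 & !is.na(g$parent) & g$name %in% probe$variants$node, ]
cfg$hidden_clades <- defined$name[order(defined$age)][1:2]
co <- simulate_cohort(cfg)

message("genealogy: ", sum(co$genealogy$age > 0), " internal nodes, ",
        sum(co$genealogy$age == 0), " tips; ", nrow(co$variants),
        " simulated SNPs")
message("withheld clades: ", paste(cfg$hidden_clades, collapse = ", "))

writeLines(write_haplotree(co$reference_tree),
           file.path(out_dir, "reference_tree.tsv"))
write_bed_mask(cfg$mask, file.path(out_dir, "mask.bed"))
for (s in names(co$observations))
  write_readcount_tsv(co$observations[[s]],
                      file.path(out_dir, paste0(s, ".readcount.tsv")))

prof <- co$profiles
idx <- match(prof$sample, co$sex_counts$sample)
prof <- data.frame(sample = prof$sample, nX = co$sex_counts$nX[idx],
                   nY = co$sex_counts$nY[idx],
                   y_haplogroup = ifelse(is.na(prof$y_haplogroup), "-",
                                         prof$y_haplogroup),
                   mt_haplogroup = prof$mt_haplogroup)
utils::write.table(prof, file.path(out_dir, "profiles.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth <- data.frame(sample = names(co$true_terminal),
                    true_terminal = unname(co$true_terminal))
utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("inputs written to ", out_dir)
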