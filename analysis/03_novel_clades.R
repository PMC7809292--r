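#!/usr/bin/env Rscript
# Novel-haplogroup discovery from the sharing patterns of derived SNPs that
# are absent from the reference tree.  Two analyses:
#   (a) the published sharing pattern — 17 SNPs carried by all 51 R-SUR51
#       samples, 6 more by the 48 Bashkirs, 9 by the two royal males plus
#       the Serbian individual (R-ARP), 9 private to the Serbian (R-UVD) —
#       must come back as four nested clades;
#   (b) the simulated cohort of 01/02, where the pipeline must rediscover
#       the withheld clades from the observations alone.

suppressPackageStartupMessages(library(ylineage))
dir.create("results", showWarnings = FALSE)

## (a) the published pattern --------------------------------------------------
samples <- c("HU3B", "HU52", "SRB1", sprintf("B%02d", 1:48))
m <- matrix("0", nrow = 51, ncol = 41, dimnames = list(samples, NULL))
m[, 1:17] <- "1"; m[4:51, 18:23] <- "1"; m[1:3, 24:32] <- "1"
m["SRB1", 33:41] <- "1"
pos <- 500000L + 1000L * seq_len(ncol(m))
vars <- data.frame(chrom = "chrY", pos = pos, anc = "A", der = "G",
                   names = paste0("V", seq_len(ncol(m))))
colnames(m) <- paste("chrY", pos, "G", sep = ":")
genotypes <- structure(m, variants = vars,
                       n_conflict = stats::setNames(integer(51), samples))

backbone <- parse_haplotree(c("R-Y2632\t-\tY2632:1000:A:G",
                              "R-Y2633\tR-Y2632\tY2633:2000:G:A"))
nv <- collect_novel_variants(genotypes, backbone)
pt <- partition_clades(nv)
tab <- partition_report(pt)
message("royal sharing pattern: ", nrow(tab), " clades, variant counts ",
        paste(tab$n_variants, collapse = "/"), ", member counts ",
        paste(tab$n_members, collapse = "/"))
named <- pt
for (k in seq_along(named$clades))
  named$clades[[k]]$name <- c("R-SUR51", "R-SUR2-SIDE", "R-ARP",
                              "R-UVD")[k]
utils::write.table(partition_report(named), "results/royal_clades.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## (b) rediscovery on the simulated cohort ------------------------------------
in_dir <- "results/simulated"
if (!dir.exists(in_dir)) stop("run analysis/01_simulate_cohort.R first")
tree <- read_haplotree(file.path(in_dir, "reference_tree.tsv"))
obs <- list()
for (f in list.files(in_dir, pattern = "\\.readcount\\.tsv$",
                     full.names = TRUE))
  obs[[sub("\\.readcount\\.tsv$", "", basename(f))]] <-
    read_observations(f, "readcount_tsv")

rep <- run_pipeline(run_config(tree = tree, observations = obs,
                               mask = file.path(in_dir, "mask.bed"),
                               policy = call_policy(damage_mode = "strict")))
utils::write.table(partition_report(rep$partition),
                   "results/simulated_clades.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(write_haplotree(rep$augmented_tree),
           "results/augmented_tree.tsv")
message("simulated cohort: ", length(rep$partition$clades),
        " clades recovered (multi-member clades correspond to withheld ",
        "haplogroups; singletons are tip-private SNP sets)")
message("tables written to results/royal_clades.tsv, ",
        "results/simulated_clades.tsv, results/augmented_tree.tsv")
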