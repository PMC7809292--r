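#!/usr/bin/env Rscript
# Place every simulated sample on the reference haplotree from its per-site
# allele observations, under the default ancient-DNA calling policy with
# the strict deamination gate.  Reads the plain-text inputs written by
# 01_simulate_cohort.R, writes results/placements.tsv, and checks the
# terminals against the generator's truth table.

suppressPackageStartupMessages(library(ylineage))

in_dir <- "results/simulated"
if (!dir.exists(in_dir)) stop("run analysis/01_simulate_cohort.R first")

tree <- read_haplotree(file.path(in_dir, "reference_tree.tsv"))
policy <- call_policy(damage_mode = "strict")
obs_files <- list.files(in_dir, pattern = "\\.readcount\\.tsv$",
                        full.names = TRUE)
placements <- list()
for (f in obs_files) {
  s <- sub("\\.readcount\\.tsv$", "", basename(f))
  obs <- read_observations(f, "readcount_tsv")
  calls <- call_sample(obs, tree$variants, policy)
  placements[[s]] <- place_sample(tree, calls)
}

rep <- placement_report(placements, tree)
utils::write.table(rep, "results/placements.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

truth <- utils::read.table(file.path(in_dir, "truth.tsv"), header = TRUE,
                           sep = "\t")
hit <- rep$terminal_name == truth$true_terminal[match(rep$sample,
                                                      truth$sample)]
message(sum(hit), "/", nrow(rep),
        " samples placed at their generating terminal ",
        "(misses are low-coverage samples stopping above it)")
message("mean fraction of path SNPs observed: ",
        round(mean(rep$fraction_path_observed), 3))
message("placements written to results/placements.tsv")
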