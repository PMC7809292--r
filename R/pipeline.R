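# End-to-end orchestration: observations -> placement -> clade discovery ->
# chronology -> sex & kinship, with per-sample failure isolation and a
# reproducible plain-text report.

#' Assemble and validate a pipeline run configuration
#'
#' Inputs may be in-memory objects or file paths (paths are loaded here, so
#' validation failures surface before any stage runs).
#'
#' @param tree a `haplo_tree` or haplotree file path
#' @param observations named list (per sample) of observation data.frames,
#'   or of file paths; `obs_format` applies to paths
#' @param obs_format `"readcount_tsv"` or `"vcf"`
#' @param mask a `region_mask` or BED path
#' @param policy a [call_policy()]
#' @param clock a [clock_config()], or `NULL` to skip dating
#' @param profiles data.frame (`sample`, `nX`, `nY`, `mt_haplogroup`) or
#'   profile-table path; `NULL` skips the sex/kinship stage
#' @param clade_names optional names for discovered clades (see
#'   [attach_clades()])
#' @param min_support passed to [partition_clades()]
#' @param seed integer recorded for provenance
#' @return validated list of class `run_config`
#' @export
run_config <- function(tree, observations, obs_format = "readcount_tsv",
                       mask = NULL, policy = call_policy(), clock = NULL,
                       profiles = NULL, clade_names = NULL,
                       min_support = 1L, seed = 1L) {
  if (is.character(tree)) tree <- read_haplotree(tree)
  stopifnot(inherits(tree, "haplo_tree"))
  if (!length(observations) || is.null(names(observations)))
    stop("observations must be a non-empty named list")
  observations <- lapply(observations, function(o)
    if (is.character(o)) read_observations(o, obs_format) else o)
  if (is.character(mask)) mask <- read_bed_mask(mask)
  if (is.character(profiles)) profiles <- read_profile_table(profiles)
  if (!is.null(clock)) stopifnot(inherits(clock, "clock_config"))
  structure(list(tree = tree, observations = observations, mask = mask,
                 policy = policy, clock = clock, profiles = profiles,
                 clade_names = clade_names,
                 min_support = as.integer(min_support),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full lineage-inference pipeline
#'
#' Stage order: allele calling over the union of reference-tree sites and
#' all observed sites, haplogroup placement per sample, novel-clade
#' discovery and attachment, SNP-count dating (when a clock is configured),
#' sex assignment and pairwise kinship exclusion (when profiles are given).
#' A sample whose calling or placement fails is reported in
#' `failed_samples` and dropped; it does not abort the cohort.
#'
#' @param config a [run_config()]
#' @return list of class `run_report`: `placements` (report data.frame),
#'   `partition`, `augmented_tree`, `dated`, `sex`, `kinship`,
#'   `failed_samples`, `provenance`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tree <- config$tree
  # interrogated sites: tree variants plus derived-looking extra sites
  site_union <- interrogation_sites(tree, config$observations)
  calls <- list(); failed <- list()
  for (s in names(config$observations)) {
    res <- tryCatch(
      call_sample(config$observations[[s]], site_union, config$policy),
      error = function(e) e)
    if (inherits(res, "error")) failed[[s]] <- conditionMessage(res)
    else calls[[s]] <- res
  }
  if (!length(calls)) stop("all samples failed calling")
  placements <- list()
  for (s in names(calls)) {
    res <- tryCatch(
      place_sample(tree, calls[[s]][!is.na(calls[[s]]$node), , drop = FALSE]),
      error = function(e) e)
    if (inherits(res, "error")) failed[[s]] <- conditionMessage(res)
    else placements[[s]] <- res
  }
  genotypes <- genotype_matrix(calls[names(placements)])
  novel <- collect_novel_variants(genotypes, tree)
  partition <- if (nrow(novel))
    partition_clades(novel, config$min_support)
  else structure(list(clades = list(),
                      dropped_variants = data.frame(key = character(),
                                                    reason = character())),
                 class = "clade_partition")
  augmented <- if (length(partition$clades))
    attach_clades(tree, partition, placements, novel,
                  names = config$clade_names, on_conflict = "skip")
  else tree
  dated <- NULL
  if (!is.null(config$clock)) {
    if (is.null(config$mask)) stop("dating requires a mask")
    counts <- branch_snp_counts(augmented, config$mask)
    dated <- date_nodes(augmented, counts, config$clock)
  }
  sex <- kinship <- NULL
  if (!is.null(config$profiles)) {
    p <- config$profiles
    sex <- cbind(sample = p$sample, assign_sex(p$nX, p$nY))
    if (is.null(p$y_haplogroup)) {
      term <- placement_report(placements, tree)
      p$y_haplogroup <- term$terminal_name[match(p$sample, term$sample)]
      p$y_haplogroup[sex$classification != "XY"] <- NA
    }
    if (nrow(p) >= 2L) kinship <- cohort_kinship_report(p)
  }
  structure(list(
    placements = placement_report(placements, tree),
    partition = partition,
    augmented_tree = augmented,
    dated = dated,
    sex = sex,
    kinship = kinship,
    failed_samples = failed,
    provenance = list(seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("ylineage")),
                      n_samples = length(config$observations))),
    class = "run_report")
}

# sites worth interrogating beyond the reference tree: any observed site
# where a non-reference base is seen (candidate novel derived allele).
interrogation_sites <- function(tree, observations) {
  v <- tree$variants
  base <- data.frame(node = v$node, chrom = v$chrom, pos = v$pos,
                     anc = v$anc, der = v$der, names = v$names)
  known <- site_key(base$chrom, base$pos)
  extra <- list()
  seen <- character(0)
  for (obs in observations) {
    # malformed tables are skipped here; they fail per-sample in calling
    if (!is.data.frame(obs) || !all(names(obs_schema()) %in% names(obs)))
      next
    for (i in seq_len(nrow(obs))) {
      k <- site_key(obs$chrom[i], obs$pos[i])
      if (k %in% known || k %in% seen) next
      cnt <- c(A = obs$count_A[i], C = obs$count_C[i], G = obs$count_G[i],
               T = obs$count_T[i])
      ref <- obs$ref[i]
      altc <- cnt[setdiff(BASES, ref)]
      if (all(altc == 0L)) next
      alt <- names(altc)[which.max(altc)]
      extra[[length(extra) + 1L]] <- data.frame(
        node = NA_character_, chrom = obs$chrom[i], pos = obs$pos[i],
        anc = ref, der = alt, names = paste0("OBS", obs$pos[i]))
      seen <- c(seen, k)
    }
  }
  out <- rbind(base, if (length(extra)) do.call(rbind, extra))
  out[order(out$chrom, out$pos), ]
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$placements), " sample(s) placed, ",
      length(x$partition$clades), " novel clade(s), ",
      length(x$failed_samples), " failed sample(s)\n", sep = "")
  invisible(x)
}

#' Write a run report as plain-text tables
#'
#' The report body is fully determined by the inputs and seed — no
#' timestamps — so a rerun under the same configuration is byte-identical.
#'
#' @param report a `run_report`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(report$placements, "placements.tsv")
  wt(partition_report(report$partition), "clades.tsv")
  writeLines(write_haplotree(report$augmented_tree),
             file.path(dir, "augmented_tree.tsv"))
  paths <- c(paths, file.path(dir, "augmented_tree.tsv"))
  if (!is.null(report$dated)) {
    wt(as.data.frame(report$dated), "node_ages.tsv")
    write_dated_newick(report$dated, file.path(dir, "dated_tree.nwk"))
    paths <- c(paths, file.path(dir, "dated_tree.nwk"))
  }
  if (!is.null(report$sex)) wt(report$sex, "sex_calls.tsv")
  if (!is.null(report$kinship)) wt(report$kinship, "kinship.tsv")
  prov <- c(paste0("seed\t", report$provenance$seed),
            paste0("package_version\t", report$provenance$package_version),
            paste0("n_samples\t", report$provenance$n_samples))
  writeLines(prov, file.path(dir, "provenance.tsv"))
  paths <- c(paths, file.path(dir, "provenance.tsv"))
  invisible(paths)
}
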