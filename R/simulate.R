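# Generative model for every pipeline input: a dated genealogy, Poisson
# mutations inside a callable mask, ancient-DNA-style per-site observations
# (sequencing error, C->T/G->A deamination damage, heavy missingness) and
# X/Y read counts for both sexes.

#' Simulation configuration
#'
#' Defaults describe a small but realistic ancient-DNA cohort: a handful of
#' male lineages coalescing a few thousand years ago, one SNP per lineage
#' per ~120 years, per-sample mean depths spanning the sub-1x to high-
#' coverage range, a 0.1% per-read error rate and a 10% per-read deamination
#' rate at damage-prone sites.  The mask defaults to a 100 kb toy region so
#' end-to-end runs take seconds; its size is a knob, not a constant.
#'
#' @param n_tips number of sampled male lineages (tips)
#' @param root_age age of the genealogy root, years before present
#' @param genealogy optional explicit dated genealogy (data.frame `name`,
#'   `parent`, `age`); when given, `n_tips`/`root_age` are ignored
#' @param snp_interval_mu mean years between SNPs on a lineage
#' @param mask a [region_mask()] for mutation placement
#' @param mean_depth per-sample mean read depth; scalar, or vector recycled
#'   over tips, or named by sample
#' @param seq_error_rate per-read probability of a wrong base
#' @param damage_rate per-read probability that a C (resp. G) is read as T
#'   (resp. A) at a C->T (G->A) variant site
#' @param missing_rate extra per-site dropout probability
#' @param hidden_clades haplogroup names withheld from the reference tree so
#'   their variants become novel to the pipeline
#' @param n_females female samples appended to the cohort (no Y lineage)
#' @param reads_per_fold sex-count reads simulated per unit of depth
#' @param female_y_rate fraction of a female's reads mismapped to Y
#' @param seed RNG seed; a fixed seed makes every generator bit-identical
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_tips = 8L, root_age = 5000, genealogy = NULL,
                       snp_interval_mu = 120,
                       mask = region_mask(data.frame(chrom = "chrY",
                                                     start = 1e6,
                                                     end = 1.1e6)),
                       mean_depth = 5, seq_error_rate = 0.001,
                       damage_rate = 0.1, missing_rate = 0.05,
                       hidden_clades = character(0), n_females = 0L,
                       reads_per_fold = 400, female_y_rate = 0.005,
                       seed = 1L) {
  stopifnot(root_age > 0, snp_interval_mu > 0,
            seq_error_rate >= 0, seq_error_rate <= 1,
            damage_rate >= 0, damage_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_tips = as.integer(n_tips), root_age = root_age,
                 genealogy = genealogy, snp_interval_mu = snp_interval_mu,
                 mask = mask, mean_depth = mean_depth,
                 seq_error_rate = seq_error_rate, damage_rate = damage_rate,
                 missing_rate = missing_rate, hidden_clades = hidden_clades,
                 n_females = as.integer(n_females),
                 reads_per_fold = reads_per_fold,
                 female_y_rate = female_y_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a dated genealogy
#'
#' A binary-splitting tree grown forward in time: split times are uniform
#' draws on (0, root_age) sorted oldest-first (the oldest is pinned at
#' `root_age`), each split subdividing a uniformly chosen active lineage.
#' All tips are sampled in the present (age 0).  An explicit
#' `config$genealogy` is validated and returned unchanged.
#'
#' @param config a [sim_config()]; the caller controls the RNG seed
#' @return data.frame `name`, `parent`, `age`: internal nodes `HG*` with
#'   positive ages, tips `S*` at age 0
#' @export
simulate_genealogy <- function(config) {
  if (!is.null(config$genealogy)) {
    g <- config$genealogy
    stopifnot(all(c("name", "parent", "age") %in% names(g)))
    return(g)
  }
  n <- config$n_tips
  stopifnot(n >= 2L)
  times <- sort(stats::runif(n - 1L, 0, config$root_age), decreasing = TRUE)
  times[1L] <- config$root_age
  nodes <- data.frame(name = "HG1", parent = NA_character_, age = times[1L])
  active <- c("HG1", "HG1")
  for (e in seq_len(n - 1L)[-1L]) {
    i <- sample.int(length(active), 1L)
    nm <- paste0("HG", e)
    nodes <- rbind(nodes, data.frame(name = nm, parent = active[i],
                                     age = times[e]))
    active <- c(active[-i], nm, nm)
  }
  tips <- data.frame(name = paste0("S", seq_len(n)), parent = active, age = 0)
  rbind(nodes, tips)
}

genealogy_as_haplotree <- function(genealogy, variants = empty_variants()) {
  haplo_tree(data.frame(name = genealogy$name, parent = genealogy$parent,
                        aliases = NA_character_), variants)
}

# map offsets 1..total_length to 1-based genomic positions inside the mask
mask_position <- function(mask, offsets) {
  iv <- mask$intervals
  len <- iv$end - iv$start
  cum <- cumsum(len)
  i <- findInterval(offsets - 1, c(0, cum), rightmost.closed = FALSE)
  data.frame(chrom = iv$chrom[i],
             pos = as.integer(iv$start[i] + (offsets - c(0, cum)[i])))
}

#' Drop Poisson mutations onto genealogy branches
#'
#' Each branch receives `Poisson(branch_years / snp_interval_mu)` SNPs.
#' Positions are drawn uniformly inside the mask without collision across
#' the whole tree; ancestral bases are uniform over A/C/G/T and derived
#' bases favour transitions 2:1 over each transversion.
#'
#' @param genealogy output of [simulate_genealogy()]
#' @param config a [sim_config()]
#' @return variant data.frame (`node`, `chrom`, `pos`, `anc`, `der`,
#'   `names`); `node` is the branch's child node
#' @export
simulate_variants <- function(genealogy, config) {
  age <- stats::setNames(genealogy$age, genealogy$name)
  branch <- genealogy[!is.na(genealogy$parent), , drop = FALSE]
  years <- age[branch$parent] - branch$age
  if (any(years < 0)) stop("child older than parent in genealogy")
  k <- stats::rpois(nrow(branch), years / config$snp_interval_mu)
  total <- sum(k)
  if (total > config$mask$total_length)
    stop("mask too small for ", total, " variants")
  if (total == 0L) return(empty_variants())
  offs <- sample.int(config$mask$total_length, total, replace = FALSE)
  loc <- mask_position(config$mask, offs)
  anc <- sample(BASES, total, replace = TRUE)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  der <- vapply(anc, function(a) {
    if (stats::runif(1) < 2 / 3) transition[[a]]
    else sample(setdiff(BASES, c(a, transition[[a]])), 1L)
  }, character(1L))
  out <- data.frame(node = rep(branch$name, k), chrom = loc$chrom,
                    pos = loc$pos, anc = anc, der = unname(der),
                    names = paste0("SIM", loc$pos))
  out[order(out$pos), ]
}

depth_for <- function(config, samples) {
  d <- config$mean_depth
  if (!is.null(names(d))) {
    out <- unname(d[samples])
    out[is.na(out)] <- stats::median(d)   # samples outside the named set
    return(stats::setNames(out, samples))
  }
  stats::setNames(rep_len(d, length(samples)), samples)
}

#' Simulate per-site observations for every sampled lineage
#'
#' For each tip and each variant site: the true allele is derived when the
#' branch carrying the variant lies on the tip's root path; read depth is
#' Poisson with the sample's mean; each read reports the true base, flipped
#' to a uniform other base with probability `seq_error_rate`; at C->T (G->A)
#' variant sites each read showing C (G) is deaminated to T (A) with
#' probability `damage_rate`; finally whole sites drop out with probability
#' `missing_rate`.  Per-read base qualities are drawn around Q37 so default
#' quality filters pass.
#'
#' @param genealogy,variants outputs of the generators above
#' @param config a [sim_config()]
#' @return named list (per tip) of observation data.frames in the
#'   [read_observations()] schema (`ref` is the ancestral base)
#' @export
simulate_observations <- function(genealogy, variants, config) {
  tips <- genealogy$name[genealogy$age == 0]
  tree <- genealogy_as_haplotree(genealogy)
  depth <- depth_for(config, tips)
  out <- list()
  for (s in tips) {
    onpath <- variants$node %in% path_to_root(tree, s)
    rows <- list()
    for (i in seq_len(nrow(variants))) {
      if (stats::runif(1) < config$missing_rate) next
      dp <- stats::rpois(1L, depth[[s]])
      if (dp == 0L) next
      true <- if (onpath[i]) variants$der[i] else variants$anc[i]
      reads <- rep(true, dp)
      err <- stats::runif(dp) < config$seq_error_rate
      if (any(err))
        reads[err] <- vapply(reads[err], function(b)
          sample(setdiff(BASES, b), 1L), character(1L))
      if (variants$anc[i] == "C" && variants$der[i] == "T") {
        dmg <- reads == "C" & stats::runif(dp) < config$damage_rate
        reads[dmg] <- "T"
      } else if (variants$anc[i] == "G" && variants$der[i] == "A") {
        dmg <- reads == "G" & stats::runif(dp) < config$damage_rate
        reads[dmg] <- "A"
      }
      quals <- pmax(2, round(stats::rnorm(dp, 37, 3)))
      cnt <- stats::setNames(integer(4L), BASES)
      q <- stats::setNames(numeric(4L), BASES)
      for (b in BASES) {
        cnt[b] <- sum(reads == b)
        q[b] <- if (cnt[b]) mean(quals[reads == b]) else 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = variants$chrom[i], pos = variants$pos[i],
        ref = variants$anc[i], depth = dp,
        count_A = cnt["A"], count_C = cnt["C"], count_G = cnt["G"],
        count_T = cnt["T"], q_A = q["A"], q_C = q["C"], q_G = q["G"],
        q_T = q["T"])
    }
    obs <- if (length(rows)) do.call(rbind, rows) else obs_schema()
    rownames(obs) <- NULL
    out[[s]] <- obs
  }
  out
}

#' Reference haplotree with clades withheld
#'
#' The reference tree is the genealogy's internal backbone (tips are the
#' sequenced samples, never reference haplogroups).  Hidden clades are
#' removed — their children reattach to the nearest kept ancestor and their
#' defining variants become invisible to the tree, i.e. novel to the
#' pipeline.  This constructs the discovery scenario where recent
#' haplogroups exist in the cohort but not in the database.
#'
#' @param genealogy,variants outputs of the generators above
#' @param hidden_clades internal node names to withhold
#' @param drop_unsupported also collapse internal nodes whose branch carries
#'   no defining variant (default TRUE: a haplogroup without defining SNPs
#'   is not ascertainable, so reference databases do not list one; the root
#'   is always kept)
#' @return a `haplo_tree` over the kept internal nodes
#' @export
make_reference_tree <- function(genealogy, variants,
                                hidden_clades = character(0),
                                drop_unsupported = TRUE) {
  internal <- genealogy[genealogy$age > 0, , drop = FALSE]
  unknown <- setdiff(hidden_clades, internal$name)
  if (length(unknown))
    stop("unknown clade name(s): ", paste(unknown, collapse = ", "))
  root <- internal$name[is.na(internal$parent)]
  if (root %in% hidden_clades) stop("cannot hide the root")
  if (drop_unsupported) {
    bare <- setdiff(internal$name[!(internal$name %in% variants$node)], root)
    hidden_clades <- union(hidden_clades, bare)
  }
  keep <- !(internal$name %in% hidden_clades)
  parent <- stats::setNames(internal$parent, internal$name)
  resolve <- function(p) {
    while (!is.na(p) && p %in% hidden_clades) p <- parent[[p]]
    p
  }
  nodes <- data.frame(name = internal$name[keep],
                      parent = unname(vapply(internal$parent[keep], resolve,
                                             character(1L))),
                      aliases = NA_character_, row.names = NULL)
  vars <- variants[variants$node %in% nodes$name, , drop = FALSE]
  haplo_tree(nodes, vars)
}

#' True terminal haplogroup of each tip on a reference tree
#' @param genealogy dated genealogy
#' @param ref_tree the (possibly pruned) reference `haplo_tree`
#' @return named character: deepest reference node on each tip's root path
#' @export
true_terminals <- function(genealogy, ref_tree) {
  full <- genealogy_as_haplotree(genealogy)
  tips <- genealogy$name[genealogy$age == 0]
  stats::setNames(vapply(tips, function(s) {
    p <- path_to_root(full, s)
    rev(p[p %in% ref_tree$nodes$name])[1L]
  }, character(1L)), tips)
}

#' Simulate X/Y read counts for sex assignment
#'
#' An XY individual contributes reads to X and Y in equal expectation (one
#' copy of each); an XX individual's Y count is a mismapping floor only.
#' Total reads scale with depth via `reads_per_fold`.
#'
#' @param true_sex named character vector of `"XY"` / `"XX"`
#' @param config a [sim_config()]
#' @return data.frame: `sample`, `nX`, `nY`, `true_sex`
#' @export
simulate_sex_counts <- function(true_sex, config) {
  depth <- depth_for(config, names(true_sex))
  rows <- lapply(names(true_sex), function(s) {
    n <- max(1L, stats::rpois(1L, config$reads_per_fold * depth[[s]]))
    nY <- if (true_sex[[s]] == "XY") stats::rbinom(1L, n, 0.5)
      else stats::rbinom(1L, n, config$female_y_rate)
    data.frame(sample = s, nX = n - nY, nY = nY, true_sex = true_sex[[s]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort with ground truth
#'
#' Runs every generator under `config$seed` and bundles pipeline inputs with
#' the truth needed by test harnesses.  Female samples (no Y lineage) are
#' appended for the sex/kinship stages with mitochondrial labels drawn from
#' a small pool; male tips get unique mt labels.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_cohort`: `genealogy`, `variants`,
#'   `reference_tree`, `observations`, `sex_counts`, `profiles`,
#'   `true_terminal`, `true_sex`, `config`
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  genealogy <- simulate_genealogy(config)
  variants <- simulate_variants(genealogy, config)
  ref_tree <- make_reference_tree(genealogy, variants, config$hidden_clades)
  observations <- simulate_observations(genealogy, variants, config)
  tips <- genealogy$name[genealogy$age == 0]
  true_sex <- stats::setNames(rep("XY", length(tips)), tips)
  if (config$n_females > 0L) {
    f <- paste0("F", seq_len(config$n_females))
    true_sex <- c(true_sex, stats::setNames(rep("XX", length(f)), f))
  }
  sex_counts <- simulate_sex_counts(true_sex, config)
  true_terminal <- true_terminals(genealogy, ref_tree)
  profiles <- data.frame(
    sample = names(true_sex),
    y_haplogroup = ifelse(true_sex == "XY",
                          true_terminal[names(true_sex)], NA),
    mt_haplogroup = paste0("MT", seq_along(true_sex)))
  rownames(profiles) <- NULL
  structure(list(genealogy = genealogy, variants = variants,
                 reference_tree = ref_tree, observations = observations,
                 sex_counts = sex_counts, profiles = profiles,
                 true_terminal = true_terminal, true_sex = true_sex,
                 config = config),
            class = "sim_cohort")
}

# ---- observation writers ----------------------------------------------------

#' Write observations in the readcount TSV dialect
#' @param obs observation data.frame ([read_observations()] schema)
#' @param path output file
#' @export
write_readcount_tsv <- function(obs, path) {
  fmt <- function(b, cnt, q) sprintf("%s:%d:%g", b, cnt, q)
  lines <- vapply(seq_len(nrow(obs)), function(i)
    paste(obs$chrom[i], obs$pos[i], obs$ref[i], obs$depth[i],
          fmt("A", obs$count_A[i], obs$q_A[i]),
          fmt("C", obs$count_C[i], obs$q_C[i]),
          fmt("G", obs$count_G[i], obs$q_G[i]),
          fmt("T", obs$count_T[i], obs$q_T[i]), sep = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write observations as a minimal VCF with allelic depths
#'
#' Biallelic records: ALT is the highest-count non-reference base (`.` when
#' only the reference is seen); reads of further bases are not representable
#' in this dialect and are dropped, so the VCF and readcount dialects agree
#' exactly in the error-free limit.
#'
#' @param obs observation data.frame
#' @param sample sample name for the single genotype column
#' @param path output file
#' @export
write_vcf_observations <- function(obs, sample, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- vapply(seq_len(nrow(obs)), function(i) {
    cnt <- c(A = obs$count_A[i], C = obs$count_C[i], G = obs$count_G[i],
             T = obs$count_T[i])
    ref <- obs$ref[i]
    altc <- cnt[setdiff(BASES, ref)]
    alt <- if (all(altc == 0L)) "." else names(altc)[which.max(altc)]
    ad <- if (alt == ".") as.character(cnt[ref]) else
      paste(cnt[ref], cnt[alt], sep = ",")
    paste(obs$chrom[i], obs$pos[i], ".", ref,
          alt, ".", "PASS", ".", "AD", ad, sep = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}
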