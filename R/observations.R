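# Per-sample per-site sequencing evidence and its reduction to
# derived / ancestral / missing / conflict states.

#' Calling policy for low-coverage ancient samples
#'
#' Controls how raw per-site base counts are reduced to an allele state.
#' With genomes down to well below 1x coverage, single-read calls must be
#' admissible (`min_depth = 1`); the `strict` damage mode compensates at
#' deamination-prone sites (C->T and G->A variants) by requiring
#' `min_depth_damage` supporting reads before accepting a derived call there.
#'
#' @param min_depth minimum total qualifying reads at a site (default 1)
#' @param min_quality minimum mean base quality per allele; alleles below it
#'   are ignored (default 20)
#' @param min_major_fraction fraction of qualifying reads an allele needs to
#'   be called (default 0.7; must be > 0.5 so at most one allele qualifies)
#' @param damage_mode `"off"` or `"strict"`
#' @param min_depth_damage reads required for a derived C->T / G->A call in
#'   strict mode (default 2)
#' @return object of class `call_policy`
#' @export
call_policy <- function(min_depth = 1L, min_quality = 20,
                        min_major_fraction = 0.7,
                        damage_mode = c("off", "strict"),
                        min_depth_damage = 2L) {
  damage_mode <- match.arg(damage_mode)
  stopifnot(min_depth >= 1, min_major_fraction > 0.5,
            min_major_fraction <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_quality = min_quality,
                 min_major_fraction = min_major_fraction,
                 damage_mode = damage_mode,
                 min_depth_damage = as.integer(min_depth_damage)),
            class = "call_policy")
}

obs_schema <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             depth = integer(),
             count_A = integer(), count_C = integer(), count_G = integer(),
             count_T = integer(),
             q_A = numeric(), q_C = numeric(), q_G = numeric(),
             q_T = numeric(), stringsAsFactors = FALSE)
}

#' Read per-site allele observations for one sample
#'
#' Two dialects are supported.  `readcount_tsv` is a per-base depth and
#' composition table:
#' `chrom<TAB>pos<TAB>ref<TAB>depth<TAB>A:count:meanq<TAB>C:...<TAB>G:...<TAB>T:...`.
#' `vcf` is VCF v4.2 with a per-sample `AD` (allelic depth) FORMAT field;
#' multi-allelic records are rejected.  VCF carries no per-allele mean base
#' quality, so observed alleles are assigned a nominal quality of 60
#' (i.e. they pass any sensible quality filter; filtering is assumed to have
#' happened upstream of the VCF).
#'
#' @param path input file
#' @param format `"readcount_tsv"` or `"vcf"`
#' @param sample sample name to extract from a multi-sample VCF (default:
#'   first sample)
#' @return data.frame with one row per site: `chrom`, `pos`, `ref`, `depth`,
#'   `count_A..count_T`, `q_A..q_T` (mean base quality, 0 where count is 0)
#' @export
read_observations <- function(path, format = c("readcount_tsv", "vcf"),
                              sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "readcount_tsv") parse_readcount_tsv(readLines(path, warn = FALSE))
  else parse_vcf_observations(path, sample)
}

parse_readcount_tsv <- function(lines) {
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop("line ", i, ": expected 8 tab-separated fields, got ", length(f))
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos)) stop("line ", i, ": bad position '", f[2L], "'")
    cnt <- stats::setNames(integer(4L), BASES)
    qual <- stats::setNames(numeric(4L), BASES)
    for (fld in f[5:8]) {
      p <- strsplit(fld, ":", fixed = TRUE)[[1L]]
      if (length(p) != 3L || !(p[1L] %in% BASES))
        stop("line ", i, ": malformed allele field '", fld, "'")
      cnt[p[1L]] <- as.integer(p[2L])
      qual[p[1L]] <- as.numeric(p[3L])
    }
    rows[[j]] <- data.frame(chrom = f[1L], pos = pos, ref = toupper(f[3L]),
                            depth = as.integer(f[4L]),
                            count_A = cnt["A"], count_C = cnt["C"],
                            count_G = cnt["G"], count_T = cnt["T"],
                            q_A = qual["A"], q_C = qual["C"],
                            q_G = qual["G"], q_T = qual["T"])
  }
  obs <- if (length(rows)) do.call(rbind, rows) else obs_schema()
  rownames(obs) <- NULL
  dup <- duplicated(site_key(obs$chrom, obs$pos))
  if (any(dup))
    stop("duplicate position(s): ",
         paste(site_key(obs$chrom, obs$pos)[dup], collapse = ", "))
  obs
}

parse_vcf_observations <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (!"AD" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":")))
    stop("VCF lacks the per-sample AD (allelic depth) FORMAT field")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(sample)) sample <- colnames(ad)[1L]
  if (!sample %in% colnames(ad)) stop("sample not in VCF: ", sample)
  n <- nrow(fix)
  obs <- obs_schema()
  for (i in seq_len(n)) {
    alt <- fix[i, "ALT"]
    if (is.na(alt) || alt == "") alt <- "."   # monomorphic record
    if (grepl(",", alt, fixed = TRUE))
      stop("multi-allelic record at ", fix[i, "CHROM"], ":", fix[i, "POS"],
           "; split upstream")
    ref <- toupper(fix[i, "REF"])
    alt <- toupper(alt)
    if (nchar(ref) != 1L || !(ref %in% BASES) || !(alt %in% c(BASES, ".")))
      stop("non-SNP record at ", fix[i, "CHROM"], ":", fix[i, "POS"])
    dp <- strsplit(ad[i, sample], ",", fixed = TRUE)[[1L]]
    dp <- suppressWarnings(as.integer(dp))
    cnt <- stats::setNames(integer(4L), BASES)
    cnt[ref] <- dp[1L]
    if (alt %in% BASES && length(dp) >= 2L) cnt[alt] <- dp[2L]
    qual <- ifelse(cnt > 0L, 60, 0)
    obs[nrow(obs) + 1L, ] <- list(fix[i, "CHROM"],
                                  as.integer(fix[i, "POS"]), ref,
                                  sum(cnt),
                                  cnt["A"], cnt["C"], cnt["G"], cnt["T"],
                                  qual[1L], qual[2L], qual[3L], qual[4L])
  }
  dup <- duplicated(site_key(obs$chrom, obs$pos))
  if (any(dup))
    stop("duplicate position(s): ",
         paste(site_key(obs$chrom, obs$pos)[dup], collapse = ", "))
  obs
}

is_damage_pair <- function(anc, der) {
  (anc == "C" & der == "T") | (anc == "G" & der == "A")
}

#' Reduce one site observation to an allele state
#'
#' Total over valid inputs: absence of data never errors, it yields a
#' `missing` call.  Alleles whose mean base quality is below
#' `policy$min_quality` are ignored entirely.  Among the remaining reads,
#' the derived (resp. ancestral) allele is called when its fraction reaches
#' `min_major_fraction`; when both alleles are present without a qualifying
#' majority the state is `conflict` — distinct from `missing` so that
#' contamination-like signals can be surfaced rather than silently dropped.
#' Under `damage_mode = "strict"`, a would-be derived call at a C->T or
#' G->A variant with fewer than `min_depth_damage` supporting reads degrades
#' to `missing` (a single T over a C could be post-mortem deamination).
#'
#' @param obs single-row observation data.frame (see [read_observations()]),
#'   or `NULL` when the site was not observed
#' @param variant single-row variant data.frame (`chrom`, `pos`, `anc`, `der`)
#' @param policy a [call_policy()]
#' @return list with `state` ("derived", "ancestral", "missing", "conflict"),
#'   `depth_support` (qualifying reads for the called allele) and `fraction`
#'   (supporting fraction of qualifying reads)
#' @export
call_state <- function(obs, variant, policy = call_policy()) {
  anc <- variant$anc; der <- variant$der
  out <- function(state, depth = 0L, fraction = NA_real_)
    list(state = state, depth_support = as.integer(depth),
         fraction = fraction)
  if (is.null(obs) || nrow(obs) == 0L) return(out("missing"))
  cnt <- c(A = obs$count_A, C = obs$count_C, G = obs$count_G, T = obs$count_T)
  qual <- c(A = obs$q_A, C = obs$q_C, G = obs$q_G, T = obs$q_T)
  cnt[qual < policy$min_quality] <- 0L
  total <- sum(cnt)
  if (total < policy$min_depth || (cnt[anc] + cnt[der]) == 0L)
    return(out("missing"))
  frac_der <- cnt[der] / total
  frac_anc <- cnt[anc] / total
  if (frac_der >= policy$min_major_fraction) {
    if (policy$damage_mode == "strict" && is_damage_pair(anc, der) &&
        cnt[der] < policy$min_depth_damage)
      return(out("missing"))
    return(out("derived", cnt[der], unname(frac_der)))
  }
  if (frac_anc >= policy$min_major_fraction)
    return(out("ancestral", cnt[anc], unname(frac_anc)))
  out("conflict", cnt[anc] + cnt[der], unname(max(frac_der, frac_anc)))
}

#' Call every variant of a site list for one sample
#'
#' @param obs observation data.frame for one sample ([read_observations()])
#' @param variants data.frame of variants (`chrom`, `pos`, `anc`, `der`,
#'   optionally `node`, `names`)
#' @param policy a [call_policy()]
#' @return `variants` with added columns `state`, `depth_support`, `fraction`
#' @export
call_sample <- function(obs, variants, policy = call_policy()) {
  need <- names(obs_schema())
  if (!is.data.frame(obs) || !all(need %in% names(obs)))
    stop("malformed observation table: expected columns ",
         paste(need, collapse = ", "))
  idx <- match(site_key(variants$chrom, variants$pos),
               site_key(obs$chrom, obs$pos))
  res <- lapply(seq_len(nrow(variants)), function(i) {
    o <- if (is.na(idx[i])) NULL else obs[idx[i], , drop = FALSE]
    call_state(o, variants[i, , drop = FALSE], policy)
  })
  variants$state <- vapply(res, `[[`, character(1L), "state")
  variants$depth_support <- vapply(res, `[[`, integer(1L), "depth_support")
  variants$fraction <- vapply(res, `[[`, numeric(1L), "fraction")
  variants
}

#' Sample-by-variant genotype matrix
#'
#' Rows are samples, columns are variants (keyed `chrom:pos:der`); entries
#' are `"1"` (derived), `"0"` (ancestral) or `"?"` (missing or conflict).
#' Conflict calls are folded into `"?"` but counted in the
#' `n_conflict` attribute so they are not silently lost.
#'
#' @param calls named list (one element per sample) of [call_sample()] output
#'   over a common variant list, in a common order
#' @return character matrix with attributes `variants` (the variant
#'   data.frame) and `n_conflict` (named integer per sample)
#' @export
genotype_matrix <- function(calls) {
  stopifnot(length(calls) >= 1L, !is.null(names(calls)))
  v0 <- calls[[1L]][, c("chrom", "pos", "anc", "der")]
  keys <- variant_key(v0$chrom, v0$pos, v0$der)
  m <- matrix("?", nrow = length(calls), ncol = length(keys),
              dimnames = list(names(calls), keys))
  n_conflict <- stats::setNames(integer(length(calls)), names(calls))
  for (s in names(calls)) {
    cs <- calls[[s]]
    if (!identical(variant_key(cs$chrom, cs$pos, cs$der), keys))
      stop("inconsistent variant ordering for sample ", s)
    m[s, ] <- ifelse(cs$state == "derived", "1",
                     ifelse(cs$state == "ancestral", "0", "?"))
    n_conflict[s] <- sum(cs$state == "conflict")
  }
  vars <- calls[[1L]][, intersect(c("chrom", "pos", "anc", "der", "names"),
                                  names(calls[[1L]]))]
  structure(m, variants = vars, n_conflict = n_conflict)
}
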