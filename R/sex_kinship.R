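# Read-ratio chromosomal sex assignment and rule-based kinship exclusion
# from uniparental (Y and mitochondrial) haplogroup profiles.

#' Assign chromosomal sex from X/Y read evidence
#'
#' The Ry statistic is `nY / (nX + nY)`.  Males (XY) carry one X and one Y,
#' so Ry concentrates near 0.5; females (XX) produce Y-mapped reads only
#' through mismapping, so Ry sits near 0.  Calls outside both thresholds are
#' `ambiguous`, never forced.  Average per-chromosome coverages may be
#' supplied in place of raw read counts: Ry is a ratio, so any common
#' scaling cancels (coverage differs from read count by read length over
#' chromosome length; using coverages slightly re-weights X vs Y, an
#' approximation documented here and accepted).
#'
#' @param nX,nY X- and Y-chromosome read counts or average coverages
#'   (vectorised)
#' @param t_male Ry at or above which the call is XY (default 0.075)
#' @param t_female Ry at or below which the call is XX (default 0.016)
#' @return data.frame: `nX`, `nY`, `Ry`, `classification`
#' @export
assign_sex <- function(nX, nY, t_male = 0.075, t_female = 0.016) {
  stopifnot(length(nX) == length(nY), t_female < t_male)
  if (any(nX + nY <= 0))
    stop("nX + nY must be positive (no reads, no call)")
  Ry <- nY / (nX + nY)
  cls <- ifelse(Ry >= t_male, "XY",
                ifelse(Ry <= t_female, "XX", "ambiguous"))
  data.frame(nX = nX, nY = nY, Ry = Ry, classification = cls)
}

#' Uniparental profile of one individual
#' @param sample sample label
#' @param y_haplogroup terminal Y haplogroup, or `NA` (females)
#' @param mt_haplogroup mitochondrial haplogroup label
#' @return list of class `uniparental_profile`
#' @export
uniparental_profile <- function(sample, y_haplogroup = NA_character_,
                                mt_haplogroup) {
  stopifnot(nzchar(sample), nzchar(mt_haplogroup))
  if (!is.na(y_haplogroup)) stopifnot(nzchar(y_haplogroup))
  structure(list(sample = sample, y_haplogroup = y_haplogroup,
                 mt_haplogroup = mt_haplogroup),
            class = "uniparental_profile")
}

RELATIONSHIPS <- c("mother_child", "full_sibling", "father_son",
                   "paternal_grandfather_grandson", "same_paternal_lineage",
                   "same_maternal_lineage")

#' Exclude pedigree relationships from uniparental markers
#'
#' Mitochondria pass mother to child; the Y passes father to son.  Hence a
#' differing mtDNA haplogroup excludes mother–child and full siblings; a
#' differing Y haplogroup excludes father–son, paternal grandfather–grandson
#' and any shared paternal lineage between two males.  Matching haplogroups
#' never *prove* a relationship — the verdicts are `compatible`, `excluded`
#' or `inapplicable` (Y-based relationships when either party has no Y).
#' Haplogroup comparison is string equality on the terminal assigned clade;
#' the placement stage is responsible for normalising aliases and depth.
#'
#' @param a,b [uniparental_profile()]s
#' @return data.frame: `relationship`, `status`
#' @export
kinship_exclusion <- function(a, b) {
  both_male <- !is.na(a$y_haplogroup) && !is.na(b$y_haplogroup)
  mt_same <- a$mt_haplogroup == b$mt_haplogroup
  y_same <- if (both_male) a$y_haplogroup == b$y_haplogroup else NA
  status <- c(
    mother_child = if (mt_same) "compatible" else "excluded",
    full_sibling = if (!mt_same) "excluded"
      else if (both_male && !y_same) "excluded" else "compatible",
    father_son = if (!both_male) "inapplicable"
      else if (y_same) "compatible" else "excluded",
    paternal_grandfather_grandson = if (!both_male) "inapplicable"
      else if (y_same) "compatible" else "excluded",
    same_paternal_lineage = if (!both_male) "inapplicable"
      else if (y_same) "compatible" else "excluded",
    same_maternal_lineage = if (mt_same) "compatible" else "excluded")
  data.frame(relationship = RELATIONSHIPS,
             status = unname(status[RELATIONSHIPS]))
}

#' Pairwise kinship verdicts over a cohort
#'
#' @param profiles data.frame with columns `sample`, `y_haplogroup` (`NA`
#'   for females), `mt_haplogroup`
#' @return data.frame, one row per unordered pair: `sample_a`, `sample_b`,
#'   one column per relationship in `RELATIONSHIPS`, plus
#'   `shared_paternal` / `shared_maternal` logical flags
#' @export
cohort_kinship_report <- function(profiles) {
  stopifnot(nrow(profiles) >= 2L)
  prof <- lapply(seq_len(nrow(profiles)), function(i)
    uniparental_profile(profiles$sample[i], profiles$y_haplogroup[i],
                        profiles$mt_haplogroup[i]))
  rows <- list()
  for (i in seq_len(nrow(profiles) - 1L)) {
    for (j in (i + 1L):nrow(profiles)) {
      v <- kinship_exclusion(prof[[i]], prof[[j]])
      st <- stats::setNames(v$status, v$relationship)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_a = profiles$sample[i], sample_b = profiles$sample[j],
        as.list(st),
        shared_paternal = identical(unname(st["same_paternal_lineage"]),
                                    "compatible"),
        shared_maternal = identical(unname(st["same_maternal_lineage"]),
                                    "compatible"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a profile table
#'
#' Tab-separated with header: `sample`, `nX`, `nY`, `y_haplogroup` (`-` or
#' empty for none), `mt_haplogroup`.
#'
#' @param path input TSV
#' @return data.frame with `y_haplogroup` normalised to `NA` where absent
#' @export
read_profile_table <- function(path) {
  p <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  need <- c("sample", "nX", "nY", "y_haplogroup", "mt_haplogroup")
  if (!all(need %in% names(p)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  p$nX <- as.numeric(p$nX); p$nY <- as.numeric(p$nY)
  p$y_haplogroup[p$y_haplogroup %in% c("", "-")] <- NA_character_
  p
}
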