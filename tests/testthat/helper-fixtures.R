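# Fixtures and independent oracles shared across the suite.  Everything is
# built in code; no binary files.

# Backbone fixture: R-Y2632 -> R-Y2633 -> R-SUR51 with 1/1/17 defining
# variants (19 sites in total).
fixture_tree_lines <- function() {
  sur <- paste(sprintf("SUR51_%d:%d:C:T", 1:17, 10000 + (1:17) * 100),
               collapse = ",")
  c("# backbone fixture",
    "R-Y2632\t-\tY2632:1000:A:G\tR1a1a1b2a2a1c3",
    "R-Y2633\tR-Y2632\tY2633:2000:G:A\tR1a1a1b2a2a1c3a",
    paste0("R-SUR51\tR-Y2633\t", sur))
}

fixture_tree <- function() parse_haplotree(fixture_tree_lines())

# Build a minimal single-row observation for call_state tests.
obs_row <- function(pos, ref, counts, quals = NULL, chrom = "chrY") {
  cnt <- stats::setNames(integer(4L), c("A", "C", "G", "T"))
  cnt[names(counts)] <- as.integer(counts)
  q <- stats::setNames(numeric(4L), c("A", "C", "G", "T"))
  if (is.null(quals)) q[cnt > 0] <- 35 else q[names(quals)] <- quals
  data.frame(chrom = chrom, pos = pos, ref = ref, depth = sum(cnt),
             count_A = cnt["A"], count_C = cnt["C"], count_G = cnt["G"],
             count_T = cnt["T"], q_A = q["A"], q_C = q["C"], q_G = q["G"],
             q_T = q["T"])
}

a_variant <- function(pos = 1L, anc = "C", der = "T", chrom = "chrY") {
  data.frame(node = NA_character_, chrom = chrom, pos = pos, anc = anc,
             der = der, names = paste0("V", pos))
}

# Genotype matrix from a plain 0/1/? character (or 0/1/NA numeric) matrix;
# columns become chrY variants at positions 1000, 2000, ... with A->G.
make_genotypes <- function(m) {
  if (is.numeric(m)) {
    mm <- matrix(as.character(m), nrow = nrow(m))
    mm[is.na(m)] <- "?"
  } else mm <- m
  if (is.null(rownames(m))) rownames(mm) <- paste0("S", seq_len(nrow(m)))
  else rownames(mm) <- rownames(m)
  pos <- 500000L + 1000L * seq_len(ncol(mm))
  vars <- data.frame(chrom = "chrY", pos = pos, anc = "A", der = "G",
                     names = paste0("V", seq_len(ncol(mm))))
  colnames(mm) <- paste("chrY", pos, "G", sep = ":")
  structure(mm, variants = vars,
            n_conflict = stats::setNames(integer(nrow(mm)), rownames(mm)))
}

empty_reference_tree <- function() {
  parse_haplotree("ROOT\t-\t")
}

# Full genealogy (internal nodes and tips) of a simulated cohort as a
# haplotree carrying the true per-branch variants.
genealogy_to_tree <- function(co) {
  haplo_tree(data.frame(name = co$genealogy$name,
                        parent = co$genealogy$parent),
             co$variants)
}

# Cohort encoding the published sharing pattern: 17 variants carried by all
# 51 samples, 6 by the 48 Bashkir-like samples, 9 by the 3 royal/Serbian
# samples, 9 private to the Serbian individual.  Complete data.
fixture_royal_matrix <- function() {
  samples <- c("HU3B", "HU52", "SRB1", sprintf("B%02d", 1:48))
  m <- matrix(0L, nrow = 51, ncol = 41, dimnames = list(samples, NULL))
  m[, 1:17] <- 1L                        # shared by all 51
  m[4:51, 18:23] <- 1L                   # Bashkir-side 6
  m[1:3, 24:32] <- 1L                    # ARP 9
  m["SRB1", 33:41] <- 1L                 # UVD private 9
  m
}

# ---- independent oracles ----------------------------------------------------

# Oracle for complete (no '?') homoplasy-free matrices: clades are the
# distinct nonzero column patterns; counts by direct tabulation.
oracle_partition_complete <- function(m01) {
  cols <- apply(m01, 2, paste, collapse = "")
  keep <- colSums(m01) > 0
  tab <- table(cols[keep])
  sig <- lapply(names(tab), function(s)
    sort(rownames(m01)[strsplit(s, "")[[1]] == "1"]))
  data.frame(members = vapply(sig, paste, character(1), collapse = ","),
             n_variants = as.integer(tab))[
               order(-lengths(sig), vapply(sig, paste, character(1),
                                           collapse = ",")), ]
}

# Exhaustive brute force over all set partitions of the variants (small
# instances): a partition is feasible when, taking each group's member set
# as the union of its variants' carriers, no variant's confident noncarrier
# falls inside its group and the family of distinct member sets is laminar.
# Returns the canonical signatures of all coarsest feasible partitions.
oracle_partition_exhaustive <- function(novel) {
  n <- nrow(novel)
  carriers <- lapply(novel$carriers, function(x) strsplit(x, ",")[[1]])
  noncar <- lapply(novel$noncarriers, function(x)
    if (nzchar(x)) strsplit(x, ",")[[1]] else character(0))
  # enumerate set partitions via restricted growth strings
  parts <- list()
  rec <- function(assign, kmax) {
    i <- length(assign) + 1L
    if (i > n) { parts[[length(parts) + 1L]] <<- assign; return(invisible()) }
    for (g in seq_len(kmax + 1L)) rec(c(assign, g), max(kmax, g))
  }
  rec(integer(0), 0L)
  best <- NULL; best_k <- Inf
  for (p in parts) {
    groups <- split(seq_len(n), p)
    ms <- lapply(groups, function(ix) sort(unique(unlist(carriers[ix]))))
    feasible <- TRUE
    for (gi in seq_along(groups)) {
      for (i in groups[[gi]])
        if (any(noncar[[i]] %in% ms[[gi]])) { feasible <- FALSE; break }
      if (!feasible) break
    }
    if (!feasible) next
    uniq <- unique(ms)
    lam <- TRUE
    if (length(uniq) > 1) {
      for (a in seq_len(length(uniq) - 1)) for (b in (a + 1):length(uniq)) {
        iv <- length(intersect(uniq[[a]], uniq[[b]]))
        if (iv != 0 && iv != length(uniq[[a]]) && iv != length(uniq[[b]])) {
          lam <- FALSE; break
        }
      }
    }
    if (!lam) next
    k <- length(uniq)
    sig <- paste(sort(vapply(seq_along(groups), function(gi)
      paste0(paste(ms[[gi]], collapse = ","), "|", length(groups[[gi]])),
      character(1))), collapse = ";")
    if (k < best_k) { best <- sig; best_k <- k }
    else if (k == best_k) best <- union(best, sig)
  }
  best
}

partition_signature <- function(partition) {
  paste(sort(vapply(partition$clades, function(cl)
    paste0(paste(cl$members, collapse = ","), "|",
           length(cl$variant_keys)), character(1))), collapse = ";")
}

# Random laminar clade family over the given samples (recursive splitting),
# returned as a list of member-name vectors including the full set.
random_laminar_family <- function(samples, p_split = 0.7) {
  out <- list(samples)
  rec <- function(s) {
    if (length(s) < 2 || stats::runif(1) > p_split) return(invisible())
    k <- sample(1:(length(s) - 1), 1)
    a <- sample(s, k); b <- setdiff(s, a)
    for (part in list(a, b)) {
      if (length(part) >= 1 && length(part) < length(samples) &&
          stats::runif(1) < 0.8) {
        out[[length(out) + 1L]] <<- sort(part)
        rec(part)
      }
    }
  }
  rec(samples)
  unique(out)
}

# Matrix for a laminar family: one to three variants per clade, complete.
matrix_from_family <- function(family, samples, vars_per_clade = NULL) {
  if (is.null(vars_per_clade))
    vars_per_clade <- sample(1:3, length(family), replace = TRUE)
  cols <- list()
  for (i in seq_along(family))
    for (j in seq_len(vars_per_clade[i]))
      cols[[length(cols) + 1L]] <- as.integer(samples %in% family[[i]])
  m <- do.call(cbind, cols)
  rownames(m) <- samples
  m
}

novel_from_matrix <- function(m) {
  collect_novel_variants(make_genotypes(m), empty_reference_tree())
}
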