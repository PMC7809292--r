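# Discovery of novel haplogroups from sharing patterns of derived SNPs that
# are absent from the reference tree, under a perfect-phylogeny (laminar
# carrier-set) model with missing data treated as uninformative.

#' Collect derived variants absent from the reference tree
#'
#' A site qualifies when at least one sample carries the derived allele and
#' its (chrom, pos, der) key is not indexed on the reference tree.  For each
#' such variant the cohort is partitioned into carriers (state 1),
#' confident noncarriers (state 0) and unknown (`?`).
#'
#' @param genotypes matrix from [genotype_matrix()] (tree variants plus any
#'   extra interrogated sites)
#' @param tree the reference `haplo_tree`
#' @return data.frame, one row per novel variant: `key`, `chrom`, `pos`,
#'   `anc`, `der`, `carriers`, `noncarriers`, `unknown` (comma-joined sample
#'   names), `n_carriers`
#' @export
collect_novel_variants <- function(genotypes, tree) {
  vars <- attr(genotypes, "variants")
  keys <- colnames(genotypes)
  known <- tree_by_site(tree)$key
  rows <- list()
  for (j in seq_along(keys)) {
    if (keys[j] %in% known) next
    col <- genotypes[, j]
    carriers <- rownames(genotypes)[col == "1"]
    if (!length(carriers)) next
    rows[[length(rows) + 1L]] <- data.frame(
      key = keys[j], chrom = vars$chrom[j], pos = vars$pos[j],
      anc = vars$anc[j], der = vars$der[j],
      carriers = paste(sort(carriers), collapse = ","),
      noncarriers = paste(sort(rownames(genotypes)[col == "0"]),
                          collapse = ","),
      unknown = paste(sort(rownames(genotypes)[col == "?"]), collapse = ","),
      n_carriers = length(carriers))
  }
  if (!length(rows))
    return(data.frame(key = character(), chrom = character(),
                      pos = integer(), anc = character(), der = character(),
                      carriers = character(), noncarriers = character(),
                      unknown = character(), n_carriers = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

split_set <- function(x) if (!nzchar(x)) character(0) else
  strsplit(x, ",", fixed = TRUE)[[1L]]

laminar_with <- function(m, sets) {
  for (s in sets) {
    i <- length(intersect(m, s))
    if (i != 0L && i != length(m) && i != length(s)) return(FALSE)
  }
  TRUE
}

#' Group novel variants into nested clades
#'
#' Perfect-phylogeny clustering of carrier sets with missing data treated as
#' a joker: an unknown state never vetoes clade membership; a variant only
#' conflicts with a clade through a confident ancestral (noncarrier) call
#' inside it.  Variants with identical carrier sets seed one proto-clade
#' each; proto-clades are then merged to a fixpoint whenever the union of
#' their member sets contains no confident noncarrier of any supporting
#' variant — the parsimony choice: observations never force the extra clade
#' apart, so one clade explains them.  Two true clades survive as separate
#' whenever some member of one is confidently ancestral for a variant of the
#' other.  Clades whose member sets still violate the laminar
#' (pairwise nested-or-disjoint) structure after merging are homoplasy
#' signals; they are dropped greedily, fewest members first, with reason
#' `"incompatible"`.
#'
#' @param novel_variants output of [collect_novel_variants()]
#' @param min_support minimum supporting variants per clade (default 1: a
#'   clade may rest on one sample's private SNPs)
#' @return object of class `clade_partition`: `clades` (list of
#'   `members`, `variant_keys`, `name`, `parent` index) ordered by decreasing
#'   member count, and `dropped_variants` (data.frame `key`, `reason`)
#' @export
partition_clades <- function(novel_variants, min_support = 1L) {
  nv <- novel_variants
  stopifnot(nrow(nv) >= 1L)
  ord <- order(-nv$n_carriers, nv$carriers, nv$key)
  nv <- nv[ord, , drop = FALSE]
  noncar <- lapply(nv$noncarriers, split_set)
  # one proto-clade per distinct carrier signature
  groups <- split(seq_len(nrow(nv)), factor(nv$carriers,
                                            levels = unique(nv$carriers)))
  clades <- lapply(groups, function(ix)
    list(members = sort(split_set(nv$carriers[ix[1L]])), variant_idx = ix))
  names(clades) <- NULL
  mergeable <- function(a, b) {
    m <- union(a$members, b$members)
    for (i in c(a$variant_idx, b$variant_idx))
      if (any(noncar[[i]] %in% m)) return(FALSE)
    TRUE
  }
  repeat {
    done <- TRUE
    for (i in seq_along(clades)) {
      if (!done) break
      for (j in seq_along(clades)) {
        if (j <= i) next
        if (mergeable(clades[[i]], clades[[j]])) {
          clades[[i]] <- list(
            members = sort(union(clades[[i]]$members, clades[[j]]$members)),
            variant_idx = c(clades[[i]]$variant_idx,
                            clades[[j]]$variant_idx))
          clades[[j]] <- NULL
          done <- FALSE
          break
        }
      }
    }
    if (done) break
  }
  # enforce laminarity: drop offending clades, fewest members first
  dropped <- data.frame(key = character(), reason = character())
  repeat {
    bad <- rep(FALSE, length(clades))
    for (i in seq_along(clades))
      bad[i] <- !laminar_with(clades[[i]]$members,
                              lapply(clades[-i], `[[`, "members"))
    if (!any(bad)) break
    sz <- vapply(clades, function(cl) length(cl$members), integer(1L))
    nvars <- vapply(clades, function(cl) length(cl$variant_idx), integer(1L))
    cand <- which(bad)
    k <- cand[order(sz[cand], nvars[cand])][1L]
    dropped <- rbind(dropped,
                     data.frame(key = nv$key[clades[[k]]$variant_idx],
                                reason = "incompatible"))
    clades[[k]] <- NULL
  }
  keep <- vapply(clades, function(cl)
    length(cl$variant_idx) >= min_support, logical(1L))
  for (cl in clades[!keep])
    dropped <- rbind(dropped, data.frame(key = nv$key[cl$variant_idx],
                                         reason = "below_min_support"))
  clades <- clades[keep]
  # order by decreasing size, then lexicographic, and resolve nesting
  if (length(clades)) {
    o <- order(-vapply(clades, function(cl) length(cl$members), integer(1L)),
               vapply(clades, function(cl) paste(cl$members, collapse = ","),
                      character(1L)))
    clades <- clades[o]
    for (k in seq_along(clades)) {
      m <- clades[[k]]$members
      sup <- which(vapply(clades, function(cl)
        length(cl$members) > length(m) && all(m %in% cl$members),
        logical(1L)))
      clades[[k]]$parent <- if (length(sup)) {
        sizes <- vapply(clades[sup], function(cl) length(cl$members),
                        integer(1L))
        sup[which.min(sizes)]
      } else NA_integer_
      clades[[k]]$name <- paste0("NOVEL-", k)
      clades[[k]]$variant_keys <- nv$key[clades[[k]]$variant_idx]
      clades[[k]]$variant_idx <- NULL
    }
  }
  structure(list(clades = clades, dropped_variants = dropped),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("<clade_partition> ", length(x$clades), " clade(s), ",
      nrow(x$dropped_variants), " dropped variant(s)\n", sep = "")
  for (cl in x$clades)
    cat("  ", cl$name, ": ", length(cl$members), " member(s), ",
        length(cl$variant_keys), " variant(s)",
        if (!is.na(cl$parent)) paste0(" < ", x$clades[[cl$parent]]$name),
        "\n", sep = "")
  invisible(x)
}

#' Tabular clade partition report
#' @param partition a `clade_partition`
#' @return data.frame: `name`, `parent`, `n_members`, `members`,
#'   `n_variants`, `variants`
#' @export
partition_report <- function(partition) {
  rows <- lapply(partition$clades, function(cl)
    data.frame(name = cl$name,
               parent = if (is.na(cl$parent)) "-" else
                 partition$clades[[cl$parent]]$name,
               n_members = length(cl$members),
               members = paste(cl$members, collapse = ","),
               n_variants = length(cl$variant_keys),
               variants = paste(cl$variant_keys, collapse = ",")))
  if (!length(rows))
    return(data.frame(name = character(), parent = character(),
                      n_members = integer(), members = character(),
                      n_variants = integer(), variants = character()))
  do.call(rbind, rows)
}

#' Four-gamete compatibility check
#'
#' Two binary sites are incompatible with a single mutation history on a
#' non-recombining chromosome when all four gametes 00, 01, 10, 11 occur.
#' Only samples fully observed for the pair are considered.
#'
#' @param genotypes matrix over `"0"`, `"1"`, `"?"`
#' @return data.frame of incompatible pairs (`site_a`, `site_b`); zero rows
#'   when the matrix is compatible with a perfect phylogeny
#' @export
four_gamete_check <- function(genotypes) {
  keys <- colnames(genotypes)
  out <- data.frame(site_a = character(), site_b = character())
  if (length(keys) < 2L) return(out)
  for (a in seq_len(length(keys) - 1L)) {
    for (b in (a + 1L):length(keys)) {
      ga <- genotypes[, a]; gb <- genotypes[, b]
      ok <- ga != "?" & gb != "?"
      pat <- unique(paste0(ga[ok], gb[ok]))
      if (all(c("00", "01", "10", "11") %in% pat))
        out <- rbind(out, data.frame(site_a = keys[a], site_b = keys[b]))
    }
  }
  out
}

#' Attach discovered clades below their members' terminal node
#'
#' A novel clade refines the tree *below* the deepest backbone node its
#' members reach, so all members of a clade must share one terminal
#' haplogroup in `placements`; a clade whose members sit on different
#' backbone branches spans an incompatible backbone and is an error (or is
#' skipped, with its descendants, under `on_conflict = "skip"` — the
#' defensive choice for noisy cohort runs).  Nested clades attach under
#' their parent clade's new node.  New nodes carry the clade's supporting
#' variants as their defining variants.
#'
#' @param tree reference `haplo_tree`
#' @param partition a `clade_partition`
#' @param placements named list of [place_sample()] results covering every
#'   clade member
#' @param novel_variants the [collect_novel_variants()] table (source of
#'   variant coordinates)
#' @param names optional character vector of clade names, in the
#'   partition's clade order (default `NOVEL-1`, `NOVEL-2`, ...)
#' @param on_conflict `"error"` or `"skip"` for clades spanning branches
#' @return augmented `haplo_tree` (attribute `skipped_clades` lists any
#'   clade names skipped under `on_conflict = "skip"`)
#' @export
attach_clades <- function(tree, partition, placements, novel_variants,
                          names = NULL, on_conflict = c("error", "skip")) {
  on_conflict <- match.arg(on_conflict)
  if (!length(partition$clades)) return(tree)
  members <- unique(unlist(lapply(partition$clades, `[[`, "members")))
  miss <- setdiff(members, base::names(placements))
  if (length(miss))
    stop("clade member(s) without placement: ", paste(miss, collapse = ", "))
  if (is.null(names)) {
    names <- vapply(partition$clades, `[[`, character(1L), "name")
  } else stopifnot(length(names) == length(partition$clades))
  nodes <- tree$nodes
  vars <- tree$variants
  skipped <- integer(0)
  for (k in seq_along(partition$clades)) {   # parents precede children
    cl <- partition$clades[[k]]
    if (!is.na(cl$parent) && cl$parent %in% skipped) {
      skipped <- c(skipped, k)
      next
    }
    parent <- if (!is.na(cl$parent)) names[cl$parent] else {
      terms <- unique(vapply(cl$members, function(s) placements[[s]]$terminal,
                             character(1L)))
      if (length(terms) != 1L) {
        if (on_conflict == "error")
          stop("members of clade ", names[k],
               " place on different backbone branches: ",
               paste(terms, collapse = ", "))
        skipped <- c(skipped, k)
        next
      }
      terms
    }
    nodes <- rbind(nodes, data.frame(name = names[k], parent = parent,
                                     aliases = NA_character_))
    nv <- novel_variants[novel_variants$key %in% cl$variant_keys, ,
                         drop = FALSE]
    if (nrow(nv))
      vars <- rbind(vars, data.frame(node = names[k], chrom = nv$chrom,
                                     pos = nv$pos, anc = nv$anc,
                                     der = nv$der,
                                     names = paste0("SNP", nv$pos)))
  }
  out <- haplo_tree(nodes, vars)
  attr(out, "skipped_clades") <- names[skipped]
  out
}
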