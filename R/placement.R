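# Tree-guided haplogroup placement: descend the reference haplotree over a
# sample's allele calls, excluding sibling branches via ancestral calls and
# tolerating heavy missingness.

#' Tally a sample's calls over one branch's defining variants
#'
#' @param calls [call_sample()] output for the sample (must include `node`)
#' @param tree a `haplo_tree`
#' @param node node name whose branch is scored
#' @return one-row data.frame: `node`, `n_defining`, `n_observed` (non-missing
#'   calls), `n_derived`, `n_ancestral`, `n_conflict`
#' @export
score_branch <- function(calls, tree, node) {
  st <- calls$state[calls$node == node]
  n_def <- sum(tree$variants$node == node)
  data.frame(node = node,
             n_defining = n_def,
             n_observed = sum(st != "missing"),
             n_derived = sum(st == "derived"),
             n_ancestral = sum(st == "ancestral"),
             n_conflict = sum(st == "conflict"))
}

#' Place one sample on the haplotree
#'
#' Walks from the root toward the tips.  A child branch is *supported* when
#' at least one of its defining variants is called derived and derived calls
#' outnumber ancestral calls on the branch; descent stops at the first node
#' with no supported child.  When two or more children are supported the walk
#' follows the one with the larger derived fraction
#' (`n_derived / n_observed`); an exact tie stops the walk and the tied
#' children are reported as ambiguous rather than guessed at.  Siblings of
#' the chosen child with at least one ancestral call are recorded as
#' positively excluded branches.
#'
#' @param tree a `haplo_tree`
#' @param calls [call_sample()] output over the tree's variants (column
#'   `node` identifies each variant's branch)
#' @param min_derived minimum derived calls for a branch to be supported
#' @return object of class `placement`: `terminal`, `path` (data.frame of
#'   branch supports root..terminal), `excluded_siblings`,
#'   `ambiguous_children`, `qc` (`fraction_path_observed`,
#'   `conflicts_on_path`)
#' @export
place_sample <- function(tree, calls, min_derived = 1L) {
  cur <- tree_root(tree)
  path <- list(score_branch(calls, tree, cur))
  excluded <- data.frame(node = character(), n_ancestral = integer())
  ambiguous <- character(0)
  repeat {
    kids <- tree_children(tree, cur)
    if (!length(kids)) break
    sup <- do.call(rbind, lapply(kids, function(k) score_branch(calls, tree, k)))
    supported <- sup$n_derived >= min_derived & sup$n_derived > sup$n_ancestral
    if (!any(supported)) break
    cand <- sup[supported, , drop = FALSE]
    frac <- cand$n_derived / pmax(cand$n_observed, 1L)
    best <- which(frac == max(frac))
    if (length(best) > 1L) {
      ambiguous <- cand$node[best]
      break
    }
    chosen <- cand$node[best]
    sib <- sup[sup$node != chosen & sup$n_ancestral >= 1L, , drop = FALSE]
    if (nrow(sib))
      excluded <- rbind(excluded, sib[, c("node", "n_ancestral")])
    path[[length(path) + 1L]] <- sup[sup$node == chosen, , drop = FALSE]
    cur <- chosen
  }
  path <- do.call(rbind, path)
  rownames(path) <- NULL
  n_def <- sum(path$n_defining)
  structure(list(
    terminal = cur,
    path = path,
    excluded_siblings = excluded,
    ambiguous_children = ambiguous,
    qc = list(
      fraction_path_observed = if (n_def == 0L) 0 else
        sum(path$n_observed) / n_def,
      conflicts_on_path = sum(path$n_conflict))),
    class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat("<placement> terminal ", x$terminal,
      " (path depth ", nrow(x$path) - 1L,
      ", ", round(100 * x$qc$fraction_path_observed), "% of path SNPs observed",
      if (length(x$ambiguous_children)) "; AMBIGUOUS" else "", ")\n", sep = "")
  invisible(x)
}

#' Tabular placement report for a cohort
#'
#' One row per sample with the terminal haplogroup under both stored naming
#' authorities (shorthand node name plus any aliases, e.g. ISOGG longhand).
#'
#' @param placements named list of [place_sample()] results
#' @param tree the `haplo_tree` the placements were made on
#' @return data.frame: `sample`, `terminal_name`, `terminal_aliases`, `path`,
#'   `fraction_path_observed`, `conflicts`, `ambiguity_flag`
#' @export
placement_report <- function(placements, tree) {
  stopifnot(length(placements) >= 1L, !is.null(names(placements)))
  rows <- lapply(names(placements), function(s) {
    p <- placements[[s]]
    al <- node_aliases(tree, p$terminal)
    data.frame(sample = s,
               terminal_name = p$terminal,
               terminal_aliases = if (length(al)) paste(al, collapse = ",")
                 else "-",
               path = paste(p$path$node, collapse = ">"),
               fraction_path_observed = p$qc$fraction_path_observed,
               conflicts = p$qc$conflicts_on_path,
               ambiguity_flag = length(p$ambiguous_children) > 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
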