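# ---- internal helpers -------------------------------------------------------

BASES <- c("A", "C", "G", "T")

variant_key <- function(chrom, pos, der) paste(chrom, pos, der, sep = ":")

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

empty_variants <- function() {
  data.frame(node = character(), chrom = character(), pos = integer(),
             anc = character(), der = character(), names = character(),
             stringsAsFactors = FALSE)
}

#' Construct a haplotree from node and variant tables
#'
#' A haplotree is a rooted reference tree of Y-chromosome haplogroups whose
#' branches carry defining variants.  The branch leading into a node carries
#' that node's `defining variants`: a sample carrying the derived allele at
#' those sites belongs to the node's clade (or deeper).
#'
#' @param nodes data.frame with columns `name`, `parent` (`NA` for the root)
#'   and optionally `aliases` (comma-separated alternative labels, e.g. the
#'   ISOGG longhand next to a shorthand name).
#' @param variants data.frame with columns `node`, `chrom`, `pos` (1-based),
#'   `anc`, `der` (single bases) and `names` ("/"-separated SNP labels).
#' @return object of class `haplo_tree` with elements `nodes` and `variants`.
#' @export
haplo_tree <- function(nodes, variants = empty_variants()) {
  stopifnot(is.data.frame(nodes), all(c("name", "parent") %in% names(nodes)))
  nodes$name <- as.character(nodes$name)
  nodes$parent <- as.character(nodes$parent)
  if (is.null(nodes$aliases)) nodes$aliases <- NA_character_
  if (anyDuplicated(nodes$name))
    stop("duplicate node name(s): ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  roots <- nodes$name[is.na(nodes$parent)]
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  missing_parent <- setdiff(stats::na.omit(nodes$parent), nodes$name)
  if (length(missing_parent))
    stop("orphan parent reference(s): ", paste(missing_parent, collapse = ", "))
  if (nrow(variants)) {
    variants$pos <- as.integer(variants$pos)
    bad <- !(variants$node %in% nodes$name)
    if (any(bad))
      stop("variant(s) assigned to unknown node: ",
           paste(unique(variants$node[bad]), collapse = ", "))
    if (any(variants$anc == variants$der))
      stop("variant with identical ancestral and derived allele at pos ",
           paste(variants$pos[variants$anc == variants$der], collapse = ", "))
    if (!all(variants$anc %in% BASES) || !all(variants$der %in% BASES))
      stop("variant alleles must be A/C/G/T")
    key <- variant_key(variants$chrom, variants$pos, variants$der)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      on <- variants$node[key == d]
      stop("variant ", d, " assigned to more than one branch: ",
           paste(on, collapse = ", "))
    }
  }
  tr <- structure(list(nodes = nodes, variants = variants),
                  class = "haplo_tree")
  # cycle check: every node must reach the root
  for (nm in nodes$name) path_to_root(tr, nm)
  tr
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("<haplo_tree> ", nrow(x$nodes), " nodes, ", nrow(x$variants),
      " defining variants, root ", tree_root(x), "\n", sep = "")
  invisible(x)
}

#' Root node name of a haplotree
#' @param tree a `haplo_tree`
#' @return character scalar
#' @export
tree_root <- function(tree) tree$nodes$name[is.na(tree$nodes$parent)]

#' Child nodes of a haplotree node
#' @param tree a `haplo_tree`
#' @param name node name
#' @return character vector of child names (possibly empty), in file order
#' @export
tree_children <- function(tree, name) {
  tree$nodes$name[!is.na(tree$nodes$parent) & tree$nodes$parent == name]
}

#' Defining variants of one branch
#' @param tree a `haplo_tree`
#' @param name node name
#' @return data.frame of the variants on the branch leading into `name`
#' @export
node_variants <- function(tree, name) {
  tree$variants[tree$variants$node == name, , drop = FALSE]
}

#' Site index of a haplotree
#'
#' One row per defining variant, keyed by (chrom, pos, der); used to decide
#' whether an observed derived allele is already represented on the tree.
#'
#' @param tree a `haplo_tree`
#' @return data.frame with columns of `tree$variants` plus `key`
#' @export
tree_by_site <- function(tree) {
  v <- tree$variants
  v$key <- variant_key(v$chrom, v$pos, v$der)
  v
}

#' Path from the root to a node
#' @param tree a `haplo_tree`
#' @param node_name node name
#' @return character vector of node names, root first, `node_name` last
#' @export
path_to_root <- function(tree, node_name) {
  if (!node_name %in% tree$nodes$name) stop("unknown node: ", node_name)
  parent <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  path <- node_name
  cur <- node_name
  n <- nrow(tree$nodes)
  while (!is.na(parent[[cur]])) {
    cur <- parent[[cur]]
    path <- c(cur, path)
    if (length(path) > n) stop("cycle detected at node ", node_name)
  }
  path
}

#' Validate a haplotree
#'
#' Structural problems are returned, not raised: nodes without defining
#' variants (warning; legitimate for structural haplogroups), duplicated
#' positions (error), nodes unreachable from the root (error).
#'
#' @param tree a `haplo_tree`
#' @return data.frame with columns `severity` ("warning"/"error") and
#'   `message`; zero rows when the tree is clean
#' @export
validate_tree <- function(tree) {
  issues <- list()
  push <- function(severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(severity = severity,
                                                 message = message)
  n_def <- table(factor(tree$variants$node, levels = tree$nodes$name))
  for (nm in names(n_def)[n_def == 0L])
    push("warning", paste0("node ", nm, " has no defining variants"))
  sk <- site_key(tree$variants$chrom, tree$variants$pos)
  for (d in unique(sk[duplicated(sk)]))
    push("error", paste0("position ", d, " used by more than one variant"))
  reachable <- unlist(lapply(tree$nodes$name,
                             function(nm) tryCatch(path_to_root(tree, nm)[1L],
                                                   error = function(e) NA)))
  root <- tree_root(tree)
  for (nm in tree$nodes$name[is.na(reachable) | reachable != root])
    push("error", paste0("node ", nm, " unreachable from root"))
  if (!length(issues))
    return(data.frame(severity = character(), message = character()))
  do.call(rbind, issues)
}

# ---- text format ------------------------------------------------------------

#' Parse the tab-separated haplotree format
#'
#' One node per line: `name<TAB>parent-or-"-"<TAB>variant specs`, where the
#' third field is a comma-separated list of `pos:anc:der:label1/label2`
#' entries (empty or absent for structural nodes).  An optional fourth field
#' carries comma-separated node aliases (e.g. an ISOGG longhand).  Lines
#' starting with `#` and blank lines are ignored.  Parents may be declared
#' after their children.
#'
#' @param text character vector of lines, or a single string with newlines
#' @param chrom contig label assigned to every variant (the format is
#'   single-chromosome)
#' @return a `haplo_tree`
#' @export
parse_haplotree <- function(text, chrom = "chrY") {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  keep <- !grepl("^\\s*(#|$)", text)
  recs <- which(keep)
  nodes <- list(); vars <- list()
  for (i in recs) {
    f <- strsplit(text[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("record ", i, ": expected at least 2 tab-separated fields")
    nm <- trimws(f[1L]); pa <- trimws(f[2L])
    if (nm == "") stop("record ", i, ": empty node name")
    nodes[[length(nodes) + 1L]] <- data.frame(
      name = nm,
      parent = if (pa %in% c("-", "")) NA_character_ else pa,
      aliases = if (length(f) >= 4L && nzchar(trimws(f[4L])))
        trimws(f[4L]) else NA_character_,
      line = i)
    if (length(f) >= 3L && nzchar(trimws(f[3L]))) {
      for (spec in strsplit(trimws(f[3L]), ",", fixed = TRUE)[[1L]]) {
        p <- strsplit(trimws(spec), ":", fixed = TRUE)[[1L]]
        if (length(p) != 4L)
          stop("record ", i, ": malformed variant spec '", spec,
               "' (want pos:anc:der:names)")
        pos <- suppressWarnings(as.integer(p[2L]))
        if (is.na(pos) || pos < 1L)
          stop("record ", i, ": bad position in '", spec, "'")
        vars[[length(vars) + 1L]] <- data.frame(
          node = nm, chrom = chrom, pos = pos,
          anc = toupper(p[3L]), der = toupper(p[4L]), names = p[1L])
      }
    }
  }
  if (!length(nodes)) stop("no records in haplotree input")
  nodes <- do.call(rbind, nodes)
  if (anyDuplicated(nodes$name)) {
    d <- nodes$name[duplicated(nodes$name)][1L]
    stop("duplicate node name '", d, "' at records ",
         paste(nodes$line[nodes$name == d], collapse = ", "))
  }
  nodes$line <- NULL
  variants <- if (length(vars)) do.call(rbind, vars) else empty_variants()
  # reorder columns to canonical layout (names field holds "/"-joined labels)
  if (nrow(variants))
    variants <- variants[, c("node", "chrom", "pos", "anc", "der", "names")]
  haplo_tree(nodes, variants)
}

#' Read a haplotree file
#' @param path file in the format of [parse_haplotree()]
#' @inheritParams parse_haplotree
#' @return a `haplo_tree`
#' @export
read_haplotree <- function(path, chrom = "chrY") {
  parse_haplotree(readLines(path, warn = FALSE), chrom = chrom)
}

#' Serialise a haplotree to its text format
#' @param tree a `haplo_tree`
#' @param path optional file to write; when `NULL` the lines are returned
#' @return character vector of lines, invisibly when written to a file
#' @export
write_haplotree <- function(tree, path = NULL) {
  lines <- vapply(seq_len(nrow(tree$nodes)), function(i) {
    nm <- tree$nodes$name[i]
    v <- node_variants(tree, nm)
    spec <- if (nrow(v))
      paste(sprintf("%s:%d:%s:%s", v$names, v$pos, v$anc, v$der),
            collapse = ",") else ""
    pa <- tree$nodes$parent[i]
    al <- tree$nodes$aliases[i]
    out <- paste(nm, if (is.na(pa)) "-" else pa, spec, sep = "\t")
    if (!is.na(al)) out <- paste(out, al, sep = "\t")
    out
  }, character(1L))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Newick string of the haplotree topology (names only)
#' @param tree a `haplo_tree`
#' @return single newick string terminated by ";"
#' @export
haplotree_newick <- function(tree) {
  rec <- function(nm) {
    kids <- tree_children(tree, nm)
    if (!length(kids)) return(nm)
    paste0("(", paste(vapply(kids, rec, character(1L)), collapse = ","),
           ")", nm)
  }
  paste0(rec(tree_root(tree)), ";")
}

#' Aliases of a haplogroup node
#' @param tree a `haplo_tree`
#' @param name node name
#' @return character vector of alternative labels (length 0 if none stored)
#' @export
node_aliases <- function(tree, name) {
  a <- tree$nodes$aliases[tree$nodes$name == name]
  if (!length(a) || is.na(a)) character(0) else
    trimws(strsplit(a, ",", fixed = TRUE)[[1L]])
}
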