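# SNP-count coalescence dating inside a callable-region mask, calibrated on
# an anchor node of known age and/or a fixed years-per-SNP interval.

#' Construct a callable-region mask
#'
#' Intervals follow the BED convention: 0-based, half-open `[start, end)`.
#' Variant positions in this package are 1-based, so a variant at 1-based
#' position p is inside `[start, end)` iff `start < p <= end` — the
#' conversion is done once, explicitly, in [mask_variants()].
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#' @return object of class `region_mask`; intervals sorted and checked
#'   non-overlapping, with a `total_length` field
#' @export
region_mask <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  iv <- intervals[order(intervals$chrom, intervals$start),
                  c("chrom", "start", "end")]
  iv$start <- as.numeric(iv$start); iv$end <- as.numeric(iv$end)
  if (any(iv$end <= iv$start)) stop("empty or inverted mask interval")
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv))
      if (iv$chrom[i] == iv$chrom[i - 1L] && iv$start[i] < iv$end[i - 1L])
        stop("overlapping mask intervals at ", iv$chrom[i], ":", iv$start[i])
  }
  rownames(iv) <- NULL
  structure(list(intervals = iv, total_length = sum(iv$end - iv$start)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> ", nrow(x$intervals), " interval(s), ",
      format(x$total_length, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Read a BED3 mask file
#' @param path BED file (3 columns, 0-based half-open; `#`/track lines
#'   ignored)
#' @return a [region_mask()]
#' @export
read_bed_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  f <- utils::read.table(text = lines, sep = "\t",
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "numeric", "numeric"))
  region_mask(f)
}

#' Write a mask as BED3
#' @param mask a `region_mask`
#' @param path output file
#' @export
write_bed_mask <- function(mask, path) {
  utils::write.table(mask$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Split variants by mask membership
#'
#' @param variants data.frame with `chrom` and 1-based `pos`
#' @param mask a `region_mask`
#' @return list with `in_mask` and `out_mask` data.frames and counts
#'   `n_in`, `n_out`
#' @export
mask_variants <- function(variants, mask) {
  iv <- mask$intervals
  inside <- vapply(seq_len(nrow(variants)), function(i) {
    any(iv$chrom == variants$chrom[i] &
          iv$start < variants$pos[i] & variants$pos[i] <= iv$end)
  }, logical(1L))
  list(in_mask = variants[inside, , drop = FALSE],
       out_mask = variants[!inside, , drop = FALSE],
       n_in = sum(inside), n_out = sum(!inside))
}

#' Per-branch in-mask SNP counts
#' @param tree a `haplo_tree` (typically after [attach_clades()])
#' @param mask a `region_mask`
#' @return data.frame: `node`, `k` (in-mask defining variants), `k_total`
#' @export
branch_snp_counts <- function(tree, mask) {
  out <- data.frame(node = tree$nodes$name, k = 0L, k_total = 0L)
  for (i in seq_len(nrow(out))) {
    v <- node_variants(tree, out$node[i])
    out$k_total[i] <- nrow(v)
    out$k[i] <- if (nrow(v)) mask_variants(v, mask)$n_in else 0L
  }
  out
}

#' Clock configuration for SNP-count dating
#'
#' @param anchor_node haplogroup whose age is known externally
#' @param anchor_age that age, in years before present
#' @param snp_interval two-element vector `[mu_min, mu_max]`, years per SNP
#' @param rate_mode `"anchor_path"` (calibrate years/SNP on the anchor) or
#'   `"fixed_interval"` (use `snp_interval` directly)
#' @param averaging `"mean_over_tips"` (rho-style mean SNP distance over
#'   descendant tips, the default) or `"single_path"` (one designated tip,
#'   for reproducing single-lineage arithmetic)
#' @param path_tip tip node used when `averaging = "single_path"`
#' @return object of class `clock_config`
#' @export
clock_config <- function(anchor_node = NULL, anchor_age = 4100,
                         snp_interval = c(100, 150),
                         rate_mode = c("anchor_path", "fixed_interval"),
                         averaging = c("mean_over_tips", "single_path"),
                         path_tip = NULL) {
  rate_mode <- match.arg(rate_mode)
  averaging <- match.arg(averaging)
  stopifnot(length(snp_interval) == 2L,
            snp_interval[1L] <= snp_interval[2L], anchor_age > 0)
  if (rate_mode == "anchor_path" && is.null(anchor_node))
    stop("anchor_path mode needs an anchor_node")
  if (averaging == "single_path" && is.null(path_tip))
    stop("single_path averaging needs a path_tip")
  structure(list(anchor_node = anchor_node, anchor_age = anchor_age,
                 snp_interval = snp_interval, rate_mode = rate_mode,
                 averaging = averaging, path_tip = path_tip),
            class = "clock_config")
}

tree_tips <- function(tree) {
  setdiff(tree$nodes$name, stats::na.omit(tree$nodes$parent))
}

descendant_tips <- function(tree, node) {
  tips <- tree_tips(tree)
  tips[vapply(tips, function(t) node %in% path_to_root(tree, t),
              logical(1L))]
}

# SNP distance from `node` down to each tip in `tips`: sum of branch counts
# strictly below `node` on the path
snp_distance_to_tips <- function(tree, counts, node, tips) {
  kmap <- stats::setNames(counts$k, counts$node)
  vapply(tips, function(t) {
    p <- path_to_root(tree, t)
    i <- match(node, p)
    if (is.na(i)) stop(t, " does not descend from ", node)
    if (i == length(p)) 0 else sum(kmap[p[(i + 1L):length(p)]])
  }, numeric(1L))
}

#' Calibrate the years-per-SNP rate on an anchor node
#'
#' `rate = anchor_age / D`, where `D` is the SNP distance from the anchor to
#' the present: the mean over the anchor's descendant tips of the summed
#' in-mask branch counts (rho-style), or a single designated tip's sum.
#'
#' @param tree a `haplo_tree`
#' @param counts [branch_snp_counts()] output
#' @param config a [clock_config()]
#' @return list: `rate` (years per SNP), `D` (SNP distance used)
#' @export
estimate_rate_from_anchor <- function(tree, counts, config) {
  anchor <- config$anchor_node
  if (!anchor %in% tree$nodes$name) stop("unknown anchor node: ", anchor)
  tips <- if (config$averaging == "single_path") {
    if (!config$path_tip %in% descendant_tips(tree, anchor))
      stop("path_tip does not descend from the anchor")
    config$path_tip
  } else descendant_tips(tree, anchor)
  if (!length(tips)) stop("anchor has no descendant tips")
  D <- mean(snp_distance_to_tips(tree, counts, anchor, tips))
  if (D == 0) stop("zero SNP distance below anchor: cannot calibrate")
  list(rate = config$anchor_age / D, D = D)
}

#' Date every tree node by masked SNP counts
#'
#' Each node's SNP distance to the present is the mean over its descendant
#' tips of the summed in-mask branch counts below it (its own branch does
#' not count: the node marks the *appearance* of its defining SNPs).  Under
#' `anchor_path` the age is `rate * distance` with the rate calibrated on
#' the anchor — the anchor's age then equals `anchor_age` by construction.
#' Under `fixed_interval` the age interval is
#' `[distance * mu_min, distance * mu_max]` with the midpoint reported as
#' the point age.  Ages are clamped non-increasing from the root toward the
#' tips.
#'
#' @param tree a `haplo_tree`
#' @param counts [branch_snp_counts()] output
#' @param config a [clock_config()]
#' @return object of class `dated_tree`: data.frame `node`, `k_mean` (SNP
#'   distance to present), `age`, `age_low`, `age_high`, plus attributes
#'   `rate` (NA under fixed_interval) and `tree`
#' @export
date_nodes <- function(tree, counts, config) {
  nodes <- tree$nodes$name
  k_mean <- vapply(nodes, function(n) {
    tips <- descendant_tips(tree, n)
    if (config$averaging == "single_path" && config$path_tip %in% tips)
      tips <- config$path_tip
    mean(snp_distance_to_tips(tree, counts, n, tips))
  }, numeric(1L))
  if (config$rate_mode == "anchor_path") {
    rate <- estimate_rate_from_anchor(tree, counts, config)$rate
    age <- rate * k_mean
    low <- high <- age
  } else {
    rate <- NA_real_
    low <- k_mean * config$snp_interval[1L]
    high <- k_mean * config$snp_interval[2L]
    age <- (low + high) / 2
  }
  out <- data.frame(node = nodes, k_mean = k_mean, age = age,
                    age_low = low, age_high = high)
  # clamp: no child older than its parent
  parent <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  for (n in ordered_by_depth(tree)) {
    p <- parent[[n]]
    if (is.na(p)) next
    i <- match(n, out$node); j <- match(p, out$node)
    out$age[i] <- min(out$age[i], out$age[j])
    out$age_low[i] <- min(out$age_low[i], out$age_low[j])
    out$age_high[i] <- min(out$age_high[i], out$age_high[j])
  }
  rownames(out) <- NULL
  structure(out, rate = rate, tree = tree, class = c("dated_tree",
                                                     "data.frame"))
}

ordered_by_depth <- function(tree) {
  d <- vapply(tree$nodes$name, function(n) length(path_to_root(tree, n)),
              integer(1L))
  tree$nodes$name[order(d)]
}

#' Age of one node in a dated tree
#' @param dated a `dated_tree`
#' @param node node name
#' @return numeric age in years before present
#' @export
node_age <- function(dated, node) {
  i <- match(node, dated$node)
  if (is.na(i)) stop("unknown node: ", node)
  dated$age[i]
}

#' Write a dated tree as newick with branch lengths in years
#'
#' Branch lengths are parent age minus child age, so path lengths from any
#' tip (age 0) back to the root recover node ages.  Node ages themselves are
#' in the companion table written by [write_node_age_table()].
#'
#' @param dated a `dated_tree`
#' @param path output file; `NULL` returns the string
#' @return newick string (invisibly when written)
#' @export
write_dated_newick <- function(dated, path = NULL) {
  tree <- attr(dated, "tree")
  if (is.null(tree) || !nrow(tree$nodes)) stop("empty dated tree")
  age <- stats::setNames(dated$age, dated$node)
  rec <- function(nm) {
    kids <- tree_children(tree, nm)
    lab <- if (!length(kids)) nm else
      paste0("(", paste(vapply(kids, rec, character(1L)), collapse = ","),
             ")", nm)
    pa <- tree$nodes$parent[tree$nodes$name == nm]
    if (is.na(pa)) lab else
      paste0(lab, ":", format(age[[pa]] - age[[nm]], scientific = FALSE))
  }
  nwk <- paste0(rec(tree_root(tree)), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Write the node-age table
#' @param dated a `dated_tree`
#' @param path output TSV
#' @export
write_node_age_table <- function(dated, path) {
  utils::write.table(as.data.frame(dated), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
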