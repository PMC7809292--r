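test_that("mask membership uses half-open BED intervals against 1-based positions", {
  mask <- region_mask(data.frame(chrom = "chrY", start = 100, end = 108))
  v <- data.frame(chrom = "chrY", pos = c(100L, 101L, 108L, 109L))
  mv <- mask_variants(v, mask)
  # BED [100,108) covers 1-based 101..108: pos 100 out, 101 in, 108 in, 109 out
  expect_equal(mv$in_mask$pos, c(101L, 108L))
  expect_equal(mv$n_in, 2L)
  expect_equal(mv$n_out, 2L)
  empty_like <- mask_variants(v, region_mask(data.frame(chrom = "chr1",
                                                        start = 0, end = 10)))
  expect_equal(empty_like$n_in, 0L)
  # nine variants, eight covered
  nine <- data.frame(chrom = "chrY", pos = c(101:108, 500L))
  expect_equal(mask_variants(nine, mask)$n_in, 8L)
})

test_that("BED round-trip and malformed masks", {
  mask <- region_mask(data.frame(chrom = c("chrY", "chrY"),
                                 start = c(0, 1000), end = c(10, 2000)))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed_mask(mask, p)
  expect_equal(read_bed_mask(p)$intervals, mask$intervals)
  expect_equal(read_bed_mask(p)$total_length, 1010)
  expect_error(region_mask(data.frame(chrom = "chrY", start = 5, end = 5)),
               "empty or inverted")
  expect_error(region_mask(data.frame(chrom = "chrY", start = c(0, 5),
                                      end = c(10, 15))), "overlapping")
})

test_that("branch counts respect the mask", {
  rc <- royal_clock_tree()
  counts <- branch_snp_counts(rc$tree, rc$mask)
  k <- stats::setNames(counts$k, counts$node)
  expect_equal(unname(k[c("R-SUR51", "R-SUR2", "R-ARP", "R-UVD")]),
               c(17L, 6L, 9L, 9L))
  expect_equal(unname(k["R-Y2633"]), 0L)
  # drop one ARP SNP from the mask: k falls to 8 (printed in-mask count)
  v <- node_variants(rc$tree, "R-ARP")
  hole_start <- v$pos[1] - 1
  m2 <- region_mask(data.frame(chrom = "chrY",
                               start = c(0, hole_start + 1),
                               end = c(hole_start, 1e6)))
  expect_equal(branch_snp_counts(rc$tree, m2)$k[
    counts$node == "R-ARP"], 8L)
})

test_that("anchor calibration reproduces the single-path arithmetic", {
  rc <- royal_clock_tree()
  counts <- branch_snp_counts(rc$tree, rc$mask)
  cfg <- clock_config(anchor_node = "R-Y2633", anchor_age = 4100,
                      averaging = "single_path", path_tip = "R-UVD")
  est <- estimate_rate_from_anchor(rc$tree, counts, cfg)
  expect_equal(est$D, 35)                      # 17 + 9 + 9
  expect_equal(est$rate, 4100 / 35, tolerance = 1e-12)
  # equal path sums collapse the mean to that value
  cfg2 <- clock_config(anchor_node = "R-ARP", anchor_age = 1000)
  est2 <- estimate_rate_from_anchor(rc$tree, counts, cfg2)
  expect_equal(est2$D, 9)                      # single descendant tip
  # an anchor with zero SNPs below cannot calibrate
  bare <- parse_haplotree(c("A\t-\t", "B\tA\t"))
  cnt0 <- branch_snp_counts(bare, rc$mask)
  expect_error(estimate_rate_from_anchor(
    bare, cnt0, clock_config(anchor_node = "A")), "cannot calibrate")
})

test_that("node ages reproduce the published coalescence arithmetic", {
  rc <- royal_clock_tree()
  counts <- branch_snp_counts(rc$tree, rc$mask)
  cfg <- clock_config(anchor_node = "R-Y2633", anchor_age = 4100,
                      averaging = "single_path", path_tip = "R-UVD")
  dated <- date_nodes(rc$tree, counts, cfg)
  expect_equal(node_age(dated, "R-Y2633"), 4100)          # calibration identity
  expect_equal(node_age(dated, "R-SUR51"), 4100 * 18 / 35,
               tolerance = 1e-12)                         # ~2109: the split
  expect_equal(node_age(dated, "R-ARP"), 4100 * 9 / 35, tolerance = 1e-12)
  expect_equal(node_age(dated, "R-UVD"), 0)
  # fixed-interval recipes for the youngest split: 9 SNPs at 100 y/SNP,
  # equivalently 6 in-mask SNPs at 150 y/SNP, both give 900 years
  fixed <- date_nodes(rc$tree, counts,
                      clock_config(anchor_node = "R-Y2633",
                                   rate_mode = "fixed_interval",
                                   averaging = "single_path",
                                   path_tip = "R-UVD"))
  i <- match("R-ARP", fixed$node)
  expect_equal(fixed$age_low[i], 9 * 100)
  in6 <- counts; in6$k[in6$node == "R-UVD"] <- 6L
  fixed6 <- date_nodes(rc$tree, in6,
                       clock_config(anchor_node = "R-Y2633",
                                    rate_mode = "fixed_interval",
                                    averaging = "single_path",
                                    path_tip = "R-UVD"))
  expect_equal(fixed6$age_high[match("R-ARP", fixed6$node)], 6 * 150)
})

test_that("ages are monotone from root to tips on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    co <- simulate_cohort(sim_config(n_tips = 7, seed = seed))
    tr <- genealogy_to_tree(co)
    counts <- branch_snp_counts(tr, co$config$mask)
    anchor <- tr$nodes$name[is.na(tr$nodes$parent)]
    cfg <- tryCatch(clock_config(anchor_node = anchor, anchor_age = 5000),
                    error = function(e) NULL)
    dated <- tryCatch(date_nodes(tr, counts, cfg), error = function(e) NULL)
    if (is.null(dated)) next
    parent <- stats::setNames(tr$nodes$parent, tr$nodes$name)
    for (nm in dated$node) {
      pa <- parent[[nm]]
      if (!is.na(pa))
        expect_lte(node_age(dated, nm), node_age(dated, pa) + 1e-9)
    }
  }
})

test_that("simulated node ages are recovered without bias", {
  # mu = 120 years/SNP; anchor at the root pinned to its true age; three
  # depths of the same fixed genealogy, 100 replicates
  mu <- 120
  g <- data.frame(
    name = c("N1", "N2", "N3", "T1", "T2", "T3", "T4"),
    parent = c(NA, "N1", "N2", "N1", "N2", "N3", "N3"),
    age = c(4800, 3000, 1200, 0, 0, 0, 0))
  est <- matrix(NA_real_, nrow = 100, ncol = 2,
                dimnames = list(NULL, c("N2", "N3")))
  set.seed(909)
  cfg <- sim_config(genealogy = g, snp_interval_mu = mu,
                    mask = region_mask(data.frame(chrom = "chrY", start = 0,
                                                  end = 1e6)))
  for (r in 1:100) {
    vars <- simulate_variants(g, cfg)
    tr <- haplo_tree(data.frame(name = g$name, parent = g$parent), vars)
    counts <- branch_snp_counts(tr, cfg$mask)
    dated <- tryCatch(
      date_nodes(tr, counts, clock_config(anchor_node = "N1",
                                          anchor_age = 4800)),
      error = function(e) NULL)
    if (is.null(dated)) next
    est[r, "N2"] <- node_age(dated, "N2")
    est[r, "N3"] <- node_age(dated, "N3")
  }
  for (nm in colnames(est)) {
    x <- est[!is.na(est[, nm]), nm]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g$age[g$name == nm]), 2 * se + 1e-9)
  }
})

test_that("dated newick round-trips through an independent parser", {
  skip_if_not_installed("ape")
  rc <- royal_clock_tree()
  counts <- branch_snp_counts(rc$tree, rc$mask)
  dated <- date_nodes(rc$tree, counts,
                      clock_config(anchor_node = "R-Y2633", anchor_age = 4100,
                                   averaging = "single_path",
                                   path_tip = "R-UVD"))
  p <- withr::local_tempfile(fileext = ".nwk")
  write_dated_newick(dated, p)
  ph <- ape::read.tree(p)
  expect_setequal(ph$tip.label, c("R-SUR2", "R-UVD"))
  # root-to-tip path length equals the root age for the calibrated tip
  depths <- ape::node.depth.edgelength(ph)
  tip_depth <- depths[match("R-UVD", ph$tip.label)]
  expect_equal(tip_depth, node_age(dated, "R-Y2633"), tolerance = 1e-6)
  expect_error(write_dated_newick(structure(data.frame(),
                                            class = c("dated_tree",
                                                      "data.frame"))),
               "empty")
})
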