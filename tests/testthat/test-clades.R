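test_that("only derived sites absent from the tree are collected", {
  tr <- fixture_tree()
  # matrix over two tree sites and one extra site
  m <- matrix(c("1", "1", "0",
                "1", "0", "1"), nrow = 2, byrow = TRUE,
              dimnames = list(c("X", "Y"), NULL))
  vars <- data.frame(chrom = "chrY", pos = c(1000L, 2000L, 55L),
                     anc = c("A", "G", "C"), der = c("G", "A", "T"),
                     names = c("Y2632", "Y2633", "NEW"))
  colnames(m) <- paste(vars$chrom, vars$pos, vars$der, sep = ":")
  g <- structure(m, variants = vars,
                 n_conflict = c(X = 0L, Y = 0L))
  nv <- collect_novel_variants(g, tr)
  expect_equal(nrow(nv), 1L)
  expect_equal(nv$pos, 55L)
  expect_equal(nv$carriers, "Y")
  expect_equal(nv$noncarriers, "X")
  # all sites on tree -> none
  expect_equal(nrow(collect_novel_variants(g[, 1:2], tr)), 0L)
  # site derived in no sample -> excluded
  m0 <- make_genotypes(matrix(0L, nrow = 2, ncol = 1))
  expect_equal(nrow(collect_novel_variants(m0, empty_reference_tree())), 0L)
})

test_that("the royal sharing pattern yields four nested clades 17/6/9/9", {
  nv <- novel_from_matrix(fixture_royal_matrix())
  expect_equal(nrow(nv), 41L)
  pt <- partition_clades(nv)
  expect_length(pt$clades, 4L)
  n_members <- vapply(pt$clades, function(cl) length(cl$members), integer(1))
  n_vars <- vapply(pt$clades, function(cl) length(cl$variant_keys),
                   integer(1))
  expect_equal(n_members, c(51L, 48L, 3L, 1L))
  expect_equal(n_vars, c(17L, 6L, 9L, 9L))
  # nesting: 48 under 51, 3 under 51, 1 under 3
  expect_equal(vapply(pt$clades, function(cl) cl$parent, integer(1)),
               c(NA_integer_, 1L, 1L, 3L))
  expect_setequal(pt$clades[[3]]$members, c("HU3B", "HU52", "SRB1"))
  expect_equal(pt$clades[[4]]$members, "SRB1")
  expect_equal(nrow(pt$dropped_variants), 0L)
})

test_that("all variants carried by everyone collapse to one clade", {
  m <- matrix(1L, nrow = 4, ncol = 5)
  pt <- partition_clades(novel_from_matrix(m))
  expect_length(pt$clades, 1L)
  expect_length(pt$clades[[1]]$variant_keys, 5L)
})

test_that("partition matches the unique-column oracle on clean matrices", {
  set.seed(101)
  for (rep in 1:20) {
    ns <- sample(3:6, 1)
    samples <- paste0("S", seq_len(ns))
    fam <- random_laminar_family(samples)
    m <- matrix_from_family(fam, samples)
    if (ncol(m) > 12) m <- m[, 1:12, drop = FALSE]
    if (all(colSums(m) == 0)) next
    pt <- partition_clades(novel_from_matrix(m))
    oracle <- oracle_partition_complete(m)
    got <- data.frame(
      members = vapply(pt$clades, function(cl)
        paste(cl$members, collapse = ","), character(1)),
      n_variants = vapply(pt$clades, function(cl)
        length(cl$variant_keys), integer(1)))
    expect_equal(got[order(got$members), ],
                 oracle[order(oracle$members), ],
                 ignore_attr = TRUE)
  }
})

test_that("partition is among the coarsest feasible laminar hierarchies", {
  set.seed(202)
  tested <- 0L
  for (rep in 1:20) {
    if (tested >= 10L) break
    ns <- sample(3:6, 1)
    samples <- paste0("S", seq_len(ns))
    fam <- random_laminar_family(samples)
    if (length(fam) > 4) fam <- fam[1:4]
    vpc <- sample(1:2, length(fam), replace = TRUE)
    m <- matrix_from_family(fam, samples, vars_per_clade = vpc)
    if (ncol(m) > 8) next
    # poke holes in carrier cells only (noncarrier evidence stays
    # complete), then restore a witness wherever a member lost every
    # carrier call of one of its clades
    mm <- m
    mm[m == 1 & stats::runif(length(m)) < 0.4] <- NA
    col_clade <- rep(seq_along(fam), vpc)
    for (ci in seq_along(fam)) {
      cols <- which(col_clade == ci)
      for (s in fam[[ci]]) {
        if (all(is.na(mm[s, cols])))
          mm[s, cols[sample.int(length(cols), 1)]] <- 1L
      }
    }
    nv <- novel_from_matrix(mm)
    if (!nrow(nv) || nrow(nv) > 7) next
    sig <- oracle_partition_exhaustive(nv)
    pt <- partition_clades(nv)
    expect_true(partition_signature(pt) %in% sig)
    # and the member sets equal the generating family exactly
    got <- lapply(pt$clades, `[[`, "members")
    want <- unique(lapply(fam, sort))
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
    tested <- tested + 1L
  }
  expect_gte(tested, 5L)
})

test_that("homoplasy is detected and dropped greedily", {
  # sites 1-2 define {S1,S2}; site 3 is a recurrent mutation {S2,S3}
  m <- matrix(c(1, 1, 0,
                1, 1, 1,
                0, 0, 1,
                0, 0, 0), nrow = 4, byrow = TRUE)
  g <- make_genotypes(m)
  fg <- four_gamete_check(g)
  expect_equal(nrow(fg), 2L)   # site 3 clashes with both of 1, 2
  pt <- partition_clades(novel_from_matrix(m))
  expect_equal(pt$dropped_variants$reason, "incompatible")
  expect_equal(pt$dropped_variants$key, "chrY:503000:G")
  expect_length(pt$clades, 1L)
  # clean matrices and single columns are silent
  expect_equal(nrow(four_gamete_check(make_genotypes(m[, 1:2]))), 0L)
  expect_equal(nrow(four_gamete_check(make_genotypes(m[, 3, drop = FALSE]))),
               0L)
})

test_that("clade member sets are always nested or disjoint", {
  set.seed(303)
  for (rep in 1:10) {
    ns <- sample(4:8, 1)
    m <- matrix(stats::rbinom(ns * 10, 1, 0.4), nrow = ns)
    m[stats::runif(length(m)) < 0.15] <- NA
    nv <- novel_from_matrix(m)
    if (!nrow(nv)) next
    pt <- partition_clades(nv)
    sets <- lapply(pt$clades, `[[`, "members")
    if (length(sets) < 2) next
    for (a in seq_len(length(sets) - 1)) for (b in (a + 1):length(sets)) {
      iv <- length(intersect(sets[[a]], sets[[b]]))
      expect_true(iv == 0 || iv == length(sets[[a]]) ||
                    iv == length(sets[[b]]))
    }
    # supporting variants respect membership
    nvk <- stats::setNames(seq_len(nrow(nv)), nv$key)
    for (cl in pt$clades) for (k in cl$variant_keys) {
      i <- nvk[[k]]
      expect_true(all(strsplit(nv$carriers[i], ",")[[1]] %in% cl$members))
      nc <- nv$noncarriers[i]
      if (nzchar(nc))
        expect_false(any(strsplit(nc, ",")[[1]] %in% cl$members))
    }
  }
})

test_that("discovered clades attach below the shared terminal", {
  tr <- fixture_tree()
  m <- fixture_royal_matrix()
  # remap column positions away from tree sites (already distinct by helper)
  nv <- novel_from_matrix(m)
  pt <- partition_clades(nv)
  # everyone places at R-SUR51: fabricate placements
  pl <- lapply(rownames(m), function(s)
    structure(list(terminal = "R-SUR51"), class = "placement"))
  names(pl) <- rownames(m)
  aug <- attach_clades(tr, pt, pl, nv,
                       names = c("R-SUR51-STAR", "R-SUR2", "R-ARP", "R-UVD"))
  expect_equal(tree_children(aug, "R-SUR51"), "R-SUR51-STAR")
  expect_setequal(tree_children(aug, "R-SUR51-STAR"), c("R-SUR2", "R-ARP"))
  expect_equal(tree_children(aug, "R-ARP"), "R-UVD")
  expect_equal(nrow(node_variants(aug, "R-ARP")), 9L)
  expect_equal(nrow(node_variants(aug, "R-SUR2")), 6L)
  # empty partition leaves the tree unchanged
  empty <- structure(list(clades = list(),
                          dropped_variants = data.frame()),
                     class = "clade_partition")
  expect_identical(attach_clades(tr, empty, pl, nv), tr)
  # a member on a different backbone branch is an error
  pl$HU3B <- structure(list(terminal = "R-Y2633"), class = "placement")
  expect_error(attach_clades(tr, pt, pl, nv), "different backbone")
})
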