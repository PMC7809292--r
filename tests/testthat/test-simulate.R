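test_that("generators are deterministic under a fixed seed", {
  a <- simulate_cohort(sim_config(n_tips = 6, seed = 42, n_females = 1))
  b <- simulate_cohort(sim_config(n_tips = 6, seed = 42, n_females = 1))
  expect_identical(a$genealogy, b$genealogy)
  expect_identical(a$variants, b$variants)
  expect_identical(a$observations, b$observations)
  expect_identical(a$sex_counts, b$sex_counts)
  c <- simulate_cohort(sim_config(n_tips = 6, seed = 43, n_females = 1))
  expect_false(identical(a$variants, c$variants))
})

test_that("an explicit genealogy passes through unchanged", {
  g <- data.frame(name = c("R", "A", "B"), parent = c(NA, "R", "R"),
                  age = c(2000, 0, 0))
  set.seed(1)
  expect_identical(simulate_genealogy(sim_config(genealogy = g)), g)
})

test_that("random genealogies are binary, dated and rooted as configured", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- simulate_genealogy(sim_config(n_tips = 9, root_age = 4321))
    tips <- g[g$age == 0, ]
    expect_equal(nrow(tips), 9L)
    expect_equal(max(g$age), 4321)
    expect_equal(sum(is.na(g$parent)), 1L)
    # every internal node has exactly two children
    internal <- g$name[g$age > 0]
    kids <- table(factor(g$parent, levels = internal))
    expect_true(all(kids == 2L))
    # ages decrease toward the tips
    age <- stats::setNames(g$age, g$name)
    ok <- !is.na(g$parent)
    expect_true(all(age[g$parent[ok]] >= g$age[ok]))
  }
})

test_that("mutation counts follow the Poisson clock", {
  g <- data.frame(name = c("R", "A", "B"), parent = c(NA, "R", "R"),
                  age = c(4100, 0, 0))
  cfg <- sim_config(genealogy = g, snp_interval_mu = 117)
  set.seed(99)
  counts <- replicate(500, {
    v <- simulate_variants(g, cfg)
    sum(v$node == "A")
  })
  lambda <- 4100 / 117            # ~ 35 expected SNPs on a 4100-year branch
  se <- sqrt(lambda / 500)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # chi-square goodness of fit against the Poisson pmf
  breaks <- c(-Inf, 28, 32, 35, 38, 42, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(stats::ppois(c(-Inf, 28, 32, 35, 38, 42, Inf), lambda))
  expect_gt(stats::chisq.test(as.integer(obs), p = pr)$p.value, 0.01)
  # positions never collide and always fall inside the mask
  set.seed(100)
  v <- simulate_variants(g, cfg)
  expect_equal(anyDuplicated(v$pos), 0L)
  expect_equal(mask_variants(v, cfg$mask)$n_out, 0L)
  # the rate-zero limit produces no variants
  novar <- sim_config(genealogy = g, snp_interval_mu = 1e12)
  set.seed(101)
  expect_equal(nrow(simulate_variants(g, novar)), 0L)
})

test_that("noiseless observations recover true states exactly", {
  co <- simulate_cohort(sim_config(n_tips = 6, mean_depth = 30,
                                   seq_error_rate = 0, damage_rate = 0,
                                   missing_rate = 0, seed = 7))
  tr <- genealogy_to_tree(co)
  for (s in names(co$observations)) {
    calls <- call_sample(co$observations[[s]], co$variants, call_policy())
    onpath <- co$variants$node %in% path_to_root(tr, s)
    expect_equal(calls$state, ifelse(onpath, "derived", "ancestral"))
  }
})

test_that("zero depth leaves every site missing", {
  co <- simulate_cohort(sim_config(n_tips = 4, mean_depth = 0, seed = 3))
  expect_true(all(vapply(co$observations, nrow, integer(1)) == 0L))
})

test_that("emitted files round-trip through both dialects", {
  co <- simulate_cohort(sim_config(n_tips = 5, mean_depth = 12,
                                   seq_error_rate = 0, damage_rate = 0,
                                   missing_rate = 0.1, seed = 21))
  s <- names(co$observations)[1]
  obs <- co$observations[[s]]
  skip_if(nrow(obs) == 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_readcount_tsv(obs, tsv)
  back <- read_observations(tsv, "readcount_tsv")
  expect_equal(back$pos, obs$pos)
  expect_equal(back$count_A, obs$count_A)
  expect_equal(back$count_T, obs$count_T)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_observations(obs, s, vcf)
  vobs <- read_observations(vcf, "vcf")
  expect_equal(vobs$pos, obs$pos)
  # allele calls agree between dialects in the error-free limit
  calls_tsv <- call_sample(back, co$variants, call_policy())
  calls_vcf <- call_sample(vobs, co$variants, call_policy())
  expect_equal(calls_vcf$state, calls_tsv$state)
})

test_that("damage inflates strict-mode missingness at C>T sites only", {
  g <- data.frame(name = c("R", "A", "B"), parent = c(NA, "R", "R"),
                  age = c(50000, 0, 0))
  cfg <- sim_config(genealogy = g, snp_interval_mu = 50, mean_depth = 1,
                    seq_error_rate = 0, damage_rate = 0.5, missing_rate = 0,
                    seed = 31)
  co <- simulate_cohort(cfg)
  tr <- genealogy_to_tree(co)
  strict <- call_policy(damage_mode = "strict")
  onpath <- co$variants$node %in% path_to_root(tr, "A")
  vars_anc <- co$variants[!onpath, ]          # truly ancestral sites
  calls <- call_sample(co$observations[["A"]], vars_anc, strict)
  ct <- calls$anc == "C" & calls$der == "T" |
    calls$anc == "G" & calls$der == "A"
  skip_if(sum(ct) < 30 || sum(!ct) < 30)
  off <- call_sample(co$observations[["A"]], vars_anc, call_policy())
  # the strict gate converts single-read deamination into missingness:
  # missing is elevated at damage-prone sites relative to the others
  expect_gt(mean(calls$state[ct] == "missing"),
            mean(calls$state[!ct] == "missing") + 0.1)
  # and it suppresses most of the spurious derived calls that off lets by
  expect_lt(mean(calls$state[ct] == "derived"),
            mean(off$state[ct] == "derived") / 2)
  expect_gt(mean(off$state[ct] == "derived"),
            mean(off$state[!ct] == "derived") + 0.1)
})

test_that("hidden clades vanish from the reference tree but stay in truth", {
  co <- simulate_cohort(sim_config(n_tips = 8, seed = 13))
  g <- co$genealogy
  # hide the two youngest internal nodes
  internal <- g[g$age > 0 & !is.na(g$parent), ]
  hide <- internal$name[order(internal$age)][1:2]
  ref <- make_reference_tree(g, co$variants, hide)
  expect_false(any(hide %in% ref$nodes$name))
  hidden_keys <- with(co$variants[co$variants$node %in% hide, ],
                      paste(chrom, pos, der, sep = ":"))
  expect_false(any(hidden_keys %in% tree_by_site(ref)$key))
  # hiding nothing keeps the full internal backbone (bare nodes retained
  # only when collapsing is disabled)
  ref0 <- make_reference_tree(g, co$variants, drop_unsupported = FALSE)
  expect_setequal(ref0$nodes$name, g$name[g$age > 0])
  # with collapsing on, every non-root reference node is SNP-defined
  ref1 <- make_reference_tree(g, co$variants)
  root <- g$name[is.na(g$parent)]
  expect_true(all(setdiff(ref1$nodes$name, root) %in% co$variants$node))
  expect_error(make_reference_tree(g, co$variants, "NOPE"), "unknown clade")
})

test_that("sex counts concentrate near the expected read ratios", {
  cfg <- sim_config(mean_depth = 5, seed = 17)
  set.seed(17)
  sexes <- stats::setNames(rep(c("XY", "XX"), each = 50),
                           paste0("P", 1:100))
  sc <- simulate_sex_counts(sexes, cfg)
  ry <- sc$nY / (sc$nX + sc$nY)
  expect_true(all(ry[sc$true_sex == "XY"] > 0.4 &
                    ry[sc$true_sex == "XY"] < 0.6))
  expect_true(all(ry[sc$true_sex == "XX"] < 0.016))
  # zero mismap rate gives Ry exactly zero
  cfg0 <- sim_config(mean_depth = 5, female_y_rate = 0, seed = 18)
  set.seed(18)
  sc0 <- simulate_sex_counts(c(F1 = "XX"), cfg0)
  expect_equal(sc0$nY, 0L)
})
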