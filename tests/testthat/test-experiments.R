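# Monte-Carlo experiment layer: rate tables, false-positive scans,
# distributions, uniqueness subsampling, demographic weighting and the
# reduced-reference analysis.

make_experiment_world <- function(seed = 70L) {
  panels <- list(
    A = make_panel(seed + 1L, label = "A", y_pool = 150L,
                   y_distinct = 60L),                     # heavy sharing
    B = make_panel(seed + 2L, label = "B", y_pool = 400L,
                   y_distinct = 5000L),                   # intermediate
    C = make_panel(seed + 3L, label = "C", y_pool = 120L,
                   y_distinct = 120L)                     # all-unique
  )
  list(panels = panels, ccfg = make_clr_config(seed + 50L))
}

test_that("identification rate tables carry consistent rates and errors", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 2000L, seed = 71L)
  rt <- estimate_identification_rates(
    "sibling", w$panels["B"],
    relationships = c("sibling", "half-sibling"),
    cfg = cfg, clr_cfg = w$ccfg)
  expect_identical(dim(rt$rates), c(2L, 1L))
  expect_true(all(rt$rates >= 0 & rt$rates <= 1))
  expect_equal(rt$se, sqrt(rt$rates * (1 - rt$rates) / rt$n_pairs))
  # same config + seed reproduces the counts exactly
  rt2 <- estimate_identification_rates(
    "sibling", w$panels["B"],
    relationships = c("sibling", "half-sibling"),
    cfg = cfg, clr_cfg = w$ccfg)
  expect_identical(rt$rates, rt2$rates)
  expect_error(estimate_identification_rates("cousin", w$panels["B"],
                                             cfg = cfg, clr_cfg = w$ccfg),
               "parent-offspring or sibling")
})

test_that("identification rates fall with the degree of relatedness", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 4000L, seed = 72L)
  rels <- c("sibling", "half-sibling", "cousin", "half-cousin",
            "second-cousin")
  rt <- estimate_identification_rates("sibling", w$panels["B"],
                                      relationships = rels, cfg = cfg,
                                      clr_cfg = w$ccfg)
  r <- rt$rates[, 1]
  s <- rt$se[, 1]
  # monotone non-increasing within a 3-SE margin
  expect_true(all(diff(r) < 3 * sqrt(s[-1]^2 + s[-length(s)]^2) + 1e-12))
  # power (matching truth) strictly dominates the distant relatives
  expect_gt(r["sibling"], r["cousin"] + 3 * (s["sibling"] + s["cousin"]))
})

test_that("the sibling test admits distant relatives more than the parent test", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 4000L, seed = 73L)
  rels <- c("half-sibling", "cousin")
  po <- estimate_identification_rates("parent-offspring", w$panels["B"],
                                      relationships = rels, cfg = cfg,
                                      clr_cfg = w$ccfg)
  sib <- estimate_identification_rates("sibling", w$panels["B"],
                                       relationships = rels, cfg = cfg,
                                       clr_cfg = w$ccfg)
  # sharing >= 1 allele at *every* locus (parent test) is less likely by
  # chance than averaging one shared allele per locus (sibling test)
  expect_true(all(sib$rates >= po$rates - 3 * (sib$se + po$se)))
  expect_gt(mean(sib$rates), mean(po$rates))
})

test_that("false-positive scans count positives over chunks reproducibly", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 3e4, seed = 74L)
  ccfg_easy <- make_clr_config(120L, database_size = 50)  # permissive N
  fp <- estimate_false_positive_rates("sibling", w$panels[c("A", "B")],
                                      cfg = cfg, clr_cfg = ccfg_easy,
                                      chunk_size = 7000)
  expect_true(all(is.na(fp$rates[lower.tri(fp$rates)])))
  expect_true(all(fp$rates[upper.tri(fp$rates, diag = TRUE)] >= 0))
  # the same config, seed and chunking reproduce the counts exactly
  fp2 <- estimate_false_positive_rates("sibling", w$panels[c("A", "B")],
                                       cfg = cfg, clr_cfg = ccfg_easy,
                                       chunk_size = 7000)
  expect_identical(fp$positives, fp2$positives)
  expect_equal(fp$rates, fp$positives / cfg$n_pairs)
  # zero-positive cells carry the rule-of-three upper bound
  if (any(fp$positives == 0, na.rm = TRUE))
    expect_equal(fp$upper_bound[which(fp$positives == 0)],
                 rep(3 / cfg$n_pairs, sum(fp$positives == 0, na.rm = TRUE)))
})

test_that("an all-unique Y pool yields a structurally zero FP rate", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 1e5, seed = 75L)
  ccfg_easy <- make_clr_config(121L, database_size = 1)  # maximally permissive
  fp <- estimate_false_positive_rates("sibling", w$panels["C"],
                                      cfg = cfg, clr_cfg = ccfg_easy)
  expect_identical(fp$positives[1, 1], 0)
  expect_identical(fp$rates[1, 1], 0)
})

test_that("with universal Y sharing the FP rate is the autosomal-only rate", {
  shared <- make_panel(76L, label = "S", y_pool = 200L, y_distinct = 1L)
  ccfg <- make_clr_config(122L, database_size = 20)
  cfg <- sim_config(n_pairs = 2e4, seed = 77L)
  pooled <- shared$y_sample
  fp <- estimate_false_positive_rates("sibling", list(S = shared),
                                      cfg = cfg, clr_cfg = ccfg,
                                      pooled = pooled,
                                      chunk_size = cfg$n_pairs)
  # oracle: rerun the same seeded chunk with the Y LR forced to its
  # constant value (everyone matches; count = n, upper limit 1, LR 1)
  set.seed(famsearch:::.cell_seed(cfg$seed, 1L, 0L))
  y <- famsearch:::.unrelated_y_draws(shared, shared, cfg$n_pairs)
  expect_true(all(y$y_a == y$y_b))
  blk <- famsearch:::.unrelated_genotype_block(shared, shared,
                                               cfg$n_pairs, cfg$theta)
  lr_auto <- sapply(ccfg$reference_panels, function(tb)
    autosomal_lrs(blk, "sibling", tb))
  clr <- lr_auto * 1 / ccfg$database_size
  manual <- mean(apply(clr, 1, function(v) decide(v, ccfg)))
  expect_equal(fp$rates[1, 1], manual)
})

test_that("combined-statistic distributions are complete histograms", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 3000L, seed = 78L)
  d <- clr_distribution("sibling", w$panels$B,
                        w$ccfg$reference_panels[[1]],
                        relationships = c("sibling", "second-cousin",
                                          "unrelated"),
                        cfg = cfg, database_size = 1900000)
  for (r in names(d$by_relationship)) {
    h <- d$by_relationship[[r]]
    expect_identical(sum(h$counts) + h$zero_count, h$n)
  }
  # unrelated pairs essentially never share Y here: all mass at zero
  expect_gt(d$by_relationship$unrelated$zero_count, 0.999 * cfg$n_pairs)
  # second cousins sit stochastically left of siblings
  mids <- (d$breaks[-1] + d$breaks[-length(d$breaks)]) / 2
  mu <- function(r) {
    h <- d$by_relationship[[r]]
    sum(mids * h$counts) / sum(h$counts)
  }
  expect_gt(mu("sibling"), mu("second-cousin") + 1)
})

test_that("distributions of unrelated pairs with all-unique Y collapse to zero", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 1000L, seed = 79L)
  d <- clr_distribution("sibling", w$panels$C,
                        w$ccfg$reference_panels[[1]],
                        relationships = "unrelated", cfg = cfg)
  expect_identical(d$by_relationship$unrelated$zero_count, 1000L)
})

test_that("subsample uniqueness matches exact small-case probabilities", {
  expect_identical(subsample_uniqueness(make_y_counts(rep(1, 30)), 10L,
                                        100L, seed = 80L), 1)
  # pigeonhole: 50 haplotypes x 2 copies cannot give 100 unique
  expect_identical(subsample_uniqueness(make_y_counts(rep(2, 50)), 100L,
                                        50L, seed = 81L), 0)
  # 10 singletons + 1 duplicated pair (n = 12): P(2-subsample unique)
  # = 1 - 1/C(12,2) = 65/66
  s <- make_y_counts(c(rep(1, 10), 2))
  u <- subsample_uniqueness(s, 2L, 20000L, seed = 82L)
  want <- 1 - 1 / choose(12, 2)
  expect_lt(abs(u - want), 3 * sqrt(want * (1 - want) / 20000))
  expect_error(subsample_uniqueness(s, 13L, 10L), "exceeds")
})

test_that("demographic involvement follows the pair-weighting formula", {
  # a single group is involved in everything
  f1 <- matrix(1e-6, 1, 1, dimnames = list("g", "g"))
  expect_equal(demographic_involvement(f1, gen_demographics("g", 1)),
               c(g = 1))
  # two groups, FPs only across: both groups are involved in every FP
  f2 <- matrix(c(0, 1e-6, 1e-6, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(demographic_involvement(f2,
                                       gen_demographics(c("a", "b"),
                                                        c(1, 1))),
               c(a = 1, b = 1))
  # uniform rates over three equal groups: each involved in 5/9
  f3 <- matrix(1e-6, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(demographic_involvement(f3,
                                       gen_demographics(letters[1:3],
                                                        rep(1, 3))),
               c(a = 5 / 9, b = 5 / 9, c = 5 / 9))
  # zero total mass is undefined
  expect_error(demographic_involvement(f3 * 0,
                                       gen_demographics(letters[1:3],
                                                        rep(1, 3))),
               "undefined")
})

test_that("reduced Y references reproduce the baseline at full size", {
  w <- make_experiment_world()
  cfg <- sim_config(n_pairs = 1500L, seed = 83L)
  rels <- c("sibling", "cousin")
  base <- estimate_identification_rates("sibling", w$panels["A"],
                                        relationships = rels, cfg = cfg,
                                        clr_cfg = w$ccfg)
  full <- reduced_reference_rates("sibling", w$panels["A"],
                                  relationships = rels, cfg = cfg,
                                  clr_cfg = w$ccfg,
                                  subsample_size = 150L, seed = 84L)
  expect_identical(base$rates, full$rates)
  # undersized panels are refused
  expect_error(reduced_reference_rates("sibling", w$panels["A"],
                                       cfg = cfg, clr_cfg = w$ccfg,
                                       subsample_size = 151L),
               "fewer than")
  # a genuinely reduced reference still yields a valid table, and the
  # pooled reference shrinks to panels x subsample_size
  red <- reduced_reference_rates("sibling", w$panels, relationships = rels,
                                 cfg = sim_config(n_pairs = 800L,
                                                  seed = 85L),
                                 clr_cfg = w$ccfg, subsample_size = 103L,
                                 seed = 86L)
  expect_true(all(red$rates >= 0 & red$rates <= 1))
  reduced_pool <- pool_y_references(lapply(w$panels, function(p) {
    y_haplotype_sample(p$label, p$y_sample$haplotypes[seq_len(103L)])
  }))
  expect_identical(reduced_pool$n, 3L * 103L)
})
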