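test_that("phenotype score averages the strongest phenotypes by magnitude", {
  # constant vector: any subset has the same mean
  expect_equal(gene_score(rep(0.3, 10), rnorm(20))$phenotype_score, 0.3)
  # seven most extreme of a mixed-sign vector
  rhos <- c(-1.0, -0.9, -0.8, -0.7, -0.6, -0.5, -0.4, 0.1, 0.2, 0.3)
  expect_equal(gene_score(rhos, rnorm(20))$phenotype_score, -0.7)
})

test_that("top-k selection matches brute force over all 7-subsets", {
  set.seed(91)
  for (i in 1:200) {
    v <- rnorm(10)
    got <- gene_score(v, rnorm(15))$phenotype_score
    expect_equal(got, brute_top_k_mean(v, 7))
  }
})

test_that("Mann-Whitney p matches literal enumeration on the worked example", {
  # {5,6,7} vs {1,2,3,4}: all x above all y; 2/35 two-sided
  expect_equal(mann_whitney_p(c(5, 6, 7), c(1, 2, 3, 4)), 2 / 35)
  expect_equal(enum_mw_p(c(5, 6, 7), c(1, 2, 3, 4)), 2 / 35)
})

test_that("Mann-Whitney implementation matches enumeration up to (10, 15)", {
  # the two oracles agree with each other at small sizes...
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(enum_mw_p(x, y), gf_mw_p(x, y))
  }
  # ...and the implementation matches the generating-function count
  # across a size grid up to (10, 15)
  for (sizes in list(c(2, 3), c(5, 5), c(8, 12), c(10, 15))) {
    for (i in 1:10) {
      x <- rnorm(sizes[1]); y <- rnorm(sizes[2])
      expect_equal(mann_whitney_p(x, y), gf_mw_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("ties or large groups fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 4, 5)
  expect_equal(mann_whitney_p(x, y),
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value))
  set.seed(5)
  a <- rnorm(10); b <- rnorm(30)
  expect_equal(mann_whitney_p(a, b),
               suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE)$p.value))
})

test_that("screen score combines phenotype score and p-value with a floor", {
  rhos <- rep(-0.5, 10)
  ntc <- rnorm(730, 0, 0.01)
  s <- gene_score(rhos, ntc)
  expect_equal(s$screen_score, s$phenotype_score * -log10(max(s$p_value, 1e-16)))
  expect_lt(s$screen_score, 0)
  # degenerate p of ~0 is floored at p_floor
  s2 <- gene_score(rhos, ntc, p_floor = 1e-4)
  expect_equal(s2$screen_score, s2$phenotype_score * 4)
})

test_that("genes retaining too few sgRNAs are unscored, not errors", {
  s <- gene_score(c(-1, -2), rnorm(10), min_sgrnas = 5)
  expect_true(is.na(s$screen_score))
  expect_equal(s$n_sgrnas, 2)
})

test_that("score_screen is deterministic and ranks a spiked gene last", {
  m <- test_manifest(n_genes = 8, n_ntc = 60)
  pg <- make_pseudogenes(m, 8, seed = 2)
  truth <- screen_truth(m, effects = c(SLC003 = -0.5), sigma_abund = 0.3,
                        depth_per_sgrna = 500)
  expt <- simulate_screen(m, truth, two_arm_design(8), seed = 7)
  tab1 <- score_screen(expt, m, pg, c("treated_r1", "T0_r1"), doublings = 8)
  tab2 <- score_screen(expt, m, pg, c("treated_r1", "T0_r1"), doublings = 8)
  expect_identical(tab1, tab2)
  real <- tab1[!tab1$is_pseudogene, ]
  expect_equal(real$gene[which.min(real$screen_score)], "SLC003")
  expect_equal(sum(tab1$is_pseudogene), 8)
})

test_that("two-TSS genes are scored as units and report the stronger TSS", {
  m <- build_manifest(c(SLC = 6), two_tss_genes = 2, n_ntc = 60, seed = 3)
  pg <- make_pseudogenes(m, 6, seed = 2)
  truth <- screen_truth(m, depth_per_sgrna = 300)
  expt <- simulate_screen(m, truth, two_arm_design(6), seed = 9)
  tab <- score_screen(expt, m, pg, c("treated_r1", "T0_r1"), doublings = 6)
  real <- tab[!tab$is_pseudogene, ]
  expect_equal(nrow(real), 6)           # one row per gene despite 2 TSSs
  expect_equal(anyDuplicated(real$gene), 0)
})

test_that("replicate averaging is the arithmetic mean and keeps per-replicate scores", {
  t1 <- scored_table(c("g1", "g2"), c(0.4, -1), c(0.1, -0.1))
  t2 <- scored_table(c("g1", "g2"), c(0.6, -1), c(0.2, -0.3))
  avg <- average_replicates(list(t1, t2))
  expect_equal(avg$screen_score[avg$gene == "g1"], 0.5)
  expect_equal(avg$rep_screen_score_2[avg$gene == "g1"], 0.6)
  expect_identical(average_replicates(list(t1, t1))$screen_score,
                   t1$screen_score)
  t3 <- scored_table(c("gX", "g2"), c(1, 1), c(0, 0))
  expect_error(average_replicates(list(t1, t3)),
               class = "screenflux_alignment_error")
  # three replicates supported
  expect_equal(average_replicates(list(t1, t1, t2))$screen_score[2],
               mean(c(-1, -1, -1)))
})
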