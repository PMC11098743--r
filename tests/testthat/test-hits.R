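test_that("thresholds come from the pseudogene extremes", {
  tab <- scored_table(c("g1", "g2", "g3"), c(0.6, -0.5, 0.1),
                      c(0.49, -0.40, 0.2))
  th <- pseudogene_thresholds(tab)
  expect_equal(th$upper, 0.49)
  expect_equal(th$lower, -0.40)
  hits <- call_hits(tab)
  expect_equal(hits$class[hits$gene == "g1"], "enriched")
  expect_equal(hits$class[hits$gene == "g2"], "depleted")
  expect_equal(hits$class[hits$gene == "g3"], "none")
})

test_that("a degenerate all-zero null makes any nonzero score significant", {
  tab <- scored_table(c("g1", "g2"), c(0.01, -0.01), c(0, 0, 0))
  hits <- call_hits(tab)
  expect_equal(hits$class[!hits$is_pseudogene], c("enriched", "depleted"))
})

test_that("per-replicate pseudogene scores give the stringent threshold", {
  t1 <- scored_table("g1", -1, c(0.1, -0.2))
  t2 <- scored_table("g1", -1, c(0.3, -0.05))
  avg <- average_replicates(list(t1, t2))
  th <- pseudogene_thresholds(avg, per_replicate = TRUE)
  expect_equal(th$upper, 0.3)   # extreme before averaging
  expect_equal(th$lower, -0.2)
  th_avg <- pseudogene_thresholds(avg, per_replicate = FALSE)
  expect_equal(th_avg$upper, 0.2)
  expect_equal(th_avg$lower, -0.125)
})

test_that("untreated-arm exclusion follows the floor and overrides", {
  cond <- scored_table(c("gA", "gB"), c(-0.3, 1.8), c(0.05, -0.05))
  untreated <- scored_table(c("gA", "gB"), c(-0.2, -0.2), c(0.01, -0.01))
  hits <- call_hits(cond, untreated = untreated)
  # significant but untreated score -0.2 < -0.12: excluded
  expect_equal(hits$class[hits$gene == "gA"], "excluded")
  # very strong resistant (> 1.5) keeps its call despite the untreated score
  expect_equal(hits$class[hits$gene == "gB"], "enriched")
  # hypersensitive override: deeply depleted conditions survive too
  cond2 <- scored_table("gC", -2.0, c(0.05, -0.05))
  untr2 <- scored_table("gC", -0.2, c(0.01, -0.01))
  expect_equal(call_hits(cond2, untreated = untr2)$class[1], "depleted")
})

test_that("tables without pseudogenes cannot be thresholded", {
  tab <- scored_table("g1", 1, numeric(0))
  tab <- tab[!tab$is_pseudogene, ]
  class(tab) <- c("gene_score_table", "data.frame")
  expect_error(call_hits(tab), class = "screenflux_cannot_threshold")
})

test_that("normalization to the most depleted gene lands its score at -1", {
  tab <- scored_table(c("g1", "g2", "g3"), c(-2, -1, 0.5), c(0.1, -0.1))
  out <- normalize_to_most_depleted(tab)
  real <- out$screen_score[!out$is_pseudogene]
  expect_equal(real, c(-1, -0.5, 0.25))
  # idempotent once the minimum is -1
  expect_equal(normalize_to_most_depleted(out)$screen_score,
               out$screen_score)
  # no negative score: warn and pass through
  pos <- scored_table(c("g1", "g2"), c(0.2, 0.4), c(0.1, -0.1))
  pos$screen_score[4] <- 0.1  # make the pseudogene side harmless too
  pos2 <- scored_table(c("g1", "g2"), c(0.2, 0.4), c(0.1, 0.05))
  expect_warning(out2 <- normalize_to_most_depleted(pos2))
  expect_equal(out2$screen_score, pos2$screen_score)
})

test_that("condition correlations use significant genes and Pearson", {
  set.seed(8)
  scores <- rnorm(10)
  t1 <- scored_table(paste0("g", 1:10), scores, c(1e-3, -1e-3))
  t1 <- call_hits(t1)  # everything beyond the tiny null is significant
  t2 <- scored_table(paste0("g", 1:10), -scores, c(1e-3, -1e-3))
  t2 <- call_hits(t2)
  cc <- condition_correlation(list(a = t1, b = t2))
  expect_equal(cc$r["a", "a"], 1)
  expect_equal(cc$r["a", "b"], -1)
  # hand-computed covariance ratio on an independent pair
  other <- rnorm(10)
  t3 <- call_hits(scored_table(paste0("g", 1:10), other, c(1e-3, -1e-3)))
  cc2 <- condition_correlation(list(a = t1, c = t3))
  r_hand <- sum((scores - mean(scores)) * (other - mean(other))) /
    sqrt(sum((scores - mean(scores))^2) * sum((other - mean(other))^2))
  expect_equal(cc2$r["a", "c"], r_hand)
  expect_true(all(cc2$p >= 0 & cc2$p <= 1))
})

test_that("correlation needs at least three significant genes", {
  t1 <- call_hits(scored_table(paste0("g", 1:5), rep(0, 5), c(1, -1)))
  t2 <- call_hits(scored_table(paste0("g", 1:5), rep(0, 5), c(1, -1)))
  expect_error(condition_correlation(list(a = t1, b = t2)),
               class = "screenflux_undefined_correlation")
})

test_that("the magnitude display filter drops uniformly weak genes", {
  t1 <- call_hits(scored_table(paste0("g", 1:4), c(-0.5, -0.15, 0.3, -0.25),
                               c(1e-3, -1e-3)))
  t2 <- call_hits(scored_table(paste0("g", 1:4), c(-0.4, 0.05, 0.2, -0.22),
                               c(1e-3, -1e-3)))
  cc <- condition_correlation(list(a = t1, b = t2), magnitude_filter = TRUE)
  expect_false("g2" %in% cc$genes)  # never < -0.20 nor > 0.10
  expect_setequal(cc$genes, c("g1", "g3", "g4"))
})
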