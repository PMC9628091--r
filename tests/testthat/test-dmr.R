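# Split, bootstrap subsets, Welch test, q-values, subset screen,
# intersection and rank filtering.

test_that("the stratified split reproduces the reference cohort counts", {
  co <- toy_cohort(sprintf("S%03d", 1:143),
    c(rep("good", 109), rep("poor", 34)))
  sp <- stratified_split(co, train_fraction = 0.85, seed = 2)
  grp <- function(ids) table(co$group[match(ids, co$sample_id)])
  expect_equal(as.integer(grp(sp$train)), c(93L, 29L))
  expect_equal(as.integer(grp(sp$test)), c(16L, 5L))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), co$sample_id)

  co2 <- toy_cohort(sprintf("T%02d", 1:20), rep(c("good", "poor"), each = 10))
  sp2 <- stratified_split(co2, train_fraction = 0.5, seed = 1)
  expect_equal(as.integer(grp2 <- table(
    co2$group[match(sp2$train, co2$sample_id)])), c(5L, 5L))

  co_small <- toy_cohort(c("A", "B", "C"), c("good", "good", "poor"))
  expect_error(stratified_split(co_small), "fewer than 2")
})

test_that("bootstrap subsets preserve group composition and size", {
  co <- toy_cohort(sprintf("S%03d", 1:143),
    c(rep("good", 109), rep("poor", 34)))
  sp <- stratified_split(co, seed = 2)
  subs <- draw_subsets(sp$train, co, n_subsets = 3, seed = 5)
  expect_length(subs, 3L)
  for (s in subs) {
    expect_length(s, 122L)
    tab <- table(co$group[match(s, co$sample_id)])
    expect_equal(as.integer(tab), c(93L, 29L))
  }
  expect_identical(draw_subsets(sp$train, co, 3, seed = 5), subs)
  expect_length(draw_subsets(sp$train, co, n_subsets = 1, seed = 5), 1L)
})

test_that("welch_test agrees with the reference implementation", {
  w <- welch_test(c(0.2, 0.3, 0.4), c(0.8, 0.9, 1.0))
  expect_equal(w$diff, -0.6, tolerance = 1e-12)
  expect_equal(w$t, -7.348, tolerance = 1e-3)
  expect_equal(w$df, 4.0, tolerance = 1e-10)
  expect_equal(w$p, 0.0018, tolerance = 1e-1)
  ref <- t.test(c(0.2, 0.3, 0.4), c(0.8, 0.9, 1.0), var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)

  same <- welch_test(c(0.5, 0.6), c(0.5, 0.6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- welch_test(c(0.2, 0.2, 0.2), c(0.9, 0.9))
  expect_true(is.finite(degen$p) && degen$p > 0 && degen$p < 1e-300)
  expect_error(welch_test(0.5, c(0.1, 0.2)), ">= 2")
})

test_that("welch equals the pooled t-test under equal variances and sizes", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(8)
    y <- rnorm(8) + 0.5
    y <- (y - mean(y)) / sd(y) * sd(x) + mean(y) # force equal variance
    w <- welch_test(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH q-values match the worked example and the reference", {
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.5)),
    c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_qvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_qvalues(0.37), 0.37)
  expect_error(fdr_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdr_qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(fdr_qvalues(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # empirical-null variant never exceeds BH and stays in [0, 1]
  p <- runif(100)
  q <- fdr_qvalues(p, method = "empirical-null")
  expect_true(all(q <= fdr_qvalues(p) + 1e-15))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("screen_subset standardizes differences across tested bins", {
  # 3 bins with group differences -0.5, 0, +0.5 -> z = -1, 0, 1
  vals <- rbind(
    c(0.2, 0.2, 0.7, 0.7),
    c(0.5, 0.5, 0.5, 0.5),
    c(0.9, 0.9, 0.4, 0.4)
  )
  vals <- vals + matrix(rnorm(12, 0, 1e-6), 3) # break zero variances
  m <- toy_amf(pmin(pmax(vals, 0), 1))
  co <- toy_cohort(m$samples, c("good", "good", "poor", "poor"))
  sc <- screen_subset(m, m$samples, co, coverage_threshold = 0.5,
    z_threshold = 2, q_threshold = 0.05)
  expect_equal(sc$stats$z, c(-1, 0, 1), tolerance = 1e-3)
  expect_equal(sc$stats$diff, c(-0.5, 0, 0.5), tolerance = 1e-4)
})

test_that("coverage gating and threshold monotonicity hold", {
  set.seed(6)
  cfg <- sim_config(n_good = 20L, n_poor = 10L, n_bins = 500L, n_dmr = 25L,
    seed = 41L)
  built <- build_cohort_matrix(cfg, with_qc = FALSE)
  m <- built$matrix
  co <- built$sim$cohort
  sp <- stratified_split(co, seed = 1)
  sub <- draw_subsets(sp$train, co, 1, seed = 2)[[1]]
  strict <- screen_subset(m, sub, co, z_threshold = 2, q_threshold = 0.05)
  loose_q <- screen_subset(m, sub, co, z_threshold = 2, q_threshold = 0.20)
  loose_z <- screen_subset(m, sub, co, z_threshold = 1, q_threshold = 0.05)
  expect_true(all(strict$dmrs %in% loose_q$dmrs))
  expect_true(all(strict$dmrs %in% loose_z$dmrs))
  # higher coverage threshold tests fewer bins
  hi_cov <- screen_subset(m, sub, co, coverage_threshold = 0.99)
  expect_lte(hi_cov$n_tested, strict$n_tested)
})

test_that("a null cohort stays under the joint q/z false-selection budget", {
  cfg <- sim_config(n_good = 30L, n_poor = 15L, n_bins = 1500L, n_dmr = 0L,
    seed = 77L)
  built <- build_cohort_matrix(cfg, with_qc = FALSE)
  co <- built$sim$cohort
  sp <- stratified_split(co, seed = 3)
  # on unique samples the joint q/z gates select essentially nothing
  sc <- screen_subset(built$matrix, sp$train, co)
  expect_lte(length(sc$dmrs) / sc$n_tested, 0.01)
  frac_q <- mean(sc$stats$q < 0.05)
  expect_lte(frac_q, 0.05 + 3 * sqrt(0.05 * 0.95 / sc$n_tested))

  # bootstrap duplication inflates single-subset selection, which the
  # three-way intersection is there to suppress
  subs <- draw_subsets(sp$train, co, 3, seed = 4)
  screens <- lapply(subs, function(s) screen_subset(built$matrix, s, co))
  sel <- suppressWarnings(intersect_and_rank(screens))
  expect_lte(length(sel$intersection) / screens[[1]]$n_tested, 0.01)
})

fake_screen <- function(ids, q, z) {
  coords <- data.table::data.table(
    bin_id = ids,
    chrom = "chr1",
    start = seq_along(ids) * 100L,
    end = seq_along(ids) * 100L + 100L
  )
  stats <- cbind(coords, data.table::data.table(
    q = q, z = z, direction = "hypo"
  ))
  structure(list(stats = stats, dmrs = ids, n_tested = length(ids)),
    class = "subset_screen")
}

test_that("intersection and rank filtering follow the worked toys", {
  s1 <- fake_screen(c("A", "B", "C"), c(0.01, 0.02, 0.03), c(-3, -3, -3))
  s2 <- fake_screen(c("B", "C", "D"), c(0.01, 0.02, 0.03), c(-3, -3, -3))
  s3 <- fake_screen(c("B", "C"), c(0.01, 0.02), c(-3, -3))
  out <- intersect_and_rank(list(s1, s2, s3), top_k = 500)
  expect_setequal(out$intersection, c("B", "C"))
  expect_setequal(out$candidates, c("B", "C")) # top_k >= |intersection|

  # ranks (B: 1,1,2), (C: 2,3,1), (E: 3,2,3), top_k = 2 -> only B
  t1 <- fake_screen(c("B", "C", "E"), c(0.01, 0.02, 0.03), c(-5, -4, -3))
  t2 <- fake_screen(c("B", "E", "C"), c(0.01, 0.02, 0.03), c(-5, -4, -3))
  t3 <- fake_screen(c("C", "B", "E"), c(0.01, 0.02, 0.03), c(-5, -4, -3))
  out2 <- intersect_and_rank(list(t1, t2, t3), top_k = 2)
  expect_equal(out2$candidates, "B")

  s_disjoint <- fake_screen(c("X", "Y"), c(0.01, 0.02), c(-3, -3))
  expect_warning(out3 <- intersect_and_rank(list(s1, s_disjoint)), "empty")
  expect_length(out3$candidates, 0L)
  expect_error(intersect_and_rank(list(s1)), ">= 2")
})

test_that("candidate-set containment holds on simulated screens", {
  cfg <- sim_config(n_good = 25L, n_poor = 12L, n_bins = 800L, n_dmr = 40L,
    seed = 19L)
  built <- build_cohort_matrix(cfg, with_qc = FALSE)
  co <- built$sim$cohort
  sp <- stratified_split(co, seed = 5)
  subs <- draw_subsets(sp$train, co, 3, seed = 6)
  screens <- lapply(subs, function(s) screen_subset(built$matrix, s, co))
  sel <- intersect_and_rank(screens, top_k = 500)
  expect_true(all(sel$candidates %in% sel$intersection))
  for (sc in screens) expect_true(all(sel$intersection %in% sc$dmrs))
  expect_lte(length(sel$intersection), min(lengths(lapply(screens, `[[`, "dmrs"))))
})

test_that("candidate PCA freezes the training transform for projection", {
  cfg <- sim_config(n_good = 15L, n_poor = 8L, n_bins = 400L, n_dmr = 30L,
    missing_target = 0, seed = 59L)
  built <- build_cohort_matrix(cfg, with_qc = FALSE)
  co <- built$sim$cohort
  m <- built$matrix
  sp <- stratified_split(co, seed = 7)
  cand <- intersect(built$sim$truth$dmr_bin_ids, m$bins$bin_id)[1:10]
  pc <- candidate_pca_check(m, cand, co, sp$train, sp$test)
  expect_equal(ncol(pc$train_scores), length(cand))
  expect_equal(nrow(pc$test_scores), length(sp$test))

  # a "test" sample identical to a training sample projects identically
  pc2 <- candidate_pca_check(m, cand, co, sp$train,
    c(sp$train[1], sp$test[-1]))
  expect_equal(unname(pc2$test_scores[1, ]), unname(pc2$train_scores[
    match(sp$train[1], sp$train), ]), tolerance = 1e-10)

  one <- candidate_pca_check(m, cand[1], co, sp$train, sp$test)
  expect_equal(ncol(one$train_scores), 1L)
})
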