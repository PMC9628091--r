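# ROC/AUC, forest training, marker ranking, annotation, gene export.

test_that("ROC handles the canonical separation cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
    c("good", "good", "poor", "poor"))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6),
    rep(c("good", "poor"), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
    c("poor", "poor", "good", "good"))$auc, 0.0)
  expect_error(roc_auc(c(0.1, 0.2), c("good", "good")), "both classes")
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney statistic", {
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(3:30, 1)
    n0 <- sample(3:30, 1)
    scores <- c(rnorm(n1, 0.5), rnorm(n0))
    # ties included half the time
    if (i %% 2 == 0) scores <- round(scores, 1)
    labels <- c(rep("good", n1), rep("poor", n0))
    auc <- roc_auc(scores, labels)$auc
    u <- unname(wilcox.test(scores[labels == "good"],
      scores[labels == "poor"], exact = FALSE)$statistic)
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference when available", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- runif(40)
  labels <- rep(c("good", "poor"), 20)
  mine <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("poor", "good"), direction = "<", quiet = TRUE
  )))
  expect_equal(mine, ref, tolerance = 1e-12)
})

make_rf_fixture <- function(seed = 71L, n_bins = 300L, n_dmr = 25L) {
  cfg <- sim_config(n_good = 30L, n_poor = 14L, n_bins = n_bins,
    n_dmr = n_dmr, seed = seed)
  built <- build_cohort_matrix(cfg, with_qc = FALSE)
  co <- built$sim$cohort
  sp <- stratified_split(co, seed = 8)
  cand <- intersect(built$sim$truth$dmr_bin_ids, built$matrix$bins$bin_id)
  list(m = built$matrix, co = co, sp = sp, cand = cand,
    truth = built$sim$truth, gene_model = built$sim$gene_model)
}

test_that("train_forest is seeded, reproducible, and leak-guarded", {
  fx <- make_rf_fixture()
  cfgrf <- rf_config(n_folds = 4, n_repeats = 2, n_trees = 100, seed = 9)
  m1 <- train_forest(fx$m, fx$cand, fx$co, fx$sp$train, fx$sp$test, cfgrf)
  m2 <- train_forest(fx$m, fx$cand, fx$co, fx$sp$train, fx$sp$test, cfgrf)
  expect_identical(m1$importance, m2$importance)
  expect_identical(m1$roc_test$auc, m2$roc_test$auc)
  expect_equal(m1$best_mtry, m2$best_mtry)
  expect_true(m1$roc_test$auc >= 0 && m1$roc_test$auc <= 1)
  expect_true(all(m1$importance$gini >= 0))

  # single-class training set errors out
  co_one <- fx$co
  co_one$group <- "good"
  co_one$group[co_one$sample_id == fx$sp$test[1]] <- "poor"
  expect_error(
    train_forest(fx$m, fx$cand, co_one, fx$sp$train, fx$sp$test, cfgrf),
    "single class"
  )
})

test_that("planted features dominate the importance ranking", {
  fx <- make_rf_fixture()
  # candidates: planted DMRs plus an equal number of null bins
  null_bins <- setdiff(fx$m$bins$bin_id, fx$truth$dmr_bin_ids)
  cand <- c(fx$cand, null_bins[seq_along(fx$cand)])
  cfgrf <- rf_config(n_folds = 4, n_repeats = 1, n_trees = 200, seed = 10)
  mod <- train_forest(fx$m, cand, fx$co, fx$sp$train, fx$sp$test, cfgrf)
  imp <- mod$importance
  planted <- imp$gini[imp$bin_id %in% fx$truth$dmr_bin_ids]
  nulls <- imp$gini[!imp$bin_id %in% fx$truth$dmr_bin_ids]
  expect_gt(median(planted), median(nulls))
  expect_gt(mean(planted > median(nulls)), 0.9)
})

test_that("duplicate features split importance but keep the signal on top", {
  fx <- make_rf_fixture()
  m <- fx$m
  sig <- fx$cand[1]
  # duplicate the signal bin under a new id
  dup_id <- "chr9:0-100"
  vals <- rbind(m$values, m$values[match(sig, m$bins$bin_id), ])
  bins <- rbind(m$bins, data.table::data.table(
    bin_id = dup_id, chrom = "chr9", start = 0L, end = 100L, n_cpgs = 5L))
  m2 <- amf_matrix(vals, bins, m$samples)
  null_bins <- setdiff(m$bins$bin_id, fx$truth$dmr_bin_ids)[1:20]
  cand <- c(sig, dup_id, null_bins)
  mod <- train_forest(m2, cand, fx$co, fx$sp$train, fx$sp$test,
    rf_config(n_folds = 4, n_repeats = 1, n_trees = 300, seed = 11))
  imp <- mod$importance
  pair <- sum(imp$gini[imp$bin_id %in% c(sig, dup_id)])
  expect_gt(pair, max(imp$gini[imp$bin_id %in% null_bins]))
})

test_that("rank_markers orders by importance with coordinate tie-breaks", {
  fx <- make_rf_fixture()
  fake_model <- structure(list(
    importance = data.table::data.table(
      bin_id = c("chr1:300-400", "chr1:100-200", "chr2:0-100", "chr1:0-100"),
      gini = c(2, 5, 1, 1)
    ),
    config = rf_config(top_n = 3)
  ), class = "marker_model")
  m4 <- amf_matrix(
    fx$m$values[1:4, , drop = FALSE],
    data.table::data.table(
      bin_id = fake_model$importance$bin_id,
      chrom = c("chr1", "chr1", "chr2", "chr1"),
      start = c(300L, 100L, 0L, 0L), end = c(400L, 200L, 100L, 100L),
      n_cpgs = 5L
    ),
    fx$m$samples
  )
  mk <- rank_markers(fake_model, m4, fx$co, top_n = 3)
  # gini 5 first, then 2, then the tie (1, 1) broken by coordinate
  expect_equal(mk$bin_id, c("chr1:100-200", "chr1:300-400", "chr1:0-100"))
  expect_true(all(c("median_good", "iqr_good", "median_poor", "iqr_poor")
    %in% names(mk)))

  expect_warning(mk_all <- rank_markers(fake_model, m4, fx$co, top_n = 10),
    "truncated")
  expect_equal(nrow(mk_all), 4L)
  expect_equal(nrow(rank_markers(fake_model, m4, fx$co, top_n = 0)), 0L)
})

test_that("marker annotation uses the exon > intron > intergenic priority", {
  gm <- data.frame(
    chrom = "chr1",
    start = c(1000L, 1200L, 1900L),
    end = c(1200L, 1900L, 2100L),
    gene = "GENEA",
    feature = c("exon", "intron", "exon")
  )
  mk <- data.table::data.table(
    bin_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chrZ"),
    start = c(1050L, 1150L, 1300L, 0L),
    end = c(1150L, 1250L, 1400L, 100L)
  )
  out <- annotate_markers(mk, gm)
  expect_equal(out$feature, c("exon", "exon", "intron", "intergenic"))
  expect_equal(out$nearest_gene[1:3], rep("GENEA", 3))
  expect_equal(out$gene_distance[1:3], c(0L, 0L, 0L))
  expect_true(is.na(out$nearest_gene[4])) # chromosome absent from model

  far <- data.table::data.table(bin_id = "e", chrom = "chr1",
    start = 5000L, end = 5100L)
  out2 <- annotate_markers(far, gm)
  expect_equal(out2$feature, "intergenic")
  expect_gt(out2$gene_distance, 0) # marker right of the gene
})

test_that("gene lists are deduplicated and alphabetical", {
  ann <- data.frame(nearest_gene = c("B", "A", "A", NA))
  f <- tempfile()
  genes <- export_gene_list(ann, f)
  expect_equal(readLines(f), c("A", "B"))
  expect_warning(export_gene_list(data.frame(nearest_gene = NA_character_),
    f), "empty")
})
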