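# Binning, AMF computation, and QC gates.

test_that("conversion rate is one minus the CHH methylation fraction", {
  chh <- make_calls("chr1", c(0L, 10L), c(3L, 2L), c(600L, 400L),
    context = "CHH")
  expect_equal(conversion_rate(chh), 1 - 5 / 1000)

  none <- make_calls("chr1", 0L, 0L, 500L, context = "CHH")
  expect_equal(conversion_rate(none), 1.0)

  cpg_only <- make_calls("chr1", 0L, 1L, 2L, context = "CpG")
  expect_error(conversion_rate(cpg_only), "unratable|CHH")
})

test_that("the conversion gate at exactly 99% is strict", {
  amf <- data.frame(bin_id = "chr1:0-100", chrom = "chr1", start = 0L,
    end = 100L, n_cpgs = 5L, amf = 0.9, depth = 50, n_covered = 5L)
  chh_98 <- make_calls("chr1", 0L, 2L, 100L, context = "CHH")
  expect_false(sample_qc(amf, chh_98)$pass) # 0.98 <= 0.99
  chh_99 <- make_calls("chr1", 0L, 1L, 100L, context = "CHH")
  expect_false(sample_qc(amf, chh_99)$pass) # 0.99 not > 0.99
  chh_ok <- make_calls("chr1", 0L, 1L, 1000L, context = "CHH")
  expect_true(sample_qc(amf, chh_ok)$pass)
})

test_that("depth summary is the median per-bin average CpG depth", {
  amf <- data.frame(
    bin_id = c("chr1:0-100", "chr1:100-200", "chr1:200-300"),
    chrom = "chr1", start = c(0L, 100L, 200L), end = c(100L, 200L, 300L),
    n_cpgs = 5L, amf = c(0.9, 0.8, NA),
    depth = c(50, 10, 0), n_covered = c(5L, 5L, 0L)
  )
  chh <- make_calls("chr1", 0L, 0L, 1000L, context = "CHH")
  qc <- sample_qc(amf, chh)
  expect_equal(qc$depth_summary, median(c(50 / 5, 10 / 5))) # uncovered bin excluded
  expect_true(qc$conversion_rate > 0.99)
  expect_true(qc$pass) # median 6 >= 3 and conversion 1 > 0.99
})

test_that("compute_amf is the depth-weighted methylated fraction per eligible bin", {
  scheme <- bin_scheme(c(chr1 = 300L), bin_width = 100L, min_cpgs = 5L)
  catalog <- data.frame(
    chrom = "chr1",
    pos = c(0L, 10L, 20L, 30L, 40L, # bin 1: 5 CpGs
      110L, 120L, 130L, 140L, 150L, # bin 2: 5 CpGs, uncovered
      210L, 220L, 230L, 240L) # bin 3: only 4 CpGs -> ineligible
  )
  cs <- make_calls("chr1", c(0L, 10L, 210L), c(3L, 2L, 5L), c(5L, 3L, 5L))
  a <- compute_amf(cs, scheme, catalog)
  expect_equal(a$bin_id, c("chr1:0-100", "chr1:100-200"))
  expect_equal(a$amf[1], 5 / 8) # (3+2)/(5+3)
  expect_true(is.na(a$amf[2])) # eligible but uncovered -> missing
  expect_false("chr1:200-300" %in% a$bin_id) # 4 CpGs excluded
})

test_that("count_cpgs_per_bin respects half-open bin boundaries", {
  scheme <- bin_scheme(c(chr1 = 250L), bin_width = 100L)
  out <- count_cpgs_per_bin(data.frame(chrom = "chr1", pos = c(99L, 100L)),
    scheme)
  expect_equal(out$bin_id, c("chr1:0-100", "chr1:100-200"))
  expect_equal(out$n_cpgs, c(1L, 1L))
  # truncated last bin
  out2 <- count_cpgs_per_bin(data.frame(chrom = "chr1", pos = 210L), scheme)
  expect_equal(out2$bin_id, "chr1:200-250")
  expect_equal(nrow(count_cpgs_per_bin(
    data.frame(chrom = character(), pos = integer()), scheme)), 0L)
  expect_error(count_cpgs_per_bin(
    data.frame(chrom = "chr1", pos = 250L), scheme), "beyond")
})

test_that("assemble_matrix applies the strict null-fraction bound", {
  mk_amf <- function(amf_vals) {
    data.frame(bin_id = "chr1:0-100", chrom = "chr1", start = 0L,
      end = 100L, n_cpgs = 5L, amf = amf_vals, depth = 10, n_covered = 5L)
  }
  lst10 <- setNames(
    lapply(1:10, function(i) mk_amf(if (i == 1) NA_real_ else 0.9)),
    sprintf("S%02d", 1:10))
  asm <- assemble_matrix(lst10, qc = NULL)
  expect_equal(asm$n_bins_retained, 0L) # 1/10 = 0.10 is not < 0.10

  lst20 <- setNames(
    lapply(1:20, function(i) mk_amf(if (i == 1) NA_real_ else 0.9)),
    sprintf("S%02d", 1:20))
  expect_equal(assemble_matrix(lst20, qc = NULL)$n_bins_retained, 1L) # 0.05

  lst_all_na <- setNames(lapply(1:5, function(i) mk_amf(NA_real_)),
    sprintf("S%02d", 1:5))
  expect_equal(assemble_matrix(lst_all_na, qc = NULL)$n_bins_retained, 0L)

  qc_fail <- setNames(lapply(1:10, function(i) {
    list(sample_id = sprintf("S%02d", i), pass = FALSE)
  }), sprintf("S%02d", 1:10))
  expect_error(assemble_matrix(lst10, qc_fail), "failed QC")
})

test_that("per-bin AMF converges to the generator's true means at high depth", {
  cfg <- sim_config(n_good = 10L, n_poor = 10L, n_bins = 1000L,
    n_dmr = 0L, depth_mean = 100, missing_target = 0, sparse_fraction = 0,
    mask_fraction = 0, seed = 91L)
  built <- build_cohort_matrix(cfg, with_qc = FALSE)
  truth <- built$sim$truth$per_bin_group_means
  idx <- match(built$matrix$bins$bin_id, truth$bin_id)
  bias <- rowMeans(built$matrix$values, na.rm = TRUE) - truth$mean_poor[idx]
  expect_lt(abs(mean(bias)), 0.01)
})

test_that("eligibility and retention respond monotonically to their knobs", {
  cfg <- sim_config(n_good = 8L, n_poor = 6L, n_bins = 300L, n_dmr = 10L,
    seed = 17L)
  sim <- simulate_cohort(cfg)
  n_eligible <- function(min_cpgs) {
    scheme <- bin_scheme(sim$chrom_sizes, 100L, min_cpgs)
    b <- count_cpgs_per_bin(sim$catalog, scheme)
    sum(b$n_cpgs >= min_cpgs)
  }
  sizes <- vapply(c(1L, 5L, 8L, 11L), n_eligible, 0L)
  expect_true(all(diff(sizes) <= 0))

  built <- build_cohort_matrix(cfg, with_qc = FALSE, max_null_fraction = 0.10)
  built0 <- build_cohort_matrix(cfg, with_qc = FALSE, max_null_fraction = 0.02)
  expect_lte(built0$assembly$n_bins_retained, built$assembly$n_bins_retained)
})
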