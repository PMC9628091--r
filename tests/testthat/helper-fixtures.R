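# Shared fixtures: tiny call sets, quick cohort -> AMF matrix builders.

make_calls <- function(chrom, pos, meth, tot, context = "CpG",
                       sample_id = "S1") {
  methylation_calls(sample_id, data.frame(
    chrom = chrom, pos = pos, n_methylated = meth, n_total = tot,
    context = context
  ))
}

write_bedgraph_lines <- function(lines) {
  f <- tempfile(fileext = ".bedGraph")
  writeLines(lines, f)
  f
}

# simulate a cohort and assemble its AMF matrix the way the pipeline does
build_cohort_matrix <- function(cfg, with_qc = TRUE,
                                max_null_fraction = 0.10) {
  sim <- simulate_cohort(cfg)
  cat_calls <- methylation_calls("catalog", data.frame(
    chrom = sim$catalog$chrom, pos = sim$catalog$pos,
    n_methylated = 0L, n_total = 1L, context = "CpG"
  ))
  masked_catalog <- apply_mask(cat_calls, sim$mask)$records[, c("chrom", "pos")]
  bins_ref <- count_cpgs_per_bin(masked_catalog, sim$scheme)
  bins_ref <- bins_ref[bins_ref$n_cpgs >= sim$scheme$min_cpgs]
  amf_list <- list()
  qc <- if (with_qc) list() else NULL
  for (s in names(sim$calls)) {
    a <- compute_amf(sim$calls[[s]]$cpg, sim$scheme, masked_catalog,
      bins = bins_ref)
    amf_list[[s]] <- a
    if (with_qc) qc[[s]] <- sample_qc(a, sim$calls[[s]]$chh)
  }
  asm <- assemble_matrix(amf_list, qc, max_null_fraction = max_null_fraction)
  list(sim = sim, matrix = asm$matrix, assembly = asm)
}

# small AMF matrix built directly from a values matrix on a 100-bp grid
toy_amf <- function(values, chrom = "chr1") {
  n <- nrow(values)
  bins <- data.frame(
    bin_id = sprintf("%s:%d-%d", chrom, (seq_len(n) - 1L) * 100L,
      seq_len(n) * 100L),
    chrom = chrom, start = (seq_len(n) - 1L) * 100L,
    end = seq_len(n) * 100L, n_cpgs = 5L
  )
  samples <- colnames(values) %||% sprintf("S%02d", seq_len(ncol(values)))
  amf_matrix(values, bins, samples)
}

toy_cohort <- function(samples, groups, ...) {
  data.frame(sample_id = samples, group = groups, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
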