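# Binning, AMF computation, and sample/bin quality control.

#' Define a genome binning scheme
#'
#' Chromosomes are tiled with fixed-width half-open bins `[k*w, (k+1)*w)`,
#' the last bin truncated at the chromosome end. Bins are eligible for AMF
#' computation when they contain at least `min_cpgs` reference CpGs.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_width bin width in bases (default 100).
#' @param min_cpgs minimum reference CpGs for an eligible bin (default 5).
#' @return A `bin_scheme` object.
#' @export
bin_scheme <- function(chrom_sizes, bin_width = 100L, min_cpgs = 5L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (bin_width < 1L) stop("bin_width must be positive")
  structure(list(
    chrom_sizes = chrom_sizes,
    bin_width = as.integer(bin_width),
    min_cpgs = as.integer(min_cpgs)
  ), class = "bin_scheme")
}

#' Count reference CpGs per bin
#'
#' Assigns each reference CpG position to its half-open bin and counts
#' occupants; bins with zero CpGs are omitted from the result.
#'
#' @param cpg_positions data.frame with columns chrom, pos (0-based).
#' @param scheme a [bin_scheme()].
#' @return data.table with chrom, start, end, bin_id, n_cpgs.
#' @export
count_cpgs_per_bin <- function(cpg_positions, scheme) {
  dt <- as.data.table(cpg_positions)[, .(chrom, pos)]
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = integer(),
      end = integer(), bin_id = character(), n_cpgs = integer()))
  }
  sizes <- scheme$chrom_sizes
  unknown <- setdiff(unique(dt$chrom), names(sizes))
  if (length(unknown)) stop("chromosome not in scheme: ", unknown[1])
  bad <- dt$pos >= sizes[dt$chrom] | dt$pos < 0L
  if (any(bad)) {
    b <- dt[bad][1]
    stop(sprintf("CpG position %s:%d beyond chromosome size", b$chrom, b$pos))
  }
  w <- scheme$bin_width
  dt[, start := (pos %/% w) * w]
  out <- dt[, .(n_cpgs = .N), by = .(chrom, start)]
  out[, end := pmin(start + w, sizes[chrom])]
  out[, bin_id := bin_id(chrom, start, end)]
  setorder(out, chrom, start)
  out[, .(chrom, start, end, bin_id, n_cpgs)]
}

#' Conversion rate from CHH calls
#'
#' Cytosines in CHH context are essentially unmethylated in human DNA, so
#' residual CHH methylation measures conversion failure. The rate is
#' `1 - sum(n_methylated) / sum(n_total)` over CHH records.
#'
#' @param calls a [methylation_calls()] object containing CHH records.
#' @return Conversion rate in \[0, 1\].
#' @export
conversion_rate <- function(calls) {
  r <- calls$records[calls$records$context == "CHH"]
  if (nrow(r) == 0L || sum(r$n_total) == 0L)
    stop("no CHH coverage: sample conversion rate is unratable")
  1 - sum(as.numeric(r$n_methylated)) / sum(as.numeric(r$n_total))
}

#' Per-bin average methylation fraction for one sample
#'
#' For each eligible bin (>= `min_cpgs` reference CpGs), AMF is the ratio
#' of methylated read observations to all read observations at reference
#' CpG positions in the bin (depth-weighted, not a mean over CpGs). Bins
#' with no covered CpG are reported as NA; ineligible bins are absent.
#'
#' @param calls CpG-context [methylation_calls()], already masked.
#' @param scheme a [bin_scheme()].
#' @param catalog reference CpG positions (data.frame chrom, pos) defining
#'   bin eligibility; calls at positions outside the catalog are ignored.
#'   Masking the catalog before binning is equivalent to masking each
#'   sample's calls (the two operations commute for point CpG records).
#' @param bins optional precomputed eligible-bin table (the
#'   [count_cpgs_per_bin()] result filtered to `n_cpgs >= min_cpgs`);
#'   avoids recomputation when looping over many samples.
#' @return data.table with bin_id, chrom, start, end, n_cpgs, amf,
#'   depth (total read observations), n_covered (covered reference CpGs).
#' @export
compute_amf <- function(calls, scheme, catalog, bins = NULL) {
  if (is.null(bins)) {
    bins <- count_cpgs_per_bin(catalog, scheme)
    bins <- bins[n_cpgs >= scheme$min_cpgs]
  }
  if (nrow(bins) == 0L) stop("no eligible bins under this scheme")
  cat_dt <- as.data.table(catalog)[, .(chrom, pos)]
  r <- as.data.table(calls$records)[context == "CpG"]
  r <- r[cat_dt, on = c("chrom", "pos"), nomatch = NULL]
  w <- scheme$bin_width
  r[, start := (pos %/% w) * w]
  agg <- r[, .(
    meth = sum(as.numeric(n_methylated)),
    depth = sum(as.numeric(n_total)),
    n_covered = .N
  ), by = .(chrom, start)]
  out <- agg[bins, on = c("chrom", "start")]
  out[is.na(depth), `:=`(depth = 0, meth = 0, n_covered = 0L)]
  out[, amf := ifelse(depth > 0, meth / depth, NA_real_)]
  setorder(out, chrom, start)
  out[, .(bin_id, chrom, start, end, n_cpgs, amf, depth, n_covered)]
}

#' Sample quality control report
#'
#' A sample passes when its CHH-derived conversion rate strictly exceeds
#' `min_conversion` and the median over eligible bins of the per-bin
#' average CpG depth (total read observations / covered CpGs) is at least
#' `min_depth`.
#'
#' @param amf per-sample AMF table from [compute_amf()].
#' @param chh_calls CHH-context [methylation_calls()] for the sample.
#' @param min_conversion conversion gate, strict (default 0.99).
#' @param min_depth depth gate, inclusive (default 3).
#' @return list with sample_id, conversion_rate, depth_summary, pass.
#' @export
sample_qc <- function(amf, chh_calls, min_conversion = 0.99, min_depth = 3) {
  conv <- conversion_rate(chh_calls)
  covered <- as.data.table(amf)[n_covered > 0L]
  depth_summary <- if (nrow(covered)) {
    median(covered$depth / covered$n_covered)
  } else {
    0
  }
  list(
    sample_id = chh_calls$sample_id,
    conversion_rate = conv,
    depth_summary = depth_summary,
    pass = (conv > min_conversion) && (depth_summary >= min_depth)
  )
}

#' Construct an AMF matrix container
#'
#' @param values numeric bins x samples matrix in \[0, 1\] with NA for
#'   missing cells; rownames are bin ids.
#' @param bins data.table with bin_id, chrom, start, end, n_cpgs in row
#'   order of `values`.
#' @param samples character vector of sample ids in column order.
#' @return An `amf_matrix` object.
#' @export
amf_matrix <- function(values, bins, samples) {
  values <- as.matrix(values)
  bins <- as.data.table(bins)
  samples <- as.character(samples)
  if (nrow(values) != nrow(bins) || ncol(values) != length(samples))
    stop("values dimensions do not match bins/samples")
  if (length(values) && !all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("AMF values must lie in [0, 1]")
  }
  rownames(values) <- bins$bin_id
  colnames(values) <- samples
  structure(list(values = values, bins = bins, samples = samples),
    class = "amf_matrix")
}

#' @export
print.amf_matrix <- function(x, ...) {
  cat(sprintf(
    "<amf_matrix> %d bins x %d samples, %.1f%% missing\n",
    nrow(x$bins), length(x$samples),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' Subset an AMF matrix by bin ids
#' @param m an [amf_matrix()].
#' @param ids bin ids to keep (order preserved as given).
#' @return The subset matrix.
#' @export
amf_subset_bins <- function(m, ids) {
  idx <- match(ids, m$bins$bin_id)
  if (anyNA(idx)) stop("unknown bin id: ", ids[is.na(idx)][1])
  amf_matrix(m$values[idx, , drop = FALSE], m$bins[idx], m$samples)
}

#' Subset an AMF matrix by sample ids
#' @param m an [amf_matrix()].
#' @param ids sample ids to keep; duplicates allowed (bootstrap use).
#' @return The subset matrix (duplicated samples become repeated columns).
#' @export
amf_subset_samples <- function(m, ids) {
  idx <- match(ids, m$samples)
  if (anyNA(idx)) stop("unknown sample id: ", ids[is.na(idx)][1])
  vals <- m$values[, idx, drop = FALSE]
  structure(list(values = vals, bins = m$bins, samples = as.character(ids)),
    class = "amf_matrix")
}

#' Assemble the cohort AMF matrix
#'
#' Drops samples failing QC, aligns per-sample AMF vectors on the shared
#' eligible-bin set, and retains only bins whose missing-cell fraction
#' across retained samples is strictly below `max_null_fraction`.
#'
#' @param amf_list named list (sample_id -> [compute_amf()] table).
#' @param qc named list of [sample_qc()] reports (NULL to skip QC).
#' @param max_null_fraction strict upper bound on per-bin missingness
#'   (default 0.10).
#' @return list with `matrix` (an [amf_matrix()]), `dropped_samples`,
#'   `n_bins_total`, `n_bins_retained`.
#' @export
assemble_matrix <- function(amf_list, qc = NULL, max_null_fraction = 0.10) {
  samples <- names(amf_list)
  if (is.null(samples)) stop("amf_list must be a named list")
  dropped <- character()
  if (!is.null(qc)) {
    pass <- vapply(samples, function(s) isTRUE(qc[[s]]$pass), TRUE)
    dropped <- samples[!pass]
    samples <- samples[pass]
  }
  if (length(samples) == 0L) stop("all samples failed QC")
  if (length(samples) < 2L) stop("need >= 2 passing samples")
  amf_list <- lapply(amf_list, as.data.table)
  bins <- amf_list[[samples[1]]][, .(bin_id, chrom, start, end, n_cpgs)]
  vals <- vapply(samples, function(s) {
    a <- amf_list[[s]]
    if (!identical(a$bin_id, bins$bin_id))
      stop("per-sample AMF tables disagree on the bin set (sample ", s, ")")
    a$amf
  }, numeric(nrow(bins)))
  vals <- matrix(vals, nrow = nrow(bins),
    dimnames = list(bins$bin_id, samples))
  null_frac <- rowMeans(is.na(vals))
  keep <- null_frac < max_null_fraction
  list(
    matrix = amf_matrix(vals[keep, , drop = FALSE], bins[keep], samples),
    dropped_samples = dropped,
    n_bins_total = nrow(bins),
    n_bins_retained = sum(keep)
  )
}
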