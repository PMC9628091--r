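# External validation: recompute AMF over marker intervals from external
# per-CpG call files and compare distributions against the study groups.

#' AMF over arbitrary regions
#'
#' For each half-open region, AMF is the ratio of methylated to total read
#' observations over the CpGs whose position falls inside the region;
#' regions with no covered CpG are NA (missing, never zero).
#'
#' @param calls a CpG-context [methylation_calls()].
#' @param regions data.frame with chrom, start, end, sorted and
#'   non-overlapping.
#' @return data.table with chrom, start, end, region_id, amf, depth,
#'   n_covered.
#' @export
amf_over_regions <- function(calls, regions) {
  reg <- as.data.table(regions)[, .(chrom, start = as.integer(start),
    end = as.integer(end))]
  if (nrow(reg) == 0L) stop("regions must be non-empty")
  setorder(reg, chrom, start)
  reg[, region_id := bin_id(chrom, start, end)]
  r <- as.data.table(calls$records)[context == "CpG"]
  if (nrow(r)) {
    q <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos + 1L, r$pos + 1L))
    s <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start + 1L, reg$end))
    hit <- GenomicRanges::findOverlaps(q, s)
    agg <- data.table(
      region = S4Vectors::subjectHits(hit),
      meth = r$n_methylated[S4Vectors::queryHits(hit)],
      tot = r$n_total[S4Vectors::queryHits(hit)]
    )[, .(meth = sum(as.numeric(meth)), depth = sum(as.numeric(tot)),
      n_covered = .N), by = region]
  } else {
    agg <- data.table(region = integer(), meth = numeric(),
      depth = numeric(), n_covered = integer())
  }
  out <- copy(reg)
  out[, `:=`(amf = NA_real_, depth = 0, n_covered = 0L)]
  if (nrow(agg)) {
    out$amf[agg$region] <- agg$meth / agg$depth
    out$depth[agg$region] <- agg$depth
    out$n_covered[agg$region] <- agg$n_covered
  }
  out[]
}

#' Exclude low-coverage external samples
#'
#' A sample is retained when it has at least one covered CpG in at least
#' `min_region_fraction` of the marker regions; the rest are excluded
#' with a deterministic report.
#'
#' @param call_sets named list of CpG [methylation_calls()].
#' @param regions marker regions (chrom, start, end).
#' @param min_region_fraction retention rule (default 0.5).
#' @return list with `retained` (names), `excluded`, and a per-sample
#'   `report` data.table.
#' @export
exclude_low_coverage_samples <- function(call_sets, regions,
                                         min_region_fraction = 0.5) {
  if (length(call_sets) == 0L) stop("no samples supplied")
  nm <- names(call_sets)
  report <- rbindlist(lapply(nm, function(s) {
    a <- amf_over_regions(call_sets[[s]], regions)
    data.table(
      sample_id = s,
      regions_covered = sum(a$n_covered > 0L),
      n_regions = nrow(a),
      frac_covered = mean(a$n_covered > 0L)
    )
  }))
  setorder(report, sample_id)
  report[, retained := frac_covered >= min_region_fraction]
  if (!any(report$retained)) stop("all external samples excluded")
  list(
    retained = report$sample_id[report$retained],
    excluded = report$sample_id[!report$retained],
    report = report[]
  )
}

#' Compare external AMF distributions with the study groups
#'
#' Per region: summary statistics (n, median, IQR, min, max) for the
#' external cohort and both study groups, a two-sided Mann–Whitney test
#' of external versus the good group, and a "stringency" indicator —
#' TRUE when the external IQR does not exceed the poor-group IQR and the
#' external median is at least the poor-group median minus `tolerance`
#' (the external distribution is similar to or tighter than the
#' poor-group one). Regions uncovered in the external cohort are flagged
#' and excluded from testing.
#'
#' @param m the study [amf_matrix()] restricted to (or containing) the
#'   marker bins.
#' @param cohort study cohort table.
#' @param external_amf regions x external-samples matrix of AMF values
#'   (rownames = region ids as "chrom:start-end"), e.g. assembled from
#'   [amf_over_regions()] outputs.
#' @param tolerance median tolerance of the stringency rule (default
#'   0.05).
#' @return data.table with per-region summaries, `p_mw`, `covered`, and
#'   `stringent`.
#' @export
compare_distributions <- function(m, cohort, external_amf,
                                  tolerance = 0.05) {
  stopifnot(inherits(m, "amf_matrix"))
  cohort <- validate_cohort(cohort)
  ext <- as.matrix(external_amf)
  ids <- rownames(ext)
  if (is.null(ids)) stop("external_amf needs region ids as rownames")
  idx <- match(ids, m$bins$bin_id)
  if (anyNA(idx)) stop("region absent from study matrix: ", ids[is.na(idx)][1])
  grp <- cohort$group[match(m$samples, cohort$sample_id)]
  good <- m$values[idx, grp == "good", drop = FALSE]
  poor <- m$values[idx, grp == "poor", drop = FALSE]
  summarize <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(list(n = 0L, med = NA_real_, iqr = NA_real_,
        min = NA_real_, max = NA_real_))
    }
    list(n = length(v), med = median(v), iqr = IQR(v),
      min = min(v), max = max(v))
  }
  out <- rbindlist(lapply(seq_along(ids), function(i) {
    e <- summarize(ext[i, ])
    g <- summarize(good[i, ])
    p <- summarize(poor[i, ])
    covered <- e$n >= 2L
    p_mw <- if (covered && g$n >= 2L) {
      suppressWarnings(wilcox.test(ext[i, ], good[i, ],
        exact = FALSE)$p.value)
    } else {
      NA_real_
    }
    stringent <- if (covered && p$n >= 2L) {
      (e$iqr <= p$iqr) && (e$med >= p$med - tolerance)
    } else {
      NA
    }
    data.table(
      region_id = ids[i],
      n_external = e$n, median_external = e$med, iqr_external = e$iqr,
      min_external = e$min, max_external = e$max,
      n_good = g$n, median_good = g$med, iqr_good = g$iqr,
      n_poor = p$n, median_poor = p$med, iqr_poor = p$iqr,
      covered = covered, p_mw = p_mw, stringent = stringent
    )
  }))
  out[]
}

#' Assemble a regions x samples external AMF matrix
#'
#' Convenience wrapper running [amf_over_regions()] across external
#' samples and binding the per-region AMF vectors into a matrix.
#'
#' @param call_sets named list of CpG [methylation_calls()].
#' @param regions marker regions (chrom, start, end).
#' @return numeric matrix, rownames "chrom:start-end", one column per
#'   sample.
#' @export
external_amf_matrix <- function(call_sets, regions) {
  if (length(call_sets) == 0L) stop("no samples supplied")
  cols <- lapply(call_sets, function(cs) amf_over_regions(cs, regions))
  ids <- cols[[1]]$region_id
  vals <- vapply(cols, function(a) a$amf, numeric(length(ids)))
  vals <- matrix(vals, nrow = length(ids),
    dimnames = list(ids, names(call_sets)))
  vals
}
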