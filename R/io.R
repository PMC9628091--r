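# Readers and writers for the external formats the pipeline touches.
# Coordinates are 0-based half-open everywhere, matching the bedGraph
# dialect emitted by per-cytosine methylation callers.

#' Construct a methylation call set
#'
#' A call set holds per-cytosine counts of methylated and total read
#' observations for one sample, sorted by (chrom, pos) with no duplicate
#' (chrom, pos, context) records and `n_total >= 1` everywhere.
#'
#' @param sample_id sample identifier.
#' @param records a data.frame with columns `chrom`, `pos` (0-based),
#'   `n_methylated`, `n_total`, `context` (one of "CpG", "CHH", "CHG").
#' @return An object of class `methylation_calls`.
#' @export
methylation_calls <- function(sample_id, records) {
  dt <- as.data.table(records)
  need <- c("chrom", "pos", "n_methylated", "n_total", "context")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing call columns: ", paste(miss, collapse = ", "))
  dt <- dt[, ..need]
  if (nrow(dt)) {
    if (any(dt$n_total < 1L)) stop("call records must have n_total >= 1")
    if (any(dt$n_methylated < 0L) || any(dt$n_methylated > dt$n_total))
      stop("call records must satisfy 0 <= n_methylated <= n_total")
    bad <- !dt$context %in% c("CpG", "CHH", "CHG")
    if (any(bad)) stop("unknown context: ", dt$context[bad][1])
    setorder(dt, chrom, pos, context)
    dup <- duplicated(dt, by = c("chrom", "pos", "context"))
    if (any(dup)) {
      d <- dt[dup][1]
      stop(sprintf("duplicate call at %s:%d (%s)", d$chrom, d$pos, d$context))
    }
  }
  structure(list(sample_id = sample_id, records = dt),
    class = "methylation_calls")
}

#' @export
print.methylation_calls <- function(x, ...) {
  cat(sprintf(
    "<methylation_calls> sample %s: %d records (%s)\n",
    x$sample_id, nrow(x$records),
    paste(unique(x$records$context), collapse = "/")
  ))
  invisible(x)
}

#' Read a 6-column bedGraph methylation call file
#'
#' Parses the per-cytosine dialect written by common methylation callers:
#' chrom, start, end, methylation percentage, count methylated, count
#' unmethylated (0-based half-open, one row per cytosine). Total counts are
#' reconstructed as methylated + unmethylated; zero-coverage rows are
#' dropped; output is sorted and checked for duplicate positions.
#'
#' @param path file path.
#' @param context context label to assign ("CpG", "CHH" or "CHG"); these
#'   callers emit one file per context.
#' @param sample_id sample identifier; default is the file name stem.
#' @return A [methylation_calls()] object.
#' @export
read_calls <- function(path, context = "CpG", sample_id = NULL) {
  if (!file.exists(path)) stop("no such call file: ", path)
  dt <- tryCatch(
    suppressWarnings(fread(path, header = FALSE, sep = "\t",
      colClasses = list(character = 1L, integer = c(2L, 3L),
        numeric = 4L, integer = c(5L, 6L)))),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(dt) && ncol(dt) != 6L)
    stop("expected 6 bedGraph columns in ", path, ", found ", ncol(dt))
  if (nrow(dt)) {
    setnames(dt, c("chrom", "start", "end", "pct", "n_methylated", "n_unmethylated"))
    bad <- which(!is.finite(dt$start) | !is.finite(dt$n_methylated) |
      !is.finite(dt$n_unmethylated))
    if (length(bad)) stop("malformed line ", bad[1], " in ", path)
    neg <- which(dt$n_methylated < 0L | dt$n_unmethylated < 0L)
    if (length(neg))
      stop("negative count on line ", neg[1], " in ", path)
    dt[, `:=`(pos = start, n_total = n_methylated + n_unmethylated)]
    dt <- dt[n_total > 0L]
    dt[, context := context]
  } else {
    dt <- data.table(chrom = character(), pos = integer(),
      n_methylated = integer(), n_total = integer(), context = character())
  }
  methylation_calls(
    sample_id %||% sub("\\.[^.]*$", "", basename(path)),
    dt[, .(chrom, pos, n_methylated, n_total, context)]
  )
}

#' Write a call set as a 6-column bedGraph file
#'
#' Inverse of [read_calls()]: one row per cytosine with methylation
#' percentage and methylated/unmethylated counts.
#'
#' @param calls a [methylation_calls()] object.
#' @param path output path.
#' @param context restrict output to one context (default: all records).
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, context = NULL) {
  r <- calls$records
  if (!is.null(context)) r <- r[r$context == context]
  out <- data.table(
    chrom = r$chrom, start = r$pos, end = r$pos + 1L,
    pct = sprintf("%.2f", ifelse(r$n_total > 0, 100 * r$n_methylated / r$n_total, 0)),
    n_methylated = r$n_methylated,
    n_unmethylated = r$n_total - r$n_methylated
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED blacklist into a merged region mask
#'
#' Intervals are sorted and coalesced (overlapping or bookended intervals
#' merged) into a non-overlapping half-open mask.
#'
#' @param path BED3+ file path (only the first three columns are used).
#' @return A `region_mask`: a data.table with columns chrom, start, end.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  dt <- suppressWarnings(fread(path, header = FALSE, sep = "\t",
    fill = TRUE))
  if (is.null(dt) || nrow(dt) == 0L) {
    return(structure(
      data.table(chrom = character(), start = integer(), end = integer()),
      class = c("region_mask", "data.table", "data.frame")
    ))
  }
  dt <- dt[, 1:3]
  setnames(dt, c("chrom", "start", "end"))
  region_mask(dt)
}

#' Construct a region mask from intervals
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @return A merged `region_mask`.
#' @export
region_mask <- function(intervals) {
  dt <- as.data.table(intervals)[, .(chrom, start = as.integer(start),
    end = as.integer(end))]
  if (nrow(dt) && any(dt$start >= dt$end))
    stop("mask interval with start >= end")
  if (nrow(dt)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end)
    ))
    dt <- data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
    setorder(dt, chrom, start)
  }
  structure(dt, class = c("region_mask", "data.table", "data.frame"))
}

#' Remove calls falling inside masked regions
#'
#' A record at position `pos` is removed when `start <= pos < end` for any
#' mask interval (half-open convention: a CpG exactly at an interval end is
#' retained). An empty mask is the identity.
#'
#' @param calls a [methylation_calls()] object.
#' @param mask a [region_mask()].
#' @return The filtered call set.
#' @export
apply_mask <- function(calls, mask) {
  if (nrow(mask) == 0L || nrow(calls$records) == 0L) return(calls)
  r <- calls$records
  q <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos + 1L, r$pos + 1L))
  s <- GenomicRanges::GRanges(mask$chrom, IRanges::IRanges(mask$start + 1L, mask$end))
  hit <- GenomicRanges::countOverlaps(q, s) > 0L
  methylation_calls(calls$sample_id, r[!hit])
}

#' Write an AMF matrix as TSV
#'
#' Rows are bins keyed by "chrom:start-end", columns are samples; missing
#' cells are serialized as NA; a `n_cpgs` column records the reference CpG
#' count of each bin. Values round-trip exactly through [read_amf_table()].
#'
#' @param m an [amf_matrix()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amf_table <- function(m, path) {
  stopifnot(inherits(m, "amf_matrix"))
  if (length(m$samples) == 0L || nrow(m$bins) == 0L)
    stop("refusing to write an empty AMF matrix")
  vals <- apply(m$values, 2L, function(col) {
    ifelse(is.na(col), "NA", sprintf("%.17g", col))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(m$bins))
  out <- data.table(bin = m$bins$bin_id, n_cpgs = m$bins$n_cpgs)
  out <- cbind(out, as.data.table(vals))
  setnames(out, c("bin", "n_cpgs", m$samples))
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an AMF matrix written by [write_amf_table()]
#'
#' @param path TSV path.
#' @param samples optional expected sample order; if supplied and the file
#'   stores a different order, an error is raised rather than silently
#'   reordering.
#' @return An [amf_matrix()] object.
#' @export
read_amf_table <- function(path, samples = NULL) {
  dt <- fread(path, header = TRUE, sep = "\t", na.strings = "NA")
  if (nrow(dt) == 0L || ncol(dt) < 3L)
    stop("empty or malformed AMF table: ", path)
  stored <- setdiff(names(dt), c("bin", "n_cpgs"))
  if (!is.null(samples) && !identical(stored, as.character(samples)))
    stop("sample order in ", path, " does not match the declared order")
  bins <- parse_bin_id(dt$bin)
  bins[, n_cpgs := dt$n_cpgs]
  vals <- as.matrix(dt[, ..stored])
  rownames(vals) <- dt$bin
  amf_matrix(vals, bins, stored)
}

#' Read a cohort sample sheet
#'
#' TSV with a header; must contain `sample_id` and `group` columns, the
#' group taking exactly two levels ("good"/"poor" in the reference design);
#' remaining columns are clinical covariates (continuous or 0/1 binary).
#'
#' @param path TSV path.
#' @return A data.table with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  validate_cohort(dt)
}

#' Write a cohort sample sheet
#' @param cohort cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(cohort, path) {
  fwrite(as.data.table(cohort), path, sep = "\t", quote = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  dt <- as.data.table(cohort)
  if (!all(c("sample_id", "group") %in% names(dt)))
    stop("cohort table needs sample_id and group columns")
  if (anyDuplicated(dt$sample_id)) stop("duplicate sample_id in cohort table")
  if (length(unique(dt$group)) != 2L)
    stop("cohort group must take exactly two levels")
  dt
}

#' Read a gene model table
#'
#' Expects a TSV with columns chrom, start, end, gene, feature where
#' feature is "exon" or "intron" (0-based half-open intervals). Used for
#' exon/intron/intergenic annotation of markers.
#'
#' @param path TSV path.
#' @return A data.table gene model.
#' @export
read_gene_model <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "start", "end", "gene", "feature")
  if (!all(need %in% names(dt)))
    stop("gene model must have columns: ", paste(need, collapse = ", "))
  if (any(!dt$feature %in% c("exon", "intron")))
    stop("gene model feature must be exon or intron")
  dt
}
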