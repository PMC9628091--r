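# Internal helpers shared across modules.

#' Derive a stage seed from a global seed
#'
#' Deterministic splitting of one user-facing seed into per-stage seeds so
#' that pipeline stages are independently reproducible. Kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(stage) * 99991) %%
    2147483629)
}

# 32-bit polynomial string hash, hex-encoded; used only to fingerprint
# configurations in run reports.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  b <- as.integer(charToRaw(as.character(s)))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

bin_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

parse_bin_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed bin identifier: ", id[bad][1])
  data.table(
    bin_id = id,
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L))
  )
}

# round-half-up, used for the stratified split counts
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
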