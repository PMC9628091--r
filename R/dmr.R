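# DMR selection cascade: stratified train/test split, bootstrap subsets,
# per-bin Welch's t-test with FDR q-values and z-standardized mean
# differences, three-way intersection, and top-k rank filtering.

#' Stratified train/test split
#'
#' Per-group training counts follow round-half-up of
#' `train_fraction * group size`; assignment within group is uniform at
#' random given the seed. The reference design (109 good / 34 poor at
#' 0.85) yields 93/29 training and 16/5 test samples.
#'
#' @param cohort cohort table with sample_id and group.
#' @param train_fraction training fraction (default 0.85).
#' @param seed RNG seed.
#' @return list with `train` and `test` character vectors of sample ids.
#' @export
stratified_split <- function(cohort, train_fraction = 0.85, seed = 1L) {
  cohort <- validate_cohort(cohort)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  set.seed(seed)
  train <- character()
  for (g in sort(unique(cohort$group))) {
    ids <- cohort$sample_id[cohort$group == g]
    if (length(ids) < 2L) stop("group ", g, " has fewer than 2 samples")
    n_train <- round_half_up(train_fraction * length(ids))
    n_train <- min(max(n_train, 1L), length(ids) - 1L)
    train <- c(train, sample(ids, n_train))
  }
  ord <- match(cohort$sample_id, cohort$sample_id)
  list(
    train = cohort$sample_id[cohort$sample_id %in% train],
    test = cohort$sample_id[!cohort$sample_id %in% train]
  )
}

#' Draw bootstrap subsets of the training set
#'
#' Each subset is a with-replacement draw of the full training-set size,
#' stratified within group so group composition is preserved exactly.
#' Duplicated samples count as independent observations downstream.
#'
#' @param train_ids training sample ids.
#' @param cohort cohort table (for group membership).
#' @param n_subsets number of subsets (default 3).
#' @param seed RNG seed.
#' @return list of character vectors (multisets of sample ids).
#' @export
draw_subsets <- function(train_ids, cohort, n_subsets = 3L, seed = 1L) {
  cohort <- validate_cohort(cohort)
  if (length(train_ids) == 0L) stop("training set is empty")
  grp <- cohort$group[match(train_ids, cohort$sample_id)]
  if (anyNA(grp)) stop("training ids missing from cohort table")
  set.seed(seed)
  lapply(seq_len(n_subsets), function(i) {
    out <- character()
    for (g in sort(unique(grp))) {
      ids <- train_ids[grp == g]
      out <- c(out, sample(ids, length(ids), replace = TRUE))
    }
    out
  })
}

#' Welch's unequal-variances t-test
#'
#' Closed-form Welch statistic with Welch–Satterthwaite degrees of freedom
#' and a two-sided t-distribution p-value. When both groups are constant
#' with different means the p-value is floored at the smallest positive
#' double rather than dividing by zero.
#'
#' @param x,y numeric vectors (>= 2 non-missing values each).
#' @return list with diff (`mean(x) - mean(y)`), t, df, p.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_test needs >= 2 non-missing values per group")
  r <- row_welch(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(diff = r$diff[1], t = r$t[1], df = r$df[1], p = r$p[1])
}

# Vectorized Welch over rows of two matrices with NAs. Two-pass variance
# for numerical agreement with the reference implementation.
row_welch <- function(X, Y) {
  nx <- rowSums(!is.na(X))
  ny <- rowSums(!is.na(Y))
  mx <- rowMeans(X, na.rm = TRUE)
  my <- rowMeans(Y, na.rm = TRUE)
  vx <- rowSums((X - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((Y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  se2 <- vx / nx + vy / ny
  d <- mx - my
  t <- d / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  # degenerate: both variances zero
  zero_se <- se2 == 0
  t[zero_se & d == 0] <- 0
  df[zero_se] <- nx[zero_se] + ny[zero_se] - 2
  p <- 2 * pt(-abs(t), df)
  p[zero_se & d == 0] <- 1
  p[zero_se & d != 0] <- .Machine$double.xmin
  t[zero_se & d != 0] <- sign(d[zero_se & d != 0]) * Inf
  p <- pmax(p, .Machine$double.xmin)
  untested <- nx < 2L | ny < 2L
  t[untested] <- NA_real_
  df[untested] <- NA_real_
  p[untested] <- NA_real_
  list(diff = d, t = t, df = df, p = p, n_x = nx, n_y = ny,
    var_x = vx, var_y = vy)
}

#' FDR q-values
#'
#' Default is the Benjamini–Hochberg step-up with enforced monotonicity.
#' `method = "empirical-null"` additionally scales by an estimate of the
#' null proportion pi0 (twice the fraction of p-values above 0.5), a
#' tail-area empirical-null variant.
#'
#' @param p vector of p-values in (0, 1].
#' @param method "bh" (default) or "empirical-null".
#' @return q-values in \[0, 1\], monotone in the p-value ranks.
#' @export
fdr_qvalues <- function(p, method = c("bh", "empirical-null")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  if (method == "empirical-null") {
    pi0 <- min(1, max(2 * mean(p > 0.5), 1 / n))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Screen one bootstrap subset for DMRs
#'
#' Bins are tested when the fraction of non-missing AMF values across the
#' subset's bootstrap observations exceeds `coverage_threshold` and both
#' groups retain >= 2 observations. For tested bins, the good-minus-poor
#' mean difference is standardized across all tested bins into a z-score;
#' DMRs satisfy `q < q_threshold` and `|z| > z_threshold`, labeled
#' hypomethylated (z negative: good below poor) or hypermethylated.
#'
#' @param m the cohort [amf_matrix()] (full bin set, with missingness).
#' @param subset_ids bootstrap multiset of sample ids (duplicates carry
#'   weight as independent observations).
#' @param cohort cohort table.
#' @param coverage_threshold strict lower bound on the non-missing
#'   fraction (default 0.90).
#' @param z_threshold standardized-difference cutoff (default 2).
#' @param q_threshold q-value cutoff (default 0.05).
#' @param q_method passed to [fdr_qvalues()].
#' @return A `subset_screen`: list with `stats` (per tested bin) and
#'   `dmrs` (selected bin ids).
#' @export
screen_subset <- function(m, subset_ids, cohort, coverage_threshold = 0.90,
                          z_threshold = 2, q_threshold = 0.05,
                          q_method = "bh") {
  stopifnot(inherits(m, "amf_matrix"))
  cohort <- validate_cohort(cohort)
  sub <- amf_subset_samples(m, subset_ids)
  grp <- cohort$group[match(sub$samples, cohort$sample_id)]
  if (anyNA(grp)) stop("subset ids missing from cohort table")
  vals <- sub$values
  good <- vals[, grp == "good", drop = FALSE]
  poor <- vals[, grp == "poor", drop = FALSE]
  frac_obs <- rowMeans(!is.na(vals))
  w <- row_welch(good, poor)
  tested <- frac_obs > coverage_threshold & w$n_x >= 2L & w$n_y >= 2L
  if (!any(tested)) stop("no bins pass the coverage threshold")
  stats <- data.table(
    bin_id = m$bins$bin_id[tested],
    chrom = m$bins$chrom[tested],
    start = m$bins$start[tested],
    end = m$bins$end[tested],
    mean_good = w$diff[tested] + rowMeans(poor, na.rm = TRUE)[tested],
    mean_poor = rowMeans(poor, na.rm = TRUE)[tested],
    diff = w$diff[tested],
    t = w$t[tested],
    df = w$df[tested],
    p = w$p[tested]
  )
  stats[, z := (diff - mean(diff)) / sd(diff)]
  stats[, q := fdr_qvalues(p, method = q_method)]
  stats[, direction := "none"]
  stats[q < q_threshold & z < -z_threshold, direction := "hypo"]
  stats[q < q_threshold & z > z_threshold, direction := "hyper"]
  structure(list(
    stats = stats,
    dmrs = stats$bin_id[stats$direction != "none"],
    n_tested = nrow(stats),
    thresholds = list(coverage = coverage_threshold, z = z_threshold,
      q = q_threshold, q_method = q_method)
  ), class = "subset_screen")
}

#' Intersect subset DMR sets and apply the top-k rank filter
#'
#' The intersection keeps bins selected in every subset. Within the
#' intersection each subset independently ranks its bins by ascending
#' q-value (ties by descending |z|, then genomic coordinate); candidate
#' DMRs are those ranked within `top_k` in every subset.
#'
#' @param screens list of `subset_screen` results (>= 2).
#' @param top_k rank cutoff (default 500).
#' @return list with `intersection` (bin ids), `candidates` (bin ids),
#'   and `ranks` (per-subset ranks inside the intersection).
#' @export
intersect_and_rank <- function(screens, top_k = 500L) {
  if (length(screens) < 2L) stop("need >= 2 subset screens")
  sets <- lapply(screens, function(s) s$dmrs)
  inter <- Reduce(intersect, sets)
  if (length(inter) == 0L) {
    warning("empty DMR intersection")
    return(list(intersection = character(), candidates = character(),
      ranks = data.table()))
  }
  ranks <- lapply(seq_along(screens), function(i) {
    st <- screens[[i]]$stats[bin_id %in% inter]
    st <- st[order(q, -abs(z), chrom, start)]
    data.table(bin_id = st$bin_id, rank = seq_len(nrow(st)), subset = i)
  })
  ranks <- rbindlist(ranks)
  wide <- dcast(ranks, bin_id ~ subset, value.var = "rank")
  rank_cols <- setdiff(names(wide), "bin_id")
  in_top <- rowSums(wide[, ..rank_cols] <= top_k) == length(rank_cols)
  cand <- wide$bin_id[in_top]
  # report in genomic order, using the first screen's coordinates
  ord <- screens[[1]]$stats[bin_id %in% inter, .(bin_id, chrom, start)]
  setorder(ord, chrom, start)
  list(
    intersection = ord$bin_id,
    candidates = ord$bin_id[ord$bin_id %in% cand],
    ranks = wide
  )
}

#' Project train and test samples onto candidate-DMR principal components
#'
#' PCA is fitted on training samples only (centering and, optionally,
#' scaling learned on train); test samples are projected with the frozen
#' transform. Missing training cells are imputed with training-group
#' means; missing test cells with overall training bin means (no label
#' use on test).
#'
#' @param m the cohort [amf_matrix()].
#' @param candidates candidate bin ids.
#' @param cohort cohort table.
#' @param train_ids,test_ids sample id vectors.
#' @param scale unit-variance scaling (default FALSE).
#' @return list with `train_scores`, `test_scores`, `rotation`,
#'   `dropped` (candidates without training observations).
#' @export
candidate_pca_check <- function(m, candidates, cohort, train_ids, test_ids,
                                scale = FALSE) {
  if (length(candidates) == 0L) stop("candidate set is empty")
  imp <- impute_train_test(m, candidates, cohort, train_ids, test_ids)
  pr <- prcomp(imp$X_train, center = TRUE, scale. = scale)
  train_scores <- pr$x
  test_scores <- predict(pr, newdata = imp$X_test)
  rownames(train_scores) <- train_ids
  rownames(test_scores) <- test_ids
  list(
    train_scores = train_scores,
    test_scores = test_scores,
    rotation = pr$rotation,
    dropped = imp$dropped
  )
}

# shared leakage-guarded imputation for candidate-level learners:
# train missing <- training group mean; test missing <- overall training
# mean; candidates with no training observations are dropped with warning
impute_train_test <- function(m, candidates, cohort, train_ids, test_ids) {
  cohort <- validate_cohort(cohort)
  sub <- amf_subset_bins(m, candidates)
  tr <- amf_subset_samples(sub, train_ids)
  te <- amf_subset_samples(sub, test_ids)
  grp_tr <- cohort$group[match(train_ids, cohort$sample_id)]
  Xtr <- t(tr$values) # samples x candidates
  Xte <- t(te$values)
  overall <- colMeans(Xtr, na.rm = TRUE)
  empty <- !is.finite(overall)
  dropped <- candidates[empty]
  if (any(empty)) {
    warning("dropping ", sum(empty),
      " candidate(s) with no observed training value")
    Xtr <- Xtr[, !empty, drop = FALSE]
    Xte <- Xte[, !empty, drop = FALSE]
    overall <- overall[!empty]
  }
  if (ncol(Xtr) == 0L) stop("no candidate has observed training values")
  for (g in unique(grp_tr)) {
    idx <- which(grp_tr == g)
    blk <- Xtr[idx, , drop = FALSE]
    gm <- colMeans(blk, na.rm = TRUE)
    gm[!is.finite(gm)] <- overall[!is.finite(gm)]
    na_cells <- is.na(blk)
    blk[na_cells] <- gm[col(blk)[na_cells]]
    Xtr[idx, ] <- blk
  }
  na_te <- is.na(Xte)
  Xte[na_te] <- overall[col(Xte)[na_te]]
  list(X_train = Xtr, X_test = Xte, dropped = dropped)
}
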