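# Unsupervised structure detection: variance screening, group-mean
# imputation, PCA with a permutation-derived component cutoff, and
# correlation of retained components with clinical variables.

#' Variance screen on an AMF matrix
#'
#' Computes each bin's SD over its non-missing cells, standardizes the SD
#' vector across bins, and keeps bins with z above the threshold —
#' removing background fluctuation before PCA.
#'
#' @param m an [amf_matrix()] with >= 3 samples.
#' @param z_threshold z-score cutoff on standardized SDs (default 2).
#' @return The reduced [amf_matrix()].
#' @export
variance_screen <- function(m, z_threshold = 2) {
  stopifnot(inherits(m, "amf_matrix"))
  if (length(m$samples) < 3L) stop("variance screen needs >= 3 samples")
  sds <- apply(m$values, 1L, sd, na.rm = TRUE)
  s <- sd(sds, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("degenerate standardization: all bin SDs identical")
  z <- (sds - mean(sds, na.rm = TRUE)) / s
  keep <- which(!is.na(z) & z > z_threshold)
  if (length(keep) == 0L) stop("no bins pass the variance screen")
  amf_matrix(m$values[keep, , drop = FALSE], m$bins[keep], m$samples)
}

#' Impute missing AMF cells with group means
#'
#' Each missing cell is replaced by the mean of the bin's non-missing
#' values within the sample's group; non-missing cells are untouched.
#'
#' @param m an [amf_matrix()].
#' @param cohort cohort table with sample_id and group.
#' @return A complete [amf_matrix()].
#' @export
impute_group_means <- function(m, cohort) {
  stopifnot(inherits(m, "amf_matrix"))
  cohort <- validate_cohort(cohort)
  grp <- cohort$group[match(m$samples, cohort$sample_id)]
  if (anyNA(grp)) stop("samples missing from cohort table")
  vals <- m$values
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- vals[, idx, drop = FALSE]
    na_cells <- is.na(sub)
    if (!any(na_cells)) next
    gm <- rowMeans(sub, na.rm = TRUE)
    bad <- !is.finite(gm) & rowSums(na_cells) > 0L
    if (any(bad)) {
      stop("bin ", m$bins$bin_id[which(bad)[1]],
        " has no observed value in group ", g)
    }
    sub[na_cells] <- gm[row(sub)[na_cells]]
    vals[, idx] <- sub
  }
  amf_matrix(vals, m$bins, m$samples)
}

#' PCA with a permutation-derived significance cutoff
#'
#' Centers (optionally unit-scales) the samples x bins matrix and computes
#' the top `k` principal components by SVD. The noise cutoff is obtained
#' by independently permuting each bin's values across samples `n_perm`
#' times and recording the largest variance proportion of each permuted
#' table; the cutoff is the maximum over permutations, and components with
#' observed variance proportion above it are declared significant. Loading
#' signs are fixed so each component's largest-magnitude loading is
#' positive.
#'
#' @param m a complete [amf_matrix()] (impute first).
#' @param k number of components to report (default 30; truncated with a
#'   warning when it exceeds what the data support).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param scale unit-variance scale bins before PCA (default FALSE,
#'   center-only).
#' @return An `amf_pca` object: variance proportions, cutoff, significant
#'   PC indices, sample scores, loadings, centering/scaling vectors.
#' @export
pca_permutation_cutoff <- function(m, k = 30L, n_perm = 1000L, seed = 1L,
                                   scale = FALSE) {
  stopifnot(inherits(m, "amf_matrix"))
  if (anyNA(m$values)) stop("matrix has missing values; impute first")
  X <- t(m$values) # samples x bins
  n <- nrow(X)
  if (n < 3L) stop("PCA needs >= 3 samples")
  kmax <- min(n - 1L, ncol(X))
  if (k > kmax) {
    warning("k truncated from ", k, " to ", kmax)
    k <- kmax
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- NULL
  if (scale) {
    scl <- apply(Xc, 2L, sd)
    if (any(scl == 0)) stop("zero-variance bin: cannot unit-scale")
    Xc <- sweep(Xc, 2L, scl, "/")
  }
  tot <- sum(Xc^2)
  sv <- svd(Xc, nu = 0L, nv = k)
  prop <- (sv$d^2 / tot)[seq_len(k)]
  V <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  rownames(scores) <- m$samples
  colnames(V) <- colnames(scores)
  rownames(V) <- m$bins$bin_id

  set.seed(seed)
  small_side <- which.min(c(nrow(Xc), ncol(Xc)))
  perm_max <- vapply(seq_len(n_perm), function(b) {
    Xp <- Xc
    for (j in seq_len(ncol(Xc))) Xp[, j] <- Xc[sample.int(n), j]
    cp <- if (small_side == 1L) tcrossprod(Xp) else crossprod(Xp)
    eigen(cp, symmetric = TRUE, only.values = TRUE)$values[1] / tot
  }, 0)
  cutoff <- max(perm_max)

  structure(list(
    variance_proportions = prop,
    cutoff = cutoff,
    significant_pcs = which(prop > cutoff),
    scores = scores,
    rotation = V,
    center = ctr,
    scale = scl,
    total_variance = tot / (n - 1L),
    n_perm = n_perm,
    perm_max = perm_max,
    seed = seed
  ), class = "amf_pca")
}

#' @export
print.amf_pca <- function(x, ...) {
  cat(sprintf(
    "<amf_pca> %d PCs, cutoff %.4f, %d significant\n",
    length(x$variance_proportions), x$cutoff, length(x$significant_pcs)
  ))
  invisible(x)
}

#' Correlate principal components with clinical variables
#'
#' Pearson correlation with t-distribution p-values for continuous
#' variables; binary variables are coded 0/1 and run through the same
#' machinery (point-biserial correlation). Spearman coefficients are
#' computed in parallel. Zero-variance variables yield NA cells.
#'
#' @param pca an `amf_pca` from [pca_permutation_cutoff()].
#' @param cohort cohort table; all columns other than sample_id are used
#'   unless `variables` is given. The group column is coded good = 1,
#'   poor = 0.
#' @param variables optional character vector of covariate columns.
#' @param pcs PC indices to report (default: the significant PCs, or PC1
#'   if none are significant).
#' @return data.table with pc, variable, pearson_r, pearson_p,
#'   spearman_rho, spearman_p.
#' @export
correlate_pcs <- function(pca, cohort, variables = NULL, pcs = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(pcs)) {
    pcs <- if (length(pca$significant_pcs)) pca$significant_pcs else 1L
  }
  if (length(pcs) == 0L) stop("no retained PCs to correlate")
  if (is.null(variables)) variables <- setdiff(names(cohort), "sample_id")
  idx <- match(rownames(pca$scores), cohort$sample_id)
  if (anyNA(idx)) stop("PCA samples missing from cohort table")
  co <- cohort[idx]
  out <- list()
  for (v in variables) {
    x <- co[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) > 2L) stop("categorical variable ", v, " has > 2 levels")
      x <- if (identical(lev, c("good", "poor"))) {
        as.numeric(x == "good")
      } else {
        as.numeric(as.character(x) == lev[length(lev)])
      }
    }
    x <- as.numeric(x)
    degenerate <- length(unique(x[!is.na(x)])) < 2L
    for (p in pcs) {
      s <- pca$scores[, p]
      if (degenerate || sd(s) == 0) {
        out[[length(out) + 1L]] <- data.table(
          pc = p, variable = v, pearson_r = NA_real_, pearson_p = NA_real_,
          spearman_rho = NA_real_, spearman_p = NA_real_
        )
        next
      }
      ct <- cor.test(s, x, method = "pearson")
      st <- suppressWarnings(cor.test(s, x, method = "spearman",
        exact = FALSE))
      out[[length(out) + 1L]] <- data.table(
        pc = p, variable = v,
        pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
        spearman_rho = unname(st$estimate), spearman_p = st$p.value
      )
    }
  }
  rbindlist(out)
}
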