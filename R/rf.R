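# Random-forest marker selection: repeated stratified cross-validation
# over an mtry grid, ROC/AUC evaluation on train (out-of-fold) and
# held-out test samples, Gini-importance ranking, and marker annotation.

#' Random-forest configuration
#'
#' @param n_folds CV folds (default 10).
#' @param n_repeats CV repeats (default 10).
#' @param n_trees trees per forest (default 500).
#' @param mtry_grid candidate feature-subsample sizes; default
#'   `{floor(sqrt(p)/2), floor(sqrt(p)), 2*floor(sqrt(p))}` computed at
#'   fit time from the number of features.
#' @param metric model-selection metric: "auc" (default) or "accuracy",
#'   both computed from pooled out-of-fold CV predictions.
#' @param top_n markers to extract (default 20).
#' @param seed RNG seed.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_folds = 10L, n_repeats = 10L, n_trees = 500L,
                      mtry_grid = NULL, metric = c("auc", "accuracy"),
                      top_n = 20L, seed = 1L) {
  metric <- match.arg(metric)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  structure(list(
    n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
    n_trees = as.integer(n_trees), mtry_grid = mtry_grid,
    metric = metric, top_n = as.integer(top_n), seed = as.integer(seed)
  ), class = "rf_config")
}

# stratified fold assignment; every fold gets >= 1 minority sample when
# the minority group has at least n_folds members
stratified_folds <- function(groups, n_folds) {
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Scores are the predicted probability of the positive class. The AUC of
#' the tie-aware empirical ROC equals the normalized Mann–Whitney U
#' statistic.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels.
#' @param positive the positive-class label (default "good").
#' @return list with fpr, tpr, thresholds, auc.
#' @export
roc_auc <- function(scores, labels, positive = "good") {
  y <- labels == positive
  if (all(y) || !any(y)) stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  keep <- !duplicated(ss, fromLast = TRUE)
  tp <- cumsum(ys)[keep]
  fp <- cumsum(!ys)[keep]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(!y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, ss[keep]), auc = auc)
}

#' Train the random-forest marker model
#'
#' Builds candidate-DMR feature matrices with leakage-guarded imputation
#' (training cells from training-group means, test cells from overall
#' training means), selects mtry by repeated stratified CV on the chosen
#' metric, refits the forest on the full training set, and evaluates ROC
#' on pooled out-of-fold training predictions and on the held-out test
#' set. Variable importance is mean decrease in Gini impurity.
#'
#' @param m the cohort [amf_matrix()].
#' @param candidates candidate bin ids.
#' @param cohort cohort table.
#' @param train_ids,test_ids sample id vectors.
#' @param config an [rf_config()].
#' @return A `marker_model`: forest, best_mtry, cv_table, roc_train,
#'   roc_test, importance, plus the inputs needed by [rank_markers()].
#' @export
train_forest <- function(m, candidates, cohort, train_ids, test_ids,
                         config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  if (length(candidates) == 0L) stop("candidate set is empty")
  cohort <- validate_cohort(cohort)
  y_train <- factor(cohort$group[match(train_ids, cohort$sample_id)],
    levels = c("poor", "good"))
  y_test <- factor(cohort$group[match(test_ids, cohort$sample_id)],
    levels = c("poor", "good"))
  if (length(unique(y_train)) < 2L)
    stop("training set contains a single class")
  imp <- impute_train_test(m, candidates, cohort, train_ids, test_ids)
  Xtr <- imp$X_train
  Xte <- imp$X_test
  p <- ncol(Xtr)
  grid <- config$mtry_grid
  if (is.null(grid)) {
    base <- max(1L, floor(sqrt(p)))
    grid <- unique(pmax(1L, pmin(p, c(floor(base / 2), base, 2L * base))))
  }
  grid <- sort(unique(pmin(as.integer(grid), p)))

  set.seed(config$seed)
  n_tr <- nrow(Xtr)
  # out-of-fold probability of "good", per mtry, averaged over repeats
  oof <- array(NA_real_, dim = c(n_tr, length(grid), config$n_repeats))
  for (r in seq_len(config$n_repeats)) {
    fold <- stratified_folds(as.character(y_train), config$n_folds)
    for (f in seq_len(config$n_folds)) {
      hold <- fold == f
      if (!any(hold) || length(unique(y_train[!hold])) < 2L) next
      for (gi in seq_along(grid)) {
        fit <- randomForest(
          x = Xtr[!hold, , drop = FALSE], y = y_train[!hold],
          ntree = config$n_trees, mtry = grid[gi]
        )
        oof[hold, gi, r] <- predict(fit, Xtr[hold, , drop = FALSE],
          type = "prob")[, "good"]
      }
    }
  }
  cv_table <- rbindlist(lapply(seq_along(grid), function(gi) {
    probs <- rowMeans(oof[, gi, , drop = FALSE], dims = 1L, na.rm = TRUE)
    metric <- if (config$metric == "auc") {
      roc_auc(probs, as.character(y_train))$auc
    } else {
      mean((probs > 0.5) == (y_train == "good"))
    }
    data.table(mtry = grid[gi], cv_metric = metric)
  }))
  best_mtry <- cv_table$mtry[which.max(cv_table$cv_metric)]

  oof_best <- rowMeans(oof[, match(best_mtry, grid), , drop = FALSE],
    dims = 1L, na.rm = TRUE)
  roc_train <- roc_auc(oof_best, as.character(y_train))

  set.seed(derive_seed(config$seed, 2L))
  forest <- randomForest(x = Xtr, y = y_train, ntree = config$n_trees,
    mtry = best_mtry)
  test_prob <- predict(forest, Xte, type = "prob")[, "good"]
  roc_test <- roc_auc(test_prob, as.character(y_test))

  gini <- forest$importance[, "MeanDecreaseGini"]
  importance <- data.table(bin_id = colnames(Xtr), gini = as.numeric(gini))

  structure(list(
    forest = forest,
    best_mtry = best_mtry,
    cv_table = cv_table,
    roc_train = roc_train,
    roc_test = roc_test,
    oof_prob = setNames(oof_best, train_ids),
    test_prob = setNames(test_prob, test_ids),
    importance = importance,
    dropped = imp$dropped,
    config = config
  ), class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf(
    "<marker_model> %d features, mtry %d, CV %s %.3f, train AUC %.3f, test AUC %.3f\n",
    nrow(x$importance), x$best_mtry, x$config$metric,
    max(x$cv_table$cv_metric), x$roc_train$auc, x$roc_test$auc
  ))
  invisible(x)
}

#' Extract the top-ranked marker DMRs
#'
#' Ranks candidates by mean decrease in Gini (ties broken by genomic
#' coordinate) and attaches per-group AMF distribution summaries from the
#' full cohort matrix.
#'
#' @param model a `marker_model` from [train_forest()].
#' @param m the cohort [amf_matrix()].
#' @param cohort cohort table.
#' @param top_n markers to return (default: the model config's top_n).
#' @return data.table of markers with importance and per-group median/IQR.
#' @export
rank_markers <- function(model, m, cohort, top_n = NULL) {
  stopifnot(inherits(model, "marker_model"))
  cohort <- validate_cohort(cohort)
  top_n <- as.integer(top_n %||% model$config$top_n)
  imp <- copy(model$importance)
  if (top_n > nrow(imp)) {
    warning("top_n truncated to the ", nrow(imp), " available candidates")
    top_n <- nrow(imp)
  }
  coords <- parse_bin_id(imp$bin_id)
  imp[, `:=`(chrom = coords$chrom, start = coords$start, end = coords$end)]
  setorder(imp, -gini, chrom, start)
  markers <- imp[seq_len(top_n)]
  if (top_n == 0L) return(markers)
  grp <- cohort$group[match(m$samples, cohort$sample_id)]
  vals <- m$values[match(markers$bin_id, m$bins$bin_id), , drop = FALSE]
  for (g in unique(grp)) {
    v <- vals[, grp == g, drop = FALSE]
    markers[, paste0("median_", g) := apply(v, 1L, median, na.rm = TRUE)]
    markers[, paste0("iqr_", g) := apply(v, 1L, IQR, na.rm = TRUE)]
  }
  markers[]
}

#' Annotate markers with genomic features
#'
#' Classifies each marker by overlap priority exon > intron > intergenic
#' (any overlap counts) and attaches the nearest gene symbol with a
#' signed distance: 0 when overlapping, negative when the marker lies
#' left of the gene, positive when right. Markers on chromosomes absent
#' from the gene model are intergenic with no nearest gene.
#'
#' @param markers data.table with bin_id, chrom, start, end (e.g. from
#'   [rank_markers()]).
#' @param gene_model gene model table (see [read_gene_model()]).
#' @return The markers table with `feature`, `nearest_gene`,
#'   `gene_distance` columns added.
#' @export
annotate_markers <- function(markers, gene_model) {
  gm <- as.data.table(gene_model)
  need <- c("chrom", "start", "end", "gene", "feature")
  if (!all(need %in% names(gm)))
    stop("malformed gene model: needs ", paste(need, collapse = ", "))
  mk <- as.data.table(copy(markers))
  if (nrow(mk) == 0L) {
    mk[, `:=`(feature = character(), nearest_gene = character(),
      gene_distance = integer())]
    return(mk[])
  }
  mgr <- GenomicRanges::GRanges(mk$chrom,
    IRanges::IRanges(mk$start + 1L, mk$end))
  as_gr <- function(d) GenomicRanges::GRanges(d$chrom,
    IRanges::IRanges(d$start + 1L, d$end))
  exon_hit <- GenomicRanges::countOverlaps(mgr, as_gr(gm[feature == "exon"])) > 0L
  intron_hit <- GenomicRanges::countOverlaps(mgr, as_gr(gm[feature == "intron"])) > 0L
  mk[, feature := ifelse(exon_hit, "exon",
    ifelse(intron_hit, "intron", "intergenic"))]
  # gene spans: one interval per gene, deterministic order
  spans <- gm[, .(start = min(start), end = max(end)),
    by = .(gene, chrom)]
  setorder(spans, chrom, start, gene)
  ggr <- as_gr(spans)
  hits <- GenomicRanges::distanceToNearest(mgr, ggr, select = "arbitrary")
  mk[, `:=`(nearest_gene = NA_character_, gene_distance = NA_integer_)]
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dist <- S4Vectors::mcols(hits)$distance
  sgn <- ifelse(dist == 0L, 0L,
    ifelse(mk$end[qi] <= spans$start[si], -1L, 1L))
  mk$nearest_gene[qi] <- spans$gene[si]
  mk$gene_distance[qi] <- as.integer(sgn * dist)
  mk[]
}

#' Export a deduplicated gene list
#'
#' Writes the unique nearest-gene symbols of annotated markers, one per
#' line, alphabetically ordered — the input format expected by external
#' enrichment services.
#'
#' @param annotated annotated markers from [annotate_markers()].
#' @param path output path.
#' @return The gene vector, invisibly.
#' @export
export_gene_list <- function(annotated, path) {
  genes <- sort(unique(annotated$nearest_gene))
  genes <- genes[!is.na(genes)]
  if (length(genes) == 0L) warning("no genes to export; writing empty file")
  writeLines(genes, path)
  invisible(genes)
}
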