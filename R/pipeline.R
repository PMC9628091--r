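# End-to-end pipeline driver over the synthetic cohort: generate -> QC +
# AMF -> unsupervised PCA -> DMR screen -> random forest -> external
# validation, with a deterministic JSON run report.

#' Pipeline configuration
#'
#' Bundles every stage's configuration plus one global seed from which
#' per-stage seeds are derived (see [derive_seed()]), so stages are
#' independently reproducible. Serializes losslessly to JSON.
#'
#' @param sim a [sim_config()].
#' @param max_null_fraction strict per-bin missingness bound (default
#'   0.10).
#' @param min_conversion,min_depth sample QC gates.
#' @param pca_k,pca_n_perm,pca_scale PCA stage settings.
#' @param sd_z_threshold variance-screen cutoff (default 2).
#' @param train_fraction train/test split (default 0.85).
#' @param n_subsets bootstrap subsets (default 3).
#' @param coverage_threshold,z_threshold,q_threshold,q_method DMR screen
#'   settings.
#' @param top_k rank-intersection cutoff (default 500).
#' @param rf an [rf_config()] (its seed is overridden by the global
#'   seed derivation).
#' @param n_healthy external healthy samples to simulate (default 12).
#' @param min_region_fraction external-sample coverage rule (default
#'   0.5).
#' @param seed global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            max_null_fraction = 0.10,
                            min_conversion = 0.99, min_depth = 3,
                            pca_k = 30L, pca_n_perm = 1000L,
                            pca_scale = FALSE, sd_z_threshold = 2,
                            train_fraction = 0.85, n_subsets = 3L,
                            coverage_threshold = 0.90, z_threshold = 2,
                            q_threshold = 0.05, q_method = "bh",
                            top_k = 500L, rf = rf_config(),
                            n_healthy = 12L, min_region_fraction = 0.5,
                            seed = 1L) {
  structure(list(
    sim = sim, max_null_fraction = max_null_fraction,
    min_conversion = min_conversion, min_depth = min_depth,
    pca_k = as.integer(pca_k), pca_n_perm = as.integer(pca_n_perm),
    pca_scale = pca_scale, sd_z_threshold = sd_z_threshold,
    train_fraction = train_fraction, n_subsets = as.integer(n_subsets),
    coverage_threshold = coverage_threshold, z_threshold = z_threshold,
    q_threshold = q_threshold, q_method = q_method,
    top_k = as.integer(top_k), rf = rf,
    n_healthy = as.integer(n_healthy),
    min_region_fraction = min_region_fraction,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Runs generate -> mask + QC + AMF assembly -> variance screen +
#' permutation PCA + PC correlations -> stratified split + bootstrap DMR
#' screen + rank intersection -> random-forest marker selection and
#' annotation -> simulated healthy-cohort validation. Returns (and
#' optionally writes) a run report whose counts satisfy the containment
#' chain markers <= candidates <= intersection <= min subset DMRs <=
#' tested bins <= retained bins. Identical configs give byte-identical
#' report JSON.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for report.json and key
#'   artifacts (AMF table, marker BED, gene list).
#' @param verbose log stage boundaries with counts (default TRUE).
#' @return list with `report` plus the main in-memory objects (`matrix`,
#'   `pca`, `screens`, `selection`, `model`, `markers`, `validation`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- list(
    simulate = derive_seed(config$seed, 1L),
    pca = derive_seed(config$seed, 2L),
    split = derive_seed(config$seed, 3L),
    subsets = derive_seed(config$seed, 4L),
    rf = derive_seed(config$seed, 5L),
    healthy = derive_seed(config$seed, 6L)
  )

  # --- stage 1: simulate ----------------------------------------------
  sim_args <- unclass(config$sim)
  sim_args$seed <- seeds$simulate
  sim_cfg <- do.call(sim_config, sim_args)
  sim <- simulate_cohort(sim_cfg)
  say("simulate: %d samples, %d bins, %d planted DMRs",
    nrow(sim$cohort), sim_cfg$n_bins, length(sim$truth$dmr_bin_ids))

  # --- stage 2: QC + AMF ----------------------------------------------
  catalog <- as.data.table(sim$catalog)
  masked_catalog <- {
    cat_calls <- methylation_calls("catalog", data.table(
      chrom = catalog$chrom, pos = catalog$pos,
      n_methylated = 0L, n_total = 1L, context = "CpG"
    ))
    apply_mask(cat_calls, sim$mask)$records[, .(chrom, pos)]
  }
  bins_ref <- count_cpgs_per_bin(masked_catalog, sim$scheme)
  bins_ref <- bins_ref[n_cpgs >= sim$scheme$min_cpgs]
  amf_list <- list()
  qc <- list()
  for (s in names(sim$calls)) {
    # restricting to the masked catalog drops masked CpGs (masking and
    # binning commute), so no per-sample interval overlap is needed
    a <- compute_amf(sim$calls[[s]]$cpg, sim$scheme, masked_catalog,
      bins = bins_ref)
    amf_list[[s]] <- a
    qc[[s]] <- sample_qc(a, sim$calls[[s]]$chh,
      min_conversion = config$min_conversion, min_depth = config$min_depth)
  }
  asm <- assemble_matrix(amf_list, qc,
    max_null_fraction = config$max_null_fraction)
  m <- asm$matrix
  say("amf: %d/%d samples pass QC, %d/%d bins retained",
    length(m$samples), nrow(sim$cohort), asm$n_bins_retained,
    asm$n_bins_total)

  # --- stage 3: unsupervised ------------------------------------------
  screened <- variance_screen(m, z_threshold = config$sd_z_threshold)
  imputed <- impute_group_means(screened, sim$cohort)
  pca <- pca_permutation_cutoff(imputed, k = config$pca_k,
    n_perm = config$pca_n_perm, seed = seeds$pca, scale = config$pca_scale)
  pc_cor <- correlate_pcs(pca, sim$cohort)
  say("pca: %d screened bins, %d significant PCs (cutoff %.4f)",
    nrow(screened$bins), length(pca$significant_pcs), pca$cutoff)

  # --- stage 4: DMR screen --------------------------------------------
  split <- stratified_split(sim$cohort,
    train_fraction = config$train_fraction, seed = seeds$split)
  subsets <- draw_subsets(split$train, sim$cohort,
    n_subsets = config$n_subsets, seed = seeds$subsets)
  screens <- lapply(subsets, function(ids) {
    screen_subset(m, ids, sim$cohort,
      coverage_threshold = config$coverage_threshold,
      z_threshold = config$z_threshold, q_threshold = config$q_threshold,
      q_method = config$q_method)
  })
  selection <- intersect_and_rank(screens, top_k = config$top_k)
  say("dmr: subset DMRs %s, intersection %d, candidates %d",
    paste(vapply(screens, function(s) length(s$dmrs), 0L), collapse = "/"),
    length(selection$intersection), length(selection$candidates))

  truth_ids <- sim$truth$dmr_bin_ids
  recall <- if (length(truth_ids)) {
    mean(truth_ids %in% selection$candidates)
  } else {
    NA_real_
  }
  precision <- if (length(selection$candidates)) {
    mean(selection$candidates %in% truth_ids)
  } else {
    NA_real_
  }
  hypo_frac <- {
    sel_dir <- unlist(lapply(screens, function(s) {
      s$stats$direction[s$stats$bin_id %in% selection$candidates &
        s$stats$direction != "none"]
    }))
    if (length(sel_dir)) mean(sel_dir == "hypo") else NA_real_
  }

  # --- stage 5: random forest -----------------------------------------
  rf_cfg <- config$rf
  rf_cfg$seed <- seeds$rf
  model <- train_forest(m, selection$candidates, sim$cohort,
    split$train, split$test, config = rf_cfg)
  markers <- rank_markers(model, m, sim$cohort)
  markers <- annotate_markers(markers, sim$gene_model)
  say("rf: mtry %d, train AUC %.3f, test AUC %.3f, %d markers",
    model$best_mtry, model$roc_train$auc, model$roc_test$auc,
    nrow(markers))

  # --- stage 6: external validation -----------------------------------
  regions <- markers[, .(chrom, start, end)]
  marker_truth <- sim$truth$per_bin_group_means[
    match(markers$bin_id, bin_id)]
  healthy <- simulate_healthy_bedset(sim_cfg, regions,
    n_samples = config$n_healthy,
    region_means = marker_truth$mean_poor, seed = seeds$healthy)
  excl <- exclude_low_coverage_samples(healthy$calls, regions,
    min_region_fraction = config$min_region_fraction)
  ext <- external_amf_matrix(healthy$calls[excl$retained], regions)
  comparison <- compare_distributions(m, sim$cohort, ext)
  say("validate: %d/%d healthy samples retained, %d/%d regions compared",
    length(excl$retained), config$n_healthy,
    sum(comparison$covered), nrow(comparison))

  report <- list(
    config_hash = config_hash(unclass_config(config)),
    seeds = seeds,
    counts = list(
      n_samples = nrow(sim$cohort),
      n_samples_pass_qc = length(m$samples),
      n_bins_simulated = sim_cfg$n_bins,
      n_bins_eligible = asm$n_bins_total,
      n_bins_retained = asm$n_bins_retained,
      n_bins_variance_screened = nrow(screened$bins),
      n_train = length(split$train),
      n_test = length(split$test),
      n_tested_per_subset = vapply(screens, function(s) s$n_tested, 0L),
      n_dmrs_per_subset = vapply(screens, function(s) length(s$dmrs), 0L),
      n_intersection = length(selection$intersection),
      n_candidates = length(selection$candidates),
      n_markers = nrow(markers)
    ),
    unsupervised = list(
      n_significant_pcs = length(pca$significant_pcs),
      cutoff = pca$cutoff,
      top_pc_group_r = {
        gr <- pc_cor[variable == "group"]
        if (nrow(gr)) gr$pearson_r[which.max(abs(gr$pearson_r))] else NA_real_
      }
    ),
    dmr = list(
      recall = recall,
      precision = precision,
      hypo_fraction = hypo_frac
    ),
    rf = list(
      best_mtry = model$best_mtry,
      cv_metric = max(model$cv_table$cv_metric),
      auc_train = model$roc_train$auc,
      auc_test = model$roc_test$auc
    ),
    markers = list(
      bin_ids = markers$bin_id,
      features = markers$feature,
      genes = markers$nearest_gene
    ),
    validation = list(
      n_external_retained = length(excl$retained),
      n_regions_compared = sum(comparison$covered),
      stringent_fraction = mean(comparison$stringent, na.rm = TRUE)
    ),
    config = unclass_config(config)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_amf_table(m, file.path(outdir, "amf_table.tsv"))
    fwrite(markers, file.path(outdir, "markers.tsv"), sep = "\t")
    export_gene_list(markers, file.path(outdir, "gene_list.txt"))
  }

  invisible(list(
    report = report, sim = sim, matrix = m, pca = pca,
    pc_correlations = pc_cor, split = split, screens = screens,
    selection = selection, model = model, markers = markers,
    validation = comparison
  ))
}

# strip S3 classes recursively so the config serializes as plain JSON
unclass_config <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) if (is.list(v)) unclass_config(v) else v)
}

#' Serialize the report to a canonical JSON string
#' @param report a run report list.
#' @return A JSON character scalar.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
    pretty = TRUE))
}
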