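# Synthetic cohort generator. Emulates the study design the pipeline
# assumes: two unbalanced clinical groups, beta-distributed per-bin
# methylation concentrated near 1 with narrow spread, a minority of
# planted DMR bins hypomethylated and widened in the "good" group,
# depth-limited coverage producing missing bins, and nuisance clinical
# covariates independent of group.

#' Reference cohort counts
#'
#' Printed characteristics of the study population the generator emulates:
#' 143 patients with chronic total coronary occlusion, grouped by coronary
#' collateral circulation (CCC) grade (109 good / 34 poor), with risk-factor
#' counts. Used to parameterize the generator's covariate prevalences and
#' to re-derive prevalence percentages.
#'
#' @return Named list of integer counts.
#' @export
reference_counts <- function() {
  list(
    n_total = 143L, n_good = 109L, n_poor = 34L,
    male = 102L, hypertension = 68L, diabetes = 34L,
    smoking = 19L, hypercholesterolemia = 11L, acs = 89L,
    age_mean = 57.8, age_sd = 10.6
  )
}

#' Reference prevalences (percent)
#'
#' Re-derives risk-factor prevalence percentages from the printed counts,
#' rounded to one decimal as reported.
#'
#' @return Named numeric vector of percentages.
#' @export
reference_prevalences <- function() {
  rc <- reference_counts()
  vars <- c("male", "hypertension", "diabetes", "smoking",
    "hypercholesterolemia", "acs")
  p <- vapply(vars, function(v) round(100 * rc[[v]] / rc$n_total, 1), 0)
  setNames(p, vars)
}

#' Simulation configuration
#'
#' Defaults reproduce the reference study conditions: 109 good / 34 poor
#' samples, 100-bp bins, baseline per-bin methylation Beta(45, 5) (mean
#' 0.9, narrow, near 1), planted DMRs hypomethylated in the good group by
#' `dmr_effect` with spread widened by `dmr_spread`, per-CpG Poisson depth,
#' and a per-(bin, sample) coverage dropout calibrated to `missing_target`.
#'
#' @param n_good,n_poor group sizes.
#' @param n_bins number of genomic bins simulated.
#' @param bin_width bin width in bases.
#' @param cpgs_per_bin integer range (min, max) of CpGs in dense bins;
#'   the minimum must be >= 5 so dense bins pass the density filter.
#' @param sparse_fraction fraction of bins given fewer than 5 CpGs, to
#'   exercise the density filter.
#' @param n_dmr number of planted differential bins (among dense,
#'   unmasked bins).
#' @param baseline_beta (alpha, beta) shapes for per-bin baseline mean
#'   methylation.
#' @param within_sd within-group between-sample SD of per-bin methylation.
#' @param dmr_effect mean AMF decrease in the good group at planted bins
#'   (>= 0; 0 gives a null cohort).
#' @param dmr_spread extra good-group SD at planted bins.
#' @param depth_mean mean reads per CpG (Poisson).
#' @param missing_target expected fraction of (bin, sample) cells with zero
#'   coverage; met by a bin-level dropout with probability
#'   `p0 = (missing_target - e) / (1 - e)` where
#'   `e = mean_b exp(-k_b * depth_mean)` is the residual probability that
#'   all CpGs of a bin independently receive zero reads.
#' @param chh_error per-read CHH false-methylation probability; the true
#'   conversion rate is `1 - chh_error`.
#' @param n_chh CHH positions simulated per sample.
#' @param mask_fraction fraction of bins blacked out by the simulated
#'   blacklist.
#' @param n_chrom number of synthetic chromosomes the bins are spread over.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_good = 109L, n_poor = 34L, n_bins = 5000L,
                       bin_width = 100L, cpgs_per_bin = c(5L, 10L),
                       sparse_fraction = 0.2, n_dmr = 100L,
                       baseline_beta = c(45, 5), within_sd = 0.03,
                       dmr_effect = 0.3, dmr_spread = 0.05,
                       depth_mean = 8, missing_target = 0.05,
                       chh_error = 0.002, n_chh = 2000L,
                       mask_fraction = 0.01, n_chrom = 2L, seed = 1L) {
  cfg <- list(
    n_good = as.integer(n_good), n_poor = as.integer(n_poor),
    n_bins = as.integer(n_bins), bin_width = as.integer(bin_width),
    cpgs_per_bin = as.integer(cpgs_per_bin),
    sparse_fraction = sparse_fraction, n_dmr = as.integer(n_dmr),
    baseline_beta = as.numeric(baseline_beta), within_sd = within_sd,
    dmr_effect = dmr_effect, dmr_spread = dmr_spread,
    depth_mean = depth_mean, missing_target = missing_target,
    chh_error = chh_error, n_chh = as.integer(n_chh),
    mask_fraction = mask_fraction, n_chrom = as.integer(n_chrom),
    seed = as.integer(seed)
  )
  bad <- function(field, why) stop("invalid sim_config: ", field, " ", why)
  if (cfg$n_good < 2L) bad("n_good", "must be >= 2")
  if (cfg$n_poor < 2L) bad("n_poor", "must be >= 2")
  if (cfg$n_bins < 1L) bad("n_bins", "must be positive")
  if (cfg$n_dmr >= cfg$n_bins) bad("n_dmr", "must be < n_bins")
  if (cfg$n_dmr < 0L) bad("n_dmr", "must be >= 0")
  if (length(cfg$cpgs_per_bin) != 2L || cfg$cpgs_per_bin[1] < 5L)
    bad("cpgs_per_bin", "must be a (min >= 5, max) pair")
  if (cfg$cpgs_per_bin[2] < cfg$cpgs_per_bin[1])
    bad("cpgs_per_bin", "max must be >= min")
  if (cfg$cpgs_per_bin[2] >= cfg$bin_width)
    bad("cpgs_per_bin", "max must be < bin_width")
  for (f in c("sparse_fraction", "missing_target", "chh_error",
    "mask_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must be a probability in [0,1]")
  }
  if (cfg$dmr_effect < 0) bad("dmr_effect", "must be >= 0")
  if (cfg$dmr_spread < 0) bad("dmr_spread", "must be >= 0")
  if (cfg$within_sd <= 0) bad("within_sd", "must be > 0")
  if (cfg$depth_mean <= 0) bad("depth_mean", "must be > 0")
  if (any(cfg$baseline_beta <= 0)) bad("baseline_beta", "shapes must be > 0")
  if (cfg$n_chrom < 1L) bad("n_chrom", "must be >= 1")
  structure(cfg, class = "sim_config")
}

# beta shapes from (mean, sd), clamping sd to the feasible range near the
# boundaries so the reparameterization stays well defined
beta_shapes <- function(mean, sd) {
  mean <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  sd_max <- 0.9 * sqrt(mean * (1 - mean))
  sd <- pmin(sd, sd_max)
  nu <- mean * (1 - mean) / sd^2 - 1
  list(a = mean * nu, b = (1 - mean) * nu)
}

#' Simulate a methylation cohort
#'
#' Generates per-sample per-CpG (and per-CHH) methylation call sets, a
#' sample sheet with nuisance clinical covariates independent of group, a
#' blacklist, a gene model, the reference CpG catalog, and the ground
#' truth of planted DMRs. Per-bin per-sample methylation is beta
#' distributed around the bin's group mean; per-CpG read depth is Poisson;
#' methylated counts are binomial given depth and the sample's bin-level
#' methylation.
#'
#' @param config a [sim_config()].
#' @return A `sim_cohort` list with elements `calls` (sample_id -> list of
#'   CpG/CHH [methylation_calls()]), `cohort` (sample sheet), `truth`
#'   (dmr_bin_ids, per_bin_group_means, per_sample_conversion_rate),
#'   `catalog`, `chrom_sizes`, `mask`, `gene_model`, `scheme`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_samples <- cfg$n_good + cfg$n_poor

  # --- genome layout ---------------------------------------------------
  bins_per_chrom <- ceiling(cfg$n_bins / cfg$n_chrom)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  chrom_of_bin <- chroms[((seq_len(cfg$n_bins) - 1L) %/% bins_per_chrom) + 1L]
  start_of_bin <- (((seq_len(cfg$n_bins) - 1L) %% bins_per_chrom)) *
    cfg$bin_width
  chrom_sizes <- setNames(
    vapply(chroms, function(ch) {
      as.integer(max(start_of_bin[chrom_of_bin == ch]) + cfg$bin_width)
    }, 0L),
    chroms
  )
  bins <- data.table(
    bin = seq_len(cfg$n_bins), chrom = chrom_of_bin,
    start = as.integer(start_of_bin),
    end = as.integer(start_of_bin + cfg$bin_width)
  )
  bins[, bin_id := bin_id(chrom, start, end)]

  # CpG density: a fraction of bins falls below the 5-CpG eligibility gate
  sparse <- runif(cfg$n_bins) < cfg$sparse_fraction
  k <- integer(cfg$n_bins)
  k[!sparse] <- sample(cfg$cpgs_per_bin[1]:cfg$cpgs_per_bin[2],
    sum(!sparse), replace = TRUE)
  k[sparse] <- sample(1:4, sum(sparse), replace = TRUE)

  # blacklist: whole bins masked out
  n_masked <- round(cfg$mask_fraction * cfg$n_bins)
  masked <- rep(FALSE, cfg$n_bins)
  if (n_masked > 0L) masked[sample.int(cfg$n_bins, n_masked)] <- TRUE
  mask <- region_mask(bins[masked, .(chrom, start, end)])

  # planted DMRs only among dense, unmasked bins (recoverable truth)
  eligible <- which(!sparse & !masked)
  if (cfg$n_dmr > length(eligible))
    stop("invalid sim_config: n_dmr exceeds the number of dense unmasked bins")
  dmr_bins <- sort(sample(eligible, cfg$n_dmr))
  is_dmr <- rep(FALSE, cfg$n_bins)
  is_dmr[dmr_bins] <- TRUE

  # CpG positions, uniform within bin without collision
  offsets <- lapply(k, function(kk) sort(sample.int(cfg$bin_width - 1L, kk)))
  cpg <- data.table(
    bin = rep(seq_len(cfg$n_bins), k),
    chrom = rep(chrom_of_bin, k),
    pos = as.integer(rep(start_of_bin, k) + unlist(offsets) - 1L)
  )

  # --- group methylation model ----------------------------------------
  m0 <- rbeta(cfg$n_bins, cfg$baseline_beta[1], cfg$baseline_beta[2])
  mean_poor <- m0
  mean_good <- ifelse(is_dmr, pmax(m0 - cfg$dmr_effect, 0.02), m0)
  sd_good <- ifelse(is_dmr, cfg$within_sd + cfg$dmr_spread, cfg$within_sd)
  shp_poor <- beta_shapes(mean_poor, cfg$within_sd)
  shp_good <- beta_shapes(mean_good, sd_good)

  # dropout probability solving the missingness target (see sim_config)
  e_resid <- mean(exp(-k * cfg$depth_mean))
  p0 <- max(0, (cfg$missing_target - e_resid) / (1 - e_resid))

  # --- samples ---------------------------------------------------------
  rc <- reference_counts()
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  group <- c(rep("good", cfg$n_good), rep("poor", cfg$n_poor))
  cohort <- data.table(
    sample_id = sample_ids,
    group = group,
    age = round(rnorm(n_samples, rc$age_mean, rc$age_sd), 1),
    sex = rbinom(n_samples, 1L, rc$male / rc$n_total),
    hypertension = rbinom(n_samples, 1L, rc$hypertension / rc$n_total),
    diabetes = rbinom(n_samples, 1L, rc$diabetes / rc$n_total),
    smoking = rbinom(n_samples, 1L, rc$smoking / rc$n_total)
  )

  chh_pos <- data.table(
    chrom = sample(chroms, cfg$n_chh, replace = TRUE),
    pos = as.integer(floor(runif(cfg$n_chh) * (min(chrom_sizes) - 1L)))
  )
  chh_pos <- unique(chh_pos, by = c("chrom", "pos"))
  setorder(chh_pos, chrom, pos)

  n_cpg <- nrow(cpg)
  bin_of_cpg <- cpg$bin
  calls <- vector("list", n_samples)
  names(calls) <- sample_ids
  for (i in seq_len(n_samples)) {
    if (group[i] == "good") {
      theta_bin <- rbeta(cfg$n_bins, shp_good$a, shp_good$b)
    } else {
      theta_bin <- rbeta(cfg$n_bins, shp_poor$a, shp_poor$b)
    }
    drop_bin <- runif(cfg$n_bins) < p0
    depth <- rpois(n_cpg, cfg$depth_mean)
    depth[drop_bin[bin_of_cpg]] <- 0L
    meth <- rbinom(n_cpg, depth, theta_bin[bin_of_cpg])
    keep <- depth > 0L
    cpg_rec <- data.table(
      chrom = cpg$chrom[keep], pos = cpg$pos[keep],
      n_methylated = meth[keep], n_total = depth[keep], context = "CpG"
    )
    chh_depth <- rpois(nrow(chh_pos), cfg$depth_mean)
    chh_meth <- rbinom(nrow(chh_pos), chh_depth, cfg$chh_error)
    chh_keep <- chh_depth > 0L
    chh_rec <- data.table(
      chrom = chh_pos$chrom[chh_keep], pos = chh_pos$pos[chh_keep],
      n_methylated = chh_meth[chh_keep], n_total = chh_depth[chh_keep],
      context = "CHH"
    )
    calls[[i]] <- list(
      cpg = methylation_calls(sample_ids[i], cpg_rec),
      chh = methylation_calls(sample_ids[i], chh_rec)
    )
  }

  truth <- list(
    dmr_bin_ids = bins$bin_id[dmr_bins],
    per_bin_group_means = data.table(
      bin_id = bins$bin_id, dmr = is_dmr,
      mean_good = mean_good, mean_poor = mean_poor
    ),
    per_sample_conversion_rate = setNames(
      rep(1 - cfg$chh_error, n_samples), sample_ids
    )
  )

  structure(list(
    calls = calls,
    cohort = cohort,
    truth = truth,
    catalog = cpg[, .(chrom, pos)],
    chrom_sizes = chrom_sizes,
    mask = mask,
    gene_model = make_gene_model(chrom_sizes),
    scheme = bin_scheme(chrom_sizes, cfg$bin_width, 5L),
    config = cfg
  ), class = "sim_cohort")
}

# simple recurrent gene structure: a 2-kb gene every 5 kb with three
# 200-bp exons, introns filling the gaps; enough to exercise annotation
make_gene_model <- function(chrom_sizes) {
  rows <- list()
  gi <- 0L
  for (ch in names(chrom_sizes)) {
    starts <- seq(0L, max(0L, chrom_sizes[[ch]] - 2000L), by = 5000L)
    for (s in starts) {
      gi <- gi + 1L
      gene <- sprintf("GENE%04d", gi)
      ex <- data.table(
        chrom = ch, start = as.integer(s + c(0L, 900L, 1800L)),
        end = as.integer(s + c(200L, 1100L, 2000L)),
        gene = gene, feature = "exon"
      )
      intr <- data.table(
        chrom = ch, start = as.integer(s + c(200L, 1100L)),
        end = as.integer(s + c(900L, 1800L)),
        gene = gene, feature = "intron"
      )
      rows[[gi]] <- rbind(ex, intr)
    }
  }
  out <- rbindlist(rows)
  setorder(out, chrom, start)
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the external-format artifacts of a simulated cohort: one bedGraph
#' call file per sample per context, the sample sheet, the blacklist BED,
#' the gene model, the CpG catalog, chromosome sizes, and the ground-truth
#' table of planted DMRs.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(sim$calls)) {
    write_calls(sim$calls[[s]]$cpg, file.path(dir, paste0(s, "_CpG.bedGraph")))
    write_calls(sim$calls[[s]]$chh, file.path(dir, paste0(s, "_CHH.bedGraph")))
  }
  write_sample_sheet(sim$cohort, file.path(dir, "sample_sheet.tsv"))
  fwrite(as.data.table(sim$mask), file.path(dir, "blacklist.bed"),
    sep = "\t", col.names = FALSE, quote = FALSE)
  fwrite(sim$gene_model, file.path(dir, "gene_model.tsv"),
    sep = "\t", quote = FALSE)
  fwrite(sim$catalog, file.path(dir, "cpg_catalog.tsv"),
    sep = "\t", quote = FALSE)
  fwrite(data.table(chrom = names(sim$chrom_sizes),
    size = as.integer(sim$chrom_sizes)),
    file.path(dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE)
  tr <- sim$truth$per_bin_group_means[dmr == TRUE,
    .(bin_id, mean_good, mean_poor)]
  fwrite(tr, file.path(dir, "truth_dmrs.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Simulate an external healthy-cohort bed set
#'
#' Emulates published healthy cfDNA per-CpG call files over a set of
#' marker regions. Healthy methylation follows the near-1 narrow model of
#' the poor group, slightly tighter (between-sample SD 0.015), matching
#' the expectation that healthy cfDNA is at least as stringent as the
#' poor-group distribution.
#'
#' @param config a [sim_config()] (baseline model is reused).
#' @param marker_regions data.frame with chrom, start, end (half-open).
#' @param n_samples number of healthy samples (default 12).
#' @param region_means optional vector of true mean methylation per
#'   region (e.g. the poor-group means of the marker bins); when NULL,
#'   means are drawn fresh from the baseline beta model.
#' @param depth_mean mean reads per CpG for the healthy set (default 30:
#'   published healthy cfDNA reference sets are sequenced deeper than the
#'   depth-limited study samples).
#' @param seed seed (default: config seed).
#' @return list with `calls` (per-sample CpG [methylation_calls()]) and
#'   `truth` (per-region true healthy mean methylation).
#' @export
simulate_healthy_bedset <- function(config, marker_regions, n_samples = 12L,
                                    region_means = NULL, depth_mean = 30,
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  regions <- as.data.table(marker_regions)
  if (nrow(regions) == 0L) stop("marker_regions must be non-empty")
  set.seed(seed)
  healthy_sd <- 0.015
  k <- sample(config$cpgs_per_bin[1]:config$cpgs_per_bin[2],
    nrow(regions), replace = TRUE)
  mu <- if (is.null(region_means)) {
    rbeta(nrow(regions), config$baseline_beta[1], config$baseline_beta[2])
  } else {
    if (length(region_means) != nrow(regions))
      stop("region_means must match the number of regions")
    as.numeric(region_means)
  }
  shp <- beta_shapes(mu, healthy_sd)
  pos <- lapply(seq_len(nrow(regions)), function(i) {
    width <- regions$end[i] - regions$start[i]
    regions$start[i] + sort(sample.int(width - 1L, min(k[i], width - 1L))) - 1L
  })
  cpg <- data.table(
    region = rep(seq_len(nrow(regions)), lengths(pos)),
    chrom = rep(regions$chrom, lengths(pos)),
    pos = as.integer(unlist(pos))
  )
  calls <- vector("list", n_samples)
  ids <- sprintf("H%02d", seq_len(n_samples))
  names(calls) <- ids
  for (i in seq_len(n_samples)) {
    theta <- rbeta(nrow(regions), shp$a, shp$b)
    depth <- rpois(nrow(cpg), depth_mean)
    meth <- rbinom(nrow(cpg), depth, theta[cpg$region])
    keep <- depth > 0L
    calls[[i]] <- methylation_calls(ids[i], data.table(
      chrom = cpg$chrom[keep], pos = cpg$pos[keep],
      n_methylated = meth[keep], n_total = depth[keep], context = "CpG"
    ))
  }
  list(
    calls = calls,
    truth = data.table(
      chrom = regions$chrom, start = regions$start, end = regions$end,
      healthy_mean = mu
    )
  )
}
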