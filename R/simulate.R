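#' Configuration for a simulated reciprocal-congenic pair
#'
#' Defines the two paired expression experiments the generator emulates:
#' experiment A compares 8 vs 8 animals per group and experiment B 6 vs 6
#' (the less powerful earlier design), each profiling the same five brain
#' regions. A subset of probe sets located inside the introgressed interval
#' carries an allele-driven log2 expression shift (`delta`) identical in
#' both experiments — the biological premise of the concordance design,
#' since both congenics carry the same two alleles of each interval gene —
#' and optional trans-regulated probe sets outside the interval carry
#' effects of their own.
#'
#' The generative model for probe set g, animal i, region r is
#' `baseline_g + region_offset_r + animal_i + delta_g * [iP carrier] + noise`
#' with homoscedastic normal noise on the log2 scale. Detection calls are
#' Bernoulli with present-probability logistic in the realized log2 value
#' (midpoint 6, slope 1.5, giving realistic absent fractions for low
#' expressors).
#'
#' @param n_animals_a,n_animals_b Animals per group in experiments A and B
#'   (defaults 8 and 6).
#' @param regions Brain regions profiled (default the five study regions).
#' @param n_probe_sets Number of probe sets simulated.
#' @param cis_interval The introgressed interval ([qtl_interval()] default).
#' @param frac_interval Fraction of probe sets located inside the interval.
#' @param frac_cis_regulated Fraction of in-interval probe sets given a true
#'   allele effect.
#' @param n_trans_regulated Number of out-of-interval probe sets given
#'   effects.
#' @param delta_sd Standard deviation of the normal allele-effect
#'   distribution (mean 0), log2 units.
#' @param delta_min_abs Minimum |delta|; draws closer to zero are resampled.
#' @param delta_value Optional fixed |delta| (random sign) overriding the
#'   normal draw — used for calibration studies at a known effect size.
#' @param sigma_resid Residual (array-level) sd, log2 units.
#' @param sigma_animal Animal random-effect sd, log2 units.
#' @param region_offsets Per-region baseline shifts (named or positional).
#' @param baseline_mean,baseline_sd Log2 baseline distribution parameters.
#' @param detection_midpoint,detection_slope Logistic detection model:
#'   present-probability `plogis(slope * (value - midpoint))`.
#' @param probes_per_set Probes per probe set for the probe-level generator.
#' @param frac_snp_probes Fraction of probe sets given one SNP-offset probe.
#' @param snp_offset Log2 intensity lost by a SNP probe in iNP-allele
#'   carriers (mismatch hybridization loss), default 2.
#' @param sigma_affinity Probe affinity offset sd, log2 units.
#' @param sigma_probe Probe-level measurement noise sd, log2 units.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_animals_a = 8L, n_animals_b = 6L,
                       regions = BRAIN_REGIONS,
                       n_probe_sets = 1000L,
                       cis_interval = qtl_interval(),
                       frac_interval = 0.1,
                       frac_cis_regulated = 0.3,
                       n_trans_regulated = 0L,
                       delta_sd = 0.4, delta_min_abs = 0.1,
                       delta_value = NULL,
                       sigma_resid = 0.2, sigma_animal = 0.1,
                       region_offsets = NULL,
                       baseline_mean = 8, baseline_sd = 1.5,
                       detection_midpoint = 6, detection_slope = 1.5,
                       probes_per_set = 11L,
                       frac_snp_probes = 0,
                       snp_offset = 2.0,
                       sigma_affinity = 0.5,
                       sigma_probe = 0.2,
                       seed = 1L) {
  if (is.null(region_offsets)) {
    region_offsets <- stats::setNames(
      seq(-0.2, 0.2, length.out = length(regions)), regions)
  }
  cfg <- list(
    n_animals_a = as.integer(n_animals_a),
    n_animals_b = as.integer(n_animals_b),
    regions = as.character(regions),
    n_probe_sets = as.integer(n_probe_sets),
    cis_interval = cis_interval,
    frac_interval = frac_interval,
    frac_cis_regulated = frac_cis_regulated,
    n_trans_regulated = as.integer(n_trans_regulated),
    delta_sd = delta_sd, delta_min_abs = delta_min_abs,
    delta_value = delta_value,
    sigma_resid = sigma_resid, sigma_animal = sigma_animal,
    region_offsets = region_offsets,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    detection_midpoint = detection_midpoint,
    detection_slope = detection_slope,
    probes_per_set = as.integer(probes_per_set),
    frac_snp_probes = frac_snp_probes,
    snp_offset = snp_offset,
    sigma_affinity = sigma_affinity,
    sigma_probe = sigma_probe,
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_animals_a, cfg$n_animals_b, cfg$n_probe_sets,
              cfg$probes_per_set)
  fracs <- c(cfg$frac_interval, cfg$frac_cis_regulated, cfg$frac_snp_probes)
  sigmas <- c(cfg$delta_sd, cfg$sigma_resid, cfg$sigma_animal,
              cfg$sigma_affinity, cfg$sigma_probe)
  if (any(counts <= 0) || length(cfg$regions) < 1) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(sigmas < 0) || cfg$n_trans_regulated < 0) {
    stop("sigma values must be >= 0 and n_trans_regulated >= 0",
         call. = FALSE)
  }
  if (!inherits(cfg$cis_interval, "genomic_interval")) {
    stop("cis_interval must be a genomic_interval", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Allele log2 effects: fixed magnitude with random sign, or normal draws
# resampled away from zero.
draw_deltas <- function(n, cfg) {
  if (n == 0) return(numeric(0))
  if (!is.null(cfg$delta_value)) {
    return(sample(c(-1, 1), n, replace = TRUE) * cfg$delta_value)
  }
  d <- stats::rnorm(n, 0, cfg$delta_sd)
  while (any(abs(d) < cfg$delta_min_abs)) {
    i <- abs(d) < cfg$delta_min_abs
    d[i] <- stats::rnorm(sum(i), 0, cfg$delta_sd)
  }
  d
}

simulate_one_experiment <- function(cfg, label, n_per_group, baseline, delta) {
  regions <- cfg$regions
  animals <- c(sprintf("%s_iP_%02d", label, seq_len(n_per_group)),
               sprintf("%s_iNP_%02d", label, seq_len(n_per_group)))
  groups <- rep(c("iP", "iNP"), each = n_per_group)
  sheet <- expand.grid(animal_id = animals, region = regions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$group <- groups[match(sheet$animal_id, animals)]
  sheet$sample_id <- paste(sheet$animal_id, sheet$region, sep = ".")
  sheet <- sheet[, c("sample_id", "animal_id", "group", "region")]
  animal_eff <- stats::setNames(
    stats::rnorm(length(animals), 0, cfg$sigma_animal), animals)
  n_g <- cfg$n_probe_sets
  vals <- matrix(NA_real_, n_g, nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    allele <- if (sheet$group[j] == "iP") delta else 0
    vals[, j] <- baseline + cfg$region_offsets[[sheet$region[j]]] +
      animal_eff[[sheet$animal_id[j]]] + allele +
      stats::rnorm(n_g, 0, cfg$sigma_resid)
  }
  dimnames(vals) <- list(names(baseline), sheet$sample_id)
  p_present <- stats::plogis(
    cfg$detection_slope * (vals - cfg$detection_midpoint))
  det <- matrix(stats::runif(length(vals)) < p_present, nrow(vals),
                dimnames = dimnames(vals))
  expression_matrix(vals, sheet, det)
}

#' Simulate a pair of reciprocal congenic experiments
#'
#' Generates experiment A (iP vs P.NP design, `n_animals_a` per group) and
#' experiment B (NP.P vs iNP design, `n_animals_b` per group) over the
#' configured brain regions, with probe-set annotations and a ground-truth
#' table. Regulated probe sets share the identical allele effect `delta` in
#' both experiments; all values are log2-scale. The output is fully
#' deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `a` and `b` ([expression_matrix()] objects),
#'   `annotations` (data frame), and `truth` (data frame with columns
#'   `probe_set_id`, `locus_class` in cis/trans/null, `true_delta`,
#'   `snp_probe_id`).
#' @export
simulate_congenic_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_probe_sets
  ids <- sprintf("sim_%05d_at", seq_len(n))

  n_interval <- max(1L, round(cfg$frac_interval * n))
  in_interval <- seq_len(n_interval)
  iv <- cfg$cis_interval
  chrom <- character(n)
  pos <- numeric(n)
  chrom[in_interval] <- iv$chromosome
  pos[in_interval] <- round(stats::runif(n_interval, iv$start, iv$end))
  outside <- setdiff(seq_len(n), in_interval)
  other_chroms <- setdiff(as.character(1:20), iv$chromosome)
  chrom[outside] <- sample(other_chroms, length(outside), replace = TRUE)
  pos[outside] <- round(stats::runif(length(outside), 1, 2.5e8))
  annotations <- data.frame(
    probe_set_id = ids, chromosome = chrom, position = pos,
    gene_symbol = NA_character_, stringsAsFactors = FALSE
  )

  n_cis <- round(cfg$frac_cis_regulated * n_interval)
  cis_idx <- if (n_cis > 0) sample(in_interval, n_cis) else integer(0)
  trans_idx <- if (cfg$n_trans_regulated > 0) {
    sample(outside, min(cfg$n_trans_regulated, length(outside)))
  } else integer(0)
  delta <- numeric(n)
  delta[cis_idx] <- draw_deltas(length(cis_idx), cfg)
  delta[trans_idx] <- draw_deltas(length(trans_idx), cfg)
  locus_class <- rep("null", n)
  locus_class[cis_idx] <- "cis"
  locus_class[trans_idx] <- "trans"

  snp_probe <- rep(NA_character_, n)
  if (cfg$frac_snp_probes > 0) {
    n_snp <- round(cfg$frac_snp_probes * n)
    snp_sets <- sample(seq_len(n), n_snp)
    snp_probe[snp_sets] <- sprintf(
      "%s_p%02d", ids[snp_sets],
      sample(cfg$probes_per_set, n_snp, replace = TRUE))
  }
  truth <- data.frame(
    probe_set_id = ids, locus_class = locus_class, true_delta = delta,
    snp_probe_id = snp_probe, stringsAsFactors = FALSE
  )

  baseline <- stats::setNames(
    stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd), ids)
  a <- simulate_one_experiment(cfg, "A", cfg$n_animals_a, baseline, delta)
  b <- simulate_one_experiment(cfg, "B", cfg$n_animals_b, baseline, delta)
  list(a = a, b = b, annotations = annotations, truth = truth)
}

#' Simulate probe-level intensities for one experiment
#'
#' Expands a probe-set expression matrix to individual probe intensities:
#' each probe inherits its probe set's per-sample value plus a fixed probe
#' affinity offset and measurement noise. Probes designated as SNP probes in
#' the truth table lose `snp_offset` log2 units in iNP-allele carriers only,
#' mimicking mismatch hybridization loss over a strain-specific variant.
#'
#' @param cfg The [sim_config()] used to generate the pair.
#' @param truth Truth table from [simulate_congenic_pair()].
#' @param m The probe-set [expression_matrix()] to expand (e.g. the `a`
#'   element of the simulated pair).
#' @return A [probe_matrix()] with `probes_per_set` probes per probe set.
#' @export
simulate_probe_level <- function(cfg, truth, m) {
  stopifnot(inherits(cfg, "sim_config"), inherits(m, "expression_matrix"))
  set.seed(cfg$seed + 1L)
  ids <- rownames(m$values)
  k <- cfg$probes_per_set
  probe_ids <- as.vector(t(outer(ids, seq_len(k),
                                 function(i, j) sprintf("%s_p%02d", i, j))))
  probes <- data.frame(
    probe_id = probe_ids,
    probe_set_id = rep(ids, each = k),
    stringsAsFactors = FALSE
  )
  affinity <- stats::rnorm(nrow(probes), 0, cfg$sigma_affinity)
  vals <- m$values[probes$probe_set_id, , drop = FALSE] + affinity +
    matrix(stats::rnorm(nrow(probes) * ncol(m$values), 0, cfg$sigma_probe),
           nrow(probes))
  rownames(vals) <- probes$probe_id
  snp <- truth$snp_probe_id[match(probes$probe_set_id, truth$probe_set_id)]
  is_snp <- !is.na(snp) & probes$probe_id == snp
  inp_cols <- m$samples$group == "iNP"
  vals[is_snp, inp_cols] <- vals[is_snp, inp_cols] - cfg$snp_offset
  probe_matrix(vals, probes, m$samples)
}

#' Write a simulated experiment pair to disk
#'
#' Emits the TSV dialects consumed by the analysis functions (expression
#' matrix, detection calls and sample sheet per experiment, annotations,
#' truth table) plus a JSON manifest recording the seed and a config hash.
#'
#' @param sim Output of [simulate_congenic_pair()].
#' @param dir Output directory (created if needed).
#' @param cfg The [sim_config()] used (recorded in the manifest).
#' @return Invisibly, a character vector of the files written.
#' @export
write_simulation <- function(sim, dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, paste0(...))
  write_expression_set(sim$a, f("matrix_a.tsv"), f("samples_a.tsv"),
                       f("detection_a.tsv"))
  write_expression_set(sim$b, f("matrix_b.tsv"), f("samples_b.tsv"),
                       f("detection_b.tsv"))
  utils::write.table(sim$annotations, f("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, f("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_flat <- cfg
  cfg_flat$cis_interval <- unclass(cfg_flat$cis_interval)
  cfg_json <- jsonlite::toJSON(unclass(cfg_flat), auto_unbox = TRUE,
                               digits = NA, null = "null")
  writeLines(cfg_json, f("config.json"))
  manifest <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(f("config.json"))),
    files = c("matrix_a.tsv", "samples_a.tsv", "detection_a.tsv",
              "matrix_b.tsv", "samples_b.tsv", "detection_b.tsv",
              "annotations.tsv", "truth.tsv", "config.json")
  )
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE)
  invisible(file.path(dir, manifest$files))
}
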