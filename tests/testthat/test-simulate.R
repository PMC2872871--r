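test_that("config validation rejects impossible settings before sampling", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_probe_sets = 0), "positive")
  expect_error(sim_config(frac_cis_regulated = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(sigma_resid = -1), "sigma")
  expect_error(sim_config(cis_interval = "chr4"), "genomic_interval")
})

test_that("identical seeds reproduce the simulation exactly", {
  cfg <- sim_config(n_probe_sets = 120, frac_snp_probes = 0.2, seed = 7)
  s1 <- simulate_congenic_pair(cfg)
  s2 <- simulate_congenic_pair(cfg)
  expect_identical(s1, s2)
  p1 <- simulate_probe_level(cfg, s1$truth, s1$a)
  p2 <- simulate_probe_level(cfg, s2$truth, s2$a)
  expect_identical(p1, p2)
  s3 <- simulate_congenic_pair(sim_config(n_probe_sets = 120,
                                          frac_snp_probes = 0.2, seed = 8))
  expect_false(identical(s1$a$values, s3$a$values))
})

test_that("the null configuration yields an all-null truth table and
           near-zero group differences", {
  cfg <- sim_config(n_probe_sets = 500, frac_cis_regulated = 0,
                    n_trans_regulated = 0, seed = 3)
  sim <- simulate_congenic_pair(cfg)
  expect_true(all(sim$truth$locus_class == "null"))
  expect_true(all(sim$truth$true_delta == 0))
  res <- differential_test(average_regions(sim$a), "student")
  expect_lt(abs(mean(res$log2_diff)), 0.05)
  # truth invariant: delta zero iff null
  cfg2 <- sim_config(n_probe_sets = 500, frac_cis_regulated = 0.4,
                     n_trans_regulated = 20, seed = 3)
  tr <- simulate_congenic_pair(cfg2)$truth
  expect_true(all((tr$true_delta == 0) == (tr$locus_class == "null")))
})

test_that("annotations place cis truth inside the interval, trans outside", {
  cfg <- sim_config(n_probe_sets = 400, frac_cis_regulated = 0.5,
                    n_trans_regulated = 30, seed = 19)
  sim <- simulate_congenic_pair(cfg)
  cls <- classify_locus(sim$annotations, cfg$cis_interval)
  expect_true(all(cls[sim$truth$probe_set_id[
    sim$truth$locus_class == "cis"]] == "cis"))
  expect_true(all(cls[sim$truth$probe_set_id[
    sim$truth$locus_class == "trans"]] == "trans"))
})

test_that("regulated probe sets recover the injected effect size", {
  cfg <- sim_config(n_probe_sets = 600, frac_interval = 0.5,
                    frac_cis_regulated = 0.8, delta_value = 0.6,
                    sigma_resid = 0.2, seed = 23)
  sim <- simulate_congenic_pair(cfg)
  reg <- sim$truth$probe_set_id[sim$truth$locus_class == "cis"]
  expect_gte(length(reg), 200)
  res <- differential_test(average_regions(sim$a), "student")
  est <- res$log2_diff[match(reg, res$probe_set_id)] *
    sign(sim$truth$true_delta[match(reg, sim$truth$probe_set_id)])
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.6), 3 * se)
})

test_that("detection calls respond to expression level via the logistic
           model", {
  cfg <- sim_config(n_probe_sets = 400, frac_cis_regulated = 0,
                    baseline_mean = 6, baseline_sd = 2, seed = 31)
  sim <- simulate_congenic_pair(cfg)
  pres <- rowMeans(sim$a$detection)
  lo <- rowMeans(sim$a$values) < 5
  hi <- rowMeans(sim$a$values) > 8
  expect_gt(mean(pres[hi]), 0.95)
  expect_lt(mean(pres[lo]), 0.5)
})

test_that("probe-level generator is consistent with probe-set values and
           injects the SNP offset on the designated probe", {
  cfg <- sim_config(n_probe_sets = 250, frac_snp_probes = 1,
                    sigma_probe = 0.1, seed = 41)
  sim <- simulate_congenic_pair(cfg)
  pm <- simulate_probe_level(cfg, sim$truth, sim$a)
  expect_equal(nrow(pm$values), 250 * cfg$probes_per_set)
  avg <- average_probe_levels(pm)
  res <- probe_screen(avg)
  snp_rows <- res$probe_id %in% sim$truth$snp_probe_id
  # mean excess of the SNP probes' group difference over their set centers
  expect_equal(mean(res$residual_e[snp_rows]), cfg$snp_offset,
               tolerance = 0.05)
  # without SNP probes, residuals center on zero
  cfg0 <- sim_config(n_probe_sets = 100, frac_snp_probes = 0, seed = 41)
  sim0 <- simulate_congenic_pair(cfg0)
  pm0 <- simulate_probe_level(cfg0, sim0$truth, sim0$a)
  res0 <- probe_screen(average_probe_levels(pm0))
  expect_lt(abs(mean(res0$residual_e)), 0.02)
})

test_that("simulation files round-trip through the TSV dialects", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_probe_sets = 60, seed = 13)
  sim <- simulate_congenic_pair(cfg)
  files <- write_simulation(sim, dir, cfg)
  expect_true(all(file.exists(files)))
  m <- read_expression_set(file.path(dir, "matrix_a.tsv"),
                           file.path(dir, "samples_a.tsv"),
                           file.path(dir, "detection_a.tsv"))
  expect_equal(dim(m$values), dim(sim$a$values))
  expect_equal(m$values, sim$a$values, tolerance = 1e-5)
  expect_identical(m$detection, sim$a$detection)
  expect_identical(m$samples, sim$a$samples)
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(ann$probe_set_id, sim$annotations$probe_set_id)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 13)
  # rerunning with the same seed reproduces the manifest hash
  dir2 <- withr::local_tempdir()
  write_simulation(simulate_congenic_pair(cfg), dir2, cfg)
  manifest2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  expect_equal(manifest2$config_hash, manifest$config_hash)
})
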