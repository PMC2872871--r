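test_that("detection filter keeps probe sets present in at least one group", {
  det <- rbind(
    c(rep(TRUE, 3), rep(FALSE, 5), rep(FALSE, 8)),   # 3/8 in iP only
    c(rep(TRUE, 2), rep(FALSE, 6), rep(TRUE, 2), rep(FALSE, 6)), # 2/8 both
    rep(TRUE, 16)                                    # everywhere
  )
  vals <- matrix(8, 3, 16)
  m <- make_two_group_matrix(vals[, 1:8], vals[, 9:16], detection = det)
  kept <- detection_filter(m, "per_region")
  expect_equal(kept, rownames(m$values)[c(1, 3)])  # 3/8 >= 1/3 > 2/8

  m_nodet <- make_two_group_matrix(vals[, 1:8], vals[, 9:16])
  expect_error(detection_filter(m_nodet, "per_region"), "absent")
})

test_that("combined-scope filter needs one region in one strain only", {
  groups <- rep(c("iP", "iNP"), each = 4)
  v <- matrix(8, 2, 8, dimnames = list(c("g1", "g2"), sprintf("an%d", 1:8)))
  # g1 present on 3/4 iP arrays in amygdala only; g2 never above 1/4
  det_amy <- rbind(c(TRUE, TRUE, TRUE, rep(FALSE, 5)),
                   c(TRUE, rep(FALSE, 7)))
  det_hip <- rbind(rep(FALSE, 8),
                   c(TRUE, rep(FALSE, 7)))
  m <- make_multi_region_matrix(
    list(amygdala = v, hippocampus = v), groups,
    list(amygdala = det_amy, hippocampus = det_hip))
  expect_equal(detection_filter(m, "combined"), "g1")
  expect_error(detection_filter(m, "per_region"), "one region")
})

test_that("region averaging takes per-animal means and checks completeness", {
  animals <- sprintf("an%d", 1:4)
  groups <- c("iP", "iP", "iNP", "iNP")
  rv <- lapply(1:5, function(i) {
    matrix(i, 2, 4, dimnames = list(c("g1", "g2"), animals))
  })
  names(rv) <- BRAIN_REGIONS
  m <- make_multi_region_matrix(rv, groups)
  avg <- average_regions(m)
  expect_equal(dim(avg$values), c(2L, 4L))
  expect_true(all(avg$values == 3))  # mean of 1..5
  expect_equal(unique(avg$samples$region), "combined")
  expect_equal(avg$samples$group, groups)

  m_incomplete <- expression_matrix(
    m$values[, -1, drop = FALSE], m$samples[-1, ], NULL)
  expect_error(average_regions(m_incomplete), "an1/nucleus_accumbens")
})

test_that("student test matches an independent oracle on a fixed input", {
  ip <- matrix(c(8.1, 8.4, 7.9, 8.6,
                 5.0, 5.2, 5.1, 5.3), 2, 4, byrow = TRUE)
  inp <- matrix(c(7.2, 7.9, 7.6, 7.5,
                  5.1, 5.0, 5.2, 5.4), 2, 4, byrow = TRUE)
  m <- make_two_group_matrix(ip, inp)
  res <- differential_test(m, "student")
  for (g in 1:2) {
    oracle <- t.test(ip[g, ], inp[g, ], var.equal = TRUE)
    expect_equal(res$p[g], oracle$p.value, tolerance = 1e-12)
    expect_equal(res$t[g], unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(res$df[g], unname(oracle$parameter))
    expect_equal(res$log2_diff[g], mean(ip[g, ]) - mean(inp[g, ]))
  }
  # and against the pooled-variance formula written out from first principles
  g <- 1
  sp2 <- (sum((ip[g, ] - mean(ip[g, ]))^2) +
            sum((inp[g, ] - mean(inp[g, ]))^2)) / 6
  t_manual <- (mean(ip[g, ]) - mean(inp[g, ])) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t[g], t_manual, tolerance = 1e-12)
  expect_equal(res$p[g], 2 * pt(-abs(t_manual), 6), tolerance = 1e-12)

  welch <- differential_test(m, "welch")
  for (g in 1:2) {
    oracle <- t.test(ip[g, ], inp[g, ])
    expect_equal(welch$p[g], oracle$p.value, tolerance = 1e-12)
    expect_equal(welch$df[g], unname(oracle$parameter), tolerance = 1e-9)
  }
})

test_that("degenerate inputs follow the stated conventions", {
  m <- make_two_group_matrix(matrix(5, 2, 3), matrix(5, 2, 3))
  res <- differential_test(m, "student")
  expect_equal(res$log2_diff, c(0, 0))
  expect_equal(res$p, c(1, 1))

  m2 <- make_two_group_matrix(matrix(5, 1, 3), matrix(6, 1, 3))
  expect_error(differential_test(m2, "welch"), "zero variance")
  res2 <- differential_test(m2, "student")
  expect_equal(res2$p, 0)  # infinite evidence against equality

  m3 <- make_two_group_matrix(matrix(rnorm(4), 2, 2),
                              matrix(rnorm(2), 2, 1))
  expect_error(differential_test(m3, "student"), ">= 2 samples")
})

test_that("moderated test reduces to student when variances are equal and
           matches limma's empirical-Bayes computation otherwise", {
  # equal sample variances in every probe set -> no finite prior, student
  base <- c(-1.5, -0.5, 0.5, 1.5)
  ip <- t(sapply(1:6, function(i) i / 10 + base))
  inp <- t(sapply(1:6, function(i) base))
  m <- make_two_group_matrix(ip, inp)
  expect_equal(differential_test(m, "moderated")$p,
               differential_test(m, "student")$p, tolerance = 1e-10)

  set.seed(77)
  n_g <- 200
  ip <- matrix(rnorm(n_g * 4, 8, 0.3), n_g, 4) * runif(n_g, 0.5, 2)
  inp <- matrix(rnorm(n_g * 4, 8, 0.3), n_g, 4)
  m <- make_two_group_matrix(ip, inp)
  res <- differential_test(m, "moderated")

  design <- cbind(intercept = 1, ip = rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  expect_equal(res$p, fit$p.value[, "ip"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res$df, unname(fit$df.total), tolerance = 1e-6)
  expect_equal(res$t, fit$t[, "ip"], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("BH adjustment agrees with an independent step-up oracle", {
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(101)
  for (i in 1:50) {
    p <- runif(sample(1:500, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # adjusted values never fall below raw p under the step-up rule
  p <- runif(200)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("signed fold change and its inverse follow the ratio convention", {
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-1), -2)
  expect_equal(signed_fold_change(0), 1)
  expect_equal(to_log2(c(2, -2, 1)), c(1, -1, 0))
  expect_error(to_log2(0.5), "\\|s\\| >= 1")
  # published ratio round-trip: 2.22 <-> log2(2.22)
  expect_equal(to_log2(2.22), log2(2.22))
  expect_equal(signed_fold_change(log2(2.22)), 2.22)

  set.seed(5)
  d <- rnorm(100)
  s <- signed_fold_change(d)
  expect_true(all(abs(s) >= 1))
  expect_equal(to_log2(s), d)                      # round trip
  expect_equal(signed_fold_change(-d),
               ifelse(s == 1, 1, -s))              # odd under group swap
  expect_equal(sign(s)[d != 0], sign(d)[d != 0])
})

test_that("relative difference uses the reference-mean convention", {
  expect_equal(relative_difference(3, 3), 0)
  expect_equal(relative_difference(2, 4), 1)
  expect_equal(relative_difference(4, 2), -0.5)
  expect_error(relative_difference(0, 1), "positive")
})

test_that("count summaries match a brute-force recount", {
  regions <- BRAIN_REGIONS
  set.seed(9)
  ids <- sprintf("ps%02d", 1:40)
  results <- do.call(rbind, lapply(c(regions, "combined"), function(ctx) {
    data.frame(probe_set_id = ids, context = ctx,
               q = runif(40), stringsAsFactors = FALSE)
  }))
  s <- summarize_counts(results, threshold = 0.25)

  sig <- results[results$q <= 0.25, ]
  by_region <- sig[sig$context != "combined", ]
  tab <- table(by_region$probe_set_id)
  expect_equal(unname(s$region_total[regions]), unname(vapply(
    regions, function(r) sum(by_region$context == r), integer(1))))
  expect_equal(s$at_least_one_region, length(tab))
  expect_equal(s$multiple_regions, sum(tab > 1))
  for (r in regions) {
    singles <- names(tab)[tab == 1]
    expect_equal(unname(s$region_only[r]),
                 sum(by_region$probe_set_id[by_region$context == r]
                     %in% singles))
  }
  comb <- sig$probe_set_id[sig$context == "combined"]
  expect_equal(s$combined_total, length(comb))
  expect_equal(s$combined_only, length(setdiff(comb, names(tab))))

  none <- results
  none$q <- 1
  s0 <- summarize_counts(none)
  expect_true(all(unlist(s0) == 0))
})
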