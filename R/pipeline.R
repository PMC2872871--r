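#' Run the full single-experiment differential-expression analysis
#'
#' Orchestrates one congenic-vs-background comparison: probe sets are
#' classified against the introgressed interval, the cis and trans universes
#' are analyzed separately (their multiple-testing families never mix), each
#' brain region is detection-filtered and tested on its own, and a
#' region-averaged ("combined") analysis is run on the per-animal means
#' after combined-scope filtering. FDR adjustment is applied per context
#' within each universe.
#'
#' When the matrix carries no detection calls, filtering is skipped with a
#' warning and every probe set is analyzed.
#'
#' @param m Multi-region [expression_matrix()].
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param interval Introgressed [genomic_interval()], default
#'   [qtl_interval()].
#' @param method Test method passed to [differential_test()].
#' @param min_detection Detection-filter fraction, default 1/3.
#' @param fdr_threshold Significance cutoff on q for the count summaries,
#'   default 0.25.
#' @return List with elements `results` (long data frame over universes and
#'   contexts, with `locus_class` and `q` filled per family), `summary_cis`
#'   and `summary_trans` (from [summarize_counts()]), and `log` (per-stage
#'   input/output counts).
#' @export
run_congenic_analysis <- function(m, annotations, interval = qtl_interval(),
                                  method = c("moderated", "student", "welch"),
                                  min_detection = 1 / 3,
                                  fdr_threshold = 0.25) {
  stopifnot(inherits(m, "expression_matrix"))
  method <- match.arg(method)
  cls <- classify_locus(annotations, interval)
  ids <- rownames(m$values)
  missing_ann <- setdiff(ids, names(cls))
  if (length(missing_ann) > 0) {
    cls[missing_ann] <- "unplaced"
  }
  cls <- cls[ids]
  filtering <- !is.null(m$detection)
  if (!filtering) {
    warning("no detection calls; detection filtering disabled",
            call. = FALSE)
  }
  regions <- unique(m$samples$region)
  log_rows <- list()
  results <- list()
  for (universe in c("cis", "trans")) {
    uni_ids <- ids[cls == universe]
    if (length(uni_ids) == 0) next
    mu <- subset_probe_sets(m, uni_ids)
    for (r in regions) {
      mr <- subset_region(mu, r)
      keep <- if (filtering) {
        detection_filter(mr, "per_region", min_detection)
      } else uni_ids
      res <- differential_test(subset_probe_sets(mr, keep), method)
      res$q <- bh_fdr(res$p)
      res$locus_class <- universe
      results[[paste(universe, r)]] <- res
      log_rows[[paste(universe, r)]] <- data.frame(
        universe = universe, context = r,
        n_input = length(uni_ids), n_retained = length(keep),
        n_significant = sum(res$q <= fdr_threshold))
    }
    keep <- if (filtering) {
      detection_filter(mu, "combined", min_detection)
    } else uni_ids
    avg <- average_regions(subset_probe_sets(mu, keep))
    res <- differential_test(avg, method)
    res$q <- bh_fdr(res$p)
    res$locus_class <- universe
    results[[paste(universe, "combined")]] <- res
    log_rows[[paste(universe, "combined")]] <- data.frame(
      universe = universe, context = "combined",
      n_input = length(uni_ids), n_retained = length(keep),
      n_significant = sum(res$q <= fdr_threshold))
  }
  results <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  list(
    results = results,
    summary_cis = summarize_counts(
      results[results$locus_class == "cis", , drop = FALSE], fdr_threshold),
    summary_trans = summarize_counts(
      results[results$locus_class == "trans", , drop = FALSE], fdr_threshold),
    log = do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  )
}

#' Pair results from the two reciprocal experiments
#'
#' Joins two result tables (experiment A: iP vs P.NP; experiment B: NP.P vs
#' iNP) on probe set and context into the long pair format consumed by
#' [select_concordant()] and [concordance_report()]. Both result tables must
#' already be oriented iP-carrier minus iNP-carrier (the package's test
#' functions always are).
#'
#' @param results_a,results_b Result data frames from
#'   [differential_test()]/[run_congenic_analysis()].
#' @return Long data frame with `probe_set_id`, `context`, `ratio_a`,
#'   `ratio_b`, `p_a`, `p_b`.
#' @export
build_ratio_pairs <- function(results_a, results_b) {
  key_a <- paste(results_a$probe_set_id, results_a$context)
  key_b <- paste(results_b$probe_set_id, results_b$context)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) {
    stop("result sets share no (probe set, context) pairs", call. = FALSE)
  }
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  out <- data.frame(
    probe_set_id = results_a$probe_set_id[ia],
    context = results_a$context[ia],
    ratio_a = results_a$signed_fc[ia],
    ratio_b = results_b$signed_fc[ib],
    p_a = results_a$p[ia],
    p_b = results_b$p[ib],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Run the cross-experiment concordance analysis
#'
#' Either joins two result tables via [build_ratio_pairs()] or accepts a
#' ready-made long pair table (e.g. the packaged fixture from
#' [read_table3_ratios()]), then applies the dual-significance /
#' direction-consistency selection and computes the agreement statistics.
#'
#' @param results_a,results_b Result tables, or `NULL` when `pairs` given.
#' @param pairs Optional long pair table (fixture mode).
#' @param alpha Raw-p significance level, default 0.05.
#' @return List with `pairs`, `selection` (from [select_concordant()]) and
#'   `report` (from [concordance_report()]).
#' @export
run_concordance <- function(results_a = NULL, results_b = NULL, pairs = NULL,
                            alpha = 0.05) {
  if (is.null(pairs)) {
    pairs <- build_ratio_pairs(results_a, results_b)
  }
  list(
    pairs = pairs,
    selection = select_concordant(pairs, alpha),
    report = concordance_report(pairs, alpha)
  )
}

#' Run the probe-level SNP artifact screen
#'
#' Region-averages probe intensities within animal and screens each probe
#' set for probes whose group difference deviates from the set's overall
#' differential expression.
#'
#' @param pm A multi-region [probe_matrix()].
#' @param k,min_effect,center Passed to [probe_screen()].
#' @return List with `results` (per-probe table), `profile`
#'   ([probe_profile_table()]) and `set_flags` (flagged probe count per
#'   probe set).
#' @export
run_snp_screen <- function(pm, k = 3, min_effect = 0.5, center = "median") {
  avg <- average_probe_levels(pm)
  res <- probe_screen(avg, k = k, min_effect = min_effect, center = center)
  flags <- tapply(res$flagged, res$probe_set_id,
                  function(f) sum(f, na.rm = TRUE))
  list(
    results = res,
    profile = probe_profile_table(res),
    set_flags = data.frame(probe_set_id = names(flags),
                           n_flagged = as.integer(flags),
                           row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Recompute the published concordance statistics from packaged fixtures
#'
#' Loads the packaged reciprocal-ratio and qRT-PCR fixtures and recomputes
#' the four headline cross-experiment statistics: the combined-context
#' log2-ratio R-squared, the combined direction agreement, the number of
#' combined-discordant probe sets, and the microarray vs qRT-PCR direction
#' agreement.
#'
#' @return List with `n_pairs`, `n_same_direction`, `r_squared`,
#'   `n_discordant_combined`, `qrtpcr_n_pairs`, `qrtpcr_n_same_direction`,
#'   `qrtpcr_agreement_pct`.
#' @export
reproduce_published_tables <- function() {
  t3 <- read_table3_ratios()
  comb <- t3[t3$context == "combined", , drop = FALSE]
  agr <- direction_agreement(comb$ratio_a, comb$ratio_b)
  t2 <- read_table2_qrtpcr()
  agr2 <- direction_agreement(t2$microarray_ratio, t2$qrtpcr_ratio)
  list(
    n_pairs = unname(agr["n_total"]),
    n_same_direction = unname(agr["n_same"]),
    r_squared = log_ratio_correlation(comb$ratio_a, comb$ratio_b),
    n_discordant_combined = combined_direction_discordance(t3),
    qrtpcr_n_pairs = unname(agr2["n_total"]),
    qrtpcr_n_same_direction = unname(agr2["n_same"]),
    qrtpcr_agreement_pct = 100 * unname(agr2["n_same"] / agr2["n_total"])
  )
}
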