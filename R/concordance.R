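#' Orient a signed ratio to the common allele convention
#'
#' Both reciprocal experiments are expressed as iP-allele-carrier over
#' iNP-allele-carrier (iP/P.NP for experiment A, NP.P/iNP for experiment B),
#' so a positive ratio always means higher expression in animals carrying
#' the alcohol-preferring QTL interval. A ratio stored with the opposite
#' strain in the numerator is flipped by signed-ratio inversion (`s -> -s`;
#' a ratio of exactly 1, i.e. no difference, is unchanged).
#'
#' @param ratio Signed fold change(s), `|ratio| >= 1`.
#' @param experiment `"A"` (iP vs P.NP) or `"B"` (NP.P vs iNP).
#' @param numerator_group Strain in the numerator of the stored ratio:
#'   one of `"iP"`/`"P.NP"` for experiment A, `"NP.P"`/`"iNP"` for B.
#' @return The ratio oriented as iP-carrier over iNP-carrier.
#' @export
orient_ratio <- function(ratio, experiment = c("A", "B"), numerator_group) {
  experiment <- match.arg(experiment)
  carriers <- list(A = c(iP = "iP", iNP = "P.NP"),
                   B = c(iP = "NP.P", iNP = "iNP"))[[experiment]]
  if (!numerator_group %in% carriers) {
    stop(sprintf("unknown numerator '%s' for experiment %s (expected %s)",
                 numerator_group, experiment,
                 paste(carriers, collapse = " or ")), call. = FALSE)
  }
  if (any(abs(ratio) < 1, na.rm = TRUE)) {
    stop("signed fold changes must satisfy |s| >= 1", call. = FALSE)
  }
  if (numerator_group == carriers["iP"]) {
    ratio
  } else {
    ifelse(abs(ratio) == 1, 1, -ratio)
  }
}

#' Read the packaged reciprocal-ratio fixture
#'
#' Loads the table of 74 candidate probe sets with their signed expression
#' ratios from both reciprocal experiments (experiment A: iP vs P.NP;
#' experiment B: NP.P vs iNP) in each of the five brain regions and the
#' region-averaged ("combined") analysis, together with per-context
#' dual-significance marks, transcribed from the published comparison.
#' Missing cells (`ND`) become `NA`.
#'
#' @param path Path to the fixture; defaults to the packaged copy.
#' @return Long-format data frame with columns `probe_set_id`, `symbol`,
#'   `context`, `ratio_a`, `ratio_b`, `sig_a`, `sig_b`.
#' @export
read_table3_ratios <- function(path = system.file("extdata",
                                                  "table3_ratios.tsv",
                                                  package = "congenicDE")) {
  wide <- utils::read.delim(path, na.strings = "ND",
                            colClasses = c(symbol = "character"),
                            check.names = FALSE)
  contexts <- c(BRAIN_REGIONS, "combined")
  long <- do.call(rbind, lapply(contexts, function(ctx) {
    data.frame(
      probe_set_id = wide$probe_set_id,
      symbol = wide$symbol,
      context = ctx,
      ratio_a = as.numeric(wide[[paste0(ctx, "_ratio_a")]]),
      ratio_b = as.numeric(wide[[paste0(ctx, "_ratio_b")]]),
      sig_a = as.logical(wide[[paste0(ctx, "_sig_a")]]),
      sig_b = as.logical(wide[[paste0(ctx, "_sig_b")]]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL
  long
}

#' Read the packaged microarray vs qRT-PCR fixture
#'
#' Loads the 44 tabulated gene-by-region comparisons between microarray and
#' qRT-PCR signed expression ratios (iP vs P.NP) used for cross-platform
#' confirmation.
#'
#' @param path Path to the fixture; defaults to the packaged copy.
#' @return Data frame with columns `gene`, `region`, `microarray_ratio`,
#'   `qrtpcr_ratio`, `microarray_significant`.
#' @export
read_table2_qrtpcr <- function(path = system.file("extdata",
                                                  "table2_qrtpcr.tsv",
                                                  package = "congenicDE")) {
  utils::read.delim(path, na.strings = "ND", check.names = FALSE)
}

# Sign of the underlying log2 difference of a signed ratio: +/-1, or 0 for a
# ratio of exactly +/-1 (no difference), which agrees with nothing.
ratio_sign <- function(ratio) {
  s <- sign(ratio) * (abs(ratio) > 1)
  s[is.na(ratio)] <- NA
  s
}

#' Select probe sets concordant across the reciprocal experiments
#'
#' A context (a brain region, or `"combined"`) qualifies for a probe set
#' when the difference is significant in both experiments in that same
#' context — raw `p <= alpha` in both, or both significance marks set when
#' the input carries marks instead of p-values — and the two ratios agree in
#' sign there. A probe set is selected when at least one context qualifies.
#' Significance here is deliberately on raw p-values (the relaxed
#' cross-experiment criterion): consistency between two independent
#' experiments is itself the false-positive filter.
#'
#' @param pairs Long data frame with columns `probe_set_id`, `context`,
#'   `ratio_a`, `ratio_b` and either (`p_a`, `p_b`) or (`sig_a`, `sig_b`).
#' @param alpha Significance level applied to each experiment's raw p-value,
#'   default 0.05.
#' @return Data frame with one row per probe set: `probe_set_id`,
#'   `n_qualifying`, `qualifying_contexts` (list column), `selected`.
#' @export
select_concordant <- function(pairs, alpha = 0.05) {
  has_p <- all(c("p_a", "p_b") %in% names(pairs))
  has_sig <- all(c("sig_a", "sig_b") %in% names(pairs))
  if (!has_p && !has_sig) {
    stop("pairs need either (p_a, p_b) or (sig_a, sig_b)", call. = FALSE)
  }
  both_sig <- if (has_p) {
    !is.na(pairs$p_a) & !is.na(pairs$p_b) &
      pairs$p_a <= alpha & pairs$p_b <= alpha
  } else {
    !is.na(pairs$sig_a) & !is.na(pairs$sig_b) & pairs$sig_a & pairs$sig_b
  }
  sa <- ratio_sign(pairs$ratio_a)
  sb <- ratio_sign(pairs$ratio_b)
  same_dir <- !is.na(sa) & !is.na(sb) & sa != 0 & sa == sb
  qualifies <- both_sig & same_dir
  ids <- unique(pairs$probe_set_id)
  qual_ctx <- lapply(ids, function(id) {
    pairs$context[qualifies & pairs$probe_set_id == id]
  })
  data.frame(
    probe_set_id = ids,
    n_qualifying = vapply(qual_ctx, length, integer(1)),
    qualifying_contexts = I(qual_ctx),
    selected = vapply(qual_ctx, length, integer(1)) > 0,
    stringsAsFactors = FALSE
  )
}

#' Direction agreement between two sets of signed ratios
#'
#' Counts pairs whose signed ratios agree in sign. Pairs with a missing
#' ratio, or a ratio of exactly +/-1 (zero underlying difference, which has
#' no direction), are excluded from the total.
#'
#' @param ratio_a,ratio_b Numeric vectors of signed ratios, same length.
#' @return Named numeric vector `c(n_same, n_total)`.
#' @export
direction_agreement <- function(ratio_a, ratio_b) {
  stopifnot(length(ratio_a) == length(ratio_b))
  sa <- ratio_sign(ratio_a)
  sb <- ratio_sign(ratio_b)
  usable <- !is.na(sa) & !is.na(sb) & sa != 0 & sb != 0
  c(n_same = sum(sa[usable] == sb[usable]), n_total = sum(usable))
}

#' Squared correlation of log2-transformed ratio pairs
#'
#' Transforms each signed ratio to its log2 difference and returns the
#' squared Pearson correlation (the OLS coefficient of determination) of the
#' two log2 vectors — the cross-experiment reproducibility statistic.
#' Pairs with a missing ratio are excluded pairwise.
#'
#' @param ratio_a,ratio_b Numeric vectors of signed ratios, same length.
#' @return R-squared in `[0, 1]`.
#' @export
log_ratio_correlation <- function(ratio_a, ratio_b) {
  stopifnot(length(ratio_a) == length(ratio_b))
  ok <- !is.na(ratio_a) & !is.na(ratio_b)
  x <- to_log2(ratio_a[ok])
  y <- to_log2(ratio_b[ok])
  if (length(x) < 3) {
    stop("need at least 3 complete ratio pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance on one axis; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Count combined-context direction discordance
#'
#' Number of probe sets whose region-averaged ("combined") ratios from the
#' two experiments disagree in sign — probe sets that qualified through a
#' single region but whose overall directions differ.
#'
#' @param pairs Long data frame as in [select_concordant()], containing
#'   `context == "combined"` rows for every probe set.
#' @return Integer count of discordant probe sets.
#' @export
combined_direction_discordance <- function(pairs) {
  comb <- pairs[pairs$context == "combined", , drop = FALSE]
  agr <- direction_agreement(comb$ratio_a, comb$ratio_b)
  unname(agr["n_total"] - agr["n_same"])
}

#' Concordance summary report
#'
#' Computes the headline cross-experiment statistics over a long pair table:
#' number of complete combined-context pairs, how many agree in direction,
#' the log2-ratio R-squared, the number of probe sets passing the
#' dual-significance/direction filter, and a histogram of qualifying
#' contexts.
#'
#' @param pairs Long data frame as in [select_concordant()].
#' @param alpha Significance level for selection, default 0.05.
#' @return List with elements `n_pairs`, `n_same_direction`, `r_squared`,
#'   `n_discordant_combined`, `n_selected`, `context_histogram`.
#' @export
concordance_report <- function(pairs, alpha = 0.05) {
  comb <- pairs[pairs$context == "combined", , drop = FALSE]
  agr <- direction_agreement(comb$ratio_a, comb$ratio_b)
  sel <- select_concordant(pairs, alpha = alpha)
  ctx_hist <- table(unlist(sel$qualifying_contexts))
  list(
    n_pairs = unname(agr["n_total"]),
    n_same_direction = unname(agr["n_same"]),
    r_squared = log_ratio_correlation(comb$ratio_a, comb$ratio_b),
    n_discordant_combined = combined_direction_discordance(pairs),
    n_selected = sum(sel$selected),
    context_histogram = as.list(ctx_hist)
  )
}
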