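#' Filter probe sets by detection calls
#'
#' Probe sets not reliably detected on at least a minimum fraction of arrays
#' in at least one experimental group are removed before testing, to increase
#' power and lower the effective multiple-testing burden.
#'
#' Under `scope = "per_region"` the matrix must contain a single region, and
#' a probe set is retained when it is called present on at least
#' `min_fraction` of the arrays of either allele-carrier group in that
#' region. Under `scope = "combined"` the full multi-region matrix is used,
#' and a probe set is retained when any (region, group) cell reaches the
#' fraction — present in at least one brain region in at least one strain.
#'
#' @param m An [expression_matrix()] with detection calls.
#' @param scope `"per_region"` or `"combined"`.
#' @param min_fraction Minimum fraction of present calls, default 1/3.
#' @return Character vector of retained probe-set ids.
#' @export
detection_filter <- function(m, scope = c("per_region", "combined"),
                             min_fraction = 1 / 3) {
  stopifnot(inherits(m, "expression_matrix"))
  scope <- match.arg(scope)
  if (is.null(m$detection)) {
    stop("detection calls are absent; cannot apply the detection filter",
         call. = FALSE)
  }
  if (scope == "per_region") {
    if (length(unique(m$samples$region)) != 1) {
      stop("per-region filtering requires a matrix restricted to one region",
           call. = FALSE)
    }
    cells <- m$samples$group
  } else {
    cells <- interaction(m$samples$region, m$samples$group, drop = TRUE)
  }
  frac <- vapply(split(seq_len(ncol(m$detection)), cells), function(idx) {
    rowMeans(m$detection[, idx, drop = FALSE])
  }, numeric(nrow(m$detection)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = nrow(m$detection))
  keep <- apply(frac, 1, max) >= min_fraction
  rownames(m$values)[keep]
}

#' Average expression across brain regions within animal
#'
#' Collapses a multi-region matrix to one pseudo-sample per animal whose
#' value is the arithmetic mean of that animal's log2 values across all
#' configured regions (the geometric mean on the linear scale). Averaging
#' cancels region-specific technical variation and gains power for effects
#' shared in direction across regions. Detection calls are not carried over;
#' filtering for the combined analysis is done beforehand on the full matrix
#' with `scope = "combined"`.
#'
#' @param m An [expression_matrix()] in which every animal has a sample in
#'   every region present in the sheet.
#' @return An `expression_matrix` with one column per animal and region
#'   `"combined"`.
#' @export
average_regions <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  regions <- unique(m$samples$region)
  animals <- unique(m$samples$animal_id)
  have <- table(factor(m$samples$animal_id, animals),
                factor(m$samples$region, regions))
  if (any(have != 1)) {
    miss <- which(have == 0, arr.ind = TRUE)
    stop("animal(s) missing region(s): ",
         paste(sprintf("%s/%s", animals[miss[, 1]], regions[miss[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  avg <- vapply(animals, function(a) {
    idx <- which(m$samples$animal_id == a)
    rowMeans(m$values[, idx, drop = FALSE])
  }, numeric(nrow(m$values)))
  colnames(avg) <- animals
  sheet <- data.frame(
    sample_id = animals,
    animal_id = animals,
    group = m$samples$group[match(animals, m$samples$animal_id)],
    region = "combined",
    stringsAsFactors = FALSE
  )
  expression_matrix(avg, sheet)
}

#' Two-group differential expression test
#'
#' Tests each probe set for a difference in mean log2 expression between
#' iP-allele carriers and iNP-allele carriers. `log2_diff` is oriented as
#' iP-carrier minus iNP-carrier throughout, so a positive value means higher
#' expression in animals carrying the alcohol-preferring allele.
#'
#' Methods: `"student"` is the pooled-variance two-sample t; `"welch"` uses
#' the Satterthwaite approximation; `"moderated"` shrinks each probe set's
#' pooled variance toward a common prior value via an empirical-Bayes
#' scaled-inverse-chi-square prior whose parameters (`d0`, `s0^2`) are
#' moment-matched on the log sample variances (see [fit_variance_prior()]),
#' giving statistic `log2_diff / (s_tilde * sqrt(1/n1 + 1/n2))` on
#' `d0 + n1 + n2 - 2` degrees of freedom. When the moment equations admit no
#' finite prior the method falls back to the Student test.
#'
#' Degenerate inputs: probe sets constant and equal in both groups get
#' `p = 1` by convention; constant-but-unequal groups are an error under
#' Welch (undefined df) while the Student statistic is still defined.
#'
#' @param m An [expression_matrix()] restricted to one context (a single
#'   region, or the region-averaged matrix).
#' @param method `"student"`, `"welch"`, or `"moderated"`.
#' @return Data frame with columns `probe_set_id`, `context`, `log2_diff`,
#'   `signed_fc`, `t`, `df`, `p` and `q` (`NA` until [bh_fdr()] is applied
#'   to a testing family).
#' @export
differential_test <- function(m, method = c("student", "welch", "moderated")) {
  stopifnot(inherits(m, "expression_matrix"))
  method <- match.arg(method)
  context <- unique(m$samples$region)
  if (length(context) != 1) {
    stop("matrix spans several regions; subset to one context first",
         call. = FALSE)
  }
  ip <- m$samples$group == "iP"
  inp <- m$samples$group == "iNP"
  n1 <- sum(ip)
  n2 <- sum(inp)
  if (n1 < 2 || n2 < 2) {
    stop(sprintf("each group needs >= 2 samples (got iP=%d, iNP=%d)", n1, n2),
         call. = FALSE)
  }
  x1 <- m$values[, ip, drop = FALSE]
  x2 <- m$values[, inp, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  diff <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    if (any(se2 == 0 & diff != 0)) {
      stop("welch test undefined: zero variance in both groups with ",
           "unequal means", call. = FALSE)
    }
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- diff / sqrt(se2)
  } else {
    d_resid <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d_resid
    if (method == "moderated") {
      prior <- fit_variance_prior(s2, d_resid)
      if (is.finite(prior$d0)) {
        s2 <- (prior$d0 * prior$s0sq + d_resid * s2) / (prior$d0 + d_resid)
        df <- rep(prior$d0 + d_resid, length(s2))
      } else {
        df <- rep(d_resid, length(s2))
      }
    } else {
      df <- rep(d_resid, length(s2))
    }
    tt <- diff / sqrt(s2 * (1 / n1 + 1 / n2))
  }

  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- !is.finite(tt) & diff == 0   # constant and equal: no evidence
  tt[degenerate] <- 0
  p[degenerate] <- 1

  data.frame(
    probe_set_id = rownames(m$values),
    context = context,
    log2_diff = diff,
    signed_fc = signed_fold_change(diff),
    t = tt,
    df = df,
    p = p,
    q = NA_real_,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Moment-matched scaled-inverse-chi-square variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' an empirical-Bayes variance model from the observed per-probe-set sample
#' variances. With `s^2 | sigma^2 ~ sigma^2 chi^2_d / d` and
#' `1/sigma^2 ~ chi^2_{d0} / (d0 s0^2)`, the log sample variances satisfy
#' `E[log s^2] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)`
#' and `Var[log s^2] = trigamma(d/2) + trigamma(d0/2)`, so `d0` is recovered
#' by inverting the trigamma function on the excess variance of the log
#' sample variances, and `s0^2` from the mean. When the observed spread of
#' log variances does not exceed the sampling spread, no finite `d0` exists
#' and `d0 = Inf` is returned.
#'
#' @param s2 Numeric vector of pooled sample variances (one per probe set).
#' @param df Residual degrees of freedom of each `s2` (scalar or vector).
#' @return List with elements `d0` and `s0sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0sq = stats::median(s2[ok])))
  df <- rep_len(df, length(s2))[ok]
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2) * n / (n - 1) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR-adjusted p-values for one multiple-testing family. Families
#' are kept separate per context (each region; combined) and per locus class
#' (cis universe; trans universe); callers are responsible for passing one
#' family at a time.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted values (q), same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change from a log2 difference
#'
#' Converts an oriented log2 difference to the signed-ratio convention used
#' in the result tables: fold changes at or above 1 are reported as-is, and
#' down-regulation `r < 1` is reported as `-1/r`, so magnitudes are symmetric
#' about +/-1 (e.g. `log2_diff = -1` gives `-2.0`).
#'
#' @param log2_diff Numeric vector of oriented log2 differences.
#' @return Signed ratios with `|value| >= 1`.
#' @seealso [to_log2()] for the inverse.
#' @export
signed_fold_change <- function(log2_diff) {
  fc <- 2^log2_diff
  ifelse(fc >= 1, fc, -1 / fc)
}

#' Log2 difference from a signed fold change
#'
#' Inverse of [signed_fold_change()]: `sign(s) * log2(|s|)`. Values with
#' `|s| < 1` violate the signed-ratio convention and are rejected.
#'
#' @param signed_fc Numeric vector of signed ratios, `|signed_fc| >= 1`.
#' @return Log2 differences. `NA` inputs propagate as `NA`.
#' @export
to_log2 <- function(signed_fc) {
  bad <- !is.na(signed_fc) & abs(signed_fc) < 1
  if (any(bad)) {
    stop("signed fold changes must satisfy |s| >= 1", call. = FALSE)
  }
  sign(signed_fc) * log2(abs(signed_fc))
}

#' Relative difference of two linear-scale means
#'
#' `(b - a) / a`, the relative-difference convention used when aligning
#' expression ratios along the interval.
#'
#' @param mean_a_linear Reference mean (must be > 0).
#' @param mean_b_linear Comparison mean.
#' @return Dimensionless relative difference.
#' @export
relative_difference <- function(mean_a_linear, mean_b_linear) {
  if (any(mean_a_linear <= 0)) {
    stop("reference mean must be positive", call. = FALSE)
  }
  (mean_b_linear - mean_a_linear) / mean_a_linear
}

#' Count significant probe sets across contexts
#'
#' Summarizes one locus class's results in the layout of the published count
#' table: per region the total number of significant probe sets and the
#' number significant in that region only; the number significant in at
#' least one region and in more than one region; the combined-analysis
#' total; and the number significant only in the combined analysis.
#'
#' @param results Data frame of test results (as from [differential_test()]
#'   with `q` filled in) covering the five regions and `"combined"`, for one
#'   locus class.
#' @param threshold Significance cutoff on `q`, default 0.25.
#' @return List with elements `region_total`, `region_only` (named numeric
#'   vectors over regions), `at_least_one_region`, `multiple_regions`,
#'   `combined_total`, `combined_only`.
#' @export
summarize_counts <- function(results, threshold = 0.25) {
  regions <- setdiff(unique(results$context), "combined")
  sig <- results[!is.na(results$q) & results$q <= threshold, , drop = FALSE]
  sig_by_region <- lapply(regions, function(r) {
    sig$probe_set_id[sig$context == r]
  })
  names(sig_by_region) <- regions
  n_regions_sig <- table(unlist(sig_by_region))
  any_region <- names(n_regions_sig)
  combined_sig <- sig$probe_set_id[sig$context == "combined"]
  list(
    region_total = vapply(sig_by_region, length, integer(1)),
    region_only = vapply(regions, function(r) {
      sum(sig_by_region[[r]] %in% names(n_regions_sig)[n_regions_sig == 1])
    }, integer(1)),
    at_least_one_region = length(any_region),
    multiple_regions = sum(n_regions_sig > 1),
    combined_total = length(combined_sig),
    combined_only = length(setdiff(combined_sig, any_region))
  )
}
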