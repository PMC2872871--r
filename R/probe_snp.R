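#' Probe-level intensity matrix
#'
#' Container for background-corrected log2 intensities of the individual
#' probes of each probe set, used by the SNP-artifact screen. A sequence
#' variant between the two strains under a single probe can depress that
#' probe's hybridization in one strain and mimic a probe-set expression
#' difference; the screen looks for probes whose group difference deviates
#' from their probe set's overall difference.
#'
#' @param values Numeric matrix, probes x samples; rownames are probe ids.
#' @param probes Data frame with columns `probe_id`, `probe_set_id` mapping
#'   every probe to exactly one probe set.
#' @param samples Sample sheet as in [expression_matrix()].
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, probes, samples) {
  values <- as.matrix(values)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "probe_set_id") %in% names(probes)))
  if (anyDuplicated(probes$probe_id)) {
    stop("probe ids must be unique", call. = FALSE)
  }
  if (!identical(rownames(values), probes$probe_id)) {
    probes <- probes[match(rownames(values), probes$probe_id), , drop = FALSE]
    if (anyNA(probes$probe_id)) {
      stop("probe table must cover every row of the intensity matrix",
           call. = FALSE)
    }
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!setequal(samples$sample_id, colnames(values))) {
    stop("sample sheet ids must match matrix columns", call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  rownames(probes) <- NULL
  structure(list(values = values, probes = probes, samples = samples),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("<probe_matrix> %d probes in %d probe sets x %d samples\n",
              nrow(x$values), length(unique(x$probes$probe_set_id)),
              ncol(x$values)))
  invisible(x)
}

#' Average probe-level intensities across regions within animal
#'
#' Collapses probe-level intensities to one pseudo-sample per animal (the
#' mean across all configured brain regions), mirroring the region averaging
#' applied to probe-set data before the screen.
#'
#' @param pm A [probe_matrix()] in which every animal has every region.
#' @return A `probe_matrix` with one column per animal.
#' @export
average_probe_levels <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  regions <- unique(pm$samples$region)
  animals <- unique(pm$samples$animal_id)
  have <- table(factor(pm$samples$animal_id, animals),
                factor(pm$samples$region, regions))
  if (any(have != 1)) {
    miss <- which(have == 0, arr.ind = TRUE)
    stop("animal(s) missing region(s): ",
         paste(sprintf("%s/%s", animals[miss[, 1]], regions[miss[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  avg <- vapply(animals, function(a) {
    idx <- which(pm$samples$animal_id == a)
    rowMeans(pm$values[, idx, drop = FALSE])
  }, numeric(nrow(pm$values)))
  colnames(avg) <- animals
  sheet <- data.frame(
    sample_id = animals,
    animal_id = animals,
    group = pm$samples$group[match(animals, pm$samples$animal_id)],
    region = "combined",
    stringsAsFactors = FALSE
  )
  probe_matrix(avg, pm$probes, sheet)
}

#' Screen probes for SNP-driven hybridization artifacts
#'
#' For each probe, the between-group difference
#' `d_p = mean(iP carriers) - mean(iNP carriers)` is computed; within each
#' probe set the differences are centered on the set's overall differential
#' expression (`center_D`, the median of `d_p`, or the mean with
#' `center = "mean"`), leaving residuals `e_p = d_p - center_D`. Centering
#' removes the genuine expression difference so that even a small deviant
#' probe stands out against a large overall group difference. Residuals are
#' scaled by the set's MAD (`1.4826 * median|e|`), and a probe is flagged
#' when `|robust_z| > k` **and** `|e_p| >= min_effect`: the robust median/MAD
#' pair resists the very outlier being sought, while the absolute floor
#' prevents flagging trivial deviations in ultra-low-variance probe sets.
#'
#' Probe sets with fewer than 4 probes cannot support a meaningful robust
#' scale; they are reported with `flagged = NA` and a warning. A zero robust
#' scale with zero residuals yields no flags.
#'
#' @param pm A [probe_matrix()], normally region-averaged via
#'   [average_probe_levels()]; both groups need >= 2 animals.
#' @param k Robust-z threshold, default 3.
#' @param min_effect Minimum absolute residual in log2 units, default 0.5.
#' @param center `"median"` (default) or `"mean"` centering of `d_p`.
#' @return Data frame with columns `probe_set_id`, `probe_id`, `d_p`,
#'   `center_D`, `residual_e`, `robust_z`, `flagged`.
#' @export
probe_screen <- function(pm, k = 3, min_effect = 0.5,
                         center = c("median", "mean")) {
  stopifnot(inherits(pm, "probe_matrix"))
  center <- match.arg(center)
  ip <- pm$samples$group == "iP"
  inp <- pm$samples$group == "iNP"
  if (sum(ip) < 2 || sum(inp) < 2) {
    stop("each group needs >= 2 animals", call. = FALSE)
  }
  d_p <- rowMeans(pm$values[, ip, drop = FALSE]) -
    rowMeans(pm$values[, inp, drop = FALSE])
  sets <- split(seq_along(d_p), pm$probes$probe_set_id)
  small <- names(sets)[lengths(sets) < 4]
  if (length(small) > 0) {
    warning("probe set(s) with < 4 probes skipped by the screen: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  res <- lapply(names(sets), function(ps) {
    idx <- sets[[ps]]
    d <- d_p[idx]
    ctr <- if (center == "median") stats::median(d) else mean(d)
    e <- d - ctr
    scale <- 1.4826 * stats::median(abs(e))
    z <- ifelse(e == 0, 0, e / scale)   # 0/0 -> no deviation
    flag <- if (length(idx) < 4) NA else abs(z) > k & abs(e) >= min_effect
    data.frame(
      probe_set_id = ps,
      probe_id = pm$probes$probe_id[idx],
      d_p = d,
      center_D = ctr,
      residual_e = e,
      robust_z = z,
      flagged = flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tidy per-probe residual profile table
#'
#' Reshapes screen results into a tidy table of residual differential
#' expression per probe within probe set, suitable for profile plots or
#' reports.
#'
#' @param results Data frame from [probe_screen()].
#' @return Data frame with columns `probe_set_id`, `probe_index`,
#'   `probe_id`, `residual_e`, `flagged`.
#' @export
probe_profile_table <- function(results) {
  if (nrow(results) == 0) {
    return(data.frame(probe_set_id = character(0), probe_index = integer(0),
                      probe_id = character(0), residual_e = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  idx <- stats::ave(seq_len(nrow(results)), results$probe_set_id,
                    FUN = seq_along)
  out <- data.frame(
    probe_set_id = results$probe_set_id,
    probe_index = as.integer(idx),
    probe_id = results$probe_id,
    residual_e = results$residual_e,
    flagged = results$flagged,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
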