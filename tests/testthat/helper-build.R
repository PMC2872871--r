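# Small builders shared across test files.

# Two-group, single-region expression matrix from a list of per-group value
# matrices (probe sets x animals).
make_two_group_matrix <- function(ip, inp, region = "nucleus_accumbens",
                                  detection = NULL) {
  ip <- as.matrix(ip)
  inp <- as.matrix(inp)
  vals <- cbind(ip, inp)
  n1 <- ncol(ip)
  n2 <- ncol(inp)
  ids <- c(sprintf("iP_%02d", seq_len(n1)), sprintf("iNP_%02d", seq_len(n2)))
  colnames(vals) <- paste0(ids, ".", region)
  if (is.null(rownames(vals))) {
    rownames(vals) <- sprintf("ps_%03d", seq_len(nrow(vals)))
  }
  sheet <- data.frame(
    sample_id = colnames(vals),
    animal_id = ids,
    group = rep(c("iP", "iNP"), c(n1, n2)),
    region = region,
    stringsAsFactors = FALSE
  )
  if (!is.null(detection)) {
    dimnames(detection) <- dimnames(vals)
  }
  expression_matrix(vals, sheet, detection)
}

# Multi-region matrix: values[probe, animal] replicated (or offset) per
# region via `region_values`, a named list region -> matrix.
make_multi_region_matrix <- function(region_values, groups,
                                     detection_values = NULL) {
  regions <- names(region_values)
  animals <- colnames(region_values[[1]])
  vals <- do.call(cbind, lapply(regions, function(r) {
    v <- region_values[[r]]
    colnames(v) <- paste0(animals, ".", r)
    v
  }))
  sheet <- do.call(rbind, lapply(regions, function(r) {
    data.frame(sample_id = paste0(animals, ".", r), animal_id = animals,
               group = groups, region = r, stringsAsFactors = FALSE)
  }))
  det <- NULL
  if (!is.null(detection_values)) {
    det <- do.call(cbind, lapply(regions, function(r) {
      d <- detection_values[[r]]
      colnames(d) <- paste0(animals, ".", r)
      d
    }))
    dimnames(det) <- dimnames(vals)
  }
  expression_matrix(vals, sheet, det)
}

# Independent Benjamini-Hochberg step-up oracle: q_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, computed directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
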