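#' Brain regions profiled in the congenic experiments
#' @export
BRAIN_REGIONS <- c("nucleus_accumbens", "amygdala", "frontal_cortex",
                   "hippocampus", "caudate_putamen")

#' Allele-carrier group labels
#'
#' `"iP"` marks animals carrying the alcohol-preferring (iP) allele of the
#' introgressed QTL segment (iP background strain, or NP.P congenic);
#' `"iNP"` marks carriers of the nonpreferring allele (P.NP congenic, or iNP
#' background strain). All oriented differences are iP-carrier minus
#' iNP-carrier.
#' @export
ALLELE_GROUPS <- c("iP", "iNP")

#' Expression matrix with sample metadata
#'
#' Container for log2-normalized probe-set expression over samples, with an
#' optional boolean detection-call matrix of identical shape, and a sample
#' sheet giving each array's animal, allele-carrier group, and brain region.
#'
#' @param values Numeric matrix, probe sets x samples, log2 scale; rownames
#'   are probe-set ids, colnames are sample ids. All values must be finite.
#' @param samples Data frame with columns `sample_id`, `animal_id`, `group`
#'   (one of `"iP"`, `"iNP"`), `region` (a brain region or `"combined"`),
#'   one row per column of `values`, in the same order or matched by
#'   `sample_id`.
#' @param detection Optional logical matrix (TRUE = present) with identical
#'   dimnames as `values`.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, detection = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have probe-set rownames and sample colnames",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "animal_id", "group", "region")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!setequal(samples$sample_id, colnames(values)) ||
      anyDuplicated(samples$sample_id)) {
    stop("sample sheet ids must match matrix columns exactly", call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad_group <- setdiff(unique(samples$group), ALLELE_GROUPS)
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  # each animal belongs to exactly one group; (animal, region) unique
  g_per_animal <- tapply(samples$group, samples$animal_id,
                         function(g) length(unique(g)))
  if (any(g_per_animal > 1)) {
    stop("animal(s) assigned to more than one group: ",
         paste(names(g_per_animal)[g_per_animal > 1], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples[, c("animal_id", "region")])) {
    stop("duplicated (animal_id, region) combinations in sample sheet",
         call. = FALSE)
  }
  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (!identical(dim(detection), dim(values)) ||
        !identical(dimnames(detection), dimnames(values))) {
      stop("detection matrix must have identical shape and dimnames as values",
           call. = FALSE)
    }
    storage.mode(detection) <- "logical"
  }
  structure(
    list(values = values, detection = detection, samples = samples),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d probe sets x %d samples (%s); detection: %s\n",
    nrow(x$values), ncol(x$values),
    paste(unique(x$samples$region), collapse = ", "),
    if (is.null(x$detection)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Restrict an expression matrix to one brain region
#'
#' @param m An [expression_matrix()].
#' @param region Region name to keep.
#' @return An `expression_matrix` containing only that region's samples.
#' @export
subset_region <- function(m, region) {
  stopifnot(inherits(m, "expression_matrix"))
  keep <- m$samples$region == region
  if (!any(keep)) stop("no samples in region: ", region, call. = FALSE)
  expression_matrix(
    m$values[, keep, drop = FALSE],
    m$samples[keep, , drop = FALSE],
    if (!is.null(m$detection)) m$detection[, keep, drop = FALSE]
  )
}

#' Restrict an expression matrix to a set of probe sets
#'
#' @param m An [expression_matrix()].
#' @param probe_set_ids Character vector of probe-set ids to keep.
#' @return An `expression_matrix` with only those rows.
#' @export
subset_probe_sets <- function(m, probe_set_ids) {
  stopifnot(inherits(m, "expression_matrix"))
  keep <- rownames(m$values) %in% probe_set_ids
  expression_matrix(
    m$values[keep, , drop = FALSE],
    m$samples,
    if (!is.null(m$detection)) m$detection[keep, , drop = FALSE]
  )
}

#' Read an expression set from tab-separated files
#'
#' The expression file is a TSV matrix whose first column is `probe_set_id`
#' and remaining columns are sample ids; the companion sample sheet has
#' columns `sample_id`, `animal_id`, `group`, `region`; the optional
#' detection matrix uses the same layout as the expression file with cells
#' `P` (present) or `A` (absent).
#'
#' @param values_path Path to the expression TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @param detection_path Optional path to the detection-call TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_set <- function(values_path, samples_path,
                                detection_path = NULL) {
  vals <- utils::read.delim(values_path, check.names = FALSE)
  if (names(vals)[1] != "probe_set_id") {
    stop("expression file must start with a probe_set_id column",
         call. = FALSE)
  }
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$probe_set_id
  samples <- utils::read.delim(samples_path, colClasses = "character",
                               check.names = FALSE)
  det <- NULL
  if (!is.null(detection_path)) {
    dv <- utils::read.delim(detection_path, check.names = FALSE,
                            colClasses = "character")
    dm <- as.matrix(dv[, -1, drop = FALSE])
    rownames(dm) <- dv$probe_set_id
    det <- dm == "P"
    det <- det[rownames(m), colnames(m), drop = FALSE]
  }
  expression_matrix(m, samples, det)
}

#' Write an expression set as tab-separated files
#'
#' Inverse of [read_expression_set()]; numeric values are written with six
#' significant digits so that reruns are byte-reproducible.
#'
#' @param m An [expression_matrix()].
#' @param values_path,samples_path Output paths.
#' @param detection_path Optional output path for detection calls (P/A).
#' @return Invisibly, the paths written.
#' @export
write_expression_set <- function(m, values_path, samples_path,
                                 detection_path = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(probe_set_id = rownames(m$values),
                   signif(m$values, 6), check.names = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(values_path, samples_path)
  if (!is.null(detection_path)) {
    if (is.null(m$detection)) stop("no detection calls to write", call. = FALSE)
    dd <- data.frame(probe_set_id = rownames(m$detection),
                     ifelse(m$detection, "P", "A"), check.names = FALSE)
    utils::write.table(dd, detection_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, detection_path)
  }
  invisible(paths)
}
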