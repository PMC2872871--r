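#' Genomic interval
#'
#' Constructs a 1-based, fully closed genomic interval used to define the
#' introgressed (congenic) segment. Probe sets anchored inside the interval
#' are candidate *cis*-regulated loci; everything placed elsewhere in the
#' genome belongs to the *trans* universe.
#'
#' @param chromosome Chromosome label (string; compared after normalization,
#'   so `"4"`, `"chr4"` and `"Chr4"` are equivalent).
#' @param start,end Interval bounds in base pairs, 1-based and inclusive on
#'   both ends. `start` must be >= 1 and `end >= start`.
#'
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("4", 29413686, 128186835)
#' @export
genomic_interval <- function(chromosome, start, end) {
  stopifnot(length(chromosome) == 1, length(start) == 1, length(end) == 1)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start) {
    stop("invalid interval: need start >= 1 and end >= start", call. = FALSE)
  }
  structure(
    list(chromosome = as.character(chromosome), start = start, end = end),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> chr%s:%s-%s\n", x$chromosome,
              format(x$start, big.mark = ","), format(x$end, big.mark = ",")))
  invisible(x)
}

#' Default introgressed chromosome 4 QTL interval
#'
#' The rat chromosome 4 alcohol-preference QTL segment carried by the
#' reciprocal congenic strains, bounded by the microsatellite markers flanking
#' the introgressed region: 29,413,686 to 128,186,835 bp.
#'
#' @return A [genomic_interval()].
#' @export
qtl_interval <- function() {
  genomic_interval("4", 29413686, 128186835)
}

# Chromosome labels tolerate annotation dialects: case-insensitive, optional
# "chr" prefix.
normalize_chromosome <- function(x) {
  x <- tolower(trimws(as.character(x)))
  sub("^chr", "", x)
}

#' Classify probe sets as cis, trans, or unplaced
#'
#' A probe set is *cis* when its anchor position lies inside the introgressed
#' interval (both bounds inclusive), *trans* when it is placed anywhere else
#' in the genome (including the same chromosome outside the interval), and
#' *unplaced* when chromosome or position is missing (e.g. ESTs aligning to
#' multiple loci). Unplaced probe sets belong to neither multiple-testing
#' family.
#'
#' @param annotations Data frame with columns `probe_set_id`, `chromosome`,
#'   `position` (and optionally `gene_symbol`), as returned by
#'   [read_annotations()]. Missing placement is encoded as `NA`.
#' @param interval A [genomic_interval()]; defaults to [qtl_interval()].
#'
#' @return Character vector (`"cis"`, `"trans"` or `"unplaced"`), named by
#'   `probe_set_id`, one element per row.
#' @export
classify_locus <- function(annotations, interval = qtl_interval()) {
  stopifnot(inherits(interval, "genomic_interval"))
  annotations <- as.data.frame(annotations)
  required <- c("probe_set_id", "chromosome", "position")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols) > 0) {
    stop("annotations lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  chrom <- normalize_chromosome(annotations$chromosome)
  pos <- as.numeric(annotations$position)
  placed <- !is.na(chrom) & chrom != "" & !is.na(pos)
  inside <- placed & chrom == normalize_chromosome(interval$chromosome) &
    pos >= interval$start & pos <= interval$end
  cls <- ifelse(!placed, "unplaced", ifelse(inside, "cis", "trans"))
  names(cls) <- annotations$probe_set_id
  cls
}

#' Read probe-set genomic annotations
#'
#' Reads a tab-separated annotation file with header columns
#' `probe_set_id`, `chromosome`, `position`, `gene_symbol`. Empty cells mean
#' the placement (or symbol) is absent.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with one row per probe set.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("", "NA"), check.names = FALSE)
  required <- c("probe_set_id", "chromosome", "position", "gene_symbol")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation file missing header column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- ann$probe_set_id[duplicated(ann$probe_set_id)]
  if (length(dup) > 0) {
    stop("duplicate probe_set_id in annotations: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  ann$position <- as.numeric(ann$position)
  if (any(!is.na(ann$position) & is.na(ann$chromosome))) {
    stop("annotation rows with a position but no chromosome", call. = FALSE)
  }
  ann
}
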