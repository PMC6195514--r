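#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end
#' @importFrom IRanges IRanges ranges width pintersect overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All genomic coordinates in this package are 0-based half-open (BED
# convention), both in memory and on disk.  GRanges (1-based closed) is used
# only as an internal engine for overlap queries; the two helpers below are
# the single conversion point.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @return A [GenomicRanges::GRanges] (1-based closed) preserving row order.
#' @keywords internal
#' @noRd
as_granges0 <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Validate an interval table
#'
#' Checks the invariants every genomic interval in the package must satisfy:
#' non-empty chromosome name and `0 <= start < end`.
#'
#' @param x data.frame with `chrom`, `start`, `end` columns.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, ": expected a data.frame with chrom/start/end columns")
  bad <- which(is.na(x$chrom) | !nzchar(as.character(x$chrom)) |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(what, ": invalid interval at row ", bad[1],
         " (need non-empty chrom and 0 <= start < end)")
  invisible(x)
}

#' Base-pair overlap of interval pairs
#'
#' Vectorized over two equally sized interval tables (or two single
#' intervals): returns, per pair, the number of shared base pairs under
#' 0-based half-open coordinates.  Intervals on different chromosomes share
#' zero bp; abutting intervals (`a$end == b$start`) also overlap by zero.
#'
#' @param a,b data.frames with `chrom`, `start`, `end`; recycled to a common
#'   length if one has a single row.
#' @return Integer vector of overlap lengths in bp.
#' @examples
#' overlap_len(data.frame(chrom = "chr1", start = 100, end = 200),
#'             data.frame(chrom = "chr1", start = 150, end = 250))  # 50
#' @export
overlap_len <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  if (nrow(a) != nrow(b))
    stop("overlap_len: a and b must have equal (or recyclable) row counts")
  len <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  len[as.character(a$chrom) != as.character(b$chrom)] <- 0L
  as.integer(len)
}

#' Flag queries overlapping any subject interval
#'
#' For each query interval, reports whether it shares at least one base pair
#' with at least one subject interval.  The result does not depend on the
#' ordering of either input.
#'
#' @param queries,subjects data.frames with `chrom`, `start`, `end`.
#' @return Logical vector, one flag per query row.
#' @export
any_overlap_flags <- function(queries, subjects) {
  if (nrow(queries) == 0L) return(logical(0))
  if (nrow(subjects) == 0L) return(rep(FALSE, nrow(queries)))
  # seqlevel mismatches are expected here (subsets of chromosomes); exact
  # name validation is check_chrom_names()'s job
  suppressWarnings(
    IRanges::overlapsAny(as_granges0(queries), as_granges0(subjects)))
}

#' Effective summit position of peaks
#'
#' The single-bp summit used for TSS distance, category annotation and
#' state tie-breaking: `start + summit_offset` where the caller reported a
#' summit, and the interval midpoint `floor((start + end) / 2)` where the
#' summit is unknown (`NA`).
#'
#' @param peaks peak data.frame (see [parse_narrowpeak()]).
#' @return Integer vector of 0-based genomic summit positions.
#' @export
effective_summit <- function(peaks) {
  s <- peaks$start + peaks$summit_offset
  mid <- (peaks$start + peaks$end) %/% 2L
  unknown <- is.na(peaks$summit_offset)
  s[unknown] <- mid[unknown]
  as.integer(s)
}

#' Warn about chromosome names present in only one of two inputs
#'
#' Chromosome matching everywhere in the package is exact string equality
#' (no "chr" prefix normalization); this validation helper surfaces likely
#' naming mismatches between two inputs.
#'
#' @param a,b character vectors (or interval tables) of chromosome names.
#' @param labels length-2 character, names for the two inputs in the warning.
#' @return Invisibly, a list with the two difference sets.
#' @export
check_chrom_names <- function(a, b, labels = c("first input", "second input")) {
  if (is.data.frame(a)) a <- a$chrom
  if (is.data.frame(b)) b <- b$chrom
  a <- unique(as.character(a)); b <- unique(as.character(b))
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b))
    warning("chromosome names differ between inputs: ",
            if (length(only_a)) paste0(labels[1], " only: ",
                                       paste(only_a, collapse = ",")) else "",
            if (length(only_a) && length(only_b)) "; " else "",
            if (length(only_b)) paste0(labels[2], " only: ",
                                       paste(only_b, collapse = ",")) else "",
            call. = FALSE)
  invisible(list(only_a = only_a, only_b = only_b))
}
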