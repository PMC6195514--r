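# Cross-cell-line peak-set comparison and chromatin-state assignment.

#' Per-reference-set overlap counts for up to three peak sets
#'
#' `count(X -> Y)` is the number of X peaks overlapping (>= 1 bp) at least
#' one Y peak; counts are reference-set-specific, not symmetric (the number
#' of X regions touching Y differs in general from the number of Y regions
#' touching X).  `count(X -> YZ)` counts X peaks overlapping at least one
#' peak in each of the other two sets.
#'
#' @param A,B,C interval data.frames (peak sets); `C` may be `NULL` or empty
#'   for pairwise mode.
#' @param names length-3 character, the set labels.
#' @return list with `sizes` (named sizes), `pairwise` (data.frame `from`,
#'   `to`, `count`), and `triple` (data.frame `from`, `count`; empty in
#'   pairwise mode).
#' @export
venn_counts <- function(A, B, C = NULL,
                        names = c("A", "B", "C")) {
  sets <- list(A, B, C)
  if (is.null(C)) sets[[3]] <- data.frame(chrom = character(0),
                                          start = integer(0),
                                          end = integer(0))
  names(sets) <- names
  use <- if (nrow(sets[[3]]) == 0) 1:2 else 1:3
  pw <- list(); k <- 0L
  flags <- list()
  for (i in use) for (j in use) if (i != j) {
    f <- any_overlap_flags(sets[[i]], sets[[j]])
    flags[[paste(i, j)]] <- f
    k <- k + 1L
    pw[[k]] <- data.frame(from = names[i], to = names[j], count = sum(f),
                          stringsAsFactors = FALSE)
  }
  triple <- if (length(use) == 3) {
    do.call(rbind, lapply(use, function(i) {
      oth <- setdiff(use, i)
      data.frame(from = names[i],
                 count = sum(flags[[paste(i, oth[1])]] &
                               flags[[paste(i, oth[2])]]),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(from = character(0), count = integer(0))
  list(sizes = stats::setNames(vapply(sets[use], nrow, integer(1)),
                               names[use]),
       pairwise = do.call(rbind, pw),
       triple = triple)
}

#' Percentage of a count over a total
#'
#' Full-precision `100 * count / total`; rounding to a printed precision is
#' a display concern, not done here.
#'
#' @param count,total numeric; `0 <= count <= total`, `total > 0`.
#' @return numeric percentage.
#' @export
percent <- function(count, total) {
  if (any(total <= 0)) stop("percent: total must be > 0")
  if (any(count < 0 | count > total))
    stop("percent: need 0 <= count <= total")
  100 * count / total
}

#' Assign each peak to a chromatin state
#'
#' The state whose segments share the most base pairs with the peak wins;
#' exact bp ties go to the state covering the peak's effective summit (or,
#' if none covers it, the alphabetically first tied state); peaks touching
#' no segment at all fall back to "Quies", counted in the returned warning
#' attribute.
#'
#' @param peaks peak data.frame.
#' @param segments chromatin-state data.frame from
#'   `parse_bed(states = TRUE)`; segments must be non-overlapping per
#'   chromosome.
#' @return character vector of state labels, one per peak, with attribute
#'   `n_unassigned` = number of peaks that needed the Quies fallback.
#' @export
assign_state <- function(peaks, segments) {
  seg_gr <- as_granges0(segments)
  if (!IRanges::isDisjoint(seg_gr))
    stop("assign_state: state segments overlap within a chromosome")
  peak_gr <- as_granges0(peaks)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(peak_gr, seg_gr))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  bp <- overlap_len(peaks[qh, c("chrom", "start", "end")],
                    segments[sh, c("chrom", "start", "end")])
  summit <- effective_summit(peaks)
  state <- rep(NA_character_, nrow(peaks))
  for (i in unique(qh)) {
    rows <- which(qh == i)
    tally <- tapply(bp[rows], segments$state[sh[rows]], sum)
    best <- names(tally)[tally == max(tally)]
    if (length(best) > 1L) {
      at_summit <- rows[summit[i] >= segments$start[sh[rows]] &
                          summit[i] < segments$end[sh[rows]]]
      cover <- intersect(unique(segments$state[sh[at_summit]]), best)
      best <- if (length(cover)) cover[1] else sort(best)[1]
    }
    state[i] <- best[1]
  }
  n_un <- sum(is.na(state))
  state[is.na(state)] <- "Quies"
  attr(state, "n_unassigned") <- n_un
  state
}

#' Chromatin-state distribution of peak subsets
#'
#' Per-subset fraction of peaks assigned to each of the 15 coreMarks states
#' (e.g. all peaks, peaks shared with a reference set, set-specific peaks).
#'
#' @param states character vector of per-peak state labels from
#'   [assign_state()].
#' @param subsets named list of logical vectors (same length as `states`)
#'   selecting the peak subsets.
#' @return data.frame with `subset`, `state`, `n`, `fraction` (fractions sum
#'   to 1 within each non-empty subset).
#' @export
state_distribution <- function(states, subsets) {
  out <- lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]]
    n <- table(factor(states[sel], levels = CHROMATIN_STATES))
    tot <- sum(n)
    data.frame(subset = nm, state = CHROMATIN_STATES, n = as.integer(n),
               fraction = if (tot > 0) as.numeric(n) / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
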