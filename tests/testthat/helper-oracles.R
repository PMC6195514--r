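# Independent brute-force oracles and small fixture builders.  Every oracle
# recomputes its quantity by direct enumeration, never through the package
# code paths it is checking.

random_intervals <- function(n, chroms = c("c1", "c2"), span = 10000,
                             max_width = 300) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

random_peak_df <- function(n, chroms = c("c1", "c2"), span = 10000) {
  iv <- random_intervals(n, chroms, span)
  iv$name <- sprintf("rp%04d", seq_len(n))
  iv$score <- 0L
  iv$strand <- "."
  iv$fold_enrichment <- round(runif(n, 1, 20), 3)
  iv$neglog10_p <- round(runif(n, 2, 30), 3)
  iv$neglog10_q <- round(runif(n, 1, 20), 3)
  iv$summit_offset <- as.integer((iv$end - iv$start) %/% 2)
  iv
}

# shared-bp count by direct coordinate comparison, one pair at a time
brute_overlap_len <- function(a, b) {
  mapply(function(ac, as, ae, bc, bs, be) {
    if (ac != bc) return(0L)
    sum(seq(as, ae - 1L) %in% seq(bs, be - 1L))
  }, a$chrom, a$start, a$end, b$chrom, b$start, b$end, USE.NAMES = FALSE)
}

# all-pairs overlap flags
brute_any_overlap <- function(queries, subjects) {
  vapply(seq_len(nrow(queries)), function(i) {
    any(subjects$chrom == queries$chrom[i] &
          subjects$start < queries$end[i] &
          subjects$end > queries$start[i])
  }, logical(1))
}

# nearest TSS by exhaustive search with the lexicographic tie rule
brute_closest_tss <- function(summit, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NA_character_)
  d <- abs(g$tss - summit)
  sort(g$gene_id[d == min(d)])[1]
}

# per-state bp tally by coordinate sweep, max-overlap rule with summit tie
brute_assign_state <- function(peak, summit, segments) {
  segs <- segments[segments$chrom == peak$chrom, , drop = FALSE]
  bp <- pmax(0L, pmin(segs$end, peak$end) - pmax(segs$start, peak$start))
  if (!any(bp > 0)) return("Quies")
  tally <- tapply(bp, segs$state, sum)
  tally <- tally[tally > 0]
  best <- names(tally)[tally == max(tally)]
  if (length(best) > 1) {
    cover <- segs$state[summit >= segs$start & summit < segs$end]
    hit <- intersect(cover, best)
    best <- if (length(hit)) hit[1] else sort(best)[1]
  }
  best
}

# exhaustive window scoring on both strands, position by position
brute_scan <- function(seq, pwm, frac_threshold = 0.8) {
  L <- nrow(pwm$probs)
  n <- nchar(seq)
  cutoff <- frac_threshold * pwm_max_score(pwm)
  hits <- list()
  score_window <- function(w) {
    b <- strsplit(w, "")[[1]]
    sum(vapply(seq_len(L), function(j) {
      if (b[j] %in% c("A", "C", "G", "T"))
        log(pwm$probs[j, b[j]] / 0.25) else 0
    }, numeric(1)))
  }
  rc <- function(w) paste(rev(strsplit(chartr("ACGT", "TGCA", w),
                                       "")[[1]]), collapse = "")
  for (off in 0:(n - L)) {
    w <- substr(seq, off + 1, off + L)
    s <- score_window(w)
    if (s >= cutoff)
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "+",
                                             score = s)
    s <- score_window(rc(w))
    if (s >= cutoff)
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "-",
                                             score = s)
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, hits)
}

# upper-tail hypergeometric by direct pmf summation
brute_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

sort_hits <- function(h) {
  h <- h[order(h$offset, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

tiny_genes <- function() {
  data.frame(gene_id = c("gA", "gB", "gC"),
             chrom = c("c1", "c1", "c2"),
             strand = c("+", "-", "+"),
             start = c(4000L, 6500L, 100L),
             end = c(6000L, 7001L, 700L),
             tss = c(4000L, 7000L, 100L),
             exon_starts = c("4000,5000", "6600", ""),
             exon_ends = c("4200,5400", "6900", ""),
             stringsAsFactors = FALSE)
}
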