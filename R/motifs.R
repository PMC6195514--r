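# Motif-class decomposition of peak sets: four-way classification by
# ETS/RUNX content, summit-centering profiles, class-fraction-vs-threshold
# curves, group fold-enrichment tests and the ETS-IRF compound search.

#' The four-way motif classification labels
#' @format character vector of the peak class vocabulary.
#' @export
MOTIF_CLASSES <- c("ETS_ONLY", "RUNX_ONLY", "ETS_RUNX", "NEITHER")

#' Four-way motif classification of peaks
#'
#' A peak with at least one ETS-family and one RUNX-family hit is
#' `ETS_RUNX`; one family alone gives `ETS_ONLY` / `RUNX_ONLY`; no hit in
#' either family gives `NEITHER`.  Separately, `has_ets_irf_compound` flags
#' peaks with at least one hit of the ETS-IRF compound family (reported in
#' any class, of interest mainly within `NEITHER`).
#'
#' @param peak_names character vector of all peak names to classify.
#' @param hits motif-hit data.frame from [scan_peaks()].
#' @return data.frame with `peak_name`, `class`, `has_ets_irf_compound`.
#' @export
classify_peaks <- function(peak_names, hits) {
  has <- function(fam)
    peak_names %in% hits$peak_name[hits$family == fam]
  ets <- has("ETS"); runx <- has("RUNX")
  cls <- ifelse(ets & runx, "ETS_RUNX",
         ifelse(ets, "ETS_ONLY",
         ifelse(runx, "RUNX_ONLY", "NEITHER")))
  data.frame(peak_name = peak_names, class = cls,
             has_ets_irf_compound = has("ETS_IRF_COMPOUND"),
             stringsAsFactors = FALSE)
}

#' Histogram of motif-hit centers around peak summits
#'
#' For every hit, the signed offset of the hit center
#' (`offset + floor(L/2)` within the peak) from the peak's effective summit
#' is binned into `[-window, window)` with bins of width `bin`, per motif
#' family.  Offsets outside the window are dropped.
#'
#' @param hits motif-hit data.frame from [scan_peaks()].
#' @param peaks peak data.frame (for summit positions).
#' @param pwms the PWM list used for scanning (for motif lengths).
#' @param window half-width in bp.
#' @param bin bin width in bp; must divide `window`.
#' @return data.frame with `family`, `bin_start`, `bin_end`, `count`.
#' @export
summit_centering_profile <- function(hits, peaks, pwms,
                                     window = 500, bin = 50) {
  if (window %% bin != 0)
    stop("summit_centering_profile: window must be divisible by bin")
  starts <- seq(-window, window - bin, by = bin)
  summit_in_peak <- effective_summit(peaks) - peaks$start
  fams <- unique(vapply(pwms, `[[`, "", "family"))
  out <- list()
  lens <- vapply(pwms, function(p) nrow(p$probs), integer(1))
  names(lens) <- vapply(pwms, `[[`, "", "id")
  for (fam in fams) {
    h <- hits[hits$family == fam, , drop = FALSE]
    count <- integer(length(starts))
    if (nrow(h)) {
      center <- h$offset + lens[h$pwm_id] %/% 2L
      rel <- center - summit_in_peak[match(h$peak_name, peaks$name)]
      rel <- rel[!is.na(rel) & rel >= -window & rel < window]
      idx <- floor(rel / bin) - (-window %/% bin) + 1L
      count <- tabulate(idx, nbins = length(starts))
    }
    out[[fam]] <- data.frame(family = fam, bin_start = starts,
                             bin_end = starts + bin, count = count,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif-class composition above each fold-enrichment threshold
#'
#' At every grid threshold `t`, the fraction of peaks with FE >= `t` falling
#' in each of the four motif classes.  Fractions sum to 1 across classes at
#' every threshold with at least one retained peak; a threshold retaining no
#' peaks reports `NA` fractions.
#'
#' @param peaks peak data.frame.
#' @param classes output of [classify_peaks()] for these peaks.
#' @param grid numeric thresholds (default [fe_grid()]).
#' @return data.frame with `threshold`, `n_peaks` and one `frac_<class>`
#'   column per motif class.
#' @export
class_fraction_curve <- function(peaks, classes, grid = fe_grid()) {
  cls <- classes$class[match(peaks$name, classes$peak_name)]
  rows <- lapply(grid, function(t) {
    keep <- peaks$fold_enrichment >= t
    n <- sum(keep)
    fr <- if (n > 0) {
      as.numeric(table(factor(cls[keep], levels = MOTIF_CLASSES)) / n)
    } else rep(NA_real_, length(MOTIF_CLASSES))
    stats::setNames(
      data.frame(t, n, fr[1], fr[2], fr[3], fr[4]),
      c("threshold", "n_peaks", paste0("frac_", MOTIF_CLASSES)))
  })
  do.call(rbind, rows)
}

#' Pooled-variance two-sample t-test on fold enrichments
#'
#' The classical Student's t with pooled variance, two-tailed p from the t
#' distribution with `nA + nB - 2` degrees of freedom.  Degenerate groups
#' with zero pooled variance give `t = 0, p = 1` when the means are equal
#' and `t = +/-Inf, p = 0` otherwise.  Also reports each group's median and
#' 5th/95th percentiles (type-7 quantiles) for whisker plots.
#'
#' @param a,b numeric vectors of fold enrichments; each of length >= 2.
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, and `summary`, a
#'   data.frame of per-group n / median / 5th / 95th percentiles.
#' @export
group_fe_test <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("group_fe_test: each group needs n >= 2")
  ma <- mean(a); mb <- mean(b)
  if (welch) {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    se2 <- va + vb
    df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (se2 == 0) {
    tt <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
  } else {
    tt <- (ma - mb) / sqrt(se2)
    p <- 2 * stats::pt(-abs(tt), df)
  }
  qs <- function(x) stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  qa <- qs(a); qb <- qs(b)
  list(t = tt, df = df, p = p, mean_a = ma, mean_b = mb,
       summary = data.frame(group = c("A", "B"), n = c(na, nb),
                            p5 = c(qa[1], qb[1]), median = c(qa[2], qb[2]),
                            p95 = c(qa[3], qb[3])))
}

#' IRF and ETS-IRF compound content of motif-free peaks
#'
#' Among peaks classified `NEITHER` (no ETS, no RUNX motif), counts how many
#' carry an IRF-family hit and how many carry the ETS-IRF compound motif,
#' split by expression-correlated status.
#'
#' @param classes output of [classify_peaks()].
#' @param hits motif-hit data.frame from [scan_peaks()].
#' @param expr_correlated logical vector aligned with `classes` rows.
#' @return data.frame with one row per expression status:
#'   `expression_correlated`, `n_neither`, `n_irf`, `n_compound`.
#' @export
compound_motif_report <- function(classes, hits, expr_correlated) {
  stopifnot(length(expr_correlated) == nrow(classes))
  neither <- classes$class == "NEITHER"
  irf_peaks <- unique(hits$peak_name[hits$family == "IRF"])
  comp_peaks <- unique(hits$peak_name[hits$family == "ETS_IRF_COMPOUND"])
  res <- lapply(c(TRUE, FALSE), function(flag) {
    sel <- neither & expr_correlated == flag
    data.frame(expression_correlated = flag,
               n_neither = sum(sel),
               n_irf = sum(classes$peak_name[sel] %in% irf_peaks),
               n_compound = sum(classes$peak_name[sel] %in% comp_peaks))
  })
  do.call(rbind, res)
}

#' Mononucleotide shuffle of sequences
#' @param seqs character vector of sequences.
#' @return character vector with each sequence's bases permuted.
#' @keywords internal
#' @noRd
shuffle_seqs <- function(seqs) {
  vapply(seqs, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Empirical motif enrichment against shuffled sequences
#'
#' Compares the fraction of peak sequences carrying at least one hit of each
#' PWM with the same fraction in mononucleotide-shuffled copies of the
#' sequences, giving a fold enrichment and an empirical one-sided p-value
#' over `n_shuffles` rounds (a frequency-based stand-in for a discovery
#' tool's per-motif enrichment statistic).
#'
#' @param seqs named character vector of peak sequences.
#' @param pwms named list of PWM objects.
#' @param frac_threshold scan threshold (see [scan_peaks()]).
#' @param n_shuffles number of shuffle rounds.
#' @param seed RNG seed for the shuffles.
#' @return data.frame with `pwm_id`, `family`, `frac_hits`,
#'   `mean_frac_shuffled`, `fold_enrichment`, `empirical_p`.
#' @export
motif_enrichment_report <- function(seqs, pwms, frac_threshold = 0.8,
                                    n_shuffles = 100, seed = 1) {
  obs <- scan_peaks(seqs, pwms, frac_threshold)
  n <- length(seqs)
  obs_frac <- vapply(pwms, function(p)
    length(unique(obs$peak_name[obs$pwm_id == p$id])) / n, numeric(1))
  shuf_frac <- matrix(0, n_shuffles, length(pwms))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(n_shuffles)) {
    sh <- shuffle_seqs(seqs)
    names(sh) <- names(seqs)
    hits <- scan_peaks(sh, pwms, frac_threshold)
    shuf_frac[r, ] <- vapply(pwms, function(p)
      length(unique(hits$peak_name[hits$pwm_id == p$id])) / n, numeric(1))
  }
  mean_sh <- colMeans(shuf_frac)
  emp_p <- vapply(seq_along(pwms), function(j)
    (1 + sum(shuf_frac[, j] >= obs_frac[j])) / (1 + n_shuffles), numeric(1))
  data.frame(pwm_id = vapply(pwms, `[[`, "", "id"),
             family = vapply(pwms, `[[`, "", "family"),
             frac_hits = obs_frac,
             mean_frac_shuffled = mean_sh,
             fold_enrichment = ifelse(mean_sh > 0, obs_frac / mean_sh, NA),
             empirical_p = emp_p,
             row.names = NULL)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
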