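test_that("log-odds scoring: consensus is maximal, uniform PWM scores zero", {
  pwm <- consensus_pwm("ACGTAC", "m1", "ETS")
  cons <- pwm_consensus(pwm)
  expect_equal(log_odds_score(cons, pwm), pwm_max_score(pwm))
  set.seed(31)
  for (i in 1:20)
    expect_lte(log_odds_score(random_dna(6), pwm), pwm_max_score(pwm))
  unif <- new_pwm("u", "OTHER", matrix(0.25, 6, 4))
  expect_equal(log_odds_score("ACGTAC", unif), 0)
  expect_equal(log_odds_score("NNNNNN", pwm), 0)  # N contributes nothing
  expect_error(log_odds_score("ACGT", pwm), "length")
})

test_that("log-odds scoring matches independent per-position recomputation", {
  set.seed(32)
  pwm <- consensus_pwm("GGAATTCC", "m2", "ETS", match_prob = 0.7)
  for (i in 1:30) {
    w <- random_dna(8)
    b <- strsplit(w, "")[[1]]
    expected <- sum(vapply(1:8, function(j)
      log(pwm$probs[j, b[j]] / 0.25), numeric(1)))
    expect_equal(log_odds_score(w, pwm), expected, tolerance = 1e-12)
  }
})

test_that("scanning finds planted consensus on both strands at the right offsets", {
  pwm <- consensus_pwm("ACCGGAAGTG", "ets", "ETS")
  cons <- pwm_consensus(pwm)
  seq <- paste0(strrep("T", 10), cons, strrep("T", 20))
  h <- scan_sequence(seq, pwm)
  expect_equal(h$offset, 10L)
  expect_equal(h$strand, "+")
  seq_rc <- paste0(strrep("T", 5), revcomp(cons), strrep("T", 25))
  h2 <- scan_sequence(seq_rc, pwm)
  expect_equal(h2$offset, 5L)
  expect_equal(h2$strand, "-")
})

test_that("scanning equals the exhaustive sliding-window oracle", {
  set.seed(33)
  pwm <- consensus_pwm("GGAAGT", "m", "ETS", match_prob = 0.55)  # permissive
  for (i in 1:20) {
    seq <- random_dna(80)
    got <- sort_hits(scan_sequence(seq, pwm, 0.7))
    want <- sort_hits(brute_scan(seq, pwm, 0.7))
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("scanning is strand-symmetric under reverse complementation", {
  set.seed(34)
  pwm <- consensus_pwm("TGTGGT", "r", "RUNX", match_prob = 0.6)
  for (i in 1:10) {
    seq <- random_dna(60)
    fwd <- sort_hits(scan_sequence(seq, pwm, 0.75))
    rev <- scan_sequence(revcomp(seq), pwm, 0.75)
    # a + hit at offset o maps to a - hit at n - L - o, and vice versa
    rev$offset <- nchar(seq) - nrow(pwm$probs) - rev$offset
    rev$strand <- chartr("+-", "-+", rev$strand)
    rev <- sort_hits(rev)
    expect_equal(fwd$offset, rev$offset)
    expect_equal(fwd$strand, rev$strand)
    expect_equal(fwd$score, rev$score, tolerance = 1e-10)
  }
})

test_that("peak classification partitions by ETS/RUNX content", {
  hits <- data.frame(
    peak_name = c("p1", "p2", "p2", "p4"),
    pwm_id = c("e", "e", "r", "c"),
    family = c("ETS", "ETS", "RUNX", "ETS_IRF_COMPOUND"),
    offset = 0L, strand = "+", score = 10)
  cl <- classify_peaks(c("p1", "p2", "p3", "p4"), hits)
  expect_equal(cl$class, c("ETS_ONLY", "ETS_RUNX", "NEITHER", "NEITHER"))
  expect_equal(cl$has_ets_irf_compound, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(sum(table(factor(cl$class, MOTIF_CLASSES))), 4)
})

test_that("summit centering profile bins hit centers and conserves counts", {
  pwms <- list(consensus_pwm("ACGTACGTAC", "e", "ETS"))
  peaks <- random_peak_df(2, chroms = "c1")
  peaks$start <- c(0L, 1000L); peaks$end <- c(500L, 1500L)
  peaks$summit_offset <- c(250L, 250L)
  hits <- data.frame(peak_name = c("rp0001", "rp0001", "rp0002"),
                     pwm_id = "e", family = "ETS",
                     offset = c(245L, 100L, 600L),  # centers 250, 105, 605
                     strand = "+", score = 10)
  prof <- summit_centering_profile(hits, peaks, pwms, window = 200, bin = 50)
  expect_equal(sum(prof$count), 2)   # center 605 is 355 bp off, outside
  expect_equal(prof$count[prof$bin_start == 0], 1)      # exactly at summit
  expect_equal(prof$count[prof$bin_start == -150], 1)   # center - summit = -145
  empty <- summit_centering_profile(hits[0, ], peaks, pwms)
  expect_true(all(empty$count == 0))
  expect_error(summit_centering_profile(hits, peaks, pwms, 200, 30),
               "divisible")
})

test_that("planted Gaussian hit offsets produce a summit-centered modal bin", {
  set.seed(35)
  n <- 400
  peaks <- data.frame(chrom = "c1", start = 0L, end = 1000L,
                      name = sprintf("p%03d", 1:n), summit_offset = 500L)
  L <- 10L
  center <- 500L + as.integer(round(rnorm(n, 0, 40)))
  hits <- data.frame(peak_name = peaks$name, pwm_id = "e", family = "ETS",
                     offset = center - L %/% 2L, strand = "+", score = 10)
  pwms <- list(consensus_pwm("ACGTACGTAC", "e", "ETS"))
  prof <- summit_centering_profile(hits, peaks, pwms)
  modal <- prof[which.max(prof$count), ]
  expect_true(modal$bin_start %in% c(-50, 0))  # one of the two summit bins
})

test_that("class fractions sum to one per threshold and handle empty tails", {
  peaks <- random_peak_df(40)
  peaks$fold_enrichment <- runif(40, 3, 6)
  cl <- data.frame(peak_name = peaks$name,
                   class = sample(MOTIF_CLASSES, 40, replace = TRUE))
  curve <- class_fraction_curve(peaks, cl, grid = c(3, 5, 7))
  fr <- as.matrix(curve[, paste0("frac_", MOTIF_CLASSES)])
  expect_equal(rowSums(fr)[curve$n_peaks > 0],
               rep(1, sum(curve$n_peaks > 0)), ignore_attr = TRUE)
  expect_true(all(is.na(fr[curve$n_peaks == 0, ])))
  cl$class <- "ETS_ONLY"
  curve2 <- class_fraction_curve(peaks, cl, grid = c(3, 4))
  expect_equal(curve2$frac_ETS_ONLY, c(1, 1))
})

test_that("the pooled t-test matches the closed form and stats::t.test", {
  g <- group_fe_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$t, 0)
  expect_equal(g$p, 1)
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  g2 <- group_fe_test(a, b)
  # hand computation: pooled var 5/3, se = sqrt(5/3 * 1/2), df = 6
  expect_equal(g2$t, -1 / sqrt(5 / 3 / 2), tolerance = 1e-12)
  expect_equal(g2$df, 6)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(g2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(g2$p, tt$p.value, tolerance = 1e-12)
  w <- group_fe_test(a, b + 10, welch = TRUE)
  tw <- t.test(a, b + 10)
  expect_equal(w$t, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(w$p, tw$p.value, tolerance = 1e-12)
  # degenerate: zero variance in both groups, equal means
  expect_equal(group_fe_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(group_fe_test(c(2, 2), c(3, 3))$p, 0)
  expect_error(group_fe_test(1, c(1, 2)), "n >= 2")
  expect_equal(g2$summary$median, c(2.5, 3.5))
})

test_that("compound motif report recounts planted IRF/compound content", {
  cl <- data.frame(peak_name = sprintf("p%02d", 1:10),
                   class = rep(c("NEITHER", "ETS_ONLY"), each = 5),
                   has_ets_irf_compound = FALSE)
  hits <- data.frame(peak_name = c("p01", "p02", "p03", "p06"),
                     pwm_id = c("cmp", "cmp", "irf", "cmp"),
                     family = c("ETS_IRF_COMPOUND", "ETS_IRF_COMPOUND",
                                "IRF", "ETS_IRF_COMPOUND"),
                     offset = 0L, strand = "+", score = 5)
  flag <- c(TRUE, TRUE, FALSE, FALSE, FALSE, rep(FALSE, 5))
  rep_ <- compound_motif_report(cl, hits, flag)
  ec <- rep_[rep_$expression_correlated, ]
  non <- rep_[!rep_$expression_correlated, ]
  expect_equal(ec$n_neither, 2)
  expect_equal(ec$n_compound, 2)
  expect_equal(ec$n_irf, 0)
  expect_equal(non$n_neither, 3)
  expect_equal(non$n_compound, 0)
  expect_equal(non$n_irf, 1)
  none <- compound_motif_report(cl, hits[0, ], flag)
  expect_true(all(none$n_irf == 0) && all(none$n_compound == 0))
})

test_that("shuffle-based enrichment flags a planted motif but not a random one", {
  set.seed(36)
  cons <- "ACCGGAAGTG"
  seqs <- vapply(1:60, function(i) {
    s <- random_dna(120)
    substr(s, 50, 59) <- cons
    s
  }, character(1))
  names(seqs) <- sprintf("p%02d", 1:60)
  pwms <- list(ets = consensus_pwm(cons, "ets", "ETS"),
               other = consensus_pwm("TTGACGTCAA", "other", "OTHER"))
  rep_ <- motif_enrichment_report(seqs, pwms, n_shuffles = 20, seed = 9)
  expect_equal(rep_$frac_hits[rep_$pwm_id == "ets"], 1)
  expect_lt(rep_$empirical_p[rep_$pwm_id == "ets"], 0.05)
  expect_gt(rep_$empirical_p[rep_$pwm_id == "other"], 0.2)
})
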