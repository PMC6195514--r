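small_cfg <- function(seed = 5, ...) {
  synthetic_config(seed = seed, n_chroms = 2, chrom_length = 3e5,
                   n_genes = 300, n_peaks = 200, n_blacklist = 5, ...)
}

test_that("the generator is deterministic under its seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_workspace(small_cfg(), d1)
  generate_workspace(small_cfg(), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 12)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  d3 <- withr::local_tempdir()
  generate_workspace(small_cfg(seed = 6), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "peaks.narrowPeak"))),
                         unname(tools::md5sum(file.path(d3, "peaks.narrowPeak")))))
})

test_that("generated files re-parse cleanly through the package readers", {
  d <- withr::local_tempdir()
  generate_workspace(small_cfg(), d)
  expect_no_warning({
    peaks <- parse_narrowpeak(file.path(d, "peaks.narrowPeak"))
    parse_narrowpeak(file.path(d, "peaks_B.narrowPeak"))
    parse_narrowpeak(file.path(d, "peaks_C.narrowPeak"))
    genes <- parse_gene_table(file.path(d, "genes.tsv"))
    parse_bed(file.path(d, "blacklist.bed"))
    segs <- parse_bed(file.path(d, "states.bed"), states = TRUE)
    parse_gene_list(file.path(d, "modulated_genes.tsv"))
    seqs <- parse_fasta(file.path(d, "peak_seqs.fa"))
    parse_pwm_text(file.path(d, "pwms.txt"))
  })
  expect_equal(nrow(peaks), 200)
  expect_equal(nrow(genes), 300)
  expect_setequal(names(seqs), peaks$name)
  # state segments are a disjoint tiling
  expect_true(all(tapply(seq_len(nrow(segs)), segs$chrom, function(i) {
    s <- segs[i, ][order(segs$start[i]), ]
    all(s$start[-1] >= s$end[-nrow(s)])
  })))
})

test_that("genome generation gives the requested shape and ~uniform composition", {
  cfg <- synthetic_config(seed = 3, n_chroms = 2, chrom_length = 1e5)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$sizes), 2)
  expect_equal(nchar(g$seqs[[1]]), 1e5)
  comp <- table(strsplit(g$seqs[[1]], "")[[1]]) / 1e5
  # binomial CI around 0.25 at n = 1e5 is ~ +/- 0.004; allow 4 sigma
  expect_true(all(abs(comp - 0.25) < 0.006))
  sizes_only <- generate_genome(cfg, with_sequence = FALSE)
  expect_null(sizes_only$seqs)
  expect_equal(sizes_only$sizes, g$sizes)
})

test_that("generated genes satisfy the gene-model invariants", {
  cfg <- small_cfg()
  genome <- generate_genome(cfg, with_sequence = FALSE)
  genes <- generate_genes(cfg, genome)
  expect_equal(nrow(genes), 300)
  expect_true(all(genes$tss >= genes$start & genes$tss < genes$end))
  expect_true(all(genes$tss == ifelse(genes$strand == "+", genes$start,
                                      genes$end - 1L)))
  ex <- strsplit(genes$exon_starts, ",")
  ee <- strsplit(genes$exon_ends, ",")
  for (i in seq_len(nrow(genes))) {
    es <- as.integer(ex[[i]]); en <- as.integer(ee[[i]])
    expect_true(all(es >= genes$start[i] & en <= genes$end[i] & es < en))
  }
})

test_that("planted class priors and FE separation are recovered at n = 2000", {
  cfg <- synthetic_config(seed = 8, n_chroms = 3, chrom_length = 2e6,
                          n_peaks = 2000, n_genes = 1000)
  genome <- generate_genome(cfg, with_sequence = FALSE)
  pk <- generate_peaks(cfg, genome)
  expect_equal(nrow(pk$peaks), 2000)
  tab <- table(pk$truth$class) / 2000
  for (cl in MOTIF_CLASSES) {
    p0 <- cfg$class_priors[[cl]]
    ci <- 4 * sqrt(p0 * (1 - p0) / 2000)
    expect_lt(abs(tab[[cl]] - p0), ci)
  }
  # ETS-containing classes drawn from a higher FE distribution
  fe <- pk$peaks$fold_enrichment
  ets <- fe[pk$truth$class == "ETS_ONLY"]
  nei <- fe[pk$truth$class == "NEITHER"]
  gt <- group_fe_test(ets, nei)
  expect_gt(gt$mean_a, gt$mean_b)
  expect_lt(gt$p, 0.01)
  # peaks are placed non-overlapping within each chromosome
  for (ch in unique(pk$peaks$chrom)) {
    p <- pk$peaks[pk$peaks$chrom == ch, ]
    expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
})

test_that("degenerate priors plant no motifs", {
  cfg <- small_cfg(class_priors = c(ETS_ONLY = 0, RUNX_ONLY = 0,
                                    ETS_RUNX = 0, NEITHER = 1),
                   compound_rate = 0, irf_rate = 0)
  genome <- generate_genome(cfg)
  before <- genome$seqs
  pk <- generate_peaks(cfg, genome)
  expect_identical(pk$genome$seqs, before)
  expect_true(all(pk$truth$class == "NEITHER"))
})

test_that("expression coupling plants disjoint up/down sets tied to peak strength", {
  cfg <- small_cfg()
  genome <- generate_genome(cfg, with_sequence = FALSE)
  genes <- generate_genes(cfg, genome)
  pk <- generate_peaks(cfg, genome)
  assoc <- associate_closest_tss(pk$peaks, genes)
  expr <- generate_expression(cfg, assoc)
  expect_length(intersect(expr$up, expr$down), 0)
  expect_equal(length(expr$modulated), length(expr$up) + length(expr$down))
  expect_lte(length(expr$modulated), expr$universe_size)
  # null coupling: equal rates make the Fisher p-curve flat in expectation;
  # the planted signal must vanish (no row hugely more significant)
  cfg0 <- small_cfg(coupling = list(t0 = 4.5, base_rate = 0.1,
                                    boosted_rate = 0.100001))
  expr0 <- generate_expression(cfg0, assoc)
  sw0 <- sweep_thresholds(assoc, expr0)
  expect_gt(min(sw0$rows$fisher_p), 1e-4)
})

test_that("companion sets carry the planted overlap fractions", {
  cfg <- synthetic_config(seed = 9, n_chroms = 3, chrom_length = 2e6,
                          n_peaks = 2000, n_genes = 500)
  genome <- generate_genome(cfg, with_sequence = FALSE)
  pk <- generate_peaks(cfg, genome)
  comp <- generate_companion_sets(cfg, pk$peaks)
  expect_equal(nrow(comp$B), 2000)
  expect_equal(nrow(comp$C), 3000)
  fAB <- sum(any_overlap_flags(pk$peaks, comp$B)) / 2000
  fAC <- sum(any_overlap_flags(pk$peaks, comp$C)) / 2000
  ciAB <- 4 * sqrt(0.19 * 0.81 / 2000)
  ciAC <- 4 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(fAB - 0.19), ciAB + 0.02)  # small slack for jitter contacts
  expect_lt(abs(fAC - 0.05), ciAC + 0.02)
  # p_AB = 0 plants nothing shared
  cfg0 <- small_cfg(overlap = list(p_AB = 0, p_AC = 0, p_ABC = 0))
  genome0 <- generate_genome(cfg0, with_sequence = FALSE)
  pk0 <- generate_peaks(cfg0, genome0)
  comp0 <- generate_companion_sets(cfg0, pk0$peaks)
  expect_equal(sum(any_overlap_flags(pk0$peaks, comp0$B)), 0)
})

test_that("state bias separates shared and specific peaks", {
  cfg <- small_cfg(state_bias = list(shared = 1, specific = 1))
  genome <- generate_genome(cfg, with_sequence = FALSE)
  pk <- generate_peaks(cfg, genome)
  shared <- rep(c(TRUE, FALSE), length.out = nrow(pk$peaks))
  segs <- generate_states(cfg, pk$peaks, shared)
  st <- assign_state(pk$peaks, segs)
  expect_true(all(st[shared] %in% c("TssAFlnk", "Enh")))
  expect_true(all(st[!shared] == "Quies"))
})
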