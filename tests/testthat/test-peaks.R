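test_that("peak filtering applies the fold-enrichment cap, q-value and blacklist rules", {
  p <- random_peak_df(4, chroms = "c1")
  p$fold_enrichment <- c(55, 50, 5, 5)    # "above 50" is strict
  p$neglog10_q <- c(10, 10, 10, 0.5)      # q = 10^-0.5 > 0.1 fails
  p$start <- c(1000L, 2000L, 3000L, 4000L)
  p$end <- p$start + 100L
  bl <- data.frame(chrom = "c1", start = 3099L, end = 3500L)  # 1 shared bp
  f <- filter_peaks(p, bl)
  expect_equal(f$retained$name, p$name[2])
  expect_equal(f$rejected$reason[f$rejected$name == p$name[1]], "fe_cap")
  expect_equal(f$rejected$reason[f$rejected$name == p$name[3]], "blacklist")
  expect_equal(f$rejected$reason[f$rejected$name == p$name[4]], "q_value")
})

test_that("filtering is idempotent, conserves counts, and matches brute force", {
  set.seed(11)
  p <- random_peak_df(200)
  p$fold_enrichment <- runif(200, 1, 80)
  p$neglog10_q <- runif(200, 0, 5)
  bl <- random_intervals(20)
  f <- filter_peaks(p, bl)
  expect_equal(nrow(f$retained) + sum(f$counts), nrow(p))
  f2 <- filter_peaks(f$retained, bl)
  expect_equal(f2$retained, f$retained)
  expect_equal(sum(f2$counts), 0)
  keep <- p$fold_enrichment <= 50 & p$neglog10_q >= 1 - 1e-9 &
    !brute_any_overlap(p, bl)
  expect_equal(f$retained$name, p$name[keep])
})

test_that("closest-TSS association minimizes summit distance with the tie rule", {
  genes <- tiny_genes()
  p <- random_peak_df(2, chroms = "c1")
  p$start <- c(4900L, 5400L); p$end <- c(5100L, 5600L)
  p$summit_offset <- c(100L, 100L)        # summits 5000 and 5500
  a <- associate_closest_tss(p, genes)
  expect_equal(a$gene_id, c("gA", "gA"))  # 5000: d=1000 vs 2000; 5500: tie -> gA
  expect_equal(a$distance, c(1000L, 1500L))
  # summit 5000 is downstream of gA (+ strand TSS 4000): positive sign
  expect_equal(a$signed_distance[1], 1000L)
  # against the minus-strand gene gB (TSS 7000), 5500 would be upstream
  aB <- associate_closest_tss(p, genes[genes$gene_id == "gB", ])
  expect_equal(aB$signed_distance, c(2000L, 1500L))
  expect_error(associate_closest_tss(p, genes[0, ]), "empty gene set")
})

test_that("closest-TSS association equals exhaustive search on random fixtures", {
  set.seed(12)
  for (rep in 1:3) {
    genes <- data.frame(gene_id = sprintf("g%03d", sample(300)),
                        chrom = sample(c("c1", "c2"), 300, replace = TRUE),
                        strand = sample(c("+", "-"), 300, replace = TRUE),
                        tss = sample.int(50000, 300, replace = TRUE))
    genes$start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 999L)
    genes$end <- genes$start + 1000L
    p <- random_peak_df(300, chroms = c("c1", "c2", "c3"), span = 50000)
    a <- associate_closest_tss(p, genes)
    s <- effective_summit(p)
    expected <- vapply(seq_len(nrow(p)),
                       function(i) brute_closest_tss(s[i], p$chrom[i], genes),
                       character(1))
    expect_identical(a$gene_id, expected)
    expect_true(all(a$unassigned == (p$chrom == "c3")))
  }
})

test_that("genomic categories follow genic precedence then upstream bins", {
  genes <- tiny_genes()
  mk <- function(chrom, summit) {
    p <- random_peak_df(1, chroms = chrom)
    p$start <- summit - 50L; p$end <- summit + 50L; p$summit_offset <- 50L
    p
  }
  categ <- function(p) annotate_category(p, genes,
                                         associate_closest_tss(p, genes))
  expect_equal(categ(mk("c1", 5100L)), "EXON")      # inside gA exon 2
  expect_equal(categ(mk("c1", 4500L)), "INTRON")    # in gA span, no exon
  expect_equal(categ(mk("c2", 99L)), "PROXIMAL")    # 1 bp upstream of gC
  expect_equal(categ(mk("c1", 3500L)), "PROXIMAL")  # 500 bp upstream of gA
  expect_equal(categ(mk("c1", 9000L)), "PROXIMAL")  # 2000 bp upstream of gB(-)
  expect_equal(categ(mk("c1", 12000L)), "DISTAL")   # 5 kb upstream of gB(-)
  expect_equal(categ(mk("c1", 30000L)), "FIVE_D")   # 23 kb upstream of gB(-)
  p <- mk("c2", 5000L)                              # 4.9 kb downstream of gC
  expect_equal(categ(p), "OTHER")
})

test_that("upstream bins use the documented thresholds at their boundaries", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                      start = 200000L, end = 210000L, tss = 200000L,
                      exon_starts = "", exon_ends = "")
  at <- function(d) {
    p <- random_peak_df(1, chroms = "c1")
    p$start <- 200000L - d - 50L; p$end <- p$start + 100L
    p$summit_offset <- 50L
    annotate_category(p, genes, associate_closest_tss(p, genes))
  }
  expect_equal(at(2000L), "PROXIMAL")
  expect_equal(at(2001L), "DISTAL")
  expect_equal(at(10000L), "DISTAL")
  expect_equal(at(10001L), "FIVE_D")
  expect_equal(at(100000L), "FIVE_D")
  expect_equal(at(100001L), "OTHER")
})

test_that("every peak gets exactly one category and frequencies sum to one", {
  set.seed(13)
  genes <- tiny_genes()
  p <- random_peak_df(150, chroms = c("c1", "c2"), span = 20000)
  a <- associate_closest_tss(p, genes)
  categ <- annotate_category(p, genes, a)
  expect_length(categ, nrow(p))
  expect_true(all(categ %in% ANNOTATION_CATEGORIES))
  expect_equal(sum(table(categ) / nrow(p)), 1)
})

test_that("TSS distance profile bins half-open and conserves in-window counts", {
  a <- data.frame(signed_distance = c(-500L, 0L, 999L, 10500L, -10000L,
                                      10000L, NA))
  prof <- tss_distance_profile(a, window = 10000, bin = 1000)
  expect_equal(nrow(prof), 20)
  expect_equal(sum(prof$count), 4)  # 10500, 10000 (half-open) and NA excluded
  expect_equal(prof$count[prof$bin_start == -1000], 1)
  expect_equal(prof$count[prof$bin_start == 0], 2)
  expect_equal(prof$count[prof$bin_start == -10000], 1)
  expect_error(tss_distance_profile(a, window = 10000, bin = 300),
               "divisible")
  set.seed(14)
  a2 <- data.frame(signed_distance = sample(-15000:15000, 100))
  p2 <- tss_distance_profile(a2)
  expect_equal(sum(p2$count),
               sum(a2$signed_distance >= -10000 & a2$signed_distance < 10000))
})

test_that("expression-correlated peaks are those whose closest gene is modulated", {
  expr <- expression_set(up = "gA", down = "gB", universe_size = 10)
  a <- data.frame(gene_id = c("gA", "gC", NA, "gB"))
  expect_equal(flag_expression_correlated(a, expr),
               c(TRUE, FALSE, FALSE, TRUE))
})
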