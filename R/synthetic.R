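# Seeded generator of a complete synthetic input workspace with planted
# ground truth: peak motif classes with class-dependent fold-enrichment
# distributions, a logistic-style coupling between peak strength and gene
# modulation status, planted cross-cell-line overlap fractions, and
# chromatin-state bias for shared vs. specific peaks.  Every stage draws
# from its own child seed, so stages can be regenerated independently and
# every output is byte-identical across runs with the same seed.

#' Configuration of the synthetic workspace generator
#'
#' Defaults encode the study conditions the pipeline is calibrated against:
#' a NEITHER (no ETS, no RUNX motif) prior of 0.38, a planted
#' fold-enrichment/expression coupling change-point at `t0 = 4.5` with
#' modulation rates 0.5 above and 0.01 below, ETS-containing classes drawn
#' from a higher log-mean fold-enrichment distribution, companion-set
#' overlap fractions of 0.19 / 0.05 (0.035 triple), and chromatin-state
#' bias pushing shared peaks into TssAFlnk/Enh and specific peaks onto
#' Quies.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_chroms,chrom_length genome shape (bp per chromosome).
#' @param n_genes number of genes (also the calibration universe size).
#' @param n_peaks number of primary peaks.
#' @param class_priors named probabilities over the four motif classes.
#' @param fe_meanlog,fe_sdlog per-class lognormal parameters of fold
#'   enrichment.
#' @param coupling list `t0`, `base_rate`, `boosted_rate`: a gene whose best
#'   associated peak has FE >= `t0` is modulated with `boosted_rate`, else
#'   `base_rate`.
#' @param up_weight probability a modulated gene is upregulated (59:88
#'   up:down style split).
#' @param overlap list `p_AB`, `p_AC`, `p_ABC` of planted companion overlap
#'   fractions (`p_ABC <= min(p_AB, p_AC)`).
#' @param companion_sizes named target sizes of companion sets B and C.
#' @param state_bias list `shared` (probability a shared peak's region is
#'   relabeled TssAFlnk/Enh) and `specific` (probability a specific peak's
#'   region stays Quies).
#' @param motif_offset_sigma bp spread (Gaussian SD) of planted motif
#'   centers around peak summits.
#' @param peak_width_range min/max peak width in bp (uniform).
#' @param compound_rate,irf_rate fraction of NEITHER peaks receiving a
#'   planted ETS-IRF compound / lone IRF consensus.
#' @param mutation_rate per-base mutation probability applied to planted
#'   motif instances (0 = exact consensus).
#' @param n_blacklist number of random blacklist intervals.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chroms = 3,
                             chrom_length = 2e6,
                             n_genes = 3000,
                             n_peaks = 2000,
                             class_priors = c(ETS_ONLY = 0.30,
                                              RUNX_ONLY = 0.17,
                                              ETS_RUNX = 0.15,
                                              NEITHER = 0.38),
                             fe_meanlog = c(ETS_ONLY = 1.7,
                                            RUNX_ONLY = 1.35,
                                            ETS_RUNX = 1.7,
                                            NEITHER = 1.35),
                             fe_sdlog = 0.45,
                             coupling = list(t0 = 4.5, base_rate = 0.01,
                                             boosted_rate = 0.5),
                             up_weight = 59 / 147,
                             overlap = list(p_AB = 0.19, p_AC = 0.05,
                                            p_ABC = 0.035),
                             companion_sizes = c(B = 2000, C = 3000),
                             state_bias = list(shared = 0.9,
                                               specific = 0.8),
                             motif_offset_sigma = 40,
                             peak_width_range = c(200, 600),
                             compound_rate = 0.15,
                             irf_rate = 0.10,
                             mutation_rate = 0,
                             n_blacklist = 20) {
  stopifnot(identical(sort(names(class_priors)), sort(MOTIF_CLASSES)),
            abs(sum(class_priors) - 1) < 1e-9,
            all(class_priors >= 0),
            coupling$base_rate > 0, coupling$base_rate < 1,
            coupling$boosted_rate > coupling$base_rate,
            coupling$boosted_rate < 1,
            overlap$p_AB >= 0, overlap$p_AB <= 1,
            overlap$p_AC >= 0, overlap$p_AC <= 1,
            overlap$p_ABC <= min(overlap$p_AB, overlap$p_AC),
            chrom_length >= 1e4)
  structure(as.list(environment()), class = "synthetic_config")
}

child_seed <- function(config, stage) {
  offsets <- c(genome = 1L, genes = 2L, peaks = 3L, expression = 4L,
               companions = 5L, states = 6L, blacklist = 7L)
  (as.integer(config$seed) %% 20000000L) * 100L + offsets[[stage]]
}

#' Generate a random genome
#'
#' Uniform-random A/C/G/T sequence per chromosome, reproducible under the
#' config seed.
#'
#' @param config a [synthetic_config()].
#' @param with_sequence set `FALSE` to generate only the sizes table
#'   (coordinate-level stages do not need sequence).
#' @return list with `sizes` (data.frame `chrom`, `length`) and `seqs`
#'   (named character vector, or `NULL`).
#' @export
generate_genome <- function(config, with_sequence = TRUE) {
  set.seed(child_seed(config, "genome"))
  chroms <- sprintf("chrS%d", seq_len(config$n_chroms))
  sizes <- data.frame(chrom = chroms,
                      length = rep(as.integer(config$chrom_length),
                                   config$n_chroms))
  seqs <- NULL
  if (with_sequence) {
    seqs <- vapply(chroms, function(ch)
      paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                   replace = TRUE), collapse = ""), character(1))
  }
  list(sizes = sizes, seqs = seqs)
}

#' Generate gene models
#'
#' TSS positions uniform over the genome, random strands, gene spans of
#' 2-20 kb (clipped to the chromosome) and 1-5 exons per gene.
#'
#' @param config a [synthetic_config()].
#' @param genome output of [generate_genome()].
#' @return gene data.frame in the layout of [parse_gene_table()].
#' @export
generate_genes <- function(config, genome) {
  set.seed(child_seed(config, "genes"))
  n <- config$n_genes
  sizes <- genome$sizes
  chrom <- sample(sizes$chrom, n, replace = TRUE,
                  prob = sizes$length / sum(sizes$length))
  clen <- sizes$length[match(chrom, sizes$chrom)]
  tss <- as.integer(floor(runif(n, 1000, clen - 1000)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  glen <- as.integer(round(runif(n, 2000, 20000)))
  start <- ifelse(strand == "+", tss, pmax(0L, tss + 1L - glen))
  end <- ifelse(strand == "+", pmin(clen, tss + glen), tss + 1L)
  start <- as.integer(start); end <- as.integer(end)
  exon_starts <- exon_ends <- character(n)
  n_ex <- sample(1:5, n, replace = TRUE)
  for (i in seq_len(n)) {
    w <- end[i] - start[i]
    es <- sort(as.integer(floor(runif(n_ex[i], start[i], end[i] - 50))))
    ee <- pmin(end[i], es + as.integer(round(runif(n_ex[i], 100, 500))))
    keep <- es < ee
    exon_starts[i] <- paste(es[keep], collapse = ",")
    exon_ends[i] <- paste(ee[keep], collapse = ",")
  }
  data.frame(gene_id = sprintf("g%06d", seq_len(n)), chrom = chrom,
             strand = strand, start = start, end = end, tss = tss,
             exon_starts = exon_starts, exon_ends = exon_ends,
             stringsAsFactors = FALSE)
}

plant_motif <- function(seq, pos, motif, mutation_rate) {
  if (mutation_rate > 0) {
    b <- strsplit(motif, "")[[1]]
    mut <- runif(length(b)) < mutation_rate
    b[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    motif <- paste(b, collapse = "")
  }
  substr(seq, pos + 1L, pos + nchar(motif)) <- motif
  seq
}

#' Generate primary peaks with planted motif classes
#'
#' Peaks are placed non-overlapping (sorted within each chromosome), each
#' drawing a latent motif class from the class priors and a fold enrichment
#' from that class's lognormal (ETS-containing classes have a higher
#' log-mean, so stronger peaks are ETS-enriched by construction).  When
#' genome sequence is present, consensus instances of the class's motifs
#' are written into it at Gaussian offsets around the summit; a fraction of
#' NEITHER peaks instead receives an ETS-IRF compound or a lone IRF
#' consensus.  The hidden truth table records every planted class and
#' motif.
#'
#' @param config a [synthetic_config()].
#' @param genome output of [generate_genome()]; sequence may be `NULL`, in
#'   which case no motifs are planted (coordinate-only mode).
#' @return list with `peaks` (narrowPeak-layout data.frame), `truth`
#'   (data.frame `name`, `class`, `planted_irf`, `planted_compound`), and
#'   `genome` (the genome, with motifs planted into its sequence).
#' @export
generate_peaks <- function(config, genome) {
  set.seed(child_seed(config, "peaks"))
  n <- config$n_peaks
  sizes <- genome$sizes
  n_per <- as.vector(stats::rmultinom(1, n,
                                      sizes$length / sum(sizes$length)))
  pwms <- bundled_pwms()
  consensus <- vapply(pwms, pwm_consensus, character(1))
  fam <- vapply(pwms, `[[`, "", "family")
  rows <- list()
  for (ci in seq_len(nrow(sizes))) {
    nc <- n_per[ci]
    if (nc == 0) next
    clen <- sizes$length[ci]
    width <- as.integer(round(runif(nc, config$peak_width_range[1],
                                    config$peak_width_range[2])))
    free <- clen - sum(width)
    if (free <= nc + 1)
      stop("generate_peaks: chromosome too short for the requested peaks")
    cuts <- sort(runif(nc, 0, 1))
    gaps <- floor(free * diff(c(0, cuts)))
    start <- as.integer(cumsum(gaps) + c(0L, cumsum(width[-nc])))
    rows[[ci]] <- data.frame(chrom = sizes$chrom[ci], start = start,
                             end = start + width,
                             stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  n <- nrow(peaks)
  width <- peaks$end - peaks$start
  cls <- sample(MOTIF_CLASSES, n, replace = TRUE,
                prob = config$class_priors[MOTIF_CLASSES])
  fe <- pmin(49.5, stats::rlnorm(n, config$fe_meanlog[cls], config$fe_sdlog))
  summit <- pmin.int(width - 6L,
                     pmax.int(5L, as.integer(round(
                       width / 2 + stats::rnorm(n, 0, width / 10)))))
  nlq <- 1 + stats::rexp(n, 1 / 3)
  peaks$name <- sprintf("peak_%05d", seq_len(n))
  peaks$score <- as.integer(round(10 * fe))
  peaks$strand <- "."
  peaks$fold_enrichment <- round(fe, 4)
  peaks$neglog10_q <- round(nlq, 4)
  peaks$neglog10_p <- round(nlq + runif(n, 0, 2), 4)
  peaks$summit_offset <- summit
  peaks <- peaks[, c("chrom", "start", "end", "name", "score", "strand",
                     "fold_enrichment", "neglog10_p", "neglog10_q",
                     "summit_offset")]
  truth <- data.frame(name = peaks$name, class = cls,
                      planted_irf = FALSE, planted_compound = FALSE,
                      stringsAsFactors = FALSE)
  if (!is.null(genome$seqs)) {
    u <- runif(n)
    truth$planted_compound <- cls == "NEITHER" & u < config$compound_rate
    truth$planted_irf <- cls == "NEITHER" & !truth$planted_compound &
      u < config$compound_rate + config$irf_rate
    for (i in seq_len(n)) {
      motifs <- switch(cls[i],
                       ETS_ONLY = consensus[fam == "ETS"],
                       RUNX_ONLY = consensus[fam == "RUNX"],
                       ETS_RUNX = c(consensus[fam == "ETS"],
                                    consensus[fam == "RUNX"]),
                       NEITHER = character(0))
      if (truth$planted_compound[i])
        motifs <- consensus[fam == "ETS_IRF_COMPOUND"]
      if (truth$planted_irf[i])
        motifs <- consensus[fam == "IRF"]
      if (!length(motifs)) next
      ch <- peaks$chrom[i]
      used <- cbind(start = integer(0), end = integer(0))
      for (m in motifs) {
        L <- nchar(m)
        for (try in 1:20) {
          off <- summit[i] - L %/% 2L +
            as.integer(round(stats::rnorm(1, 0, config$motif_offset_sigma)))
          off <- min(max(off, 0L), width[i] - L)
          clash <- nrow(used) > 0 &&
            any(off < used[, "end"] & off + L > used[, "start"])
          if (!clash) break
        }
        used <- rbind(used, cbind(start = off, end = off + L))
        genome$seqs[[ch]] <- plant_motif(genome$seqs[[ch]],
                                         peaks$start[i] + off, m,
                                         config$mutation_rate)
      }
    }
  }
  list(peaks = peaks, truth = truth, genome = genome)
}

#' Generate up/down modulated gene lists with planted coupling
#'
#' Each gene's modulation probability depends on the fold enrichment of its
#' best (strongest) associated peak: `boosted_rate` at or above the planted
#' change-point `t0`, `base_rate` below (genes without any peak use the
#' base rate).  Modulated genes split into up/down at the configured
#' weight.
#'
#' @param config a [synthetic_config()].
#' @param associations output of [associate_closest_tss()] on the truth
#'   peaks.
#' @return an [expression_set()] with `universe_size = config$n_genes`.
#' @export
generate_expression <- function(config, associations) {
  set.seed(child_seed(config, "expression"))
  best <- tapply(associations$fold_enrichment, associations$gene_id, max)
  all_genes <- sprintf("g%06d", seq_len(config$n_genes))
  best_fe <- stats::setNames(rep(0, config$n_genes), all_genes)
  best_fe[names(best)] <- best
  rate <- ifelse(best_fe >= config$coupling$t0,
                 config$coupling$boosted_rate, config$coupling$base_rate)
  modulated <- all_genes[runif(config$n_genes) < rate]
  up <- modulated[runif(length(modulated)) < config$up_weight]
  expression_set(up = up, down = setdiff(modulated, up),
                 universe_size = config$n_genes)
}

random_peaks <- function(prefix, n, sizes, width_range, avoid = NULL,
                         max_try = 100) {
  draw <- function(m) {
    ci <- sample.int(nrow(sizes), m, replace = TRUE, prob = sizes$length)
    w <- as.integer(round(runif(m, width_range[1], width_range[2])))
    s <- as.integer(floor(runif(m, 0, sizes$length[ci] - w)))
    data.frame(chrom = sizes$chrom[ci], start = s, end = s + w,
               stringsAsFactors = FALSE)
  }
  res <- draw(n)
  if (!is.null(avoid) && n > 0) {
    for (try in seq_len(max_try)) {
      bad <- which(any_overlap_flags(res, avoid))
      if (!length(bad)) break
      res[bad, ] <- draw(length(bad))
    }
  }
  if (n > 0) res$name <- sprintf("%s%05d", prefix, seq_len(n))
  else res$name <- character(0)
  res
}

#' Generate two companion peak sets with planted overlap fractions
#'
#' Each primary peak is copied (jittered by at most 50 bp) into companion
#' set B with probability `p_AB`, into C with `p_AC`, and into both jointly
#' with `p_ABC`.  Companions are padded to their target sizes with private
#' peaks placed away from the primary set.
#'
#' @param config a [synthetic_config()].
#' @param peaks primary peak data.frame.
#' @return list with `B` and `C` (narrowPeak-layout data.frames) and
#'   `truth` (data.frame `name`, `in_B`, `in_C`).
#' @export
generate_companion_sets <- function(config, peaks) {
  set.seed(child_seed(config, "companions"))
  n <- nrow(peaks)
  p <- config$overlap
  u <- runif(n)
  in_both <- u < p$p_ABC
  in_B <- in_both | (u >= p$p_ABC & u < p$p_AB)
  in_C <- in_both | (u >= p$p_AB & u < p$p_AB + (p$p_AC - p$p_ABC))
  sizes <- data.frame(chrom = unique(peaks$chrom),
                      length = as.integer(config$chrom_length))
  jitter_copy <- function(sel, prefix) {
    d <- peaks[sel, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(d)) {
      j <- as.integer(round(runif(nrow(d), -50, 50)))
      d$start <- pmax(0L, d$start + j)
      d$end <- d$end + j
      d$name <- sprintf("%s_sh%05d", prefix, seq_len(nrow(d)))
    } else d$name <- character(0)
    d
  }
  finish <- function(shared, n_target, prefix) {
    n_priv <- max(0L, n_target - nrow(shared))
    priv <- random_peaks(paste0(prefix, "_pv"), n_priv, sizes,
                         config$peak_width_range,
                         avoid = peaks[, c("chrom", "start", "end")])
    d <- rbind(shared[, c("chrom", "start", "end", "name")],
               priv[, c("chrom", "start", "end", "name")])
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    rownames(d) <- NULL
    nn <- nrow(d)
    d$score <- 100L
    d$strand <- "."
    d$fold_enrichment <- round(stats::rlnorm(nn, 1.5, 0.4), 4)
    d$neglog10_q <- round(1 + stats::rexp(nn, 1 / 3), 4)
    d$neglog10_p <- round(d$neglog10_q + runif(nn, 0, 2), 4)
    d$summit_offset <- (d$end - d$start) %/% 2L
    d[, c("chrom", "start", "end", "name", "score", "strand",
          "fold_enrichment", "neglog10_p", "neglog10_q", "summit_offset")]
  }
  B <- finish(jitter_copy(in_B, "B"), config$companion_sizes[["B"]], "B")
  C <- finish(jitter_copy(in_C, "C"), config$companion_sizes[["C"]], "C")
  list(B = B, C = C,
       truth = data.frame(name = peaks$name, in_B = in_B, in_C = in_C,
                          stringsAsFactors = FALSE))
}

#' Generate a chromatin-state segmentation with planted bias
#'
#' The genome is tiled with a Quies background; regions around shared peaks
#' are relabeled TssAFlnk or Enh with probability `state_bias$shared`, and
#' regions around specific peaks leave Quies (for a random other state)
#' with probability `1 - state_bias$specific`.  Segments are
#' non-overlapping within each chromosome.
#'
#' @param config a [synthetic_config()].
#' @param peaks primary peak data.frame.
#' @param shared logical vector: is each primary peak shared with the
#'   reference companion set.
#' @return chromatin-state data.frame (`chrom`, `start`, `end`, `state`).
#' @export
generate_states <- function(config, peaks, shared) {
  stopifnot(length(shared) == nrow(peaks))
  set.seed(child_seed(config, "states"))
  other_states <- setdiff(CHROMATIN_STATES, c("Quies", "TssAFlnk", "Enh"))
  lab <- rep("Quies", nrow(peaks))
  u <- runif(nrow(peaks))
  lab[shared & u < config$state_bias$shared] <-
    sample(c("TssAFlnk", "Enh"), sum(shared & u < config$state_bias$shared),
           replace = TRUE)
  flip <- !shared & u < (1 - config$state_bias$specific)
  lab[flip] <- sample(other_states, sum(flip), replace = TRUE)
  segs <- list()
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    idx <- idx[order(peaks$start[idx])]
    pos <- 0L
    chunks <- list()
    for (i in idx) {
      s <- max(pos, peaks$start[i] - 100L)
      e <- min(config$chrom_length, peaks$end[i] + 100L)
      if (s >= e || s < pos) next
      if (s > pos)
        chunks[[length(chunks) + 1L]] <-
          data.frame(chrom = ch, start = pos, end = s, state = "Quies")
      chunks[[length(chunks) + 1L]] <-
        data.frame(chrom = ch, start = s, end = e, state = lab[i])
      pos <- e
    }
    if (pos < config$chrom_length)
      chunks[[length(chunks) + 1L]] <-
        data.frame(chrom = ch, start = pos,
                   end = as.integer(config$chrom_length), state = "Quies")
    segs[[ch]] <- do.call(rbind, chunks)
  }
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  res$start <- as.integer(res$start); res$end <- as.integer(res$end)
  res
}

#' Generate a small random blacklist
#' @param config a [synthetic_config()].
#' @param genome output of [generate_genome()] (sizes used).
#' @return interval data.frame.
#' @export
generate_blacklist <- function(config, genome) {
  set.seed(child_seed(config, "blacklist"))
  bl <- random_peaks("bl", config$n_blacklist, genome$sizes, c(500, 2000))
  bl[, c("chrom", "start", "end", "name")]
}

#' Extract peak sequences from the genome
#' @param genome output of [generate_genome()] with sequence.
#' @param peaks peak data.frame.
#' @return named character vector (names = peak names).
#' @export
extract_peak_sequences <- function(genome, peaks) {
  if (is.null(genome$seqs)) stop("genome was generated without sequence")
  stats::setNames(
    substring(genome$seqs[peaks$chrom], peaks$start + 1L, peaks$end),
    peaks$name)
}

#' Materialize a complete synthetic workspace on disk
#'
#' Runs every generator stage and writes all pipeline inputs (genome FASTA
#' and sizes, gene table, primary and companion narrowPeak files, blacklist
#' BED, chromatin-state BED, modulated gene list, peak-sequence FASTA, PWM
#' library) plus the hidden truth tables, into `dir`.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return named list of the written file paths, invisibly; also returns
#'   the in-memory objects in `$objects`.
#' @export
generate_workspace <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  genes <- generate_genes(config, genome)
  pk <- generate_peaks(config, genome)
  genome <- pk$genome
  assoc <- associate_closest_tss(pk$peaks, genes)
  expr <- generate_expression(config, assoc)
  comp <- generate_companion_sets(config, pk$peaks)
  states <- generate_states(config, pk$peaks, comp$truth$in_B)
  blacklist <- generate_blacklist(config, genome)
  seqs <- extract_peak_sequences(genome, pk$peaks)
  paths <- list(
    genome_fasta = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    genes = file.path(dir, "genes.tsv"),
    peaks = file.path(dir, "peaks.narrowPeak"),
    peaks_b = file.path(dir, "peaks_B.narrowPeak"),
    peaks_c = file.path(dir, "peaks_C.narrowPeak"),
    blacklist = file.path(dir, "blacklist.bed"),
    states = file.path(dir, "states.bed"),
    gene_list = file.path(dir, "modulated_genes.tsv"),
    peak_seqs = file.path(dir, "peak_seqs.fa"),
    pwms = file.path(dir, "pwms.txt"),
    truth_peaks = file.path(dir, "truth_peaks.tsv"),
    truth_overlap = file.path(dir, "truth_overlap.tsv"))
  write_fasta(genome$seqs, paths$genome_fasta)
  write_tsv_report(genome$sizes, paths$chrom_sizes)
  write_tsv_report(genes[, c("gene_id", "chrom", "strand", "start", "end",
                             "exon_starts", "exon_ends")], paths$genes)
  write_narrowpeak(pk$peaks, paths$peaks)
  write_narrowpeak(comp$B, paths$peaks_b)
  write_narrowpeak(comp$C, paths$peaks_c)
  utils::write.table(blacklist, paths$blacklist, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(states, paths$states, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_report(
    data.frame(gene_id = c(expr$up, expr$down),
               direction = rep(c("up", "down"),
                               c(length(expr$up), length(expr$down)))),
    paths$gene_list)
  write_fasta(seqs, paths$peak_seqs)
  write_pwm_text(bundled_pwms(), paths$pwms)
  write_tsv_report(pk$truth, paths$truth_peaks)
  write_tsv_report(comp$truth, paths$truth_overlap)
  paths$objects <- list(genome = genome, genes = genes, peaks = pk$peaks,
                        truth = pk$truth, associations = assoc,
                        expression = expr, companions = comp,
                        states = states, blacklist = blacklist)
  invisible(paths)
}
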