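# QC filtering of raw peak calls, closest-TSS association, genomic-category
# annotation and the TSS distance profile.

#' The genomic annotation categories
#' @format character vector: EXON, INTRON, PROXIMAL (<= 2 kb upstream of the
#'   TSS), DISTAL (2-10 kb upstream), FIVE_D (10-100 kb upstream), OTHER.
#' @export
ANNOTATION_CATEGORIES <- c("EXON", "INTRON", "PROXIMAL", "DISTAL",
                           "FIVE_D", "OTHER")

#' Quality-filter raw peak calls
#'
#' Discards peaks with fold enrichment strictly above `fe_cap` (extreme
#' enrichments are typical caller artifacts), q-value above `q_max`
#' (equivalently `-log10 q` below `-log10(q_max)`), or at least one shared
#' base pair with a blacklisted region.  Each rejected peak is logged with a
#' single reason, assessed in that order.
#'
#' @param peaks peak data.frame from [parse_narrowpeak()].
#' @param blacklist data.frame of blacklist intervals (may be `NULL` or
#'   empty).
#' @param fe_cap maximal retained fold enrichment (boundary retained:
#'   "above" is strict).
#' @param q_max maximal retained q-value.
#' @return list with `retained` (peak data.frame), `rejected` (data.frame of
#'   `name`, `reason`), and `counts` (named integer vector over the reasons
#'   `fe_cap`, `q_value`, `blacklist`).
#' @export
filter_peaks <- function(peaks, blacklist = NULL, fe_cap = 50, q_max = 0.1) {
  reason <- rep(NA_character_, nrow(peaks))
  reason[peaks$fold_enrichment > fe_cap] <- "fe_cap"
  too_weak <- peaks$neglog10_q < -log10(q_max) - 1e-9
  reason[is.na(reason) & too_weak] <- "q_value"
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    hit <- any_overlap_flags(peaks, blacklist)
    reason[is.na(reason) & hit] <- "blacklist"
  }
  keep <- is.na(reason)
  counts <- c(fe_cap = sum(reason == "fe_cap", na.rm = TRUE),
              q_value = sum(reason == "q_value", na.rm = TRUE),
              blacklist = sum(reason == "blacklist", na.rm = TRUE))
  list(retained = peaks[keep, , drop = FALSE],
       rejected = data.frame(name = peaks$name[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE),
       counts = counts)
}

#' Associate each peak to the gene with the closest TSS
#'
#' Distance is the unstranded absolute distance between the peak's effective
#' summit (reported summit, or interval midpoint when unknown) and the gene
#' TSS.  Equidistant ties go to the lexicographically smallest `gene_id`, so
#' the result is independent of input ordering.  `signed_distance` is
#' negative when the summit lies upstream of the TSS relative to the gene's
#' strand, positive downstream.  Peaks on chromosomes without any gene are
#' returned unassigned (`NA` gene and distances).
#'
#' @param peaks peak data.frame.
#' @param genes gene data.frame from [parse_gene_table()].
#' @return data.frame with one row per peak: `peak_name`, `chrom`, `summit`,
#'   `fold_enrichment`, `gene_id`, `distance`, `signed_distance`,
#'   `unassigned`.
#' @export
associate_closest_tss <- function(peaks, genes) {
  if (is.null(genes) || nrow(genes) == 0L)
    stop("associate_closest_tss: empty gene set")
  summit <- effective_summit(peaks)
  res <- data.frame(peak_name = peaks$name,
                    chrom = peaks$chrom,
                    summit = summit,
                    fold_enrichment = peaks$fold_enrichment,
                    gene_id = NA_character_,
                    distance = NA_integer_,
                    signed_distance = NA_integer_,
                    stringsAsFactors = FALSE)
  strand_by_gene <- stats::setNames(genes$strand, genes$gene_id)
  tss_by_gene <- stats::setNames(genes$tss, genes$gene_id)
  for (chr in unique(peaks$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    pidx <- which(peaks$chrom == chr)
    if (nrow(g) == 0L) next
    # collapse genes sharing a TSS to the smallest gene_id up front so the
    # tie rule is already resolved within each position
    ord <- order(g$tss, g$gene_id)
    g <- g[ord, , drop = FALSE]
    utss <- unique(g$tss)
    first_gene <- g$gene_id[match(utss, g$tss)]
    for (i in pidx) {
      s <- summit[i]
      j <- findInterval(s, utss)
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(utss)))
      d <- abs(utss[cand] - s)
      best <- cand[d == min(d)]
      gene <- min(first_gene[best])          # lexicographic tie-break
      res$gene_id[i] <- gene
      res$distance[i] <- abs(s - tss_by_gene[[gene]])
      sd <- s - tss_by_gene[[gene]]
      if (strand_by_gene[[gene]] == "-") sd <- -sd
      res$signed_distance[i] <- sd
    }
  }
  res$unassigned <- is.na(res$gene_id)
  res
}

#' Genomic-category annotation of peaks
#'
#' Assigns exactly one category per peak, by precedence: if the effective
#' summit lies inside any gene's span, the peak is genic — `EXON` when the
#' summit falls in an exon of a covering gene, else `INTRON`.  Otherwise the
#' closest-TSS association decides, for summits upstream of the TSS
#' (strand-aware): `PROXIMAL` within 2 kb, `DISTAL` within 10 kb, `FIVE_D`
#' within 100 kb.  Everything else — further upstream, downstream of the
#' gene, or unassigned — is `OTHER`.
#'
#' @param peaks peak data.frame.
#' @param genes gene data.frame.
#' @param associations output of [associate_closest_tss()] for these peaks.
#' @return character vector of categories, one per peak.
#' @export
annotate_category <- function(peaks, genes, associations) {
  stopifnot(identical(peaks$name, associations$peak_name))
  summit <- effective_summit(peaks)
  pts <- data.frame(chrom = peaks$chrom, start = summit, end = summit + 1L)
  spans <- data.frame(chrom = genes$chrom, start = genes$start,
                      end = genes$end)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(pts), as_granges0(spans)))
  cat <- rep(NA_character_, nrow(peaks))
  if (length(ov)) {
    exons <- exon_list(genes)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (i in unique(qh)) {
      gs <- sh[qh == i]
      in_exon <- any(vapply(gs, function(gi) {
        ex <- exons[[gi]]
        nrow(ex) > 0 && any(summit[i] >= ex[, "start"] & summit[i] < ex[, "end"])
      }, logical(1)))
      cat[i] <- if (in_exon) "EXON" else "INTRON"
    }
  }
  inter <- which(is.na(cat))
  sd <- associations$signed_distance[inter]
  d <- associations$distance[inter]
  upstream <- !is.na(sd) & sd < 0
  cat[inter] <- ifelse(!upstream, "OTHER",
                ifelse(d <= 2000, "PROXIMAL",
                ifelse(d <= 10000, "DISTAL",
                ifelse(d <= 100000, "FIVE_D", "OTHER"))))
  cat
}

#' Binned profile of peak summits around the TSS
#'
#' Counts associations whose signed summit-to-TSS distance falls in
#' `[-window, window)` into consecutive bins of width `bin`
#' (`floor(signed_distance / bin)`), the histogram behind a +/- 10 kb
#' TSS-flanking profile.
#'
#' @param associations output of [associate_closest_tss()].
#' @param window half-width of the profile in bp.
#' @param bin bin width in bp; must divide `window`.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
tss_distance_profile <- function(associations, window = 10000, bin = 1000) {
  if (window %% bin != 0)
    stop("tss_distance_profile: window must be divisible by bin")
  sd <- associations$signed_distance
  sd <- sd[!is.na(sd) & sd >= -window & sd < window]
  starts <- seq(-window, window - bin, by = bin)
  idx <- floor(sd / bin) - (-window %/% bin) + 1L
  count <- tabulate(idx, nbins = length(starts))
  data.frame(bin_start = starts, bin_end = starts + bin, count = count)
}

#' Flag expression-correlated peaks
#'
#' A peak is expression-correlated iff its closest gene belongs to the
#' modulated (differentially expressed) gene set.
#'
#' @param associations output of [associate_closest_tss()].
#' @param expr expression modulation set from [expression_set()].
#' @return logical vector, one flag per association row.
#' @export
flag_expression_correlated <- function(associations, expr) {
  !is.na(associations$gene_id) & associations$gene_id %in% expr$modulated
}
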