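# Readers and writers for the on-disk formats the pipeline touches.
# All of them are strict: a malformed record stops with an error naming the
# offending line instead of being silently coerced.

#' The 15 coreMarks chromatin-state labels
#' @format character vector of the fixed state vocabulary.
#' @export
CHROMATIN_STATES <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG",
                      "Enh", "ZNF/Rpts", "Het", "TssBiv", "BivFlnk",
                      "EnhBiv", "ReprPC", "ReprPCWk", "Quies")

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

num_field <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop("parse error in ", path, " line ", lineno[bad[1]],
         ": non-numeric ", what, " '", x[bad[1]], "'")
  v
}

check_ncol <- function(fields, n, lineno, path, fmt) {
  lens <- lengths(fields)
  bad <- which(lens != n)
  if (length(bad))
    stop("parse error in ", path, " line ", lineno[bad[1]], ": expected ", n,
         " tab-separated ", fmt, " columns, found ", lens[bad[1]])
}

#' Read ENCODE narrowPeak (BED6+4) peak calls
#'
#' Parses the 10-column narrowPeak format emitted by MACS-style peak callers:
#' chrom, start, end, name, score, strand, signalValue (fold enrichment over
#' control), -log10 p-value, -log10 q-value, and summit offset relative to
#' `start` (the sentinel -1 means the summit is unknown and maps to `NA`).
#' Coordinates are 0-based half-open. Input order is preserved.
#'
#' @param path path to a narrowPeak file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `fold_enrichment`, `neglog10_p`, `neglog10_q`, `summit_offset`.
#' @seealso [write_narrowpeak()]
#' @export
parse_narrowpeak <- function(path) {
  d <- read_data_lines(path)
  f <- split_fields(d$lines)
  check_ncol(f, 10L, d$lineno, path, "narrowPeak")
  m <- do.call(rbind, f)
  start <- num_field(m[, 2], d$lineno, path, "start")
  end   <- num_field(m[, 3], d$lineno, path, "end")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("parse error in ", path, " line ", d$lineno[bad[1]],
         ": invalid interval (need 0 <= start < end)")
  fe <- num_field(m[, 7], d$lineno, path, "fold enrichment")
  bad <- which(fe <= 0)
  if (length(bad))
    stop("parse error in ", path, " line ", d$lineno[bad[1]],
         ": fold enrichment must be > 0")
  summit <- as.integer(num_field(m[, 10], d$lineno, path, "summit offset"))
  summit[summit < 0L] <- NA_integer_
  bad <- which(!is.na(summit) & summit >= end - start)
  if (length(bad))
    stop("parse error in ", path, " line ", d$lineno[bad[1]],
         ": summit offset outside the peak")
  peaks <- data.frame(
    chrom = m[, 1], start = as.integer(start), end = as.integer(end),
    name = m[, 4],
    score = num_field(m[, 5], d$lineno, path, "score"),
    strand = m[, 6],
    fold_enrichment = fe,
    neglog10_p = num_field(m[, 8], d$lineno, path, "-log10 p"),
    neglog10_q = num_field(m[, 9], d$lineno, path, "-log10 q"),
    summit_offset = summit,
    stringsAsFactors = FALSE)
  if (anyDuplicated(peaks$name))
    stop("parse error in ", path, ": duplicated peak name '",
         peaks$name[anyDuplicated(peaks$name)], "'")
  validate_intervals(peaks, paste0("narrowPeak ", path))
}

#' Write peaks as narrowPeak
#'
#' Inverse of [parse_narrowpeak()]: a written file re-parses to identical
#' values. Unknown summits are written as the -1 sentinel.
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  summit <- peaks$summit_offset
  summit[is.na(summit)] <- -1L
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$name,
                 peaks$score, peaks$strand,
                 format(peaks$fold_enrichment, trim = TRUE, digits = 15),
                 format(peaks$neglog10_p, trim = TRUE, digits = 15),
                 format(peaks$neglog10_q, trim = TRUE, digits = 15),
                 summit, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read BED3 intervals (blacklists) or BED4 labeled segments
#'
#' Three-column BED gives plain intervals (e.g. artifact blacklists).  A
#' fourth column is kept as `name`; with `states = TRUE` it is validated
#' against the fixed 15-label chromatin-state vocabulary (coreMarks labels,
#' optionally prefixed with a state number as in Roadmap files, e.g.
#' "15_Quies").
#'
#' @param path path to a BED3/BED4 file.
#' @param states validate the 4th column as a coreMarks state label.
#' @return data.frame with `chrom`, `start`, `end` and, when present, `name`
#'   (aliased to `state` when `states = TRUE`).
#' @export
parse_bed <- function(path, states = FALSE) {
  d <- read_data_lines(path)
  f <- split_fields(d$lines)
  lens <- lengths(f)
  if (any(lens < 3L))
    stop("parse error in ", path, " line ", d$lineno[which(lens < 3L)[1]],
         ": expected >= 3 tab-separated BED columns")
  ncol <- min(lens)
  m <- do.call(rbind, lapply(f, `[`, seq_len(ncol)))
  start <- num_field(m[, 2], d$lineno, path, "start")
  end <- num_field(m[, 3], d$lineno, path, "end")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("parse error in ", path, " line ", d$lineno[bad[1]],
         ": invalid interval (need 0 <= start < end)")
  out <- data.frame(chrom = m[, 1], start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (ncol >= 4L) {
    nm <- m[, 4]
    if (states) {
      nm <- sub("^[0-9]+_", "", nm)
      bad <- which(!nm %in% CHROMATIN_STATES)
      if (length(bad))
        stop("parse error in ", path, " line ", d$lineno[bad[1]],
             ": unknown chromatin state '", nm[bad[1]], "'")
      out$state <- nm
    } else out$name <- nm
  } else if (states) {
    stop("parse error in ", path, ": chromatin-state BED needs a 4th column")
  }
  validate_intervals(out, paste0("BED ", path))
}

#' Read gene models from BED12 or a gene TSV
#'
#' Two layouts are accepted.  BED12: standard 12-column gene models whose
#' blocks become exons.  TSV: a headered table with columns `gene_id`,
#' `chrom`, `strand`, `start`, `end` and optional comma-separated
#' `exon_starts`/`exon_ends` (absolute 0-based half-open coordinates).
#' The TSS is derived from strand: `start` for "+" genes, `end - 1` for "-"
#' genes (the last covered base of the span).
#'
#' @param path path to the gene file.
#' @param format `"auto"` (sniff: a header containing `gene_id` means TSV),
#'   `"bed12"` or `"tsv"`.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `exon_starts`, `exon_ends` (the last two comma-joined
#'   strings, possibly empty).
#' @export
parse_gene_table <- function(path, format = c("auto", "bed12", "tsv")) {
  format <- match.arg(format)
  d <- read_data_lines(path)
  if (!length(d$lines)) stop("parse error in ", path, ": no gene records")
  if (format == "auto")
    format <- if (grepl("gene_id", d$lines[1])) "tsv" else "bed12"
  if (format == "bed12") {
    f <- split_fields(d$lines)
    check_ncol(f, 12L, d$lineno, path, "BED12")
    m <- do.call(rbind, f)
    start <- as.integer(num_field(m[, 2], d$lineno, path, "start"))
    end <- as.integer(num_field(m[, 3], d$lineno, path, "end"))
    strand <- m[, 6]
    sizes <- strsplit(sub(",$", "", m[, 11]), ",", fixed = TRUE)
    offs <- strsplit(sub(",$", "", m[, 12]), ",", fixed = TRUE)
    exon_starts <- exon_ends <- character(length(start))
    for (i in seq_along(start)) {
      bs <- start[i] + as.integer(offs[[i]])
      be <- bs + as.integer(sizes[[i]])
      if (anyNA(bs) || anyNA(be) || any(bs < start[i]) || any(be > end[i]))
        stop("parse error in ", path, " line ", d$lineno[i],
             ": exon blocks outside the gene span")
      exon_starts[i] <- paste(bs, collapse = ",")
      exon_ends[i] <- paste(be, collapse = ",")
    }
    genes <- data.frame(gene_id = m[, 4], chrom = m[, 1], strand = strand,
                        start = start, end = end,
                        exon_starts = exon_starts, exon_ends = exon_ends,
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    if (!all(need %in% names(tab)))
      stop("parse error in ", path, ": gene TSV needs columns ",
           paste(need, collapse = ", "))
    genes <- tab[, need]
    genes$exon_starts <- if ("exon_starts" %in% names(tab))
      as.character(tab$exon_starts) else ""
    genes$exon_ends <- if ("exon_ends" %in% names(tab))
      as.character(tab$exon_ends) else ""
    genes$exon_starts[is.na(genes$exon_starts)] <- ""
    genes$exon_ends[is.na(genes$exon_ends)] <- ""
  }
  if (!all(genes$strand %in% c("+", "-")))
    stop("parse error in ", path, ": gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id))
    stop("parse error in ", path, ": duplicated gene_id")
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  validate_intervals(genes, paste0("gene table ", path))
  genes[, c("gene_id", "chrom", "strand", "start", "end", "tss",
            "exon_starts", "exon_ends")]
}

#' Read an up/down modulated-gene list
#'
#' A headered TSV with columns `gene_id` and `direction` ("up" or "down"),
#' e.g. differentially expressed genes from a companion expression study.
#'
#' @param path path to the TSV.
#' @return data.frame with `gene_id` and `direction`.
#' @seealso [expression_set()]
#' @export
parse_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction") %in% names(tab)))
    stop("parse error in ", path,
         ": gene list needs columns gene_id, direction")
  if (!all(tab$direction %in% c("up", "down")))
    stop("parse error in ", path, ": direction must be 'up' or 'down'")
  if (anyDuplicated(tab$gene_id))
    stop("parse error in ", path, ": duplicated gene_id")
  tab[, c("gene_id", "direction")]
}

#' Read a FASTA file as a named character vector
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)),
                  sub("\\s.*$", "", names(ss)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a TSV report table
#'
#' Plain tab-separated output with a header, no quoting and no row names —
#' the layout every stage of the pipeline uses for its tables, re-readable
#' with [utils::read.delim()].
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

exon_list <- function(genes) {
  Map(function(s, e) {
    if (!nzchar(s)) return(cbind(start = integer(0), end = integer(0)))
    cbind(start = as.integer(strsplit(s, ",")[[1]]),
          end = as.integer(strsplit(e, ",")[[1]]))
  }, genes$exon_starts, genes$exon_ends)
}
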