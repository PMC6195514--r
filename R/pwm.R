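# Position weight matrices and log-odds scanning.  Scoring semantics are
# fixed package-wide: background uniform 0.25 for A/C/G/T, pseudocount 0.01
# on probabilities, N scores log(0.25/0.25) = 0, and a hit is any window
# (either strand) reaching a configurable fraction of the matrix's maximal
# achievable score.

MOTIF_FAMILIES <- c("ETS", "RUNX", "IRF", "ETS_IRF_COMPOUND", "OTHER")
PWM_PSEUDOCOUNT <- 0.01

new_pwm <- function(id, family, probs) {
  family <- match.arg(family, MOTIF_FAMILIES)
  probs <- as.matrix(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  if (nrow(probs) < 4L) stop("PWM '", id, "': length must be >= 4")
  probs <- (probs + PWM_PSEUDOCOUNT) / (1 + 4 * PWM_PSEUDOCOUNT)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("PWM '", id, "': position probabilities must sum to 1")
  structure(list(id = id, family = family, probs = probs), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(", x$family, "), length", nrow(x$probs),
      ", consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm a PWM object.
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm$probs)[max.col(pwm$probs, ties.method = "first")],
        collapse = "")
}

#' Build a PWM from a consensus sequence
#'
#' Each position gives probability `match_prob` (before pseudocount) to the
#' consensus base and splits the remainder over the other three — a sharp
#' matrix whose hits at the default scan threshold are essentially exact
#' consensus matches.
#'
#' @param consensus string over A/C/G/T.
#' @param id,family motif name and family label.
#' @param match_prob pre-pseudocount probability of the consensus base.
#' @return a PWM object.
#' @export
consensus_pwm <- function(consensus, id, family, match_prob = 0.97) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("consensus must be over A/C/G/T")
  probs <- matrix((1 - match_prob) / 3, nrow = length(bases), ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <-
    match_prob
  new_pwm(id, family, probs)
}

#' The bundled example motif library
#'
#' Sharp consensus-built matrices for the four motif families the peak
#' classification uses: an ETS site (GGAA core with flanking purines, the
#' class bound directly by ETS-domain factors such as ETV6), a RUNX site
#' (TGTGGT core, the Runt-domain class), an IRF site (GAAA repeats), and an
#' EICE-style ETS-IRF compound element (GGAA immediately fused to an IRF
#' half-site).  These stand in for motifs a discovery tool would report.
#'
#' @return named list of PWM objects.
#' @export
bundled_pwms <- function() {
  list(
    ETS_core  = consensus_pwm("ACCGGAAGTG", "ETS_core", "ETS"),
    RUNX_core = consensus_pwm("TGTGGTTTGT", "RUNX_core", "RUNX"),
    IRF_core  = consensus_pwm("GAAAGTGAAA", "IRF_core", "IRF"),
    ETS_IRF   = consensus_pwm("GGAAGTGAAAC", "ETS_IRF", "ETS_IRF_COMPOUND"))
}

#' Read a JASPAR-style PWM text library
#'
#' Records look like
#' \preformatted{>motif_id FAMILY
#' A [ 10  2  0 ... ]
#' C [  1  3  0 ... ]
#' G [  0  9 12 ... ]
#' T [  1  0  0 ... ]}
#' Counts (or probabilities) per column are normalized to probabilities and
#' the package pseudocount is applied.  The second header token is the
#' family label (one of ETS, RUNX, IRF, ETS_IRF_COMPOUND, OTHER; missing
#' means OTHER).
#'
#' @param path path to the text file.
#' @return named list of PWM objects.
#' @export
parse_pwm_text <- function(path) {
  d <- read_data_lines(path)
  hdr <- which(startsWith(d$lines, ">"))
  if (!length(hdr)) stop("parse error in ", path, ": no '>' motif headers")
  out <- list()
  for (h in seq_along(hdr)) {
    i <- hdr[h]
    last <- if (h < length(hdr)) hdr[h + 1] - 1L else length(d$lines)
    toks <- strsplit(sub("^>", "", d$lines[i]), "\\s+")[[1]]
    id <- toks[1]
    family <- if (length(toks) >= 2 && toks[2] %in% MOTIF_FAMILIES)
      toks[2] else "OTHER"
    body <- d$lines[(i + 1L):last]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4L)
      stop("parse error in ", path, " line ", d$lineno[i],
           ": motif '", id, "' needs exactly 4 base rows")
    rows <- lapply(body, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.]+(e-?[0-9]+)?", l))[[1]]
      suppressWarnings(as.numeric(nums))
    })
    base_letters <- toupper(substr(trimws(body), 1, 1))
    if (!identical(base_letters, c("A", "C", "G", "T")))
      stop("parse error in ", path, " line ", d$lineno[i],
           ": motif '", id, "' rows must be in A,C,G,T order")
    if (length(unique(lengths(rows))) != 1L || anyNA(unlist(rows)))
      stop("parse error in ", path, " line ", d$lineno[i],
           ": motif '", id, "' has ragged or non-numeric count rows")
    counts <- t(do.call(rbind, rows))          # L x 4
    tot <- rowSums(counts)
    if (any(tot <= 0))
      stop("parse error in ", path, " line ", d$lineno[i],
           ": motif '", id, "' has a zero-count column")
    out[[id]] <- new_pwm(id, family, counts / tot)
  }
  out
}

#' Write a PWM list as JASPAR-style text
#' @param pwms named list of PWM objects.
#' @param path output path.
#' @param counts_scale counts written as `round(prob * counts_scale)`.
#' @return `path`, invisibly.
#' @export
write_pwm_text <- function(pwms, path, counts_scale = 10000) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    # invert the parse-time pseudocount so that writing then re-parsing
    # reproduces the same probability matrix (up to count rounding)
    raw <- pmax(p$probs * (1 + 4 * PWM_PSEUDOCOUNT) - PWM_PSEUDOCOUNT, 0)
    writeLines(paste0(">", p$id, " ", p$family), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ",
                        paste(round(raw[, b] * counts_scale),
                              collapse = " "), " ]"), con)
  }
  invisible(path)
}

encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L   # anything non-ACGT scores as N
  codes
}

#' Reverse complement of a DNA string
#' @param seq character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", seq), "")[[1]]),
        collapse = "")
}

log_odds_matrix <- function(pwm) {
  lom <- log(pwm$probs / 0.25)
  cbind(lom, N = 0)                       # L x 5; N contributes 0
}

#' Log-odds score of one window against a PWM
#'
#' `sum_i log(p_i(base_i) / 0.25)` over the window, with any N contributing
#' zero.  Errors unless the window length equals the PWM length.
#'
#' @param window character scalar of length `nrow(pwm$probs)`.
#' @param pwm a PWM object.
#' @return numeric score (natural-log units).
#' @export
log_odds_score <- function(window, pwm) {
  L <- nrow(pwm$probs)
  if (nchar(window) != L)
    stop("window length ", nchar(window), " != PWM length ", L)
  lom <- log_odds_matrix(pwm)
  sum(lom[cbind(seq_len(L), encode_dna(window))])
}

#' Maximal achievable log-odds score of a PWM
#' @param pwm a PWM object.
#' @return numeric.
#' @export
pwm_max_score <- function(pwm) sum(log(apply(pwm$probs, 1, max) / 0.25))

scan_codes <- function(codes, lom) {
  L <- nrow(lom)
  noff <- length(codes) - L + 1L
  if (noff < 1L) return(numeric(0))
  s <- numeric(noff)
  for (j in seq_len(L))
    s <- s + lom[j, codes[j:(j + noff - 1L)]]
  s
}

#' Scan one sequence with a PWM on both strands
#'
#' Reports every offset/strand whose log-odds score reaches
#' `frac_threshold * pwm_max_score(pwm)`.  Minus-strand windows score the
#' reverse complement; their `offset` is still the 0-based position of the
#' window's leftmost base on the given (plus-strand) sequence, so scanning
#' is strand-symmetric.
#'
#' @param seq character scalar (the peak sequence).
#' @param pwm a PWM object.
#' @param frac_threshold hit threshold as a fraction of the maximal score.
#' @return data.frame with `offset`, `strand`, `score` (possibly 0 rows).
#' @export
scan_sequence <- function(seq, pwm, frac_threshold = 0.8) {
  L <- nrow(pwm$probs)
  n <- nchar(seq)
  lom <- log_odds_matrix(pwm)
  cutoff <- frac_threshold * pwm_max_score(pwm)
  fwd <- scan_codes(encode_dna(seq), lom)
  rev <- scan_codes(encode_dna(revcomp(seq)), lom)
  hit_f <- which(fwd >= cutoff)
  hit_r <- which(rev >= cutoff)
  data.frame(
    offset = c(hit_f - 1L, n - L - (hit_r - 1L)),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]),
    stringsAsFactors = FALSE)
}

#' Scan many peak sequences with a PWM library
#'
#' @param seqs named character vector of peak sequences (names = peak names).
#' @param pwms named list of PWM objects.
#' @param frac_threshold hit threshold as a fraction of each PWM's maximum.
#' @return data.frame of motif hits with `peak_name`, `pwm_id`, `family`,
#'   `offset`, `strand`, `score`.
#' @export
scan_peaks <- function(seqs, pwms, frac_threshold = 0.8) {
  out <- vector("list", length(seqs) * length(pwms))
  k <- 0L
  for (p in pwms) {
    for (i in seq_along(seqs)) {
      hits <- scan_sequence(seqs[[i]], p, frac_threshold)
      if (nrow(hits)) {
        k <- k + 1L
        hits$peak_name <- names(seqs)[i]
        hits$pwm_id <- p$id
        hits$family <- p$family
        out[[k]] <- hits
      }
    }
  }
  if (!k)
    return(data.frame(peak_name = character(0), pwm_id = character(0),
                      family = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res[, c("peak_name", "pwm_id", "family", "offset", "strand", "score")]
}
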