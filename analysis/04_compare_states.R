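#!/usr/bin/env Rscript
# Compare the threshold-selected peak set against the two companion peak
# sets (per-reference-set Venn counts) and assign every selected peak to a
# chromatin state, splitting the distribution into all / shared / specific.

suppressPackageStartupMessages(library(peakcalibre))

ws <- "results/workspace"
cal <- read.delim("results/tables/calibration.tsv")
tstar <- cal$threshold[cal$selected]
filt <- read.delim("results/tables/filtered_peaks.tsv")
sel <- filt[filt$fold_enrichment >= tstar, ]

B <- parse_narrowpeak(file.path(ws, "peaks_B.narrowPeak"))
C <- parse_narrowpeak(file.path(ws, "peaks_C.narrowPeak"))
v <- venn_counts(sel, B, C)
ab <- v$pairwise$count[v$pairwise$from == "A" & v$pairwise$to == "B"]
ac <- v$pairwise$count[v$pairwise$from == "A" & v$pairwise$to == "C"]
tri <- v$triple$count[v$triple$from == "A"]
cat(sprintf("venn (A = %d selected peaks): A&B %d (%.2f%%), A&C %d (%.2f%%), A&B&C %d (%.2f%%)\n",
            nrow(sel), ab, percent(ab, nrow(sel)),
            ac, percent(ac, nrow(sel)), tri, percent(tri, nrow(sel))))
write_tsv_report(rbind(
  data.frame(from = v$pairwise$from, to = v$pairwise$to,
             count = v$pairwise$count),
  data.frame(from = v$triple$from, to = "both_others",
             count = v$triple$count)), "results/tables/venn.tsv")

segs <- parse_bed(file.path(ws, "states.bed"), states = TRUE)
st <- assign_state(sel, segs)
shared <- any_overlap_flags(sel, B)
dist <- state_distribution(st, list(all = rep(TRUE, nrow(sel)),
                                    shared = shared, specific = !shared))
write_tsv_report(dist, "results/tables/state_distribution.tsv")
top <- function(sub) {
  d <- dist[dist$subset == sub, ]
  d <- d[order(-d$fraction), ][1:2, ]
  sprintf("%s %.0f%% / %s %.0f%%", d$state[1], 100 * d$fraction[1],
          d$state[2], 100 * d$fraction[2])
}
cat("top chromatin states, shared peaks:  ", top("shared"), "\n")
cat("top chromatin states, specific peaks:", top("specific"), "\n")
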