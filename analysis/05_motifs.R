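#!/usr/bin/env Rscript
# Scan selected peak sequences for ETS / RUNX / IRF / ETS-IRF compound
# motifs, classify peaks by ETS/RUNX content, and compute the analyses the
# classification feeds: summit-centering profiles, class composition
# against the fold-enrichment threshold grid, the pooled t-test of group
# fold enrichments, and the compound-motif content of motif-free peaks.

suppressPackageStartupMessages(library(peakcalibre))

ws <- "results/workspace"
cal <- read.delim("results/tables/calibration.tsv")
tstar <- cal$threshold[cal$selected]
filt <- read.delim("results/tables/filtered_peaks.tsv")
sel <- filt[filt$fold_enrichment >= tstar, ]
assoc <- read.delim("results/tables/associations.tsv")
assoc <- assoc[match(sel$name, assoc$peak_name), ]
gl <- parse_gene_list(file.path(ws, "modulated_genes.tsv"))
expr <- expression_set(gl$gene_id[gl$direction == "up"],
                       gl$gene_id[gl$direction == "down"], 1e6)
expr_flag <- flag_expression_correlated(assoc, expr)

seqs <- parse_fasta(file.path(ws, "peak_seqs.fa"))[sel$name]
pwms <- parse_pwm_text(file.path(ws, "pwms.txt"))
hits <- scan_peaks(seqs, pwms)
classes <- classify_peaks(sel$name, hits)
write_tsv_report(hits, "results/tables/motif_hits.tsv")
write_tsv_report(classes, "results/tables/peak_classes.tsv")
cat("motif classes among selected peaks:\n")
print(round(100 * table(classes$class) / nrow(classes), 1))

prof <- summit_centering_profile(hits, sel, pwms)
write_tsv_report(prof, "results/tables/summit_profile.tsv")
curve <- class_fraction_curve(sel, classes)
write_tsv_report(curve, "results/tables/class_fraction_curve.tsv")
lo <- curve[1, ]; hi <- curve[nrow(curve), ]
cat(sprintf("ETS-containing fraction: %.2f at FE >= %.1f -> %.2f at FE >= %.1f\n",
            lo$frac_ETS_ONLY + lo$frac_ETS_RUNX, lo$threshold,
            hi$frac_ETS_ONLY + hi$frac_ETS_RUNX, hi$threshold))

ets <- sel$fold_enrichment[classes$class %in% c("ETS_ONLY", "ETS_RUNX")]
nei <- sel$fold_enrichment[classes$class == "NEITHER"]
gt <- group_fe_test(ets, nei)
cat(sprintf("pooled t-test ETS-containing vs NEITHER: t = %.2f, p = %.3g\n",
            gt$t, gt$p))

comp <- compound_motif_report(classes, hits, expr_flag)
write_tsv_report(comp, "results/tables/compound_report.tsv")
ec <- comp[comp$expression_correlated, ]
cat(sprintf("expression-correlated NEITHER peaks: %d, of which %d carry the ETS-IRF compound\n",
            ec$n_neither, ec$n_compound))
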