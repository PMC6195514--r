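#!/usr/bin/env Rscript
# QC-filter the raw peak calls (blacklist overlap, fold-enrichment cap of
# 50, q <= 0.1) and associate every retained peak to its closest gene TSS.

suppressPackageStartupMessages(library(peakcalibre))

ws <- "results/workspace"
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

peaks <- parse_narrowpeak(file.path(ws, "peaks.narrowPeak"))
blacklist <- parse_bed(file.path(ws, "blacklist.bed"))
genes <- parse_gene_table(file.path(ws, "genes.tsv"))

filt <- filter_peaks(peaks, blacklist)
cat(sprintf("filter: %d peaks in, %d retained (%s)\n", nrow(peaks),
            nrow(filt$retained),
            paste(names(filt$counts), filt$counts, sep = "=",
                  collapse = ", ")))
write_tsv_report(filt$retained, "results/tables/filtered_peaks.tsv")
write_tsv_report(filt$rejected, "results/tables/rejections.tsv")

assoc <- associate_closest_tss(filt$retained, genes)
assoc$category <- annotate_category(filt$retained, genes, assoc)
write_tsv_report(assoc, "results/tables/associations.tsv")
cat("association categories:\n")
print(round(100 * table(assoc$category) / nrow(assoc), 1))

prof <- tss_distance_profile(assoc)
write_tsv_report(prof, "results/tables/tss_profile.tsv")
cat(sprintf("%d of %d peaks (%0.f%%) lie within +/-10 kb of a TSS\n",
            sum(prof$count), nrow(assoc),
            100 * sum(prof$count) / nrow(assoc)))
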