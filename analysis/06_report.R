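#!/usr/bin/env Rscript
# Run the packaged end-to-end pipeline on the simulated workspace and print
# the machine-readable summary it writes.  Stage drivers 02-05 and this
# orchestrated run compute the same quantities; the pipeline additionally
# verifies that the summary re-derives from the stage TSVs.

suppressPackageStartupMessages(library(peakcalibre))

s <- run_all(pipeline_config("results/workspace", "results/report"))
cat("\nsummary.json:\n")
cat(readLines("results/report/summary.json"), sep = "\n")
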