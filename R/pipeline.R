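# End-to-end orchestration: filter -> associate -> calibrate -> select ->
# annotate -> compare -> motif-classify, with a TSV/JSON report bundle and
# an auditable run log.

PIPELINE_DEFAULTS <- list(
  fe_cap = 50, q_max = 0.1,
  grid_min = 3, grid_max = 7, grid_step = 0.1,
  sidedness = "greater",
  motif_frac_threshold = 0.8,
  motif_shuffles = 0,
  profile_window = 10000, profile_bin = 1000,
  centering_window = 500, centering_bin = 50,
  seed = 1)

#' Build a pipeline configuration
#'
#' Assembles input paths and analysis parameters for [run_all()].  Paths
#' default to the file layout [generate_workspace()] writes.  `universe_size`
#' is the gene-universe size for the Fisher calibration (defaults to the
#' number of genes in the gene table).
#'
#' @param workspace directory holding the input files.
#' @param out_dir directory for the report bundle.
#' @param ... overrides for any default parameter
#'   (`fe_cap`, `q_max`, `grid_min`, `grid_max`, `grid_step`, `sidedness`,
#'   `motif_frac_threshold`, `motif_shuffles`, `profile_window`,
#'   `profile_bin`, `centering_window`, `centering_bin`, `seed`) or input
#'   path (`peaks`, `peaks_b`, `peaks_c`, `blacklist`, `genes`,
#'   `gene_list`, `states`, `peak_seqs`, `pwms`, `universe_size`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(workspace, out_dir = file.path(workspace, "out"),
                            ...) {
  cfg <- c(list(
    workspace = workspace,
    out_dir = out_dir,
    peaks = file.path(workspace, "peaks.narrowPeak"),
    peaks_b = file.path(workspace, "peaks_B.narrowPeak"),
    peaks_c = file.path(workspace, "peaks_C.narrowPeak"),
    blacklist = file.path(workspace, "blacklist.bed"),
    genes = file.path(workspace, "genes.tsv"),
    gene_list = file.path(workspace, "modulated_genes.tsv"),
    states = file.path(workspace, "states.bed"),
    peak_seqs = file.path(workspace, "peak_seqs.fa"),
    pwms = file.path(workspace, "pwms.txt"),
    universe_size = NA_integer_), PIPELINE_DEFAULTS)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$workspace)) stop("config must name a 'workspace'")
  do.call(pipeline_config,
          c(list(workspace = y$workspace),
            y[setdiff(names(y), "workspace")]))
}

#' Run the full analysis pipeline
#'
#' Executes the whole analysis in the order of the study it emulates:
#' QC-filter the peak calls (blacklist, fold-enrichment cap, q-value);
#' associate retained peaks to the closest TSS; sweep fold-enrichment
#' thresholds against the modulated-gene set and select the most enriched
#' one; restrict to peaks at or above it; annotate genomic categories and
#' the TSS distance profile; compare against the two companion peak sets
#' (per-reference-set Venn counts) and assign chromatin states for all /
#' shared / specific peaks; scan peak sequences for ETS/RUNX/IRF motifs,
#' classify peaks, and compute class-composition curves, group
#' fold-enrichment tests and the ETS-IRF compound report.  Writes one TSV
#' per stage plus `summary.json` and `run_log.txt` into `config$out_dir`,
#' then re-derives the summary counts from the written TSVs and aborts on
#' any mismatch.  Outputs are pure functions of (inputs, config, seed).
#'
#' @param config a `pipeline_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return the summary list, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  say("peakcalibre ", as.character(utils::packageVersion("peakcalibre")),
      " | seed=", config$seed,
      " | fe_cap=", config$fe_cap, " q_max=", config$q_max,
      " grid=[", config$grid_min, ",", config$grid_max, "] step=",
      config$grid_step, " motif_frac=", config$motif_frac_threshold)

  peaks <- stage("parse", parse_narrowpeak(config$peaks))
  blacklist <- stage("parse", if (file.exists(config$blacklist))
    parse_bed(config$blacklist) else NULL)
  genes <- stage("parse", parse_gene_table(config$genes))
  gl <- stage("parse", parse_gene_list(config$gene_list))
  universe <- if (is.na(config$universe_size)) nrow(genes)
              else as.integer(config$universe_size)
  expr <- stage("parse", expression_set(gl$gene_id[gl$direction == "up"],
                                        gl$gene_id[gl$direction == "down"],
                                        universe))
  if (!length(expr$modulated))
    stop("pipeline stage 'calibrate' failed: empty modulated gene list",
         call. = FALSE)

  filt <- stage("filter", filter_peaks(peaks, blacklist,
                                       config$fe_cap, config$q_max))
  say("filter: ", nrow(peaks), " in -> ", nrow(filt$retained),
      " retained (fe_cap=", filt$counts[["fe_cap"]],
      ", q_value=", filt$counts[["q_value"]],
      ", blacklist=", filt$counts[["blacklist"]], ")")
  write_tsv_report(filt$retained, file.path(out, "filtered_peaks.tsv"))
  write_tsv_report(filt$rejected, file.path(out, "rejections.tsv"))

  check_chrom_names(filt$retained, genes, c("peaks", "genes"))
  assoc <- stage("associate", associate_closest_tss(filt$retained, genes))
  say("associate: ", sum(!assoc$unassigned), " peaks assigned, ",
      sum(assoc$unassigned), " unassigned")

  grid <- fe_grid(config$grid_min, config$grid_max, config$grid_step)
  cal <- stage("calibrate", sweep_thresholds(assoc, expr, grid,
                                             alternative = config$sidedness))
  tstar <- cal$selected_threshold
  say("calibrate: selected threshold ", tstar, " (min Fisher p = ",
      format(min(cal$rows$fisher_p)), ")")
  write_tsv_report(cal$rows, file.path(out, "calibration.tsv"))

  sel <- filt$retained[filt$retained$fold_enrichment >= tstar, , drop = FALSE]
  assoc_sel <- assoc[match(sel$name, assoc$peak_name), , drop = FALSE]
  expr_flag <- flag_expression_correlated(assoc_sel, expr)
  categ <- stage("annotate", annotate_category(sel, genes, assoc_sel))
  assoc_out <- cbind(assoc_sel,
                     category = categ, expression_correlated = expr_flag)
  write_tsv_report(assoc_out, file.path(out, "selected_peaks.tsv"))
  profile <- stage("annotate",
                   tss_distance_profile(assoc_sel, config$profile_window,
                                        config$profile_bin))
  write_tsv_report(profile, file.path(out, "tss_profile.tsv"))
  say("annotate: ", nrow(sel), " peaks at FE >= ", tstar, "; ",
      sum(expr_flag), " expression-correlated")

  B <- stage("compare", parse_narrowpeak(config$peaks_b))
  C <- stage("compare", parse_narrowpeak(config$peaks_c))
  vn <- stage("compare", venn_counts(sel, B, C, names = c("A", "B", "C")))
  venn_tab <- rbind(
    data.frame(from = names(vn$sizes), to = "", count = vn$sizes),
    data.frame(from = vn$pairwise$from, to = vn$pairwise$to,
               count = vn$pairwise$count),
    data.frame(from = vn$triple$from, to = "both_others",
               count = vn$triple$count))
  write_tsv_report(venn_tab, file.path(out, "venn.tsv"))
  shared <- any_overlap_flags(sel, B)
  say("compare: |A|=", nrow(sel), " shared-with-B=", sum(shared))

  segs <- stage("states", parse_bed(config$states, states = TRUE))
  st <- stage("states", assign_state(sel, segs))
  write_tsv_report(data.frame(peak_name = sel$name, state = st,
                              shared_with_B = shared),
                   file.path(out, "peak_states.tsv"))
  dist <- stage("states", state_distribution(
    st, list(all = rep(TRUE, length(st)), shared = shared,
             specific = !shared)))
  write_tsv_report(dist, file.path(out, "state_distribution.tsv"))

  seqs <- stage("motifs", parse_fasta(config$peak_seqs))
  missing <- setdiff(sel$name, names(seqs))
  if (length(missing))
    stop("pipeline stage 'motifs' failed: no sequence for peak ",
         missing[1], call. = FALSE)
  seqs <- seqs[sel$name]
  pwms <- stage("motifs", if (!is.null(config$pwms) &&
                                file.exists(config$pwms))
    parse_pwm_text(config$pwms) else bundled_pwms())
  hits <- stage("motifs", scan_peaks(seqs, pwms,
                                     config$motif_frac_threshold))
  write_tsv_report(hits, file.path(out, "motif_hits.tsv"))
  classes <- stage("motifs", classify_peaks(sel$name, hits))
  write_tsv_report(classes, file.path(out, "peak_classes.tsv"))
  curve <- stage("motifs", class_fraction_curve(sel, classes, grid))
  write_tsv_report(curve, file.path(out, "class_fraction_curve.tsv"))
  prof <- stage("motifs",
                summit_centering_profile(hits, sel, pwms,
                                         config$centering_window,
                                         config$centering_bin))
  write_tsv_report(prof, file.path(out, "summit_profile.tsv"))

  cls <- classes$class
  ets_fe <- sel$fold_enrichment[cls %in% c("ETS_ONLY", "ETS_RUNX")]
  nei_fe <- sel$fold_enrichment[cls == "NEITHER"]
  gt <- if (length(ets_fe) >= 2 && length(nei_fe) >= 2)
    stage("motifs", group_fe_test(ets_fe, nei_fe)) else NULL
  if (!is.null(gt))
    write_tsv_report(
      data.frame(comparison = "ETS_containing_vs_NEITHER",
                 t = gt$t, df = gt$df, p = gt$p,
                 mean_a = gt$mean_a, mean_b = gt$mean_b),
      file.path(out, "group_tests.tsv"))
  comp_rep <- stage("motifs",
                    compound_motif_report(classes, hits, expr_flag))
  write_tsv_report(comp_rep, file.path(out, "compound_report.tsv"))
  if (config$motif_shuffles > 0) {
    enr <- stage("motifs",
                 motif_enrichment_report(seqs, pwms,
                                         config$motif_frac_threshold,
                                         config$motif_shuffles,
                                         seed = config$seed))
    write_tsv_report(enr, file.path(out, "motif_enrichment.tsv"))
  }
  say("motifs: classes ",
      paste(names(table(cls)), as.integer(table(cls)),
            sep = "=", collapse = " "))

  sel_row <- cal$rows[cal$rows$selected, ]
  summary <- list(
    n_input_peaks = nrow(peaks),
    n_retained = nrow(filt$retained),
    rejections = as.list(filt$counts),
    selected_threshold = tstar,
    n_selected_peaks = nrow(sel),
    n_genes = sel_row$n_genes,
    n_mod_overlap = sel_row$n_mod_overlap,
    pct_mod = sel_row$pct_mod,
    pct_all = sel_row$pct_all,
    enrichment_ratio = sel_row$enrichment_ratio,
    fisher_p = sel_row$fisher_p,
    n_expression_correlated = sum(expr_flag),
    venn = stats::setNames(as.list(venn_tab$count),
                           paste0(venn_tab$from,
                                  ifelse(nzchar(venn_tab$to), "_", ""),
                                  venn_tab$to)),
    n_shared_with_B = sum(shared),
    class_counts = as.list(table(factor(cls, levels = MOTIF_CLASSES))),
    category_counts = as.list(table(factor(categ,
                                           levels = ANNOTATION_CATEGORIES))),
    group_test = if (!is.null(gt)) list(t = gt$t, p = gt$p) else NULL,
    parameters = config[setdiff(names(PIPELINE_DEFAULTS), "seed")],
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  verify_report(out, summary)
  invisible(summary)
}

# Recompute the headline counts from the stage TSVs and fail on mismatch:
# the summary must always be re-derivable from the written tables.
verify_report <- function(out, summary) {
  filt <- utils::read.delim(file.path(out, "filtered_peaks.tsv"))
  if (nrow(filt) != summary$n_retained)
    stop("report verification failed: retained peak count")
  cal <- utils::read.delim(file.path(out, "calibration.tsv"))
  selrow <- cal[cal$selected, ]
  if (nrow(selrow) != 1 ||
      abs(selrow$threshold - summary$selected_threshold) > 1e-9)
    stop("report verification failed: selected threshold")
  classes <- utils::read.delim(file.path(out, "peak_classes.tsv"))
  tab <- table(factor(classes$class, levels = MOTIF_CLASSES))
  if (!all(as.integer(tab) ==
             unlist(summary$class_counts[MOTIF_CLASSES])))
    stop("report verification failed: motif class counts")
  if (nrow(classes) != summary$n_selected_peaks)
    stop("report verification failed: selected peak count")
  invisible(TRUE)
}
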