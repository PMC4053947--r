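# End-to-end pipeline wiring: filter -> segment -> call -> global stats ->
# expression correlation, with deterministic seeded outputs.

#' Pipeline configuration
#'
#' Collects paths, thresholds and the simulator sub-config. All thresholds
#' default to the reference analysis values: invariant cutoffs 0.9/0.1,
#' alpha 0.05, strong-correlation threshold 0.5, 3 kb run gap, 50-probe
#' window, 3-probe minimum.
#'
#' @param betas,annotation,design,expression input paths (or NULL to
#'   simulate).
#' @param out_dir output directory.
#' @param hi,lo invariant thresholds.
#' @param alpha family-wise significance level.
#' @param strong strong-correlation threshold.
#' @param max_gap run-breaking gap (bp).
#' @param max_window maximum segment length (probes).
#' @param min_probes minimum probes per call.
#' @param bonferroni `"per-group"` or `"global"`.
#' @param drop_snp,drop_chromosomes probe filters.
#' @param sim simulator config ([sim_config()]) used when no input paths are
#'   given.
#' @param seed integer seed for any stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(betas = NULL, annotation = NULL, design = NULL,
                            expression = NULL, out_dir = tempfile("tdmr_"),
                            hi = 0.9, lo = 0.1, alpha = 0.05, strong = 0.5,
                            max_gap = 3000, max_window = 50, min_probes = 3,
                            bonferroni = "per-group", drop_snp = TRUE,
                            drop_chromosomes = c("chrX", "chrY"),
                            sim = NULL, seed = 1L) {
  stopifnot(hi > lo, alpha >= 0, alpha <= 1, strong > 0, max_gap > 0,
            max_window >= 1, min_probes >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full tDMR pipeline
#'
#' Executes filter, segmentation, calling, global statistics and (when
#' expression data is available) methylation-expression correlation, writing
#' all tables, BED files, a run log and a machine-readable stage summary to
#' `cfg$out_dir`. With no input paths, a dataset is simulated from
#' `cfg$sim` (ground truth written alongside, plus a truth-vs-called
#' recovery table).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("tdmrseg %s", as.character(utils::packageVersion("tdmrseg"))),
           sprintf("seed: %d", cfg$seed),
           sprintf("thresholds: hi=%g lo=%g alpha=%g strong=%g", cfg$hi,
                   cfg$lo, cfg$alpha, cfg$strong),
           sprintf("segmentation: max_gap=%d max_window=%d min_probes=%d bonferroni=%s",
                   cfg$max_gap, cfg$max_window, cfg$min_probes,
                   cfg$bonferroni))
  truth <- NULL; expr <- NULL
  if (is.null(cfg$betas)) {
    sim_cfg <- if (is.null(cfg$sim)) sim_config(seed = cfg$seed) else cfg$sim
    ds <- simulate_dataset(sim_cfg)
    ann <- ds$ann; design <- ds$design; bm <- ds$betas; truth <- ds$truth
    write_beta_matrix(bm, file.path(cfg$out_dir, "betas.tsv"))
    write_annotation(ann, file.path(cfg$out_dir, "annotation.csv"))
    write_design(design, file.path(cfg$out_dir, "design.csv"))
    utils::write.table(truth, file.path(cfg$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- c(log, sprintf("simulated: %d probes, %d samples, %d planted DMRs",
                          nrow(bm), ncol(bm), nrow(truth)))
    gene_beta <- average_beta_by_gene(bm, ann, design)
    if (nrow(gene_beta))
      expr <- generate_expression(gene_beta, rho = -0.6,
                                  seed = cfg$seed + 2L)
  } else {
    ann <- read_annotation(cfg$annotation)
    bm <- read_beta_matrix(cfg$betas, ann)
    design <- read_design(cfg$design)
    if (!is.null(cfg$expression)) {
      e <- utils::read.delim(cfg$expression, check.names = FALSE)
      expr <- as.matrix(e[, -1, drop = FALSE])
      rownames(expr) <- e[[1]]
    }
  }

  # 1. filter
  bm <- filter_probes(bm, ann, cfg$drop_snp, cfg$drop_chromosomes)
  rep_filter <- attr(bm, "removal_report")
  ann_f <- ann[match(rownames(bm), ann$probe_id), , drop = FALSE]
  log <- c(log, paste("filtered:", paste(names(rep_filter), rep_filter,
                                         sep = "=", collapse = " ")))

  # 2. segment
  segments <- segment_all(bm, ann_f, design, cfg$max_gap, cfg$max_window)
  utils::write.table(
    segments[c("segment_id", "run_id", "chromosome", "start_pos", "end_pos",
               "n_probes", "dl_bits")],
    file.path(cfg$out_dir, "segments.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # 3. call
  calls <- call_tdmrs(bm, design, segments, cfg$alpha, cfg$min_probes,
                      cfg$bonferroni)
  calls <- annotate_calls(calls, ann_f)
  write_calls(calls[setdiff(names(calls), c("start_idx", "end_idx"))],
              file.path(cfg$out_dir, "tdmrs.tsv"))
  bed <- calls
  bed$name <- paste(bed$segment_id, bed$target_group, bed$direction,
                    sep = "|")
  write_regions_bed(bed, file.path(cfg$out_dir, "tdmrs.bed"))
  summ <- summarize_calls(calls)
  utils::write.table(summ$per_group,
                     file.path(cfg$out_dir, "tdmr_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 4. global stats
  labels <- classify_invariant(bm, cfg$hi, cfg$lo)
  inv_counts <- data.frame(label = c("InvariantHyper", "InvariantHypo",
                                     "Variable"),
                           count = c(sum(labels == "InvariantHyper"),
                                     sum(labels == "InvariantHypo"),
                                     sum(labels == "Variable")))
  inv_counts$percent <- percent_half_up(inv_counts$count, length(labels))
  utils::write.table(inv_counts, file.path(cfg$out_dir, "invariant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dist_reg <- distribution_by_region(ann_f, "gene_region", bm = bm)
  utils::write.table(dist_reg$counts,
                     file.path(cfg$out_dir, "region_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- tissue_mean_profiles(bm, design)
  cm <- tissue_correlation_matrix(prof)
  utils::write.table(round(cm, 4),
                     file.path(cfg$out_dir, "tissue_correlation.tsv"),
                     sep = "\t", quote = FALSE)
  tree <- cluster_tissues(prof)
  writeLines(tree$newick, file.path(cfg$out_dir, "tissue_tree.nwk"))
  r2_t <- variance_explained(bm, design, "tissue_group")
  r2_i <- variance_explained(bm, design, "individual_id")
  utils::write.table(
    data.frame(probe_id = names(r2_t$r2), r2_tissue = round(r2_t$r2, 5),
               r2_individual = round(r2_i$r2, 5)),
    file.path(cfg$out_dir, "variance_explained.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  log <- c(log, sprintf("variance explained: tissue %.1f%%, individual %.1f%%",
                        100 * r2_t$mean_r2, 100 * r2_i$mean_r2))

  # 5. expression correlation
  corr <- NULL
  if (!is.null(expr)) {
    corr <- correlation_table(bm, ann_f, design, expr,
                              strong = cfg$strong)
    utils::write.table(corr, file.path(cfg$out_dir, "expression_corr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # recovery vs truth (simulated inputs only)
  recovery <- NULL
  if (!is.null(truth) && nrow(truth)) {
    recovery <- recovery_table(calls, truth)
    utils::write.table(recovery$per_dmr,
                       file.path(cfg$out_dir, "recovery.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <- c(log, sprintf("recovery: sensitivity %.3f, FDP %.3f",
                          recovery$sensitivity, recovery$fdp))
  }

  counts <- c(probes = nrow(bm), samples = ncol(bm),
              segments = nrow(segments), calls = nrow(calls))
  writeLines(c(log, paste("counts:", paste(names(counts), counts, sep = "=",
                                           collapse = " "))),
             file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(bm = bm, ann = ann_f, design = design, segments = segments,
                 calls = calls, summary = summ, invariant = inv_counts,
                 correlation = cm, tree = tree, r2_tissue = r2_t,
                 r2_individual = r2_i, expression_corr = corr,
                 truth = truth, recovery = recovery,
                 removal_report = rep_filter))
}

#' Compare tDMR calls against planted ground truth
#'
#' A planted DMR counts as recovered when at least one call in its target
#' group, with matching direction, shares a probe with it. A call is a
#' false positive when its probes overlap no planted DMR (any group);
#' calls at a true locus but in another group or direction are neither
#' recovered truths nor false positives.
#'
#' @param calls call table (annotated or not).
#' @param truth truth table from [generate_betas()].
#' @return list with `per_dmr` data.frame (dmr_id, detected), `sensitivity`,
#'   `fdp`, `n_false`, `n_calls`.
#' @export
recovery_table <- function(calls, truth) {
  truth_probes <- strsplit(truth$probe_ids, ";", fixed = TRUE)
  call_probes <- strsplit(calls$probe_ids, ";", fixed = TRUE)
  detected <- vapply(seq_len(nrow(truth)), function(ti) {
    hit <- vapply(seq_len(nrow(calls)), function(ci) {
      calls$target_group[ci] == truth$target_group[ti] &&
        calls$direction[ci] == truth$direction[ti] &&
        length(intersect(call_probes[[ci]], truth_probes[[ti]])) > 0
    }, TRUE)
    any(hit)
  }, TRUE)
  all_truth <- unlist(truth_probes)
  false_pos <- vapply(call_probes, function(p)
    length(intersect(p, all_truth)) == 0, TRUE)
  list(per_dmr = data.frame(dmr_id = truth$dmr_id,
                            target_group = truth$target_group,
                            direction = truth$direction,
                            detected = detected),
       sensitivity = if (nrow(truth)) mean(detected) else NA_real_,
       fdp = if (nrow(calls)) mean(false_pos) else 0,
       n_false = sum(false_pos), n_calls = nrow(calls))
}

#' Simulate-and-analyse demonstration run
#'
#' Simulates a default dataset, runs the full pipeline on it and returns the
#' results (see [run_pipeline()]).
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param sim optional [sim_config()] override.
#' @return the [run_pipeline()] result list.
#' @export
tdmr_demo <- function(seed = 1L, out_dir = tempfile("tdmr_demo_"),
                      sim = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  run_pipeline(pipeline_config(out_dir = out_dir, sim = sim, seed = seed))
}
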