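#' Run the full synthetic TE expression benchmark end-to-end
#'
#' Convenience driver: plants a synthetic genome, selects expressed TE
#' instances, simulates the two-set/five-replicate count matrix and FASTQ
#' reads, quantifies them with the baseline k-mer + EM mapper against the
#' full library, and evaluates detection (F-scores, strata, r^2(TP)) and
#' differential expression (ground-truth DETE set, TPR/FDR curve, TPR at
#' FDR 0.1, FP-inflation diagnostic) against the simulated truth.
#'
#' @param seed Integer seed governing every random step.
#' @param genome_length,specs Passed to [plant_and_annotate()].
#' @param n_expressed Number of TEs selected for expression.
#' @param layout,coverage,dete_frac,fc_up,fc_down Passed to
#'   [simulation_design()].
#' @param work_dir Directory for FASTQ/annotation files (default: a
#'   session temporary directory).
#' @param max_mismatches,multimap_cap Passed to [quantify_baseline()].
#' @param error_model Passed to [simulate_reads()].
#' @param quality_profile Optional [learn_quality_profile()] object.
#' @return A `te_benchmark` object: list with `genome`, `design`, `truth`
#'   (count matrix), `reads`, `tool_counts`, `detection`
#'   ([evaluate_detection()] result), `truth_detes`, `de`
#'   ([nb_de_test()] on tool counts), `curve`, `tpr_at_0.1` and
#'   `fp_diagnostic`.
#' @export
run_te_benchmark <- function(seed = 1L, genome_length = 2e6,
                             specs = default_family_specs(),
                             n_expressed = 200L, layout = "PE100",
                             coverage = 20, dete_frac = 0.05,
                             fc_up = 2, fc_down = 0.5,
                             work_dir = tempfile("tebench_"),
                             max_mismatches = 2L, multimap_cap = 100L,
                             error_model = "none", quality_profile = NULL) {
  pg <- plant_and_annotate(genome_length = genome_length, specs = specs,
                           seed = seed)
  sel <- select_instances(pg$library, n_expressed, seed = seed + 1L)
  design <- simulation_design(pg$library, te_ids = sel, layout = layout,
                              coverage = coverage, dete_frac = dete_frac,
                              fc_up = fc_up, fc_down = fc_down,
                              seed = seed + 2L)
  truth <- simulate_count_matrix(design, seed = seed + 3L)
  reads <- simulate_reads(truth, pg$library, design, out_dir = work_dir,
                          seed = seed + 4L, error_model = error_model,
                          quality_profile = quality_profile)
  tool <- quantify_baseline(reads$files, pg$library,
                            max_mismatches = max_mismatches,
                            multimap_cap = multimap_cap)
  detection <- evaluate_detection(truth, tool, instances = pg$instances)
  truth_detes <- ground_truth_detes(truth)
  de <- nb_de_test(tool)
  curve <- if (length(truth_detes) > 0L) tpr_fdr_curve(de, truth_detes)
           else NULL
  fp <- fp_inflation_diagnostic(truth, tool, de = de)
  structure(list(genome = pg, design = design, truth = truth,
                 reads = reads, tool_counts = tool, detection = detection,
                 truth_detes = truth_detes, de = de, curve = curve,
                 tpr_at_0.1 = if (!is.null(curve))
                   tpr_at_fixed_fdr(curve, 0.1) else NA_real_,
                 fp_diagnostic = fp, work_dir = work_dir),
            class = "te_benchmark")
}

#' @export
print.te_benchmark <- function(x, ...) {
  cat("Synthetic TE expression benchmark\n")
  cat("  planted TEs:", nrow(x$genome$instances),
      "| expressed:", nrow(x$design$tes),
      "| layout:", x$design$layout, "\n")
  cat("  baseline quantifier mean F-score:",
      round(x$detection$mean_f, 3L), "\n")
  cat("  ground-truth DETEs:", length(x$truth_detes),
      "| TPR at FDR 0.1:", round(x$tpr_at_0.1, 3L), "\n")
  invisible(x)
}
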