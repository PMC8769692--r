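# Detection & quantification evaluation: low-count filtering, per-replicate
# confusion at the detection cutoff of 5 reads, F-scores overall and
# stratified by Kimura bin / TE order, per-set baseMeans and r^2 over true
# positives.

#' Remove TEs with low total counts
#'
#' Drops every row whose counts summed over all samples are less than or
#' equal to `threshold` (default 10 over the 10 samples, i.e. on average
#' more than one read per sample is required). The boundary is exclusive: a
#' row summing exactly to the threshold is removed.
#'
#' @param matrix Count matrix (rows = TEs, columns = samples).
#' @param threshold Total-count threshold (default 10).
#' @return The filtered matrix.
#' @export
filter_low_counts <- function(matrix, threshold = 10) {
  matrix[rowSums(matrix) > threshold, , drop = FALSE]
}

#' Classify one (truth, tool) count pair at the detection cutoff
#'
#' A TE counts as detected when the reported value is greater than or equal
#' to `cutoff` (default 5; boundary inclusive). The same cutoff is applied
#' to the simulated truth, and the 2x2 rule gives TP (both detected), FP
#' (tool only), FN (truth only) or TN (neither).
#'
#' @param truth_count,tool_count Non-negative counts (vectorized).
#' @param cutoff Detection cutoff (default 5). Fractional tool counts are
#'   compared unrounded.
#' @return Character vector in `{"TP","FP","FN","TN"}`.
#' @export
classify_detection <- function(truth_count, tool_count, cutoff = 5) {
  t_det <- truth_count >= cutoff
  x_det <- tool_count >= cutoff
  ifelse(x_det & t_det, "TP",
         ifelse(x_det & !t_det, "FP",
                ifelse(!x_det & t_det, "FN", "TN")))
}

# recall/precision/F from confusion counts; zero denominators give 0
.prf <- function(tp, fp, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(recall = recall, precision = precision, f_score = f)
}

#' Per-replicate recall, precision and F-score
#'
#' @param classes Character matrix of detection classes (rows = TEs,
#'   columns = replicates), as produced inside [evaluate_detection()].
#' @return Data frame with one row per replicate (TP/FP/FN/TN counts,
#'   recall, precision, f_score) plus the mean F across replicates as
#'   attribute `"mean_f"`.
#' @export
f_score_summary <- function(classes) {
  out <- do.call(rbind, lapply(seq_len(ncol(classes)), function(j) {
    cl <- classes[, j]
    tp <- sum(cl == "TP"); fp <- sum(cl == "FP")
    fn <- sum(cl == "FN"); tn <- sum(cl == "TN")
    data.frame(sample = colnames(classes)[j], TP = tp, FP = fp, FN = fn,
               TN = tn, t(.prf(tp, fp, fn)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "mean_f") <- mean(out$f_score)
  out
}

#' Kimura-distance bin labels
#'
#' Half-open bins of width `width`: \[0,5), \[5,10), ...
#'
#' @param kimura Numeric Kimura distances (percent).
#' @param width Bin width (default 5).
#' @return Character labels like `"[5,10)"`; `NA` for unknown distances.
#' @export
kimura_bin <- function(kimura, width = 5) {
  lo <- floor(kimura / width) * width
  ifelse(is.na(kimura), NA_character_,
         sprintf("[%g,%g)", lo, lo + width))
}

#' Mean F-scores per stratum
#'
#' Recomputes the confusion within each stratum (Kimura bin or TE order)
#' before deriving recall/precision/F per replicate, then averages F across
#' the replicates. Strata without TEs are absent from the output, not zero.
#'
#' @param classes Character matrix of detection classes (rows = TEs).
#' @param strata Character vector of stratum labels, one per TE row.
#' @return Data frame `stratum`, `n_tes`, `mean_f`, `mean_recall`,
#'   `mean_precision`.
#' @export
stratified_f_scores <- function(classes, strata) {
  stopifnot(length(strata) == nrow(classes))
  keep <- !is.na(strata)
  levs <- sort(unique(strata[keep]))
  out <- do.call(rbind, lapply(levs, function(s) {
    sub <- classes[keep & strata == s, , drop = FALSE]
    prf <- vapply(seq_len(ncol(sub)), function(j) {
      cl <- sub[, j]
      .prf(sum(cl == "TP"), sum(cl == "FP"), sum(cl == "FN"))
    }, numeric(3L))
    data.frame(stratum = s, n_tes = nrow(sub),
               mean_f = mean(prf["f_score", ]),
               mean_recall = mean(prf["recall", ]),
               mean_precision = mean(prf["precision", ]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean expression (baseMean) of a TE over a set's replicates
#'
#' `baseMean_i = sum_j n_ij / j`: the arithmetic mean of TE `i`'s counts
#' over the replicates of one set.
#'
#' @param counts Numeric vector (one TE, one set's replicates) or matrix
#'   (TEs x replicates).
#' @return Scalar or per-row vector of means.
#' @export
base_mean <- function(counts) {
  if (is.matrix(counts)) rowMeans(counts) else mean(counts)
}

#' Coefficient of determination over true positives
#'
#' Squared Pearson correlation of recovered vs simulated baseMeans,
#' restricted to true-positive TEs. With `log = TRUE` both sides are
#' log10-transformed first, zeros mapped to 0 (the display rule used for
#' the recovery scatter plots).
#'
#' @param sim,rec Simulated and recovered baseMeans (equal length).
#' @param tp_mask Logical mask of true positives.
#' @param log Compute on log10 scale?
#' @return r^2 in \[0,1\], or `NA` (with a message) when fewer than 3 TPs
#'   remain or the simulated values are constant.
#' @export
r2_true_positives <- function(sim, rec, tp_mask, log = FALSE) {
  s <- sim[tp_mask]; r <- rec[tp_mask]
  if (log) {
    s <- ifelse(s == 0, 0, log10(s))
    r <- ifelse(r == 0, 0, log10(r))
  }
  if (length(s) < 3L || stats::sd(s) == 0 || stats::sd(r) == 0) {
    message("r2(TP) undefined: fewer than 3 TPs or zero variance")
    return(NA_real_)
  }
  stats::cor(s, r)^2
}

#' Evaluate a tool's count table against the simulated truth
#'
#' Runs the full detection/quantification evaluation: each matrix is
#' low-count filtered on its own row sums, the evaluation runs over the
#' union of surviving rows (absent rows count 0), every TE is classified
#' TP/FP/FN/TN per replicate at the detection cutoff, and recall, precision
#' and F-score are summarized overall and stratified by Kimura bin and TE
#' order. Per set, baseMeans are compared and r^2 over true positives
#' computed (TP at the baseMean level, both baseMeans >= cutoff, matching
#' the recovery scatter convention); TN rows are excluded from the scatter
#' export.
#'
#' @param truth Simulated (reference) count matrix.
#' @param tool Tool count matrix (fractional counts allowed); columns must
#'   cover the same samples.
#' @param instances Instance metadata data frame with `te_id`, `kimura`,
#'   `order` (default: parsed from the TE ids).
#' @param cutoff Detection cutoff (default 5).
#' @param filter_threshold Low-count filter total (default 10).
#' @param id_base Coordinate base for [parse_te_id()] when `instances` is
#'   `NULL`.
#' @param r2_log Compute r^2(TP) on log10 scale?
#' @return A `detection_eval` object: list with `per_replicate`, `mean_f`,
#'   `by_kimura`, `by_order`, `quant` (per set: TP/FP/FN counts and
#'   r2_tp), `scatter` (per-set baseMean pairs, TN dropped) and `classes`.
#' @export
evaluate_detection <- function(truth, tool, instances = NULL, cutoff = 5,
                               filter_threshold = 10, id_base = 1L,
                               r2_log = FALSE) {
  samples <- colnames(truth)
  miss <- setdiff(samples, colnames(tool))
  if (length(miss) > 0L)
    stop("tool matrix lacks sample(s): ", paste(miss, collapse = ", "))
  tool <- tool[, samples, drop = FALSE]
  meta <- sample_meta(samples)

  truth_f <- filter_low_counts(truth, filter_threshold)
  tool_f <- filter_low_counts(tool, filter_threshold)
  ids <- union(rownames(truth_f), rownames(tool_f))

  tr <- matrix(0, nrow = length(ids), ncol = length(samples),
               dimnames = list(ids, samples))
  to <- tr
  tr[rownames(truth_f), ] <- truth_f
  to[rownames(tool_f), ] <- tool_f

  classes <- matrix(classify_detection(as.vector(tr), as.vector(to), cutoff),
                    nrow = length(ids), dimnames = list(ids, samples))
  per_rep <- f_score_summary(classes)

  if (is.null(instances)) instances <- parse_te_id(ids, base = id_base)
  ii <- match(ids, instances$te_id)
  if (anyNA(ii)) stop("instance metadata missing for some TE ids")
  kim <- instances$kimura[ii]
  ords <- instances$order[ii]

  by_kimura <- stratified_f_scores(classes, kimura_bin(kim))
  by_order <- stratified_f_scores(classes, ords)

  quant <- list(); scatter <- list()
  for (s in 1:2) {
    cols <- meta$sample[meta$set == s]
    bm_t <- base_mean(tr[, cols, drop = FALSE])
    bm_x <- base_mean(to[, cols, drop = FALSE])
    cl <- classify_detection(bm_t, bm_x, cutoff)
    r2 <- r2_true_positives(bm_t, bm_x, cl == "TP", log = r2_log)
    quant[[paste0("set", s)]] <- data.frame(
      set = s, TP = sum(cl == "TP"), FP = sum(cl == "FP"),
      FN = sum(cl == "FN"), r2_tp = r2)
    keep <- cl != "TN"      # TNs excluded from scatter exports
    scatter[[paste0("set", s)]] <- data.frame(
      te_id = ids[keep], set = s, simulated = bm_t[keep],
      recovered = bm_x[keep], class = cl[keep], stringsAsFactors = FALSE)
  }
  quant <- do.call(rbind, quant); rownames(quant) <- NULL
  scatter <- do.call(rbind, scatter); rownames(scatter) <- NULL

  structure(list(per_replicate = per_rep, mean_f = attr(per_rep, "mean_f"),
                 by_kimura = by_kimura, by_order = by_order,
                 quant = quant, scatter = scatter, classes = classes,
                 cutoff = cutoff, filter_threshold = filter_threshold),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat("Detection evaluation (cutoff ", x$cutoff, ", filter > ",
      x$filter_threshold, " total reads)\n", sep = "")
  cat("  mean F-score over ", nrow(x$per_replicate), " replicates: ",
      round(x$mean_f, 3L), "\n", sep = "")
  cat("  mean recall ", round(mean(x$per_replicate$recall), 3L),
      ", mean precision ", round(mean(x$per_replicate$precision), 3L),
      "\n", sep = "")
  cat("  per-set baseMean confusion / r2(TP):\n")
  print(x$quant, row.names = FALSE)
  cat("  F by Kimura bin:\n")
  print(x$by_kimura[, c("stratum", "n_tes", "mean_f")], row.names = FALSE)
  invisible(x)
}
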