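# Differential-expression arm: built-in negative-binomial Wald test
# (pluggable stand-in for an external DE engine; external result tables can
# be imported), ground-truth DETE derivation, cumulative TPR/FDR curves,
# TPR at a fixed FDR, the FP-inflation diagnostic and tool ranking.

#' Median-of-ratios size factors
#'
#' Library-size normalization: per sample, the median ratio of its counts
#' to the per-TE geometric mean across samples, taken over TEs with all
#' counts positive.
#'
#' @param matrix Count matrix (TEs x samples).
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(matrix) {
  pos <- rowSums(matrix > 0) == ncol(matrix)
  if (!any(pos)) return(stats::setNames(rep(1, ncol(matrix)),
                                        colnames(matrix)))
  lg <- log(matrix[pos, , drop = FALSE])
  gm <- rowMeans(lg)
  apply(lg, 2L, function(x) exp(stats::median(x - gm)))
}

#' Negative-binomial Wald test for differential TE expression
#'
#' The built-in DE engine: counts are normalized by median-of-ratios size
#' factors; per TE a method-of-moments dispersion is estimated from the
#' pooled within-set variance and shrunk (geometric mean in log space)
#' toward a log-log mean-dispersion trend fitted across all TEs; the Wald
#' statistic on the log2 fold change (Set 2 vs Set 1) uses the delta-method
#' standard error \eqn{\sqrt{(1/\mu_1+\alpha_1)/n_1+(1/\mu_2+\alpha_2)/n_2}
#' /\ln 2} and a normal reference. p-values are Benjamini-Hochberg adjusted
#' over the tested TEs. Rows failing the independent low-count filter (and
#' all-zero rows) are excluded from testing and reported with `NA`s.
#'
#' @param matrix Count matrix with `set1_rep*` / `set2_rep*` columns (a
#'   fractional tool matrix is acceptable).
#' @param samples Optional sample names (default: column names).
#' @param filter_threshold Independent low-count filter on row totals
#'   (default 10, exclusive boundary as in [filter_low_counts()]).
#' @param pseudocount Added to set means for the fold change when a mean is
#'   zero (default 0.5).
#' @return A `de_table` data frame: `te_id`, `base_mean`, `log2_fold_change`,
#'   `p_value`, `adjusted_p` (BH), `tested`.
#' @export
nb_de_test <- function(matrix, samples = colnames(matrix),
                       filter_threshold = 10, pseudocount = 0.5) {
  meta <- sample_meta(samples)
  if (any(table(meta$set) < 2L))
    stop("each set needs at least 2 replicates")
  sf <- size_factors(matrix)
  norm <- sweep(matrix, 2L, sf, "/")
  s1 <- meta$sample[meta$set == 1L]
  s2 <- meta$sample[meta$set == 2L]
  n1 <- length(s1); n2 <- length(s2)
  m1 <- rowMeans(norm[, s1, drop = FALSE])
  m2 <- rowMeans(norm[, s2, drop = FALSE])
  v1 <- apply(norm[, s1, drop = FALSE], 1L, stats::var)
  v2 <- apply(norm[, s2, drop = FALSE], 1L, stats::var)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)

  tested <- rowSums(matrix) > filter_threshold & mu > 0
  # method-of-moments dispersion: var = mu + alpha mu^2
  mbar <- (m1 + m2) / 2
  a_mom <- pmax((vw - mbar) / mbar^2, 1e-8)
  # log-log trend alpha ~ mu over tested TEs
  ok <- tested & is.finite(a_mom) & a_mom > 1e-8 & mbar > 0
  if (sum(ok) >= 10L) {
    fit <- stats::lm(log(a_mom[ok]) ~ log(mbar[ok]))
    a_trend <- pmax(exp(fit$coefficients[1L] +
                          fit$coefficients[2L] * log(pmax(mbar, 1e-8))),
                    1e-8)
  } else {
    a_trend <- rep(stats::median(a_mom[tested], na.rm = TRUE), length(mu))
  }
  # shrink toward the trend; per-TE estimates may only raise the dispersion
  # above it (floored MoM values would otherwise understate the SE)
  alpha <- pmax(a_trend, exp((log(a_mom) + log(a_trend)) / 2))
  alpha[!is.finite(alpha)] <- a_trend[!is.finite(alpha)]

  lfc <- log2((m2 + ifelse(m2 == 0 | m1 == 0, pseudocount, 0)) /
                (m1 + ifelse(m2 == 0 | m1 == 0, pseudocount, 0)))
  se_ln <- sqrt((1 / pmax(m1, 1e-8) + alpha) / n1 +
                  (1 / pmax(m2, 1e-8) + alpha) / n2)
  z <- (lfc * log(2)) / se_ln
  p <- 2 * stats::pnorm(-abs(z))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(te_id = rownames(matrix),
                    base_mean = mu,
                    log2_fold_change = lfc,
                    p_value = p, adjusted_p = padj,
                    tested = tested, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat("DE table:", nrow(x), "TEs,", sum(x$tested), "tested,",
      sum(x$adjusted_p < 0.05, na.rm = TRUE), "significant (padj < 0.05)\n")
  print.data.frame(utils::head(x[order(x$adjusted_p), ], 5L),
                   row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Import an externally produced DE result table
#'
#' Plugs real external DE output (e.g. a DESeq2 result exported as TSV with
#' id, log2 fold change, p-value and adjusted p-value columns) into the
#' evaluation in place of the built-in engine.
#'
#' @param file TSV path.
#' @param columns Named character vector mapping the required fields
#'   (`te_id`, `log2_fold_change`, `p_value`, `adjusted_p`) to the file's
#'   column names.
#' @return A `de_table` data frame.
#' @export
import_de_table <- function(file,
                            columns = c(te_id = "te_id",
                                        log2_fold_change = "log2FC",
                                        p_value = "p",
                                        adjusted_p = "padj")) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t", as.is = TRUE,
                           check.names = FALSE)
  miss <- setdiff(unname(columns), names(tab))
  if (length(miss) > 0L)
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(te_id = as.character(tab[[columns[["te_id"]]]]),
                    base_mean = NA_real_,
                    log2_fold_change = tab[[columns[["log2_fold_change"]]]],
                    p_value = tab[[columns[["p_value"]]]],
                    adjusted_p = tab[[columns[["adjusted_p"]]]],
                    stringsAsFactors = FALSE)
  out$tested <- !is.na(out$p_value)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Derive the ground-truth DETE set from the simulated counts
#'
#' Runs the DE engine on the simulated (truth) count matrix and keeps the
#' TEs significant at `alpha` (adjusted p < 0.05 by default). This set is
#' the benchmark truth: spiked TEs may escape it (low expression, high
#' dispersion) and unspiked TEs may enter it — by construction, a perfect
#' aligner evaluated against it has a power of exactly 1.
#'
#' @param truth_matrix Simulated count matrix.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param de_fun DE engine, defaulting to [nb_de_test()]; any function
#'   returning a `de_table` may be plugged in.
#' @return Character vector of TE ids.
#' @export
ground_truth_detes <- function(truth_matrix, alpha = 0.05,
                               de_fun = nb_de_test) {
  de <- de_fun(truth_matrix)
  de$te_id[!is.na(de$adjusted_p) & de$adjusted_p < alpha]
}

#' Cumulative TPR/FDR curve of a DE result against the truth set
#'
#' The three-step evaluation: (1) sort the DE table in ascending order of
#' adjusted p-value (ties broken by raw p, then TE id, for determinism);
#' (2) count true and false positives cumulatively down the ranking;
#' (3) at each rank `k`, `TPR = cumTP / |truth|` and `FDR = cumFP / k`.
#' Untested rows (`NA` adjusted p) never enter the ranking; truth TEs
#' absent from the table cap the final TPR.
#'
#' @param de A `de_table`.
#' @param truth_set Character vector of ground-truth DETE ids (non-empty).
#' @return A `tpr_fdr_curve` data frame: `rank`, `te_id`, `adjusted_p`,
#'   `cum_tp`, `cum_fp`, `tpr`, `fdr`.
#' @export
tpr_fdr_curve <- function(de, truth_set) {
  if (length(truth_set) == 0L) stop("empty truth set")
  d <- de[!is.na(de$adjusted_p), , drop = FALSE]
  d <- d[order(d$adjusted_p, d$p_value, d$te_id), , drop = FALSE]
  is_tp <- d$te_id %in% truth_set
  out <- data.frame(rank = seq_len(nrow(d)), te_id = d$te_id,
                    adjusted_p = d$adjusted_p,
                    cum_tp = cumsum(is_tp), cum_fp = cumsum(!is_tp),
                    stringsAsFactors = FALSE)
  out$tpr <- out$cum_tp / length(truth_set)
  out$fdr <- out$cum_fp / out$rank
  class(out) <- c("tpr_fdr_curve", "data.frame")
  out
}

#' TPR attainable at a fixed FDR
#'
#' Maximum TPR over all curve points with FDR at or below the threshold
#' (default 0.1); 0 when no point qualifies.
#'
#' @param curve A [tpr_fdr_curve()] result.
#' @param fdr FDR threshold (default 0.1).
#' @return Scalar TPR.
#' @export
tpr_at_fixed_fdr <- function(curve, fdr = 0.1) {
  ok <- curve$fdr <= fdr
  if (!any(ok)) return(0)
  max(curve$tpr[ok])
}

#' False-positive inflation diagnostic
#'
#' Investigates whether detection false positives drive spurious DE calls:
#' selects the TEs wrongly detected in both sets (tool baseMean at or above
#' the cutoff while the truth baseMean is below it, in Set 1 and Set 2
#' simultaneously), reports their mean tool count across all replicates and
#' the log2 ratio of the two set baseMeans (pseudocount 0.5 when a mean is
#' 0), flags the high-expression / high-fold-change subset (mean > 20 and
#' |log2 FC| > 1), and gives the fraction of that subset also called
#' significant by the DE arm. Rows with |log2 FC| < 0.5 are dropped from
#' the exported table.
#'
#' @param truth,tool Count matrices (all 10 samples).
#' @param de Optional `de_table` computed from the tool counts.
#' @param cutoff Detection cutoff (default 5).
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param mean_cut,lfc_cut Flag thresholds (defaults 20 and 1).
#' @param export_lfc_min Minimum |log2 FC| retained in the table (0.5).
#' @return A `fp_inflation` object: list with `table` (per-TE diagnostic),
#'   `n_fp_both`, `n_flagged` and `frac_flagged_significant`.
#' @export
fp_inflation_diagnostic <- function(truth, tool, de = NULL, cutoff = 5,
                                    alpha = 0.05, mean_cut = 20,
                                    lfc_cut = 1, export_lfc_min = 0.5) {
  samples <- colnames(truth)
  tool <- tool[, samples, drop = FALSE]
  meta <- sample_meta(samples)
  ids <- union(rownames(truth), rownames(tool))
  tr <- matrix(0, length(ids), ncol(truth), dimnames = list(ids, samples))
  to <- tr
  tr[rownames(truth), ] <- truth
  to[rownames(tool), ] <- tool
  fp_set <- list()
  bm <- list()
  for (s in 1:2) {
    cols <- meta$sample[meta$set == s]
    bt <- base_mean(tr[, cols, drop = FALSE])
    bx <- base_mean(to[, cols, drop = FALSE])
    fp_set[[s]] <- bx >= cutoff & bt < cutoff
    bm[[s]] <- bx
  }
  both <- fp_set[[1L]] & fp_set[[2L]]
  b1 <- bm[[1L]][both]; b2 <- bm[[2L]][both]
  lfc <- log2((b2 + ifelse(b2 == 0 | b1 == 0, 0.5, 0)) /
                (b1 + ifelse(b2 == 0 | b1 == 0, 0.5, 0)))
  tab <- data.frame(te_id = ids[both],
                    mean_count = rowMeans(to[both, , drop = FALSE]),
                    log2_fold_change = lfc,
                    stringsAsFactors = FALSE)
  tab$flagged <- tab$mean_count > mean_cut & abs(tab$log2_fold_change) > lfc_cut
  if (!is.null(de)) {
    sig <- de$te_id[!is.na(de$adjusted_p) & de$adjusted_p < alpha]
    tab$de_significant <- tab$te_id %in% sig
    frac <- if (any(tab$flagged)) mean(tab$de_significant[tab$flagged])
            else NA_real_
  } else {
    tab$de_significant <- NA
    frac <- NA_real_
  }
  exported <- tab[abs(tab$log2_fold_change) >= export_lfc_min, , drop = FALSE]
  rownames(exported) <- NULL
  structure(list(table = exported, n_fp_both = sum(both),
                 n_flagged = sum(tab$flagged),
                 frac_flagged_significant = frac),
            class = "fp_inflation")
}

#' @export
print.fp_inflation <- function(x, ...) {
  cat("FP-inflation diagnostic:", x$n_fp_both,
      "TEs wrongly detected in both sets;", x$n_flagged,
      "with mean > 20 and |log2FC| > 1\n")
  if (!is.na(x$frac_flagged_significant))
    cat("  fraction of flagged TEs also called DE:",
        round(x$frac_flagged_significant, 3L), "\n")
  invisible(x)
}

#' Rank tools across evaluation categories
#'
#' Ranks every tool within each scoring category (average ranks on ties),
#' averages the category ranks within each evaluation part (detection,
#' quantification, differential expression by default) and ranks the means,
#' yielding one overall rank per part — the three-column ranking table
#' shape.
#'
#' @param scores Numeric matrix, rows = tools, columns = categories.
#' @param direction Character vector per category: `"higher"` (better) or
#'   `"lower"`.
#' @param parts Character vector assigning each category to an evaluation
#'   part; defaults to one part for all categories.
#' @return Data frame: one row per tool, one column of ranks per part.
#' @export
rank_tools <- function(scores, direction = rep("higher", ncol(scores)),
                       parts = rep("overall", ncol(scores))) {
  if (nrow(scores) < 2L) stop("need at least 2 tools to rank")
  if (anyNA(scores)) {
    bad <- which(is.na(scores), arr.ind = TRUE)[1L, ]
    stop("missing score for tool '", rownames(scores)[bad[1L]],
         "', category '", colnames(scores)[bad[2L]], "'")
  }
  direction <- match.arg(direction, c("higher", "lower"), several.ok = TRUE)
  direction <- rep(direction, length.out = ncol(scores))
  cat_ranks <- vapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    rank(if (direction[j] == "higher") -x else x, ties.method = "average")
  }, numeric(nrow(scores)))
  dimnames(cat_ranks) <- dimnames(scores)
  out <- data.frame(tool = rownames(scores), stringsAsFactors = FALSE)
  for (p in unique(parts)) {
    mean_rank <- rowMeans(cat_ranks[, parts == p, drop = FALSE])
    out[[p]] <- rank(mean_rank, ties.method = "average")
  }
  out
}
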