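# Two-set / five-replicate simulation design with spiked differential
# expression. Set 1 is the control; Set 2 carries 5% uniformly drawn DETEs
# (2.5% up- and 2.5% down-regulated). Counts are drawn negative-binomially
# around a 20-fold mean coverage target per TE.

.layouts <- list(
  SE50  = list(read_length = 50L,  paired = FALSE),
  SE100 = list(read_length = 100L, paired = FALSE),
  PE100 = list(read_length = 100L, paired = TRUE))

#' Sample names of the two-set / five-replicate design
#'
#' @param replicates Replicates per set.
#' @return Character vector `set1_rep1` ... `set2_rep5`.
#' @export
design_samples <- function(replicates = 5L) {
  as.vector(vapply(1:2, function(s)
    paste0("set", s, "_rep", seq_len(replicates)), character(replicates)))
}

# (set, replicate) metadata for a vector of sample names
sample_meta <- function(samples) {
  m <- regmatches(samples, regexec("^set([12])_rep([0-9]+)$", samples))
  bad <- lengths(m) == 0L
  if (any(bad)) stop("unrecognized sample name: ", samples[bad][1L])
  data.frame(sample = samples,
             set = as.integer(vapply(m, `[`, character(1L), 2L)),
             replicate = as.integer(vapply(m, `[`, character(1L), 3L)),
             stringsAsFactors = FALSE)
}

#' Select TE instances eligible for expression simulation
#'
#' Uniform sample without replacement from the instances that satisfy the
#' study's eligibility rule: length >= `min_length` (default 100 bp), order
#' among DNA/LINE/SINE/LTR, and a known Kimura distance.
#'
#' @param library A `te_library` (or its `instances` data frame).
#' @param n Number of TEs to draw.
#' @param min_length Minimum instance length in bp.
#' @param seed Optional RNG seed.
#' @return Character vector of selected TE ids.
#' @export
select_instances <- function(library, n, min_length = 100L, seed = NULL) {
  inst <- if (inherits(library, "te_library")) library$instances else library
  eligible <- inst$length >= min_length &
    inst$order %in% .rm_orders & !is.na(inst$kimura)
  pool <- inst$te_id[eligible]
  if (length(pool) < n)
    stop("eligible pool too small: ", length(pool), " instances, need ", n)
  if (!is.null(seed)) set.seed(seed)
  sample(pool, n)
}

#' Expected read (or pair) count for a TE at a coverage target
#'
#' Single-end: `round(coverage * L / read_length)` reads; paired-end:
#' `round(coverage * L / (2 * read_length))` pairs — in both layouts the
#' sequenced bases per TE equal `coverage * L`.
#'
#' @param te_length TE length in bp.
#' @param coverage Mean fold-coverage target (default 20).
#' @param read_length Read length in bp.
#' @param layout `"SE50"`, `"SE100"` or `"PE100"`.
#' @return Expected reads (SE) or fragments (PE); vectorized over
#'   `te_length`. TEs shorter than the read length yield `NA` with a
#'   warning (they are skipped by the design).
#' @export
expected_reads <- function(te_length, coverage = 20,
                           read_length = NULL, layout = "PE100") {
  lay <- .layouts[[match.arg(layout, names(.layouts))]]
  if (is.null(read_length)) read_length <- lay$read_length
  short <- te_length < read_length
  if (any(short)) {
    warning(sum(short), " TE(s) shorter than the read length skipped")
    te_length[short] <- NA_integer_
  }
  per_unit <- if (lay$paired) 2L * read_length else read_length
  round(coverage * te_length / per_unit)
}

#' Build a two-set / five-replicate spike-in simulation design
#'
#' Flags exactly `round(dete_frac/2 * N)` TEs as up- and the same number as
#' down-regulated (drawn uniformly at random), assigns fold changes applied
#' in Set 2, and stores the per-TE expected read count at the coverage
#' target. The spike-in counts are exact, not expected.
#'
#' @param library A `te_library` (or instance data frame) providing lengths.
#' @param te_ids TEs to simulate (default: all eligible per
#'   [select_instances()] rules, i.e. pass an explicit selection for the
#'   usual workflow).
#' @param layout Sequencing layout: `"PE100"` (default), `"SE50"`, `"SE100"`.
#' @param coverage Mean fold-coverage per TE (default 20).
#' @param dete_frac Fraction of TEs spiked as differentially expressed
#'   (default 0.05, split equally up/down).
#' @param fc_up,fc_down Fold changes applied in Set 2 (defaults 2 and 0.5).
#' @param size_ratio NB size as a fraction of the mean: `size = mu *
#'   size_ratio` (default 1/3, i.e. variance `= 4 mu`).
#' @param replicates Replicates per set (default 5).
#' @param seed Optional RNG seed (governs the DETE draw).
#' @return A `sim_design` object: data frame `tes` (te_id, length, mu, dete,
#'   fold_change) plus layout/coverage/replicate metadata.
#' @export
simulation_design <- function(library, te_ids = NULL, layout = "PE100",
                              coverage = 20, dete_frac = 0.05,
                              fc_up = 2, fc_down = 0.5, size_ratio = 1 / 3,
                              replicates = 5L, seed = NULL) {
  stopifnot(fc_up > 1, fc_down < 1, fc_down > 0)
  layout <- match.arg(layout, names(.layouts))
  inst <- if (inherits(library, "te_library")) library$instances else library
  if (is.null(te_ids)) te_ids <- inst$te_id
  idx <- match(te_ids, inst$te_id)
  if (anyNA(idx)) stop("te_ids absent from library: ",
                       paste(utils::head(te_ids[is.na(idx)], 3L),
                             collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  len <- inst$length[idx]
  mu <- suppressWarnings(expected_reads(len, coverage, layout = layout))
  keep <- !is.na(mu)
  if (!all(keep)) {
    warning(sum(!keep), " TE(s) shorter than the read length dropped")
    te_ids <- te_ids[keep]; len <- len[keep]; mu <- mu[keep]
  }
  n <- length(te_ids)
  n_each <- round(dete_frac / 2 * n)
  flagged <- sample(n, 2L * n_each)
  dete <- rep("none", n)
  dete[flagged[seq_len(n_each)]] <- "up"
  dete[flagged[n_each + seq_len(n_each)]] <- "down"
  fc <- ifelse(dete == "up", fc_up, ifelse(dete == "down", fc_down, 1))
  structure(list(
    tes = data.frame(te_id = te_ids, length = len, mu = mu, dete = dete,
                     fold_change = fc, stringsAsFactors = FALSE),
    layout = layout, read_length = .layouts[[layout]]$read_length,
    paired = .layouts[[layout]]$paired, coverage = coverage,
    replicates = as.integer(replicates), sets = 2L,
    size_ratio = size_ratio,
    samples = design_samples(replicates)),
    class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  tab <- table(x$tes$dete)
  cat("Simulation design:", nrow(x$tes), "TEs,", x$layout, "layout,",
      x$coverage, "x coverage\n")
  cat("  2 sets x", x$replicates, "replicates; spike-ins:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate the ground-truth count matrix
#'
#' Draws the per-TE, per-replicate read (SE) or fragment (PE) counts of the
#' design: negative-binomial with mean `mu_i` (times the fold change in
#' Set 2 for flagged TEs) and size `mu * size_ratio`. `deterministic = TRUE`
#' is the zero-dispersion limit: every cell equals its mean exactly
#' (rounded). This matrix is the reference for all downstream evaluation.
#'
#' @param design A [simulation_design()] object.
#' @param seed Optional RNG seed.
#' @param deterministic Suppress replicate noise?
#' @return Integer matrix, rows = TE ids, columns = samples
#'   (`set1_rep1` ... `set2_rep5`).
#' @export
simulate_count_matrix <- function(design, seed = NULL, deterministic = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  tes <- design$tes
  n <- nrow(tes)
  meta <- sample_meta(design$samples)
  counts <- matrix(0L, nrow = n, ncol = length(design$samples),
                   dimnames = list(tes$te_id, design$samples))
  for (j in seq_along(design$samples)) {
    mu <- if (meta$set[j] == 2L) tes$mu * tes$fold_change else tes$mu
    if (deterministic) {
      counts[, j] <- as.integer(round(mu))
    } else {
      pos <- mu > 0
      v <- integer(n)
      v[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                               size = mu[pos] * design$size_ratio)
      counts[, j] <- v
    }
  }
  counts
}
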