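# Synthetic genome with planted TE instances.
#
# Replaces the real mouse/human/killifish downloads: fabricates family
# consensus sequences, mutates per-instance copies across a controlled
# divergence spectrum (transition:transversion 2:1 by default), plants them
# at non-overlapping loci with random spacers, and emits RepeatMasker-style
# .align/.out annotation that round-trips through parse_align() to the truth
# table exactly.

.DNA <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Describe one synthetic TE family
#'
#' @param name Family name (also used as RepeatMasker repeat name).
#' @param order TE order, one of `DNA`, `LINE`, `SINE`, `LTR`.
#' @param consensus_length Consensus length in bp (>= 50).
#' @param n_instances Number of genomic copies to plant (>= 1).
#' @param divergence Range (length-2) or vector of per-site substitution
#'   rates drawn per instance; all values in \[0, 0.3\].
#' @param length_jitter Range of the truncation fraction applied per copy
#'   (5'/3' clipping), in \[0, 1).
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, order, consensus_length, n_instances,
                        divergence = c(0, 0.1), length_jitter = c(0, 0.3)) {
  order <- match.arg(order, .rm_orders)
  if (consensus_length < 50L)
    stop("consensus_length must be >= 50 (got ", consensus_length, ")")
  if (n_instances < 1L) stop("n_instances must be >= 1")
  if (any(divergence < 0) || any(divergence > 0.3))
    stop("divergence rates must lie in [0, 0.3]")
  if (any(length_jitter < 0) || any(length_jitter >= 1))
    stop("length_jitter must lie in [0, 1)")
  structure(list(name = name, order = order,
                 consensus_length = as.integer(consensus_length),
                 n_instances = as.integer(n_instances),
                 divergence = divergence, length_jitter = length_jitter),
            class = "family_spec")
}

#' Default synthetic family panel
#'
#' Four orders x three families (young / mid / old divergence bands) x
#' `n_instances` copies, with divergence targets spanning 0-25% Kimura so
#' the 5%-wide Kimura bins \[0,5), \[5,10), ... \[20,25) are all populated.
#' Consensus lengths follow typical order biology (SINEs short, LINEs long).
#'
#' @param n_instances Copies per family (default 40, i.e. 480 TEs total).
#' @return List of [family_spec()] objects.
#' @export
default_family_specs <- function(n_instances = 40L) {
  lens <- c(DNA = 800L, LINE = 3000L, SINE = 300L, LTR = 1500L)
  bands <- list(young = c(0, 0.045), mid = c(0.05, 0.13), old = c(0.14, 0.21))
  specs <- list()
  for (ord in .rm_orders)
    for (b in names(bands))
      specs[[paste(ord, b, sep = "_")]] <- family_spec(
        name = paste0(ord, "_", b), order = ord,
        consensus_length = lens[[ord]], n_instances = n_instances,
        divergence = bands[[b]])
  unname(specs)
}

.random_dna <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

#' Generate family consensus sequences
#'
#' One i.i.d.-uniform nucleotide consensus per family; the same seed yields
#' identical output.
#'
#' @param specs List of [family_spec()] objects.
#' @param seed Integer RNG seed.
#' @return Named character vector of consensus sequences.
#' @export
generate_families <- function(specs, seed = NULL) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(
    vapply(specs, function(s) .random_dna(s$consensus_length), character(1L)),
    vapply(specs, `[[`, character(1L), "name"))
}

#' Mutate a consensus into one instance copy
#'
#' Applies independent per-site substitutions: a transition with probability
#' `rate_transition` (A<->G, C<->T) and a transversion with probability
#' `rate_transversion` (uniform over the two alternatives), then optionally
#' clips a `truncation` fraction of the length, split at random between the
#' 5' and 3' ends. The retained consensus window is recorded in the
#' `"offset"` attribute (0-based start within the consensus) so realized
#' divergence can be measured against the matching consensus slice.
#'
#' @param consensus Consensus nucleotide string.
#' @param rate_transition,rate_transversion Per-site substitution rates;
#'   their sum must stay below 0.75.
#' @param seed Optional RNG seed.
#' @param truncation Fraction of the consensus length to clip (default 0).
#' @return Instance sequence (character) with attribute `offset`.
#' @export
mutate_instance <- function(consensus, rate_transition, rate_transversion,
                            seed = NULL, truncation = 0) {
  if (rate_transition < 0 || rate_transversion < 0)
    stop("substitution rates must be >= 0")
  if (rate_transition + rate_transversion >= 0.75)
    stop("rate_transition + rate_transversion must be < 0.75")
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  n <- length(s)
  u <- stats::runif(n)
  ts <- u < rate_transition
  tv <- !ts & u < rate_transition + rate_transversion
  if (any(ts)) s[ts] <- .TRANSITION[s[ts]]
  if (any(tv)) {
    pick <- stats::runif(sum(tv)) < 0.5
    alts <- vapply(seq_len(sum(tv)), function(i)
      .TRANSVERSIONS[[s[tv][i]]][if (pick[i]) 1L else 2L], character(1L))
    s[tv] <- alts
  }
  keep <- max(1L, round(n * (1 - truncation)))
  off <- if (keep < n) sample.int(n - keep + 1L, 1L) - 1L else 0L
  out <- paste(s[(off + 1L):(off + keep)], collapse = "")
  attr(out, "offset") <- off
  out
}

#' Draw synthetic TE instances (sequences + truth metadata)
#'
#' Realizes every copy of every family: draws a per-instance divergence rate
#' from the family's band (transition:transversion ratio `ts_tv_ratio`),
#' mutates and truncates the consensus, and computes the realized Kimura
#' distance of each copy against its consensus slice with
#' [kimura_distance()]. A fraction `prop_short` of copies is clipped below
#' 100 bp so the downstream length filter has work to do.
#'
#' @param specs List of [family_spec()] objects.
#' @param seed Integer RNG seed.
#' @param ts_tv_ratio Transition:transversion rate ratio (default 2).
#' @param prop_short Fraction of copies truncated to 50-99 bp (default 0.05).
#' @return List with `instances` (data frame: family metadata, realized
#'   `kimura`, `strand`, `score`, `perc_div`, `length`), `sequences`
#'   (character vector, one per instance, same order) and `consensi`.
#' @export
draw_te_instances <- function(specs, seed = NULL, ts_tv_ratio = 2,
                              prop_short = 0.05) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  if (!is.null(seed)) set.seed(seed)
  consensi <- stats::setNames(
    vapply(specs, function(s) .random_dna(s$consensus_length), character(1L)),
    vapply(specs, `[[`, character(1L), "name"))
  rows <- list()
  seqs <- character(0L)
  for (s in specs) {
    cons <- consensi[[s$name]]
    L <- s$consensus_length
    for (i in seq_len(s$n_instances)) {
      rate <- if (length(s$divergence) == 2L)
        stats::runif(1L, s$divergence[1L], s$divergence[2L])
      else sample(s$divergence, 1L)
      r_ts <- rate * ts_tv_ratio / (ts_tv_ratio + 1)
      r_tv <- rate / (ts_tv_ratio + 1)
      trunc_frac <- stats::runif(1L, s$length_jitter[1L], s$length_jitter[2L])
      if (stats::runif(1L) < prop_short)
        trunc_frac <- 1 - sample(50:99, 1L) / L
      inst <- mutate_instance(cons, r_ts, r_tv, truncation = trunc_frac)
      off <- attr(inst, "offset")
      len <- nchar(inst)
      cslice <- substr(cons, off + 1L, off + len)
      kim <- kimura_distance(cslice, inst)
      mism <- sum(strsplit(cslice, "")[[1L]] != strsplit(inst, "")[[1L]])
      rows[[length(rows) + 1L]] <- data.frame(
        order = s$order, family = s$name,
        subfamily = s$name,
        score = as.integer(round(len * (1 - rate))),
        kimura = round(kim, 2L),
        strand = sample(c("+", "-"), 1L),
        perc_div = round(100 * mism / len, 2L),
        length = len, stringsAsFactors = FALSE)
      seqs <- c(seqs, as.character(inst))
    }
  }
  inst <- do.call(rbind, rows)
  rownames(inst) <- NULL
  list(instances = inst, sequences = seqs, consensi = consensi)
}

#' Plant TE instances into a synthetic genome and annotate them
#'
#' Builds a single-chromosome genome of `genome_length` bp: instance copies
#' from [draw_te_instances()] are placed in random order at non-overlapping
#' loci separated by random uniform spacers, the remainder is filled with
#' random background sequence, and RepeatMasker-style `.align` / `.out`
#' files plus a truth TSV are written if `out_dir` is given. The realized
#' Kimura distance of each copy is written into the `.align` block, so
#' `parse_align()` on the emitted file reproduces the truth table exactly.
#'
#' @param genome_length Total genome length in bp.
#' @param specs List of [family_spec()]s (default [default_family_specs()]).
#' @param spacer_range Uniform range of inter-TE spacer lengths in bp.
#' @param seed Integer RNG seed (determinism: same seed, same genome).
#' @param out_dir If non-`NULL`, write `genome.fa`, `annotation.align`,
#'   `annotation.out`, `truth_instances.tsv` and `library.fa` there.
#' @param chrom_name Chromosome name (single-chromosome genome).
#' @param ts_tv_ratio,prop_short Passed to [draw_te_instances()].
#' @return A `planted_genome` object: list with `genome` (named character),
#'   `instances` (truth data frame with `te_id`), `library` (a
#'   [build_te_library()] result), `consensi` and `files`.
#' @export
plant_and_annotate <- function(genome_length = 2e6,
                               specs = default_family_specs(),
                               spacer_range = c(200L, 2000L),
                               seed = NULL, out_dir = NULL,
                               chrom_name = "chr1",
                               ts_tv_ratio = 2, prop_short = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  drawn <- draw_te_instances(specs, seed = NULL, ts_tv_ratio = ts_tv_ratio,
                             prop_short = prop_short)
  inst <- drawn$instances
  seqs <- drawn$sequences
  n <- nrow(inst)
  ord <- sample.int(n)
  inst <- inst[ord, , drop = FALSE]
  seqs <- seqs[ord]
  spacers <- sample(spacer_range[1L]:spacer_range[2L], n, replace = TRUE)
  total <- sum(inst$length) + sum(spacers)
  if (total > genome_length)
    stop("insufficient genome length: need >= ", total, " bp, got ",
         genome_length)
  starts <- cumsum(spacers) + c(0L, cumsum(inst$length))[seq_len(n)]
  inst$chrom <- chrom_name
  inst$start <- as.integer(starts)
  inst$end <- as.integer(starts + inst$length)
  pieces <- character(2L * n + 1L)
  pieces[2L * seq_len(n) - 1L] <- vapply(spacers, .random_dna, character(1L))
  pieces[2L * seq_len(n)] <- seqs
  pieces[2L * n + 1L] <- .random_dna(genome_length - total)
  genome <- stats::setNames(paste(pieces, collapse = ""), chrom_name)
  inst$te_id <- make_te_id(inst)
  cols <- c("chrom", "start", "end", "order", "family", "subfamily", "score",
            "kimura", "strand", "perc_div", "length", "te_id")
  inst <- inst[, cols]
  rownames(inst) <- NULL

  lib <- build_te_library(genome, inst)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      genome = file.path(out_dir, "genome.fa"),
      align = file.path(out_dir, "annotation.align"),
      out = file.path(out_dir, "annotation.out"),
      truth = file.path(out_dir, "truth_instances.tsv"),
      bed = file.path(out_dir, "library.bed"),
      fasta = file.path(out_dir, "library.fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome), files$genome)
    write_rm_align(inst, files$align,
                   chrom_sizes = stats::setNames(genome_length, chrom_name))
    write_rm_out(inst, files$out)
    utils::write.table(inst, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_bed6(inst, files$bed)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(lib$sequences), files$fasta)
  }

  structure(list(genome = genome, instances = inst, library = lib,
                 consensi = drawn$consensi, files = files),
            class = "planted_genome")
}

#' @export
print.planted_genome <- function(x, ...) {
  cat("Synthetic genome:", nchar(x$genome[[1L]]), "bp,",
      nrow(x$instances), "planted TE instances\n")
  cat("  Kimura range:",
      paste(round(range(x$instances$kimura), 1L), collapse = "-"), "%\n")
  cat("  < 100 bp:", sum(x$instances$length < 100L), "instances\n")
  invisible(x)
}
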