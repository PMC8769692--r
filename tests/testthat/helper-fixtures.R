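# Shared fixtures, built in code at test time.

# a hand-written single-block RepeatMasker .align fixture:
# coords 101-200 (+ strand), L1TestA#LINE/L1, score 739, Kimura 5.20
align_fixture_lines <- function() {
  c("739 12.50 0.00 0.00 chr1 101 200 (199800) L1TestA#LINE/L1 1 100 (0) m_b1s001i0 1",
    "",
    "  chr1             101 CCCTAACCCT 110",
    "                       i v",
    "  L1TestA            1 CCTTAACCCC 10",
    "",
    "Matrix = 20p41g.matrix",
    "Kimura (with divCpGMod) = 5.20",
    "Transitions / transversions = 2.00 (2/1)",
    "Gap_init rate = 0.00, avg. gap size = 0.00",
    "")
}

write_align_fixture <- function(lines = align_fixture_lines()) {
  f <- tempfile(fileext = ".align")
  writeLines(lines, f)
  f
}

# minimal instance table for design-level tests (no genome needed)
toy_instances <- function(n = 40L, length = 1000L, kimura = 10) {
  d <- data.frame(chrom = "chr1", start = seq_len(n) * 2000L,
                  end = seq_len(n) * 2000L + length,
                  order = rep(c("DNA", "LINE", "SINE", "LTR"),
                              length.out = n),
                  family = "fam", subfamily = "sub", score = 100L,
                  kimura = kimura, strand = "+", length = length,
                  stringsAsFactors = FALSE)
  d$te_id <- make_te_id(d)
  d
}

# small two-family library with controlled shared sequence:
# famA/famB young (near-identical copies), famC diverged
shared_sequence_library <- function(seed = 101L) {
  set.seed(seed)
  cons <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  consC <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
  seqs <- c(A1 = cons,
            A2 = cons,                                   # identical twin
            B1 = mutate_instance(consC, 0.1, 0.05, seed = 1)[1L],
            B2 = mutate_instance(consC, 0.1, 0.05, seed = 2)[1L])
  inst <- data.frame(chrom = "chrT",
                     start = c(0L, 1000L, 2000L, 3000L),
                     end = c(0L, 1000L, 2000L, 3000L) + nchar(seqs),
                     order = "LINE", family = c("A", "A", "C", "C"),
                     subfamily = c("A", "A", "C", "C"), score = 500L,
                     kimura = c(0, 0, 16, 16), strand = "+",
                     length = nchar(seqs), stringsAsFactors = FALSE)
  inst$te_id <- make_te_id(inst)
  structure(list(instances = inst,
                 sequences = stats::setNames(unname(seqs), inst$te_id)),
            class = "te_library")
}

# FASTQ writer for hand-made reads
write_test_fastq <- function(seqs, path = tempfile(fileext = ".fastq"),
                             quals = NULL) {
  if (length(seqs) == 0L) {
    writeLines(character(), path)
    return(path)
  }
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  out <- character(4L * length(seqs))
  out[seq(1, length(out), 4)] <- paste0("@r", seq_along(seqs))
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  path
}

# brute-force Benjamini-Hochberg, independent of p.adjust
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- Inf
  for (i in n:1) {
    cummin_rev <- min(cummin_rev, p[o[i]] * n / i)
    adj[o[i]] <- min(1, cummin_rev)
  }
  adj
}

# brute-force EM by direct fixed-point iteration over reads (no class
# collapapsing), independent of em_reassign's implementation
em_brute_force <- function(read_sets, n_te, iters = 2000L) {
  ab <- rep(1 / n_te, n_te)
  for (it in seq_len(iters)) {
    counts <- numeric(n_te)
    for (s in read_sets) {
      w <- ab[s]
      counts[s] <- counts[s] + w / sum(w)
    }
    ab <- counts / length(read_sets)
  }
  counts
}
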