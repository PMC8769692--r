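# FASTQ read emission from a simulated count matrix.
#
# Single-end reads are sampled uniformly over valid start positions; for
# paired-end data the fragment length is drawn from a Gaussian with mean
# 250 bp and SD 25 bp (truncated to [read_length, TE length]) and the two
# 100-bp mates read the fragment ends, mate 2 reverse-complemented.
# Sequencing errors are optional: with an empirical per-cycle quality
# profile, base qualities are drawn per cycle and a substitution is
# introduced with probability 10^(-Q/10) per base.

.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0L))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# flatten an integer quality matrix (cycles x reads) to phred-33 strings
.qual_strings <- function(qmat) {
  rl <- nrow(qmat)
  big <- rawToChar(as.raw(as.vector(qmat) + 33L))
  substring(big, seq(1L, nchar(big), by = rl), seq(rl, nchar(big), by = rl))
}

# draw per-cycle qualities and inject substitution errors; returns
# list(seqs, quals)
.apply_error_model <- function(seqs, rl, error_model, profile) {
  n <- length(seqs)
  if (error_model == "none" || n == 0L)
    return(list(seqs = seqs, quals = rep(strrep("I", rl), n)))
  stopifnot(inherits(profile, "quality_profile"))
  if (profile$read_length < rl)
    stop("quality profile shorter than the read length")
  qmat <- matrix(0L, nrow = rl, ncol = n)
  for (cyc in seq_len(rl)) {
    d <- profile$cycles[[cyc]]
    qmat[cyc, ] <- d$q[sample.int(length(d$q), n, replace = TRUE,
                                  prob = d$p)]
  }
  perr <- 10^(-qmat / 10)
  hit <- matrix(stats::runif(rl * n), nrow = rl) < perr
  if (any(hit)) {
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = rl)
    idx <- which(hit)
    orig <- chars[idx]
    # uniform over the 3 alternative bases
    alt <- vapply(orig, function(b) sample(setdiff(.DNA, b), 1L), character(1L))
    chars[idx] <- alt
    seqs <- apply(chars, 2L, paste, collapse = "")
  }
  list(seqs = seqs, quals = .qual_strings(qmat))
}

#' Emit FASTQ reads for a simulated count matrix
#'
#' Writes, per sample, exactly the number of reads (SE) or fragments (PE)
#' recorded in the count matrix, drawn from the TE library sequences. Read
#' names encode the origin TE id (`te_id;sample;index`) for truth tracking,
#' and a per-(TE, sample) origin log is returned alongside the file paths so
#' read masses can be reconciled cell-by-cell with the count matrix.
#'
#' @param counts Count matrix from [simulate_count_matrix()].
#' @param library A `te_library`.
#' @param design The [simulation_design()] the counts were drawn from.
#' @param out_dir Directory for the FASTQ files (`<sample>.fastq` or
#'   `<sample>_1.fastq` / `_2.fastq` for paired ends).
#' @param seed Optional RNG seed.
#' @param error_model `"none"` (error-free, constant Q40) or `"profile"`
#'   (empirical qualities + Phred-rate substitutions).
#' @param quality_profile A [learn_quality_profile()] object, required for
#'   `error_model = "profile"`.
#' @param fragment_mean,fragment_sd Gaussian fragment-length model for
#'   paired ends (defaults 250 and 25 bp).
#' @return A `sim_reads` object: list with `files` (data frame sample/
#'   mate1/mate2), `origin` (data frame te_id/sample/n) and `fragments`
#'   (numeric vector of realized PE fragment lengths, empty for SE).
#' @export
simulate_reads <- function(counts, library, design, out_dir,
                           seed = NULL, error_model = c("none", "profile"),
                           quality_profile = NULL,
                           fragment_mean = 250, fragment_sd = 25) {
  stopifnot(inherits(design, "sim_design"))
  error_model <- match.arg(error_model)
  if (error_model == "profile" && is.null(quality_profile))
    stop("error_model = 'profile' needs a quality_profile")
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- library$sequences
  miss <- setdiff(rownames(counts), names(seqs))
  if (length(miss) > 0L)
    stop("TE(s) absent from library: ", paste(utils::head(miss, 3L),
                                              collapse = ", "))
  rl <- design$read_length
  paired <- design$paired
  files <- data.frame(sample = colnames(counts),
                      mate1 = NA_character_, mate2 = NA_character_,
                      stringsAsFactors = FALSE)
  origin <- list()
  frag_all <- numeric(0L)
  for (j in seq_len(ncol(counts))) {
    smp <- colnames(counts)[j]
    cells <- counts[, j]
    cells <- cells[cells > 0L]
    te <- rep(names(cells), cells)
    n <- length(te)
    tseq <- seqs[te]
    L <- nchar(tseq)
    nm <- sprintf("%s;%s;%d", te, smp, seq_len(n))
    if (!paired) {
      start <- floor(stats::runif(n) * (L - rl + 1L))
      reads <- substring(tseq, start + 1L, start + rl)
      em <- .apply_error_model(reads, rl, error_model, quality_profile)
      f1 <- file.path(out_dir, paste0(smp, ".fastq"))
      .write_fastq(nm, em$seqs, em$quals, f1)
      files$mate1[j] <- f1
    } else {
      frag <- round(stats::rnorm(n, fragment_mean, fragment_sd))
      frag <- pmin(pmax(frag, rl), L)
      start <- floor(stats::runif(n) * (L - frag + 1L))
      m1 <- substring(tseq, start + 1L, start + rl)
      m2 <- .revcomp(substring(tseq, start + frag - rl + 1L, start + frag))
      e1 <- .apply_error_model(m1, rl, error_model, quality_profile)
      e2 <- .apply_error_model(m2, rl, error_model, quality_profile)
      f1 <- file.path(out_dir, paste0(smp, "_1.fastq"))
      f2 <- file.path(out_dir, paste0(smp, "_2.fastq"))
      .write_fastq(paste0(nm, "/1"), e1$seqs, e1$quals, f1)
      .write_fastq(paste0(nm, "/2"), e2$seqs, e2$quals, f2)
      files$mate1[j] <- f1
      files$mate2[j] <- f2
      frag_all <- c(frag_all, frag)
    }
    if (length(cells) > 0L)
      origin[[smp]] <- data.frame(te_id = names(cells), sample = smp,
                                  n = as.integer(cells),
                                  stringsAsFactors = FALSE)
  }
  origin <- if (length(origin) > 0L) do.call(rbind, origin) else
    data.frame(te_id = character(), sample = character(), n = integer())
  rownames(origin) <- NULL
  structure(list(files = files, origin = origin, fragments = frag_all,
                 layout = design$layout),
            class = "sim_reads")
}

.write_fastq <- function(names, seqs, quals, path) {
  if (length(seqs) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  out <- character(4L * length(seqs))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", names)
  out[seq(2L, length(out), by = 4L)] <- seqs
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- quals
  writeLines(out, path)
  invisible(path)
}

# minimal FASTQ reader: list(names, seqs, quals)
.read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    return(list(names = character(), seqs = character(),
                quals = character()))
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  i <- seq(1L, length(lines), by = 4L)
  list(names = sub("^@", "", lines[i]), seqs = lines[i + 1L],
       quals = lines[i + 3L])
}

#' Learn an empirical per-cycle quality profile from a FASTQ file
#'
#' Tallies the observed Phred quality scores at every cycle of the input
#' reads into one categorical distribution per cycle. Simulated errors then
#' reproduce the real experiment's error structure without any GC-bias
#' modelling.
#'
#' @param fastq Path to a FASTQ file.
#' @param read_length Target read length; all input reads must be at least
#'   this long (default: length of the first read).
#' @return A `quality_profile`: list with `read_length` and `cycles`, one
#'   `list(q, p)` categorical distribution per cycle.
#' @export
learn_quality_profile <- function(fastq, read_length = NULL) {
  fq <- .read_fastq(fastq)
  if (length(fq$seqs) == 0L) stop("empty FASTQ: ", fastq)
  if (is.null(read_length)) read_length <- nchar(fq$quals[1L])
  if (any(nchar(fq$quals) < read_length))
    stop("reads shorter than the target read length (", read_length, " bp)")
  qmat <- matrix(unlist(lapply(fq$quals, function(q)
    utf8ToInt(substr(q, 1L, read_length)) - 33L), use.names = FALSE),
    nrow = read_length)
  cycles <- lapply(seq_len(read_length), function(cyc) {
    tab <- table(qmat[cyc, ])
    list(q = as.integer(names(tab)), p = as.numeric(tab) / sum(tab))
  })
  structure(list(read_length = read_length, cycles = cycles),
            class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  mq <- vapply(x$cycles, function(d) sum(d$q * d$p), numeric(1L))
  cat("Quality profile:", x$read_length, "cycles; mean Q",
      round(mean(mq), 1L), "\n")
  invisible(x)
}
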