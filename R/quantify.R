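# Baseline quantifier: exact k-mer seeding + Hamming verification +
# EM re-assignment of multi-mapping reads.
#
# This is a desk-scale stand-in for the aligners used by the external tools,
# not a general aligner: substitutions only (matching the simulator), and
# reads hitting more than `multimap_cap` loci are discarded (the cap default
# 100 echoes the common tool filter removing reads that map to more than 100
# possible loci).

#' Build an exact k-mer index over a TE library
#'
#' Indexes every k-mer at every position of every library sequence. Reads
#' are later seeded with `floor(read_length / k)` disjoint k-mers, so any
#' read with fewer mismatches than seeds is guaranteed a seed hit.
#'
#' @param library A `te_library` (or named character vector of sequences).
#' @param k Seed length (default 31).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(library, k = 31L) {
  seqs <- if (inherits(library, "te_library")) library$sequences else library
  lens <- nchar(seqs)
  idx_te <- integer(0L); idx_pos <- integer(0L); kmers <- character(0L)
  parts_te <- list(); parts_pos <- list(); parts_km <- list()
  for (t in seq_along(seqs)) {
    if (lens[t] < k) next
    npos <- lens[t] - k + 1L
    parts_km[[length(parts_km) + 1L]] <-
      substring(seqs[t], seq_len(npos), seq_len(npos) + k - 1L)
    parts_te[[length(parts_te) + 1L]] <- rep.int(t, npos)
    parts_pos[[length(parts_pos) + 1L]] <- seq_len(npos) - 1L
  }
  kmers <- unlist(parts_km, use.names = FALSE)
  idx_te <- unlist(parts_te, use.names = FALSE)
  idx_pos <- unlist(parts_pos, use.names = FALSE)
  uk <- unique(kmers)
  gid <- match(kmers, uk)
  ord <- order(gid)
  cnt <- tabulate(gid, nbins = length(uk))
  start <- cumsum(c(1L, cnt[-length(cnt)]))
  structure(list(uk = uk, occ_te = idx_te[ord], occ_pos = idx_pos[ord],
                 grp_start = start, grp_count = cnt,
                 te_ids = names(seqs), seqs = unname(seqs),
                 lens = unname(lens), k = k),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index: k =", x$k, ",", length(x$te_ids), "sequences,",
      length(x$occ_te), "indexed positions\n")
  invisible(x)
}

# candidate (read, te) pairs for one orientation of a read set;
# returns data.frame(read, te, mm)
.seed_and_verify <- function(reads, index, max_mismatches) {
  k <- index$k
  rl <- nchar(reads[1L])
  n_seeds <- max(1L, rl %/% k)
  offsets <- (seq_len(n_seeds) - 1L) * k          # 0-based in-read offsets
  n <- length(reads)
  cand_read <- integer(0L); cand_te <- integer(0L); cand_off <- integer(0L)
  for (o in offsets) {
    seeds <- substring(reads, o + 1L, o + k)
    qid <- match(seeds, index$uk)
    hit <- which(!is.na(qid))
    if (length(hit) == 0L) next
    g <- qid[hit]
    cnt <- index$grp_count[g]
    occ <- sequence(cnt) - 1L + rep.int(index$grp_start[g], cnt)
    cand_read <- c(cand_read, rep.int(hit, cnt))
    cand_te <- c(cand_te, index$occ_te[occ])
    cand_off <- c(cand_off, index$occ_pos[occ] - o)
  }
  if (length(cand_read) == 0L)
    return(data.frame(read = integer(), te = integer(), mm = integer()))
  ok <- cand_off >= 0L & cand_off + rl <= index$lens[cand_te]
  cand_read <- cand_read[ok]; cand_te <- cand_te[ok]; cand_off <- cand_off[ok]
  key <- paste(cand_read, cand_te, cand_off)
  keep <- !duplicated(key)
  cand_read <- cand_read[keep]; cand_te <- cand_te[keep]
  cand_off <- cand_off[keep]
  if (length(cand_read) == 0L)
    return(data.frame(read = integer(), te = integer(), mm = integer()))
  # Hamming verification over equal-length windows, in blocks
  mm <- integer(length(cand_read))
  bs <- 20000L
  for (b in seq(1L, length(cand_read), by = bs)) {
    ii <- b:min(b + bs - 1L, length(cand_read))
    r1 <- charToRaw(paste(reads[cand_read[ii]], collapse = ""))
    r2 <- charToRaw(paste(substring(index$seqs[cand_te[ii]],
                                    cand_off[ii] + 1L,
                                    cand_off[ii] + rl), collapse = ""))
    mm[ii] <- as.integer(colSums(matrix(r1 != r2, nrow = rl)))
  }
  d <- data.frame(read = cand_read, te = cand_te, mm = mm)
  d <- d[d$mm <= max_mismatches, , drop = FALSE]
  # best mismatch count per (read, te) over alternative offsets
  if (nrow(d) > 0L) {
    d <- d[order(d$read, d$te, d$mm), , drop = FALSE]
    d <- d[!duplicated(d[, c("read", "te")]), , drop = FALSE]
  }
  d
}

#' Map reads to the TE library with the baseline seed-and-verify mapper
#'
#' For every read (or read pair), finds all library loci where it matches
#' with at most `max_mismatches` substitutions. Mates of a pair must hit the
#' same TE. Reads with more than `multimap_cap` candidate loci are discarded
#' and counted; unmapped reads are tallied.
#'
#' @param fastq1 Path to the (first-mate) FASTQ file.
#' @param library A `te_library`, or a prebuilt [build_kmer_index()].
#' @param fastq2 Optional second-mate FASTQ for paired ends.
#' @param max_mismatches Maximum Hamming distance per mate (default 2).
#' @param multimap_cap Maximum candidate loci per read/pair (default 100).
#' @param k Seed length when `library` is not already an index.
#' @return A `candidate_alignments` object: list with `cand` (data frame
#'   `read`, `te`, `mm`), `te_ids`, `n_reads`, `n_unmapped`, `n_discarded`.
#' @export
map_reads_baseline <- function(fastq1, library, fastq2 = NULL,
                               max_mismatches = 2L, multimap_cap = 100L,
                               k = 31L) {
  index <- if (inherits(library, "kmer_index")) library
           else build_kmer_index(library, k = k)
  r1 <- .read_fastq(fastq1)
  n <- length(r1$seqs)
  if (n == 0L)
    return(structure(list(cand = data.frame(read = integer(), te = integer(),
                                            mm = integer()),
                          te_ids = index$te_ids, n_reads = 0L,
                          n_unmapped = 0L, n_discarded = 0L),
                     class = "candidate_alignments"))
  c1 <- .seed_and_verify(toupper(r1$seqs), index, max_mismatches)
  if (!is.null(fastq2)) {
    r2 <- .read_fastq(fastq2)
    if (length(r2$seqs) != n) stop("mate files differ in read count")
    c2 <- .seed_and_verify(.revcomp(toupper(r2$seqs)), index, max_mismatches)
    k1 <- paste(c1$read, c1$te); k2 <- paste(c2$read, c2$te)
    shared <- intersect(k1, k2)
    m1 <- c1[match(shared, k1), , drop = FALSE]
    m2 <- c2[match(shared, k2), , drop = FALSE]
    cand <- data.frame(read = m1$read, te = m1$te, mm = m1$mm + m2$mm)
  } else {
    cand <- c1
  }
  ncand <- tabulate(cand$read, nbins = n)
  over <- which(ncand > multimap_cap)
  if (length(over) > 0L)
    cand <- cand[!(cand$read %in% over), , drop = FALSE]
  structure(list(cand = cand, te_ids = index$te_ids, n_reads = n,
                 n_unmapped = sum(ncand == 0L),
                 n_discarded = length(over)),
            class = "candidate_alignments")
}

#' @export
print.candidate_alignments <- function(x, ...) {
  cat("Candidate alignments:", x$n_reads, "reads;",
      x$n_unmapped, "unmapped,", x$n_discarded, "discarded (cap)\n")
  invisible(x)
}

#' Redistribute multi-mapping reads by expectation maximization
#'
#' Starting from uniform abundances, iterates E (responsibility of locus
#' \eqn{t} for read \eqn{r} proportional to the current abundance of
#' \eqn{t}) and M (abundance = summed responsibilities) steps until the
#' largest absolute change in per-TE counts falls below `tol` or `max_iter`
#' iterations. The per-TE counts sum to the retained read count exactly.
#' `assignment = "random"` instead hard-assigns each multi-mapper uniformly
#' at random among its candidates (the random-assignment strategy some
#' family-level tools use), yielding integer counts.
#'
#' @param candidates A [map_reads_baseline()] result.
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Convergence tolerance on per-TE counts (default 1e-6).
#' @param assignment `"em"` (default) or `"random"`.
#' @param trace Return the log-likelihood trace as attribute `"loglik"`?
#' @return Named numeric vector of per-TE counts covering every library TE
#'   (zeros included); fractional under EM.
#' @export
em_reassign <- function(candidates, max_iter = 200L, tol = 1e-6,
                        assignment = c("em", "random"), trace = FALSE) {
  assignment <- match.arg(assignment)
  cand <- candidates$cand
  tids <- candidates$te_ids
  out <- stats::setNames(numeric(length(tids)), tids)
  if (nrow(cand) == 0L) return(out)
  # collapse reads to equivalence classes over candidate TE sets
  sets <- split(cand$te, cand$read)
  sets <- lapply(sets, sort)
  key <- vapply(sets, paste, character(1L), collapse = ",")
  if (assignment == "random") {
    pick <- vapply(sets, function(s)
      if (length(s) == 1L) s else s[sample.int(length(s), 1L)], integer(1L))
    tb <- tabulate(pick, nbins = length(tids))
    out[] <- tb
    return(out)
  }
  uk <- unique(key)
  cls <- match(key, uk)
  n_c <- tabulate(cls, nbins = length(uk))
  cls_sets <- sets[match(uk, key)]
  cl_len <- lengths(cls_sets)
  flat_te <- unlist(cls_sets, use.names = FALSE)
  flat_cls <- rep.int(seq_along(uk), cl_len)
  N <- sum(n_c)
  T_ <- length(tids)
  ab <- rep(1 / T_, T_)
  counts <- ab * 0
  prev <- rep(Inf, T_)
  ll <- numeric(0L)
  n_cls <- length(uk)
  for (it in seq_len(max_iter)) {
    w <- ab[flat_te]
    denom <- numeric(n_cls)
    dsum <- rowsum(w, flat_cls)              # groups sorted numerically
    denom[as.integer(rownames(dsum))] <- dsum[, 1L]
    resp <- w / denom[flat_cls]
    add <- resp * n_c[flat_cls]
    counts <- numeric(T_)
    csum <- rowsum(add, flat_te)
    counts[as.integer(rownames(csum))] <- csum[, 1L]
    if (trace) ll <- c(ll, sum(n_c * log(denom)))
    if (max(abs(counts - prev)) < tol) break
    prev <- counts
    ab <- counts / N
  }
  out[] <- counts
  if (trace) attr(out, "loglik") <- ll
  out
}

#' Quantify all samples of a simulated experiment with the baseline mapper
#'
#' Convenience wrapper: builds the k-mer index once, maps every sample's
#' FASTQ file(s) and runs [em_reassign()], returning a unified (fractional)
#' count matrix over the full library.
#'
#' @param files Data frame with columns `sample`, `mate1` and optionally
#'   `mate2` (as returned in `simulate_reads()$files`).
#' @param library A `te_library`.
#' @inheritParams map_reads_baseline
#' @inheritParams em_reassign
#' @return Numeric matrix, rows = all library TE ids, columns = samples,
#'   with attributes `n_unmapped` and `n_discarded` (per-sample vectors).
#' @export
quantify_baseline <- function(files, library, max_mismatches = 2L,
                              multimap_cap = 100L, k = 31L,
                              assignment = c("em", "random")) {
  assignment <- match.arg(assignment)
  index <- build_kmer_index(library, k = k)
  mats <- matrix(0, nrow = length(index$te_ids), ncol = nrow(files),
                 dimnames = list(index$te_ids, files$sample))
  unm <- disc <- integer(nrow(files))
  paired <- "mate2" %in% names(files) && !all(is.na(files$mate2))
  for (j in seq_len(nrow(files))) {
    ca <- map_reads_baseline(files$mate1[j], index,
                             fastq2 = if (paired) files$mate2[j] else NULL,
                             max_mismatches = max_mismatches,
                             multimap_cap = multimap_cap)
    mats[, j] <- em_reassign(ca, assignment = assignment)
    unm[j] <- ca$n_unmapped; disc[j] <- ca$n_discarded
  }
  attr(mats, "n_unmapped") <- stats::setNames(unm, files$sample)
  attr(mats, "n_discarded") <- stats::setNames(disc, files$sample)
  mats
}

#' Read candidate alignments from a SAM file
#'
#' Parses the mandatory columns of a plain-text SAM file into the candidate
#' structure used by [em_reassign()]: one candidate per reported alignment,
#' reference names taken as TE ids. `NM` tags supply mismatch counts when
#' present (0 otherwise); unmapped records (flag 0x4) are tallied.
#'
#' @param sam_file Path to a SAM text file.
#' @param te_ids TE universe for the output counts (default: references seen
#'   in the header/alignments).
#' @return A `candidate_alignments` object.
#' @export
read_sam_candidates <- function(sam_file, te_ids = NULL) {
  lines <- readLines(sam_file, warn = FALSE)
  hdr <- grepl("^@", lines)
  sq <- lines[hdr][grepl("^@SQ", lines[hdr])]
  refs <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
  lines <- lines[!hdr & nzchar(lines)]
  if (length(lines) == 0L && is.null(te_ids) && length(refs) == 0L)
    stop("empty SAM file: ", sam_file)
  qname <- character(length(lines)); rname <- character(length(lines))
  flagv <- integer(length(lines)); nm <- integer(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed SAM row ", i)
    qname[i] <- f[1L]; flagv[i] <- as.integer(f[2L]); rname[i] <- f[3L]
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    nm[i] <- if (length(tag) > 0L) as.integer(sub("^NM:i:", "", tag[1L])) else 0L
  }
  mapped <- bitwAnd(flagv, 4L) == 0L & rname != "*"
  if (is.null(te_ids)) te_ids <- unique(c(refs, rname[mapped]))
  uq <- unique(qname)
  d <- data.frame(read = match(qname[mapped], uq),
                  te = match(rname[mapped], te_ids),
                  mm = nm[mapped])
  if (anyNA(d$te)) stop("SAM reference absent from te_ids")
  d <- d[order(d$read, d$te, d$mm), , drop = FALSE]
  d <- d[!duplicated(paste(d$read, d$te)), , drop = FALSE]
  structure(list(cand = d, te_ids = te_ids, n_reads = length(uq),
                 n_unmapped = length(setdiff(uq, qname[mapped])),
                 n_discarded = 0L),
            class = "candidate_alignments")
}
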