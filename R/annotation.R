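# RepeatMasker annotation handling: .align / .out parsing, .align -> .out
# translation, BED export and per-instance reference library construction.
#
# Coordinate discipline: both RepeatMasker formats print 1-based inclusive
# coordinates; everything inside the package is 0-based half-open, and the
# conversion happens only here, at the format boundary.

.rm_orders <- c("DNA", "LINE", "SINE", "LTR")

# split "name#class/family" into subfamily/order/family; family falls back to
# the class when the annotation gives no slash-separated family.
.split_rm_name <- function(tag) {
  hash <- regexpr("#", tag, fixed = TRUE)
  subfam <- substr(tag, 1L, hash - 1L)
  cls <- substr(tag, hash + 1L, nchar(tag))
  slash <- regexpr("/", cls, fixed = TRUE)
  ord <- ifelse(slash > 0L, substr(cls, 1L, slash - 1L), cls)
  fam <- ifelse(slash > 0L, substr(cls, slash + 1L, nchar(cls)), cls)
  list(subfamily = subfam, order = ord, family = fam)
}

.is_int_tok <- function(x) grepl("^-?[0-9]+$", x)
.is_num_tok <- function(x) grepl("^-?[0-9]+(\\.[0-9]+)?$", x)

#' Parse a RepeatMasker `.align` file into TE instances
#'
#' Reads the alignment-block headers of a RepeatMasker `.align` file (score,
#' divergence, query coordinates, strand and `name#class/family` tag) and the
#' trailing `Kimura (with divCpGMod) = x` line of each block. Alignment body
#' lines are skipped. Coordinates are converted from the file's 1-based
#' inclusive convention to 0-based half-open.
#'
#' A block without a Kimura line yields an instance with `kimura = NA`
#' ("unknown"), which downstream instance selection excludes by default.
#'
#' @param align_file Path to a `.align` file.
#' @return Data frame of TE instances: `chrom`, `start`, `end`, `order`,
#'   `family`, `subfamily`, `score`, `kimura`, `strand`, `perc_div`,
#'   `length`, `te_id`.
#' @export
parse_align <- function(align_file) {
  lines <- readLines(align_file, warn = FALSE)
  n <- length(lines)
  recs <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) recs[[length(recs) + 1L]] <<- cur
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    kim <- regmatches(ln, regexec("^Kimura.*=\\s*([0-9]+(\\.[0-9]+)?)", ln))[[1L]]
    if (length(kim) > 0L) {
      if (!is.null(cur)) cur$kimura <- as.numeric(kim[2L])
      next
    }
    # candidate header: starts with an integer score and carries a '#' tag
    looks_header <- length(tok) >= 9L && .is_int_tok(tok[1L]) &&
      any(grepl("#", tok, fixed = TRUE))
    if (!looks_header) next
    ok <- length(tok) >= 12L &&
      all(.is_num_tok(tok[2:4])) &&
      all(.is_int_tok(tok[6:7])) &&
      grepl("^\\([0-9]+\\)$", tok[8L])
    if (!ok)
      stop("malformed .align header at line ", i, ": ", ln)
    flush()
    minus <- tok[9L] == "C"
    tag <- if (minus) tok[10L] else tok[9L]
    if (!grepl("#", tag, fixed = TRUE))
      stop("malformed .align header at line ", i,
           ": repeat tag lacks '#class/family'")
    nm <- .split_rm_name(tag)
    cur <- list(chrom = tok[5L],
                start = as.integer(tok[6L]) - 1L,
                end = as.integer(tok[7L]),
                order = nm$order, family = nm$family,
                subfamily = nm$subfamily,
                score = as.integer(tok[1L]),
                kimura = NA_real_,
                strand = if (minus) "-" else "+",
                perc_div = as.numeric(tok[2L]))
  }
  flush()
  if (length(recs) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      order = character(), family = character(),
                      subfamily = character(), score = integer(),
                      kimura = numeric(), strand = character(),
                      perc_div = numeric(), stringsAsFactors = FALSE)
    out$length <- integer()
    out$te_id <- character()
    return(out)
  }
  out <- do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  out$length <- out$end - out$start
  out$te_id <- make_te_id(out)
  rownames(out) <- NULL
  out
}

#' Parse a RepeatMasker `.out` file
#'
#' Reads the tabular `.out` annotation (3 header lines skipped). The `.out`
#' format carries no Kimura column, so `kimura` is `NA` for every instance.
#'
#' @param out_file Path to a `.out` file.
#' @return Data frame of TE instances, as [parse_align()] but with
#'   `kimura = NA` and `perc_div` taken from the divergence column.
#' @export
parse_out <- function(out_file) {
  lines <- readLines(out_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keep <- vapply(lines, function(ln) {
    .is_int_tok(strsplit(trimws(ln), "[ \t]+")[[1L]][1L])
  }, logical(1L), USE.NAMES = FALSE)
  lines <- lines[keep]
  if (length(lines) == 0L) return(parse_align(tempfile_empty()))
  recs <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(tok) < 14L || !all(.is_num_tok(tok[2:4])) ||
        !all(.is_int_tok(tok[6:7])))
      stop("malformed .out row ", i, ": ", lines[i])
    cls <- strsplit(tok[11L], "/", fixed = TRUE)[[1L]]
    data.frame(chrom = tok[5L],
               start = as.integer(tok[6L]) - 1L,
               end = as.integer(tok[7L]),
               order = cls[1L],
               family = if (length(cls) > 1L) cls[2L] else cls[1L],
               subfamily = tok[10L],
               score = as.integer(tok[1L]),
               kimura = NA_real_,
               strand = if (tok[9L] == "C") "-" else "+",
               perc_div = as.numeric(tok[2L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$length <- out$end - out$start
  out$te_id <- make_te_id(out)
  rownames(out) <- NULL
  out
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".align")
  writeLines(character(), f)
  f
}

#' Translate a `.align` annotation to the `.out` format
#'
#' Writes one `.out` row per alignment block of the input. The mapping is
#' bijective on the fields the `.out` format carries (coordinates, strand,
#' score, class/family/subfamily): parsing the emitted file recovers them
#' exactly. Duplicate coordinates in the input violate bijectivity and raise
#' an error.
#'
#' @param align_file Path to a `.align` file (or a parsed instance data
#'   frame from [parse_align()]).
#' @param out_file Path of the `.out` file to write.
#' @return Invisibly, `out_file`.
#' @export
align_to_out <- function(align_file, out_file) {
  inst <- if (is.data.frame(align_file)) align_file else parse_align(align_file)
  key <- paste(inst$chrom, inst$start, inst$end)
  if (anyDuplicated(key))
    stop("duplicate coordinates in annotation (bijectivity violated): ",
         key[duplicated(key)][1L])
  write_rm_out(inst, out_file)
  invisible(out_file)
}

#' Write TE instances as a RepeatMasker `.out` file
#'
#' @param instances Data frame of TE instances (internal 0-based half-open
#'   coordinates).
#' @param out_file Output path.
#' @return Invisibly, `out_file`.
#' @export
write_rm_out <- function(instances, out_file) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  pd <- instances$perc_div
  if (is.null(pd)) pd <- rep(0, nrow(instances))
  pd[is.na(pd)] <- 0
  cls <- ifelse(instances$order == instances$family, instances$order,
                paste0(instances$order, "/", instances$family))
  rows <- sprintf("%5d %5.1f  0.0  0.0  %s %d %d (0) %s %s %s %d %d (0) %d",
                  as.integer(instances$score), pd, instances$chrom,
                  instances$start + 1L, instances$end,
                  ifelse(instances$strand == "-", "C", "+"),
                  instances$subfamily, cls,
                  1L, instances$end - instances$start,
                  seq_len(nrow(instances)))
  writeLines(c(hdr, rows), out_file)
  invisible(out_file)
}

#' Write TE instances as a `.align`-style annotation
#'
#' Emits the alignment-block headers plus per-block Kimura lines in the
#' RepeatMasker `.align` layout (alignment bodies omitted — they are not
#' consumed anywhere in the pipeline). Blocks whose Kimura is unknown get no
#' Kimura line, so [parse_align()] round-trips them back to `NA`.
#'
#' @param instances Data frame of TE instances.
#' @param align_file Output path.
#' @param chrom_sizes Optional named vector of chromosome lengths used for
#'   the `(left)` field; purely cosmetic.
#' @return Invisibly, `align_file`.
#' @export
write_rm_align <- function(instances, align_file, chrom_sizes = NULL) {
  pd <- instances$perc_div
  if (is.null(pd)) pd <- ifelse(is.na(instances$kimura), 0, instances$kimura)
  pd[is.na(pd)] <- 0
  left <- if (!is.null(chrom_sizes))
    as.integer(chrom_sizes[instances$chrom]) - instances$end else 0L
  tag <- paste0(instances$subfamily, "#",
                ifelse(instances$order == instances$family, instances$order,
                       paste0(instances$order, "/", instances$family)))
  n <- nrow(instances)
  L <- instances$end - instances$start
  blocks <- character(0L)
  for (i in seq_len(n)) {
    strand_tok <- if (instances$strand[i] == "-")
      sprintf("C %s (0) %d 1", tag[i], L[i])
    else
      sprintf("%s 1 %d (0)", tag[i], L[i])
    hdr <- sprintf("%d %.2f 0.00 0.00 %s %d %d (%d) %s m_b1s001i%d %d",
                   as.integer(instances$score[i]), pd[i], instances$chrom[i],
                   instances$start[i] + 1L, instances$end[i],
                   if (length(left) > 1L) left[i] else left,
                   strand_tok, i, i)
    blk <- hdr
    if (!is.na(instances$kimura[i]))
      blk <- c(blk, "", sprintf("Kimura (with divCpGMod) = %.2f",
                                instances$kimura[i]))
    blocks <- c(blocks, blk, "")
  }
  writeLines(blocks, align_file)
  invisible(align_file)
}

#' Write TE instances as BED6
#'
#' BED output is 0-based half-open; the name column is the TE id.
#'
#' @param instances Data frame of TE instances.
#' @param bed_file Output path.
#' @return Invisibly, `bed_file`.
#' @export
write_bed6 <- function(instances, bed_file) {
  rows <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                  instances$chrom, instances$start, instances$end,
                  instances$te_id, as.integer(instances$score),
                  instances$strand)
  writeLines(rows, bed_file)
  invisible(bed_file)
}

#' Build the per-instance TE reference library
#'
#' Extracts the genomic subsequence `[start, end)` of every annotated TE
#' instance and returns it keyed by TE id, optionally writing the BED6
#' intervals and a library FASTA whose headers are the TE ids. By default the
#' forward-strand sequence is extracted regardless of the annotated strand
#' (mirroring `bedtools getfasta` without `-s`); `stranded = TRUE`
#' reverse-complements minus-strand instances.
#'
#' @param genome A `DNAStringSet`, a named character vector of chromosome
#'   sequences, or a path to a genome FASTA.
#' @param instances Data frame of TE instances (0-based half-open).
#' @param stranded Reverse-complement minus-strand instances?
#' @param bed_file,fasta_file Optional output paths.
#' @return A `te_library` object: list with `instances` (data frame) and
#'   `sequences` (named character vector, one entry per TE id).
#' @export
build_te_library <- function(genome, instances, stranded = FALSE,
                             bed_file = NULL, fasta_file = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
    genome <- stats::setNames(as.character(genome), names(genome))
  } else {
    chrlen <- stats::setNames(nchar(genome), names(genome))
  }
  # FASTA headers often carry descriptions after the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  names(chrlen) <- names(genome)

  bad <- setdiff(unique(instances$chrom), names(genome))
  if (length(bad) > 0L) {
    ids <- instances$te_id[instances$chrom %in% bad]
    stop("chromosome(s) absent from genome: ", paste(bad, collapse = ", "),
         " (instances: ", paste(utils::head(ids, 5L), collapse = ", "), ")")
  }
  oor <- instances$start < 0L | instances$end > chrlen[instances$chrom] |
    instances$start >= instances$end
  if (any(oor))
    stop("out-of-range interval(s): ",
         paste(utils::head(instances$te_id[oor], 5L), collapse = ", "))

  seqs <- substring(genome[instances$chrom], instances$start + 1L,
                    instances$end)
  if (stranded) {
    minus <- instances$strand == "-"
    if (any(minus))
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
  }
  names(seqs) <- instances$te_id
  if (anyDuplicated(instances$te_id))
    stop("duplicate TE ids in annotation")

  if (!is.null(bed_file)) write_bed6(instances, bed_file)
  if (!is.null(fasta_file))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_file)

  structure(list(instances = instances, sequences = seqs),
            class = "te_library")
}

#' @export
print.te_library <- function(x, ...) {
  cat("TE reference library:", nrow(x$instances), "instances\n")
  tab <- table(x$instances$order)
  cat("  orders:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  kn <- sum(!is.na(x$instances$kimura))
  cat("  known Kimura:", kn, "| length range:",
      paste(range(x$instances$length), collapse = "-"), "bp\n")
  invisible(x)
}
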