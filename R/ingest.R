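# Ingestion of per-instance count tables produced by external tools, and
# coordinate-based id matching between tool-specific id dialects and the
# reference annotation.

# id-column conventions of the supported tool output shapes
.tool_dialects <- list(
  generic       = list(id_col = 1L,            coord = FALSE),
  salmonte      = list(id_col = "Name",        coord = FALSE),
  telescope     = list(id_col = "transcript",  coord = FALSE),
  tetranscripts = list(id_col = "gene.TE",     coord = FALSE),
  tetools       = list(id_col = 1L,            coord = FALSE),
  squire        = list(id_col = "TE_ID",       coord = TRUE))

#' Ingest a per-instance count table from an external tool
#'
#' Reads a tabular text file (one id column plus one numeric column per
#' sample), optionally renames the sample columns to the design's
#' `setX_repY` names via a manifest, and preserves fractional counts as
#' emitted by EM-based tools (rounding, if any, happens only at the
#' detection step per configuration).
#'
#' @param file Path to a TSV/CSV count table.
#' @param dialect Tool dialect selecting the id column: one of `generic`,
#'   `salmonte`, `telescope`, `tetranscripts`, `tetools`, `squire`.
#' @param manifest Optional data frame with columns `column` (raw column
#'   name in the file) and `sample` (design sample name); unlisted numeric
#'   columns are dropped. Without a manifest, column names are kept and must
#'   already match the design.
#' @param id_col Override the dialect's id column (name or index).
#' @param sep Field separator (default tab).
#' @return A `tool_counts` object: list with `tool`, `counts` (numeric
#'   matrix, rows = ids) and `coordinate_embedded` flag.
#' @export
ingest_count_table <- function(file, dialect = "generic", manifest = NULL,
                               id_col = NULL, sep = "\t") {
  dialect <- match.arg(dialect, names(.tool_dialects))
  d <- .tool_dialects[[dialect]]
  if (is.null(id_col)) id_col <- d$id_col
  tab <- utils::read.table(file, header = TRUE, sep = sep, as.is = TRUE,
                           check.names = FALSE, comment.char = "")
  if (is.character(id_col)) {
    # tolerate '/' vs '.' munging in header names (e.g. "gene/TE")
    hit <- which(names(tab) == id_col | make.names(names(tab)) ==
                   make.names(id_col))
    if (length(hit) == 0L)
      stop("id column '", id_col, "' not found in ", file)
    id_col <- hit[1L]
  }
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate ids in count table: ", ids[duplicated(ids)][1L])
  num <- vapply(tab, is.numeric, logical(1L))
  num[id_col] <- FALSE
  counts <- as.matrix(tab[, num, drop = FALSE])
  rownames(counts) <- ids
  if (!is.null(manifest)) {
    stopifnot(all(c("column", "sample") %in% names(manifest)))
    miss <- setdiff(manifest$column, colnames(counts))
    if (length(miss) > 0L)
      stop("manifest sample column(s) missing from table: ",
           paste(miss, collapse = ", "))
    counts <- counts[, manifest$column, drop = FALSE]
    colnames(counts) <- manifest$sample
  }
  if (ncol(counts) < 1L) stop("no numeric sample columns in ", file)
  structure(list(tool = dialect, counts = counts,
                 coordinate_embedded = d$coord),
            class = "tool_counts")
}

#' @export
print.tool_counts <- function(x, ...) {
  cat("Tool count table (", x$tool, "): ", nrow(x$counts), " ids x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Match foreign TE ids to the reference annotation by genomic coordinates
#'
#' Tool-specific ids differ from the reference TE ids, but both embed the
#' genomic coordinates of the instance, which are unique — so matching on
#' (chrom, start, end) after normalizing the coordinate base gives a
#' one-to-one relationship. Unmatched foreign ids are reported, never
#' silently dropped; two foreign ids resolving to the same reference
#' instance violate the one-to-one contract and raise an error.
#'
#' @param foreign_ids Character vector of tool ids embedding coordinates.
#' @param instances Reference instance data frame (0-based half-open), or a
#'   `te_library`.
#' @param pattern Regex with three capture groups (chrom, start, end)
#'   extracting the coordinates from a foreign id. The default accepts
#'   `chr|start|end|...`, `chr:start-end` and `chr_start_end` shapes.
#' @param base Coordinate base of the foreign starts (1 = annotation
#'   convention, 0 = BED convention).
#' @return List with `map` (named character vector: foreign id ->
#'   reference `te_id`) and `unmatched` (foreign ids without a partner).
#' @export
match_by_coordinates <- function(foreign_ids, instances,
                                 pattern = "^([^|:_]+)[|:_]([0-9]+)[|:_-]([0-9]+)",
                                 base = 1L) {
  stopifnot(base %in% c(0L, 1L))
  inst <- if (inherits(instances, "te_library")) instances$instances
          else instances
  m <- regmatches(foreign_ids, regexec(pattern, foreign_ids))
  bad <- lengths(m) < 4L
  if (any(bad))
    stop("cannot extract coordinates from foreign id: ",
         foreign_ids[bad][1L])
  chrom <- vapply(m, `[`, character(1L), 2L)
  start <- as.integer(vapply(m, `[`, character(1L), 3L)) - base
  end <- as.integer(vapply(m, `[`, character(1L), 4L))
  fkey <- paste(chrom, start, end)
  rkey <- paste(inst$chrom, inst$start, inst$end)
  hit <- match(fkey, rkey)
  matched <- !is.na(hit)
  if (anyDuplicated(hit[matched]))
    stop("one-to-one violation: multiple foreign ids map to reference id ",
         inst$te_id[hit[matched]][duplicated(hit[matched])][1L])
  list(map = stats::setNames(inst$te_id[hit[matched]],
                             foreign_ids[matched]),
       unmatched = foreign_ids[!matched])
}
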