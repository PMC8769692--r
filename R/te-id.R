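#' Build a unique TE identifier
#'
#' TE instances are tracked through the whole pipeline via a pipe-delimited
#' identifier of exactly eight fields:
#' `chr|start|end|order|family|subfamily|score|kimura`.
#' Coordinates inside the id are printed in the source annotation's 1-based
#' inclusive convention by default (`base = 1`); internally the package keeps
#' 0-based half-open coordinates throughout. The Kimura divergence is printed
#' with one decimal so ids are stable across reruns; an unknown Kimura is
#' printed as `NA`.
#'
#' @param instance A one-row data frame (or list) with fields `chrom`,
#'   `start`, `end` (0-based half-open), `order`, `family`, `subfamily`,
#'   `score`, `kimura` (percent, `NA` if unknown).
#' @param base Coordinate base used for the printed start (0 or 1).
#' @return Character vector of TE ids.
#' @seealso [parse_te_id()]
#' @examples
#' inst <- data.frame(chrom = "chr1", start = 100L, end = 200L,
#'                    order = "SINE", family = "Alu", subfamily = "AluY",
#'                    score = 1234L, kimura = 5.2)
#' make_te_id(inst)
#' @export
make_te_id <- function(instance, base = 1L) {
  stopifnot(base %in% c(0L, 1L))
  fields <- c("chrom", "start", "end", "order", "family", "subfamily",
              "score", "kimura")
  miss <- setdiff(fields, names(instance))
  if (length(miss) > 0L)
    stop("instance lacks fields: ", paste(miss, collapse = ", "))
  txt <- c(instance$chrom, instance$order, instance$family, instance$subfamily)
  if (any(grepl("|", unlist(txt), fixed = TRUE)))
    stop("pipe character '|' is not allowed inside TE id fields")
  kim <- ifelse(is.na(instance$kimura), "NA",
                formatC(round(as.numeric(instance$kimura), 1L),
                        format = "f", digits = 1L))
  paste(instance$chrom,
        as.integer(instance$start) + base,
        as.integer(instance$end),
        instance$order, instance$family, instance$subfamily,
        as.integer(instance$score),
        kim,
        sep = "|")
}

#' Parse TE identifiers back into their fields
#'
#' Inverse of [make_te_id()]: splits the eight pipe-delimited fields and
#' restores internal 0-based half-open coordinates.
#'
#' @param te_id Character vector of TE ids.
#' @param base Coordinate base the ids were printed with (0 or 1).
#' @return A data frame with columns `chrom`, `start`, `end`, `order`,
#'   `family`, `subfamily`, `score`, `kimura`, `length` and the input id as
#'   `te_id`.
#' @export
parse_te_id <- function(te_id, base = 1L) {
  stopifnot(base %in% c(0L, 1L))
  parts <- strsplit(te_id, "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 8L))
    stop("malformed TE id (expected 8 pipe-delimited fields, got ",
         nf[which(nf != 8L)[1L]], "): ", te_id[which(nf != 8L)[1L]])
  m <- do.call(rbind, parts)
  out <- data.frame(
    chrom     = m[, 1L],
    start     = as.integer(m[, 2L]) - base,
    end       = as.integer(m[, 3L]),
    order     = m[, 4L],
    family    = m[, 5L],
    subfamily = m[, 6L],
    score     = as.integer(m[, 7L]),
    kimura    = suppressWarnings(as.numeric(m[, 8L])),
    stringsAsFactors = FALSE
  )
  out$length <- out$end - out$start
  out$te_id <- te_id
  out
}
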