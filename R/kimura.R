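#' Kimura two-parameter distance between aligned sequences
#'
#' Computes the Kimura (1980) two-parameter substitution distance
#' \deqn{K = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q)}
#' where \eqn{P} and \eqn{Q} are the fractions of transition and transversion
#' sites over aligned non-gap positions. The value is reported in percent
#' (\eqn{\times 100}), matching RepeatMasker's convention for per-copy
#' divergence from the family consensus; low values mark evolutionarily
#' young copies.
#'
#' The generator plants ungapped copies, so inputs must be equal-length and
#' gap-free. Saturated pairs (log argument \eqn{\le 0}) raise an error.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return Distance in percent.
#' @examples
#' kimura_distance("ACGTACGTAC", "ACGTACGTAC")  # 0
#' @export
kimura_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b))
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  if (any(a == "-") || any(b == "-"))
    stop("gap characters are not supported (ungapped alignment expected)")
  n <- length(a)
  if (n == 0L) stop("empty sequences")
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- diff & (purine[a] == purine[b])
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("Kimura distance saturated (P=", round(P, 3), ", Q=", round(Q, 3),
         "): log argument <= 0")
  # "+ 0" normalizes IEEE negative zero (identical sequences)
  100 * (-0.5 * log(w1) - 0.25 * log(w2)) + 0
}

# expected K2P distance (percent) for per-site transition/transversion rates
k2p_expected <- function(rate_transition, rate_transversion) {
  100 * (-0.5 * log(1 - 2 * rate_transition - rate_transversion) -
           0.25 * log(1 - 2 * rate_transversion))
}
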