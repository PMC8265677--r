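#' Round half away from zero
#'
#' Printed composition tables in this field round 0.05 up (half away from
#' zero) rather than to even, so percentages reproduce published tables.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Cheap structural checksum of a genome
#'
#' Used to refuse cross-condition comparisons of call sets classified
#' against different references. Not cryptographic; catches chromosome
#' renames, length changes and sequence edits near the ends.
#'
#' @param genome a `Genome` object
#' @return a single character string
#' @keywords internal
genome_checksum <- function(genome) {
  s <- genome$seqs
  paste(length(s),
        paste(names(s), collapse = ","),
        paste(genome$lengths, collapse = ","),
        paste(substr(s, 1L, 25L), collapse = ""),
        paste(substr(s, pmax(1L, genome$lengths - 24L), genome$lengths),
              collapse = ""),
        sep = "|")
}

#' Moving average with shrinking edge windows
#'
#' Plain centred moving average; near the vector ends the window is
#' truncated rather than padded, so no positions are lost to NA.
#'
#' @param x numeric vector
#' @param width odd window width (1 = identity)
#' @return smoothed numeric vector, same length as `x`
#' @keywords internal
moving_average <- function(x, width) {
  stopifnot(width >= 1, width %% 2 == 1)
  if (width == 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
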