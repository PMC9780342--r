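#' Build a synthetic AAV vector map
#'
#' Generates a toy AAV vector sequence with two annotated inverted terminal
#' repeat (ITR) intervals at the ends and a payload interval between them.
#' The right ITR is the reverse complement of the left one (the defining
#' property of inverted terminal repeats); no attempt is made to reproduce
#' real ITR palindromic secondary structure.
#'
#' @param seed Integer RNG seed.
#' @param length Total vector length in bp (default 4700, a typical AAV
#'   genome size).
#' @param itr_length Length of each ITR in bp (default 145).
#' @return A `vector_map` object: list with `sequence`, `name`,
#'   `itr_intervals` (tibble of 0-based half-open `start`,`end`) and
#'   `payload_interval`.
#' @export
#' @examples
#' v <- build_aav_vector(seed = 1)
#' v$itr_intervals
build_aav_vector <- function(seed = 1L, length = 4700L, itr_length = 145L) {
  length <- as.integer(length)
  itr_length <- as.integer(itr_length)
  if (itr_length < 100L) stop("ITR intervals must each be >= 100 bp")
  if (length < 2L * itr_length + 200L) stop("vector too short for two ITRs")
  seq <- withr::with_seed(mix_seed(seed, 7L), random_dna(length))
  left_itr <- sub0(seq, 0L, itr_length)
  seq <- splice0(seq, length - itr_length, dna_revcomp(left_itr))
  structure(
    list(
      sequence = seq,
      name = "AAV",
      itr_intervals = tibble::tibble(
        start = c(0L, length - itr_length),
        end = c(itr_length, length)
      ),
      payload_interval = tibble::tibble(
        start = itr_length, end = length - itr_length
      ),
      seed = as.integer(seed)
    ),
    class = "vector_map"
  )
}

#' @export
print.vector_map <- function(x, ...) {
  cat("<vector_map> ", x$name, ": ", nchar(x$sequence), " bp, ITRs [",
      x$itr_intervals$start[1], ",", x$itr_intervals$end[1], ") and [",
      x$itr_intervals$start[2], ",", x$itr_intervals$end[2], ")\n", sep = "")
  invisible(x)
}

# TRUE for each position (0-based) inside an ITR interval.
in_itr <- function(pos, vector_map) {
  iv <- vector_map$itr_intervals
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv))) {
    out <- out | (pos >= iv$start[i] & pos < iv$end[i])
  }
  out
}
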