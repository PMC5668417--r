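DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute bases at given positions of a single sequence.
mutate_bases <- function(seq, pos, base) {
  if (length(pos) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- base
  paste(chars, collapse = "")
}

# For each current base, draw a uniformly chosen different base.
other_base <- function(current) {
  vapply(current, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

# Sample positions with a minimum pairwise distance. Rejection sampling with
# a deterministic evenly-spaced fallback when the layout is tight.
sample_spaced <- function(candidates, n, min_dist, max_tries = 200L) {
  if (n == 0) return(integer(0))
  if (n == 1) return(sample(candidates, 1))
  for (i in seq_len(max_tries)) {
    pos <- sort(sample(candidates, n))
    if (min(diff(pos)) >= min_dist) return(pos)
  }
  lo <- min(candidates); hi <- max(candidates)
  if (hi - lo < (n - 1L) * min_dist) {
    abort(sprintf(
      "could not place %d positions with minimum spacing %d; sequence too short or too constrained",
      n, min_dist))
  }
  step <- (hi - lo) %/% (n - 1L)
  lattice <- as.integer(lo + (seq_len(n) - 1L) * step)
  # snap to the nearest admissible position
  vapply(lattice, function(v) candidates[which.min(abs(candidates - v))],
         integer(1))
}

# All substrings of fixed width (step 1) of a single sequence.
sliding_windows <- function(seq, width) {
  n <- nchar(seq)
  if (n < width) return(character(0))
  starts <- seq_len(n - width + 1L)
  substring(seq, starts, starts + width - 1L)
}

# Exact substring containment of pattern(s) in a single subject (forward only).
contains_fixed <- function(subject, patterns) {
  stringr::str_detect(subject, stringr::fixed(patterns))
}
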