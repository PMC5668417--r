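#' Collapse a family alignment into a degenerate consensus pattern
#'
#' Every alignment column at which at least one member differs (substitution
#' or indel) becomes a wildcard carrying the ordered list of observed
#' variants (the gap character `-` counts as a variant); all other columns
#' carry the shared consensus base. Every member is reconstructable from the
#' pattern by choosing its own variant at each wildcard.
#'
#' @param alignment Named character vector of equal-length (gapped) member
#'   sequences.
#' @return A `consensus_pattern`: list with `consensus` (character vector of
#'   per-column bases, `NA` at wildcards), `wildcards` (tibble: `column`,
#'   `variants` list-column, lexicographically ordered), `n_columns`.
#' @export
build_consensus <- function(alignment) {
  if (length(alignment) == 0) abort("empty alignment")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) abort("alignment sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  n_col <- ncol(mat)
  variants <- apply(mat, 2, function(col) sort(unique(col)), simplify = FALSE)
  is_wild <- lengths(variants) > 1L
  consensus <- ifelse(is_wild, NA_character_, mat[1, ])
  structure(list(
    consensus = consensus,
    wildcards = tibble(
      column = which(is_wild),
      variants = variants[is_wild]
    ),
    n_columns = n_col,
    members = rownames(mat) %||% names(alignment)
  ), class = "consensus_pattern")
}

#' Enumerate the virtual recombination-junction fragment library
#'
#' Slides a window of `window_length` alignment columns across the
#' consensus pattern (step 1) and, in each window, generates every
#' combination of the variants observed at the window's wildcard columns --
#' the set of all possible inter-member recombination junctions readable at
#' that window. The raw cross-product is deduplicated and purged, by perfect
#' string matching on both strands, of every fragment present in the
#' reference genome; because the genome carries a copy of every parental
#' member, all single-parent windows are removed by this screen, leaving
#' only fragments diagnostic of recombination.
#'
#' Combinations containing gap variants are shorter than `window_length`
#' after gap resolution; they are re-windowed to exactly `window_length`
#' real bases by extending through following non-wildcard columns, and
#' dropped (and counted) when no unambiguous extension exists.
#'
#' @param pattern A `consensus_pattern`.
#' @param genome Reference genome sequence (character scalar) used for the
#'   purge; must contain one copy of every member.
#' @param window_length Fragment length in bp.
#' @param step Window step in columns.
#' @param max_combinations Per-window combination budget; windows exceeding
#'   it raise an error naming the offending window.
#' @return Tibble of class `junction_library`: `fragment_id` (encodes window
#'   offset and combination index), `sequence`, `window`, `combination`.
#'   Attributes `counts` (raw, deduplicated, purged, dropped_short) and
#'   `window_length`.
#' @export
enumerate_fragments <- function(pattern, genome, window_length = 145L,
                                step = 1L, max_combinations = 1e6) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  n_col <- pattern$n_columns
  if (n_col < window_length) abort("alignment shorter than window_length")
  wc <- pattern$wildcards
  cons <- pattern$consensus

  starts <- seq.int(1L, n_col - window_length + 1L, by = step)
  frag_rows <- vector("list", length(starts))
  n_raw <- 0
  n_dropped_short <- 0

  for (si in seq_along(starts)) {
    s <- starts[si]
    e <- s + window_length - 1L
    in_win <- wc$column >= s & wc$column <= e
    if (!any(in_win)) next
    cols <- wc$column[in_win]
    vars <- wc$variants[in_win]
    n_comb <- prod(lengths(vars))
    if (n_comb > max_combinations) {
      abort(sprintf("window starting at column %d yields %.3g combinations (budget %g)",
                    s, n_comb, max_combinations))
    }
    n_raw <- n_raw + n_comb
    template <- cons[s:e]
    rel <- cols - s + 1L
    grid <- expand.grid(vars, stringsAsFactors = FALSE)
    frags <- apply(as.matrix(grid), 1, function(choice) {
      x <- template
      x[rel] <- choice
      x <- x[x != "-"]
      if (length(x) < window_length) {
        # extend with following unambiguous consensus columns
        k <- e + 1L
        while (length(x) < window_length && k <= n_col && !is.na(cons[k]) && cons[k] != "-") {
          if (cons[k] != "-") x <- c(x, cons[k])
          k <- k + 1L
        }
      }
      if (length(x) < window_length) return(NA_character_)
      paste(x[seq_len(window_length)], collapse = "")
    })
    n_dropped_short <- n_dropped_short + sum(is.na(frags))
    keep <- which(!is.na(frags))
    if (length(keep)) {
      frag_rows[[si]] <- tibble(window = s, combination = keep, sequence = frags[keep])
    }
  }

  lib <- bind_rows(frag_rows)
  if (nrow(lib) == 0) {
    out <- tibble(fragment_id = character(0), sequence = character(0),
                  window = integer(0), combination = integer(0))
    return(structure(out, class = c("junction_library", class(out)),
                     counts = c(raw = n_raw, deduplicated = 0, purged = 0,
                                dropped_short = n_dropped_short),
                     window_length = window_length))
  }
  lib <- lib %>% distinct(.data$sequence, .keep_all = TRUE)
  n_dedup <- nrow(lib)

  # purge fragments occurring in the genome (either strand)
  subj <- Biostrings::DNAString(genome)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(lib$sequence))
  fwd_hits <- Biostrings::countPDict(pd, subj)
  rev_hits <- Biostrings::countPDict(pd, Biostrings::reverseComplement(subj))
  lib <- lib[fwd_hits + rev_hits == 0, ]

  lib <- lib %>%
    mutate(fragment_id = sprintf("w%d_c%d", .data$window, .data$combination)) %>%
    select("fragment_id", "sequence", "window", "combination")

  structure(lib, class = c("junction_library", class(lib)),
            counts = c(raw = n_raw, deduplicated = n_dedup, purged = nrow(lib),
                       dropped_short = n_dropped_short),
            window_length = window_length)
}

#' Build the junction library for a family in one call
#'
#' @param family A `family_model`.
#' @param ... Passed to [enumerate_fragments()].
#' @return A `junction_library`.
#' @export
build_junction_library <- function(family, ...) {
  enumerate_fragments(build_consensus(family$alignment), family$genome, ...)
}

#' Search reads for recombination-junction fragments
#'
#' A read is a recombination-read iff it contains at least one library
#' fragment as an exact substring on either strand. Multiple fragment hits
#' in one read still count as a single recombination-read; the reported rate
#' is per 1000 element-mapping reads.
#'
#' @param reads Reads (`read_pairs`, character vector, or tibble with
#'   `seq`).
#' @param library A `junction_library`.
#' @param element_mapping_read_count Denominator: number of reads mapping to
#'   the element family.
#' @return List of class `junction_hits`: `matches` (tibble: `read`,
#'   `fragment_id`, `strand`), `n_recombination_reads`, `rate_per_1000`,
#'   `n_reads_searched`, `element_mapping_read_count`.
#' @export
search_junctions <- function(reads, library, element_mapping_read_count) {
  stopifnot(inherits(library, "junction_library"))
  if (element_mapping_read_count <= 0) {
    abort("element_mapping_read_count must be positive")
  }
  seqs <- read_seqs(reads)
  hits <- junction_hit_table(seqs, library)
  n_hit <- length(unique(hits$read))
  structure(list(
    matches = hits,
    n_recombination_reads = n_hit,
    rate_per_1000 = 1000 * n_hit / element_mapping_read_count,
    n_reads_searched = length(seqs),
    element_mapping_read_count = element_mapping_read_count
  ), class = "junction_hits")
}

# Exact multi-pattern search of library fragments (both strands) in reads.
# A single forward dictionary is used; the minus strand is covered by
# searching the reverse-complemented reads.
junction_hit_table <- function(seqs, library, pdict = NULL) {
  empty <- tibble(read = integer(0), fragment_id = character(0), strand = character(0))
  if (length(seqs) == 0 || nrow(library) == 0) return(empty)
  pd <- pdict %||% Biostrings::PDict(Biostrings::DNAStringSet(library$sequence))
  out <- list(empty)
  for (str in c("+", "-")) {
    subjects <- Biostrings::DNAStringSet(if (str == "+") seqs else revcomp(seqs))
    per_read <- Biostrings::vwhichPDict(pd, subjects)
    n_per <- lengths(per_read)
    if (sum(n_per) > 0) {
      out[[length(out) + 1L]] <- tibble(
        read = rep(seq_along(seqs), n_per),
        fragment_id = library$fragment_id[unlist(per_read)],
        strand = str
      )
    }
  }
  bind_rows(out) %>% distinct(.data$read, .data$fragment_id, .keep_all = TRUE)
}

#' @export
print.junction_hits <- function(x, ...) {
  cat(sprintf("<junction_hits> %d recombination-reads among %d searched; %.2f per 1000 element-mapping reads (n = %d)\n",
              x$n_recombination_reads, x$n_reads_searched, x$rate_per_1000,
              x$element_mapping_read_count))
  invisible(x)
}
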