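#' Family-shared LTR start motif
#'
#' The first `motif_length` bases of the element, which every member must
#' share (the LTR terminus is strongly conserved). Used to recognise reads
#' that start exactly at the blunt 5' end of linear ecDNA.
#'
#' @param family A `family_model`.
#' @param motif_length Motif length in bp.
#' @return Character scalar.
#' @export
ltr_start_motif <- function(family, motif_length = 20L) {
  prefixes <- substr(family$members$sequence, 1L, motif_length)
  if (length(unique(prefixes)) != 1L) {
    abort("LTR start motif is not shared by all family members; shorten motif_length")
  }
  prefixes[1]
}

#' Find candidate blunt-end ecDNA read pairs
#'
#' A pair qualifies iff one mate begins at its very first base with the
#' family-shared LTR start motif; reads carrying the motif only at an
#' offset (i.e. with extra upstream bases, as produced by chromosomal
#' copies and their flanks) are excluded. The qualifying mate is reported
#' as the 5' mate; the other mate is reverse-complemented into element
#' orientation.
#'
#' @param pairs A `read_pairs` tibble (columns `pair_id`, `mate1`, `mate2`).
#' @param motif LTR start motif from [ltr_start_motif()].
#' @return Tibble: `pair_id`, `mate5` (blunt 5' read), `mate3` (partner,
#'   element-forward orientation).
#' @export
find_blunt_ltr_reads <- function(pairs, motif) {
  m1 <- stringr::str_starts(pairs$mate1, stringr::fixed(motif))
  m2 <- stringr::str_starts(pairs$mate2, stringr::fixed(motif))
  out <- bind_rows(
    pairs[m1, ] %>% mutate(mate5 = .data$mate1, mate3 = revcomp(.data$mate2)),
    pairs[m2 & !m1, ] %>% mutate(mate5 = .data$mate2, mate3 = revcomp(.data$mate1))
  )
  out %>% select("pair_id", "mate5", "mate3")
}

#' Expected single-parent ecDNA sequence of every member
#'
#' The linear ecDNA of a member is not its genomic copy: both ends carry the
#' reconstituted LTR (U3 from the member's 3' LTR, R/U5 from its 5' LTR; see
#' [reconstituted_ltr()]). Blunt-pair mates are matched against these forms,
#' so that a single-parent molecule of an old member is never mistaken for a
#' recombinant merely because its reconstituted LTR differs from either
#' genomic LTR copy.
#'
#' @param family A `family_model`.
#' @return Named character vector of per-member ecDNA sequences.
#' @export
member_ecdna_forms <- function(family) {
  cfg <- family$config
  L <- cfg$element_length
  ltr <- cfg$ltr_length
  vapply(cfg$labels, function(lab) {
    rl <- reconstituted_ltr(family, lab)
    paste0(rl, substr(family$alignment[[lab]], ltr + 1L, L - ltr), rl)
  }, character(1))
}

#' Retain only perfect-matching blunt pairs
#'
#' Both mates must be exact substrings of at least one member's expected
#' ecDNA sequence ([member_ecdna_forms()]); pairs with any mismatch to all
#' known forms are discarded, removing sequencing-error artefacts.
#'
#' @param candidates Output of [find_blunt_ltr_reads()].
#' @param family A `family_model` (or character vector of reference
#'   sequences to match against).
#' @return The filtered tibble.
#' @export
perfect_pair_filter <- function(candidates, family) {
  members <- if (inherits(family, "family_model")) member_ecdna_forms(family) else family
  if (nrow(candidates) == 0) return(candidates)
  ok5 <- matches_any_member(candidates$mate5, members)
  ok3 <- matches_any_member(candidates$mate3, members)
  candidates[ok5 & ok3, ]
}

#' Assign parental member sets to each mate of a blunt pair
#'
#' For every mate the set of members whose expected ecDNA sequence
#' ([member_ecdna_forms()]) contains the mate verbatim is computed. A pair
#' is `discriminatory` iff the two sets are disjoint -- direct evidence that
#' the two LTR ends of the underlying ecDNA molecule derive from different
#' members, i.e. a recombinant LTR. For members whose genomic 5' and 3' LTRs
#' are distinguishable, the matched genomic LTR copy (5', 3' or both) is
#' additionally reported whenever the mate covers a distinguishing
#' polymorphism; mates only explicable by the reconstituted LTR are marked
#' `reconstituted`.
#'
#' @param pairs Output of [perfect_pair_filter()].
#' @param family A `family_model`.
#' @return Tibble of class `blunt_pairs`: `pair_id`, `members5`, `members3`
#'   (list-columns of member labels), `ltr_end5`, `ltr_end3` (list-columns
#'   of per-member LTR-end attributions), `classification`.
#' @export
assign_pair_parents <- function(pairs, family) {
  members <- family$members
  cfg <- family$config
  L <- cfg$element_length
  ltr <- cfg$ltr_length
  forms <- member_ecdna_forms(family)

  assign_one <- function(seq) {
    labs <- character(0)
    ends <- character(0)
    for (k in seq_len(nrow(members))) {
      if (!grepl(seq, forms[[members$label[k]]], fixed = TRUE)) next
      labs <- c(labs, members$label[k])
      # genomic LTR-copy attribution where the genomic element also matches
      mseq <- members$sequence[k]
      locs <- stringr::str_locate_all(mseq, stringr::fixed(seq))[[1]]
      if (nrow(locs) == 0) {
        ends <- c(ends, "reconstituted")
        next
      }
      in5 <- any(locs[, "start"] <= ltr)
      in3 <- any(locs[, "end"] >= L - ltr + 1L)
      ends <- c(ends, if (in5 && in3) "both" else if (in5) "5" else if (in3) "3" else "internal")
    }
    list(labs = labs, ends = ends)
  }

  res5 <- lapply(pairs$mate5, assign_one)
  res3 <- lapply(pairs$mate3, assign_one)
  members5 <- lapply(res5, `[[`, "labs")
  members3 <- lapply(res3, `[[`, "labs")
  if (any(lengths(members5) == 0 | lengths(members3) == 0)) {
    abort("internal consistency error: a perfect-matching mate matched no member")
  }
  out <- pairs %>%
    mutate(
      members5 = members5,
      members3 = members3,
      ltr_end5 = lapply(res5, `[[`, "ends"),
      ltr_end3 = lapply(res3, `[[`, "ends"),
      overlap_size = purrr::map2_int(members5, members3, ~ length(intersect(.x, .y))),
      classification = if_else(.data$overlap_size == 0, "discriminatory", "non-discriminatory")
    )
  class(out) <- c("blunt_pairs", class(out))
  out
}

#' Tabulate blunt-pair parental signatures
#'
#' @param assigned A `blunt_pairs` tibble from [assign_pair_parents()].
#' @return List of class `blunt_pair_table`: `table` (counts per ordered
#'   (5' set, 3' set) signature and classification), `n_discriminatory`,
#'   `n_non_discriminatory`, `n_total`.
#' @export
tabulate_pairs <- function(assigned) {
  if (nrow(assigned) == 0) {
    return(structure(list(
      table = tibble(signature5 = character(0), signature3 = character(0),
                     classification = character(0), n = integer(0)),
      n_discriminatory = 0L, n_non_discriminatory = 0L, n_total = 0L
    ), class = "blunt_pair_table"))
  }
  tab <- assigned %>%
    mutate(
      signature5 = purrr::map_chr(.data$members5, ~ paste(sort(.x), collapse = ",")),
      signature3 = purrr::map_chr(.data$members3, ~ paste(sort(.x), collapse = ","))
    ) %>%
    count(.data$signature5, .data$signature3, .data$classification, name = "n") %>%
    arrange(dplyr::desc(.data$n))
  structure(list(
    table = tab,
    n_discriminatory = sum(assigned$classification == "discriminatory"),
    n_non_discriminatory = sum(assigned$classification == "non-discriminatory"),
    n_total = nrow(assigned)
  ), class = "blunt_pair_table")
}

#' @export
print.blunt_pair_table <- function(x, ...) {
  cat(sprintf("<blunt_pair_table> %d pairs: %d discriminatory, %d non-discriminatory\n",
              x$n_total, x$n_discriminatory, x$n_non_discriminatory))
  print(x$table, n = 10)
  invisible(x)
}
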