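#' Paint the parental origin along a (recombinant) element sequence
#'
#' Compares the sequence position-by-position against all family members
#' and, at every informative position (one where the members disagree),
#' computes the set of members compatible with the observed base. Because a
#' reverse-transcribed element's two identical LTRs are reconstituted from
#' the template's 3' LTR (U3) and 5' LTR (R/U5), a member is considered
#' compatible at LTR positions if the base matches either of its two LTR
#' copies. Maximal runs of constant compatible set become painted
#' intervals that tile the sequence; positions compatible with no member
#' are flagged as novel mutations and excluded from painting.
#'
#' A minimal-switch parent assignment (fewest parent changes, ties broken
#' by fewest distinct parents, then lexicographically by label) is reported
#' alongside the full ambiguity sets.
#'
#' @param sequence Element-length sequence (character scalar), e.g. an
#'   ecDNA molecule or reconstructed insertion; or an LTR-length sequence
#'   with `region = "ltr"`.
#' @param family A `family_model`.
#' @param region `"element"` (default, full element coordinates) or
#'   `"ltr"` (a single LTR in LTR coordinates).
#' @return A `painted_element`: list with `intervals` (tibble: `start`,
#'   `end`, `members` list-column, `n_informative`), `assignment` (tibble:
#'   `start`, `end`, `parent` -- the minimal-switch solution),
#'   `novel` (tibble: `position`, `base`), `n_parents_minimal`,
#'   `n_switches`, `length`.
#' @export
paint_parentage <- function(sequence, family, region = c("element", "ltr")) {
  region <- match.arg(region)
  cfg <- family$config
  L <- cfg$element_length
  ltr <- cfg$ltr_length
  labels <- cfg$labels
  n_mem <- length(labels)
  slen <- nchar(sequence)
  expected <- if (region == "element") L else ltr
  if (slen != expected) {
    abort(sprintf("sequence length %d does not match the %s length %d",
                  slen, region, expected))
  }
  seq_chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  mem_chars <- lapply(family$alignment, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  # per-position alternative coordinates: each painted position is compared
  # against a member's 5' and 3' LTR copy inside LTR territory
  pos <- seq_len(slen)
  if (region == "ltr") {
    c5 <- pos
    c3 <- L - ltr + pos
  } else {
    c5 <- ifelse(pos > L - ltr, pos - (L - ltr), pos)
    c3 <- ifelse(pos <= ltr, L - ltr + pos, pos)
  }
  ok_mat <- vapply(mem_chars, function(mc) {
    mc[c5] == seq_chars | mc[c3] == seq_chars
  }, logical(slen))
  if (slen == 1L) ok_mat <- matrix(ok_mat, nrow = 1L)

  n_ok <- rowSums(ok_mat)
  novel_pos <- which(n_ok == 0)
  informative <- n_ok > 0 & n_ok < n_mem
  compat <- vector("list", slen)
  for (i in which(informative)) compat[[i]] <- which(ok_mat[i, ])

  info_idx <- which(informative)
  novel <- tibble(position = novel_pos, base = seq_chars[novel_pos])

  if (length(info_idx) == 0) {
    out <- list(
      intervals = tibble(start = 1L, end = slen,
                         members = list(labels), n_informative = 0L),
      assignment = tibble(start = 1L, end = slen, parent = labels[1]),
      novel = novel,
      n_parents_minimal = 1L,
      n_switches = 0L,
      length = slen
    )
    return(structure(out, class = "painted_element"))
  }

  sets <- compat[info_idx]
  keys <- vapply(sets, paste, character(1), collapse = ",")
  run_id <- cumsum(c(1L, as.integer(keys[-1] != keys[-length(keys)])))
  run_first <- info_idx[!duplicated(run_id)]
  run_sets <- sets[!duplicated(run_id)]
  n_runs <- length(run_sets)
  run_n_info <- tabulate(run_id, nbins = n_runs)

  starts <- c(1L, run_first[-1])
  ends <- c(run_first[-1] - 1L, slen)
  intervals <- tibble(
    start = starts, end = ends,
    members = lapply(run_sets, function(s) labels[s]),
    n_informative = run_n_info
  )

  sol <- minimal_switch_assignment(run_sets, n_mem)
  assignment <- tibble(start = starts, end = ends, parent = labels[sol$path])

  structure(list(
    intervals = intervals,
    assignment = assignment,
    novel = novel,
    n_parents_minimal = length(unique(sol$path)),
    n_switches = sol$switches,
    length = slen
  ), class = "painted_element")
}

# Minimal-switch parent path through a list of compatible member sets.
# Ties: fewest distinct parents, then lexicographically smallest path
# (members compared by index). DFS over the optimal-switch paths with a
# backward bound; enumeration capped for safety (deterministic order).
minimal_switch_assignment <- function(sets, n_mem, cap = 20000L) {
  m <- length(sets)
  INF <- .Machine$integer.max %/% 2L
  min_future <- matrix(INF, nrow = m, ncol = n_mem)
  min_future[m, sets[[m]]] <- 0L
  if (m > 1) {
    for (j in (m - 1L):1L) {
      nxt <- min_future[j + 1L, ]
      for (p in sets[[j]]) {
        stay <- if (p %in% sets[[j + 1L]]) nxt[p] else INF
        move <- min(nxt[sets[[j + 1L]]]) + 1L
        min_future[j, p] <- min(stay, move)
      }
    }
  }
  best_total <- min(min_future[1L, sets[[1L]]])

  best <- NULL
  n_found <- 0L
  path <- integer(m)
  dfs <- function(j, prev, sw) {
    if (n_found >= cap) return()
    if (j > m) {
      n_found <<- n_found + 1L
      cand <- list(path = path, switches = sw,
                   distinct = length(unique(path)))
      if (is.null(best) ||
          cand$distinct < best$distinct ||
          (cand$distinct == best$distinct &&
             paste(cand$path, collapse = ",") < paste(best$path, collapse = ","))) {
        best <<- cand
      }
      return()
    }
    for (p in sort(sets[[j]])) {
      add <- if (j == 1L || p == prev) 0L else 1L
      if (sw + add + min_future[j, p] <= best_total) {
        path[j] <<- p
        dfs(j + 1L, p, sw + add)
      }
    }
  }
  dfs(1L, 0L, 0L)
  list(path = best$path, switches = best$switches)
}

#' Tabulate novel polymorphisms across painted elements
#'
#' Positions incompatible with every parental member, collected over a set
#' of painted sequences -- in a simulated burst these are the reverse
#' transcriptase errors; in real data they measure replication fidelity.
#'
#' @param painted Named list of `painted_element` objects (names are
#'   insertion/molecule ids).
#' @return Tibble: `id`, `position`, `base`.
#' @export
report_novel_polymorphisms <- function(painted) {
  if (length(painted) == 0) {
    return(tibble(id = character(0), position = integer(0), base = character(0)))
  }
  ids <- names(painted) %||% as.character(seq_along(painted))
  purrr::map2_dfr(painted, ids, function(p, id) {
    if (nrow(p$novel) == 0) return(NULL)
    tibble(id = id, position = p$novel$position, base = p$novel$base)
  })
}

#' Parental contribution scores over a set of insertions
#'
#' Each insertion is worth 12 points, shared equally among the parents of
#' its minimal-parent solution: a single-parent insertion gives that parent
#' 12 points, a two-parent recombinant 6 points each, a three-parent
#' product 4 points each, and so on. Totals and relative frequencies are
#' accumulated per member over the insertion set.
#'
#' @param painted Named list of `painted_element` objects.
#' @param members Optional character vector of all member labels (zero
#'   totals are reported for members without contributions).
#' @return List of class `contribution_table`: `per_insertion` (tibble:
#'   `id`, `member`, `score`), `totals` (tibble: `member`, `total`,
#'   `relative`), `points_per_insertion` (12).
#' @export
contribution_scores <- function(painted, members = NULL) {
  if (length(painted) == 0) abort("no painted insertions supplied")
  ids <- names(painted) %||% as.character(seq_along(painted))
  per <- purrr::map2_dfr(painted, ids, function(p, id) {
    parents <- unique(p$assignment$parent)
    k <- length(parents)
    if (k == 0) abort(sprintf("insertion '%s' has no parents", id))
    tibble(id = id, member = parents, score = 12 / k)
  })
  totals <- per %>%
    group_by(.data$member) %>%
    summarise(total = sum(.data$score), .groups = "drop")
  if (!is.null(members)) {
    totals <- tibble(member = members) %>%
      left_join(totals, by = "member") %>%
      mutate(total = dplyr::coalesce(.data$total, 0))
  }
  totals <- totals %>% mutate(relative = .data$total / sum(.data$total))
  structure(list(
    per_insertion = per,
    totals = totals,
    points_per_insertion = 12
  ), class = "contribution_table")
}

#' @export
print.painted_element <- function(x, ...) {
  cat(sprintf("<painted_element> %d bp, %d intervals, minimal solution: %d parent(s), %d switch(es), %d novel position(s)\n",
              x$length, nrow(x$intervals), x$n_parents_minimal,
              x$n_switches, nrow(x$novel)))
  invisible(x)
}

#' @export
print.contribution_table <- function(x, ...) {
  cat(sprintf("<contribution_table> %d insertions, %g points each\n",
              length(unique(x$per_insertion$id)), x$points_per_insertion))
  print(x$totals)
  invisible(x)
}
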