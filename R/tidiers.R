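#' Tidy a permutation null result
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble with one row per permutation: `permutation`,
#'   `rate_per_1000`.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_along(x$rates), rate_per_1000 = x$rates)
}

#' @rdname tidy.permutation_result
#' @return `glance()` returns a one-row summary.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(mean = x$mean, max = x$max, n_permutations = x$n_permutations,
         n_draws = x$n_draws, p_error = x$p_error, seed = x$seed)
}

#' Tidy a painted element
#'
#' @param x A `painted_element`.
#' @param ... Unused.
#' @return Tibble of painted intervals with comma-separated compatible
#'   member sets and the minimal-solution parent.
#' @export
tidy.painted_element <- function(x, ...) {
  x$intervals %>%
    mutate(members = purrr::map_chr(.data$members, paste, collapse = ","),
           parent_minimal = x$assignment$parent)
}

#' @rdname tidy.painted_element
#' @export
glance.painted_element <- function(x, ...) {
  tibble(length = x$length, n_intervals = nrow(x$intervals),
         n_parents_minimal = x$n_parents_minimal,
         n_switches = x$n_switches, n_novel = nrow(x$novel))
}

#' Tidy a junction search result
#'
#' @param x A `junction_hits`.
#' @param ... Unused.
#' @return The match tibble (`read`, `fragment_id`, `strand`).
#' @export
tidy.junction_hits <- function(x, ...) x$matches

#' @rdname tidy.junction_hits
#' @export
glance.junction_hits <- function(x, ...) {
  tibble(n_recombination_reads = x$n_recombination_reads,
         rate_per_1000 = x$rate_per_1000,
         n_reads_searched = x$n_reads_searched,
         element_mapping_read_count = x$element_mapping_read_count)
}

#' Tidy a contribution table
#'
#' @param x A `contribution_table`.
#' @param ... Unused.
#' @return Per-insertion member scores.
#' @export
tidy.contribution_table <- function(x, ...) x$per_insertion

#' @rdname tidy.contribution_table
#' @export
glance.contribution_table <- function(x, ...) {
  tibble(n_insertions = length(unique(x$per_insertion$id)),
         n_members_contributing = sum(x$totals$total > 0),
         points_per_insertion = x$points_per_insertion)
}

#' Summary of a junction library
#'
#' @param x A `junction_library`.
#' @param ... Unused.
#' @return One-row tibble with library build statistics.
#' @export
glance.junction_library <- function(x, ...) {
  cnt <- attr(x, "counts")
  tibble(n_fragments = nrow(x), raw_combinations = unname(cnt["raw"]),
         deduplicated = unname(cnt["deduplicated"]),
         dropped_short = unname(cnt["dropped_short"]),
         window_length = attr(x, "window_length"))
}
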