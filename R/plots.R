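#' Plot per-member counts
#'
#' Bar chart of normalised member counts, the standard visualisation of
#' member-specific transcript or ecDNA abundance.
#'
#' @param object A `member_counts` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.member_counts <- function(object, ...) {
  ggplot(object, aes(x = .data$member, y = .data$normalized)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reads per million mapped",
                  title = "Member-specific abundance") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of per-permutation recombination-read rates, with optional
#' observed rate and closed-form expectation overlaid.
#'
#' @param object A `permutation_result`.
#' @param observed Optional observed rate (per 1000) drawn as a line.
#' @param r_expected Optional closed-form expectation drawn as a line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_result <- function(object, observed = NULL,
                                        r_expected = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$rate_per_1000)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "recombination-reads per 1000 drawn reads",
                  y = "permutations",
                  title = "Sequencing-error null model") +
    ggplot2::theme_minimal()
  if (!is.null(r_expected)) {
    p <- p + ggplot2::geom_vline(xintercept = r_expected,
                                 linetype = "dashed", colour = "black")
  }
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red")
  }
  p
}

#' Plot a painted element
#'
#' Draws the painted intervals along the element, one horizontal track per
#' compatible parent, with the minimal-switch solution highlighted.
#'
#' @param object A `painted_element`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.painted_element <- function(object, ...) {
  long <- object$intervals %>%
    mutate(interval = row_number()) %>%
    tidyr::unnest_longer(col = "members", values_to = "member")
  sol <- object$assignment %>% mutate(member = .data$parent)
  ggplot(long, aes(xmin = .data$start, xmax = .data$end + 1,
                   ymin = as.integer(factor(.data$member)) - 0.4,
                   ymax = as.integer(factor(.data$member)) + 0.4)) +
    ggplot2::geom_rect(aes(fill = .data$member), alpha = 0.5) +
    ggplot2::geom_segment(
      data = sol,
      aes(x = .data$start, xend = .data$end + 1,
          y = as.integer(factor(.data$member, levels = sort(unique(long$member)))),
          yend = as.integer(factor(.data$member, levels = sort(unique(long$member))))),
      inherit.aes = FALSE, linewidth = 1.5) +
    ggplot2::scale_y_continuous(breaks = seq_along(sort(unique(long$member))),
                                labels = sort(unique(long$member))) +
    ggplot2::labs(x = "element position (bp)", y = NULL,
                  title = "Parental painting",
                  subtitle = sprintf("minimal solution: %d parent(s), %d switch(es)",
                                     object$n_parents_minimal, object$n_switches)) +
    ggplot2::theme_minimal()
}

#' Plot parental contribution scores
#'
#' @param object A `contribution_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contribution_table <- function(object, ...) {
  ggplot(object$totals, aes(x = .data$member, y = .data$relative)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "relative contribution",
                  title = "Parental contributions to new insertions") +
    ggplot2::theme_minimal()
}
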