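#' Parameters of the closed-form sequencing-error model
#'
#' The model predicts how many reads will deceptively look like
#' recombination junctions purely because of random sequencing errors, as
#' the product `n * ell * p_error * p_position * p_base`:
#' `n` element-mapping reads, `ell` the minimum number of error positions
#' needed to convert a parental read into a recombination-like read,
#' `p_error` the per-read probability of a random nucleotide swap in an
#' otherwise perfect read, `p_position` the probability that the swap hits
#' one required position (1/read length), and `p_base` the probability that
#' the swap produces the required base (1/3 under equal base changes).
#'
#' @param n Element-mapping read count (reads).
#' @param ell Minimum error positions for a recombination-like read.
#' @param p_error Per-read swap probability.
#' @param p_position Per-position probability (1 / read length).
#' @param p_base Required-base probability.
#' @return An `error_model_params` list.
#' @export
error_model_params <- function(n = 1000, ell = 2, p_error = 0.1415,
                               p_position = 0.0066, p_base = 0.3333) {
  probs <- c(p_error = p_error, p_position = p_position, p_base = p_base)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (ell < 1) abort("ell must be >= 1")
  if (n < 0) abort("n must be >= 0")
  structure(list(n = n, ell = ell, p_error = p_error,
                 p_position = p_position, p_base = p_base),
            class = "error_model_params")
}

#' Expected sequencing-error false recombinants (closed form)
#'
#' Evaluates the literal product of the model parameters; no internal
#' rounding (round only at reporting time).
#'
#' @param params An [error_model_params()].
#' @return Expected number of false recombination-like reads per `n`
#'   element-mapping reads.
#' @examples
#' expected_false_recombinants(error_model_params()) # 0.6225, reported as 0.62
#' @export
expected_false_recombinants <- function(params = error_model_params()) {
  stopifnot(inherits(params, "error_model_params"))
  with(params, n * ell * p_error * p_position * p_base)
}

#' Estimate the per-read error probability from element-mapping reads
#'
#' The per-read swap probability is estimated as the fraction of
#' element-mapping reads that do not match any member sequence perfectly
#' (exact substring on either strand).
#'
#' @param reads Element-mapping reads (`read_pairs`, character vector or
#'   tibble with `seq`).
#' @param members Character vector of member sequences (or a
#'   `family_model`).
#' @return List: `p_error`, `n_mismatched`, `n_total`.
#' @export
estimate_p_error <- function(reads, members) {
  if (inherits(members, "family_model")) members <- members$members$sequence
  seqs <- read_seqs(reads)
  if (length(seqs) == 0) abort("zero element-mapping reads")
  perfect <- matches_any_member(seqs, members)
  list(
    p_error = mean(!perfect),
    n_mismatched = sum(!perfect),
    n_total = length(seqs)
  )
}

# TRUE for each read that is an exact substring of >= 1 member (either strand).
matches_any_member <- function(seqs, members) {
  hit <- rep(FALSE, length(seqs))
  for (m in members) {
    rcm <- revcomp(m)
    hit <- hit | stringr::str_detect(m, stringr::fixed(seqs)) |
      stringr::str_detect(rcm, stringr::fixed(seqs))
  }
  hit
}

#' Universe of all possible synthetic reads from the member sequences
#'
#' All read-length windows at 1-bp resolution from every member, with
#' duplicates purged.
#'
#' @param members Character vector of member sequences (or a
#'   `family_model`).
#' @param read_length Window length in bp.
#' @param step Window step in bp.
#' @return Character vector of unique synthetic reads.
#' @export
build_read_universe <- function(members, read_length = 150L, step = 1L) {
  if (inherits(members, "family_model")) members <- members$members$sequence
  too_short <- nchar(members) < read_length
  if (any(too_short)) {
    warn(sprintf("%d member(s) shorter than read_length skipped", sum(too_short)))
    members <- members[!too_short]
  }
  if (length(members) == 0) abort("no member long enough for read_length")
  wins <- unlist(lapply(members, function(m) {
    w <- sliding_windows(m, read_length)
    w[seq.int(1L, length(w), by = step)]
  }))
  unique(wins)
}

#' Permutation null model for sequencing-error recombination artefacts
#'
#' Per permutation, draws `n_draws` reads with replacement from the
#' synthetic-read universe; each read is mutated with probability `p_error`
#' (a single swap at a uniformly chosen position to a uniformly chosen
#' alternative base; set `mutation_model = "poisson"` for a multi-swap
#' sensitivity mode). Only mutated reads are searched against the junction
#' library, and the recombination-read rate is reported per 1000 drawn
#' reads. Means and maxima over permutations estimate the expected
#' sequencing-error artefact level.
#'
#' @param universe Synthetic read universe from [build_read_universe()].
#' @param n_draws Reads drawn per permutation (matched to the observed
#'   element-mapping read count of the modelled sample).
#' @param p_error Per-read mutation probability.
#' @param library A `junction_library`.
#' @param n_permutations Number of permutations.
#' @param mutation_model `"single_swap"` (default) or `"poisson"`.
#' @param seed Integer seed.
#' @return List of class `permutation_result`: `rates` (per-permutation
#'   recombination-read rates per 1000 drawn reads), `mean`, `max`,
#'   `n_permutations`, `n_draws`, `p_error`, `seed`.
#' @export
permutation_null <- function(universe, n_draws, p_error, library,
                             n_permutations = 500L,
                             mutation_model = c("single_swap", "poisson"),
                             seed = 1L) {
  if (length(universe) == 0) abort("empty read universe")
  mutation_model <- match.arg(mutation_model)
  stopifnot(inherits(library, "junction_library"))
  set.seed(seed)

  # pre-build the pattern dictionary once; the minus strand is covered by
  # searching reverse-complemented reads
  have_lib <- nrow(library) > 0
  if (have_lib) {
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(library$sequence))
  }
  read_len <- nchar(universe[1])

  rates <- numeric(n_permutations)
  for (perm in seq_len(n_permutations)) {
    drawn <- universe[sample.int(length(universe), n_draws, replace = TRUE)]
    mutated_idx <- which(runif(n_draws) < p_error)
    if (length(mutated_idx) == 0 || !have_lib) {
      rates[perm] <- 0
      next
    }
    mreads <- drawn[mutated_idx]
    if (mutation_model == "single_swap") {
      pos <- sample.int(read_len, length(mreads), replace = TRUE)
      for (i in seq_along(mreads)) {
        b <- substr(mreads[i], pos[i], pos[i])
        substr(mreads[i], pos[i], pos[i]) <- sample(setdiff(DNA_BASES, b), 1)
      }
    } else {
      n_swaps <- pmax(rpois(length(mreads), 1), 1L)
      for (i in seq_along(mreads)) {
        pos <- sample.int(read_len, min(n_swaps[i], read_len))
        chars <- strsplit(mreads[i], "", fixed = TRUE)[[1]]
        chars[pos] <- other_base(chars[pos])
        mreads[i] <- paste(chars, collapse = "")
      }
    }
    hit <- lengths(Biostrings::vwhichPDict(pd_fwd, Biostrings::DNAStringSet(mreads))) > 0 |
      lengths(Biostrings::vwhichPDict(pd_fwd, Biostrings::DNAStringSet(revcomp(mreads)))) > 0
    rates[perm] <- 1000 * sum(hit) / n_draws
  }

  structure(list(
    rates = rates,
    mean = mean(rates),
    max = max(rates),
    n_permutations = n_permutations,
    n_draws = n_draws,
    p_error = p_error,
    seed = seed
  ), class = "permutation_result")
}

#' Compare an observed recombination rate with its error null
#'
#' @param observed_rate Observed recombination-read rate per 1000
#'   element-mapping reads.
#' @param permutation A `permutation_result`.
#' @param r_expected Closed-form expectation from
#'   [expected_false_recombinants()] (same per-1000 units).
#' @return One-row tibble: `observed`, `null_mean`, `null_max`,
#'   `r_expected`, `ratio_to_null_mean`, `exceeds_null_max`.
#' @export
compare_observed_to_null <- function(observed_rate, permutation, r_expected) {
  stopifnot(inherits(permutation, "permutation_result"))
  tibble(
    observed = observed_rate,
    null_mean = permutation$mean,
    null_max = permutation$max,
    r_expected = r_expected,
    ratio_to_null_mean = if (permutation$mean > 0) observed_rate / permutation$mean else Inf,
    exceeds_null_max = observed_rate > permutation$max
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations of %d draws (p_error = %.4f): mean %.2f, max %.2f per 1000 drawn reads\n",
              x$n_permutations, x$n_draws, x$p_error, x$mean, x$max))
  invisible(x)
}
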