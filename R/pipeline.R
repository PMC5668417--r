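#' Default end-to-end pipeline configuration
#'
#' All stage parameters with their defaults; unknown keys passed to
#' [run_burst_pipeline()] are rejected by name.
#'
#' @param ... Overrides of the default parameters.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_molecules = 40L,
    n_insertions = 20L,
    switch_rate = 0.2,
    r_transfer_recomb_prob = 0.8,
    rt_error_rate = 6.25e-5,
    tsd_length = 5L,
    coverage_genome = 30,
    coverage_ecdna = 20,
    per_base_error = 0,
    read_length = 150L,
    fragment_mean = 320,
    fragment_sd = 40,
    window_length = 145L,
    address_length = 70L,
    n_addresses = 3L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, overrides)
}

#' Run the full synthetic-burst benchmark pipeline
#'
#' Simulates a transposition burst on the given family, integrates a subset
#' of the ecDNA molecules into the host genome, sequences progeny and ecDNA,
#' and runs every analysis stage in dependency order: member assignment,
#' junction-library search, blunt-pair ecDNA classification, insertion
#' calling, painting and contribution scoring. A machine-readable manifest
#' recording every parameter and a content hash per output accompanies the
#' results; runs with identical seeds are reproducible.
#'
#' @param family A `family_model`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed; each stage derives its own sub-seed from it.
#' @return List of class `burst_pipeline` with components `burst`,
#'   `progeny`, `reads_progeny`, `reads_ecdna`, `addresses`, `counts`,
#'   `library`, `junction_hits`, `blunt_table`, `calls`, `painted`,
#'   `scores`, `recovery` (per-stage recall/precision summary) and
#'   `manifest`.
#' @export
run_burst_pipeline <- function(family, config = pipeline_config(), seed = 1L) {
  cfg <- family$config
  p <- config

  burst <- simulate_burst(family, n_molecules = p$n_molecules,
                          switch_rate = p$switch_rate,
                          r_transfer_recomb_prob = p$r_transfer_recomb_prob,
                          rt_error_rate = p$rt_error_rate,
                          seed = seed + 1L)
  progeny <- integrate_ecdna(burst, family, n_insertions = p$n_insertions,
                             tsd_length = p$tsd_length, seed = seed + 2L)

  reads_progeny <- sequence_reads(c(progeny_chr1 = progeny$genome),
                                  coverage = p$coverage_genome,
                                  read_length = p$read_length,
                                  fragment_mean = p$fragment_mean,
                                  fragment_sd = p$fragment_sd,
                                  per_base_error = p$per_base_error,
                                  seed = seed + 3L)
  control_reads <- sequence_reads(c(chr1 = family$genome),
                                  coverage = p$coverage_genome,
                                  read_length = p$read_length,
                                  fragment_mean = p$fragment_mean,
                                  fragment_sd = p$fragment_sd,
                                  per_base_error = p$per_base_error,
                                  seed = seed + 4L)
  ecdna_templates <- setNames(burst$ecdna$sequence,
                              paste0("ecDNA", burst$ecdna$molecule))
  reads_ecdna <- sequence_reads(ecdna_templates,
                                coverage = p$coverage_ecdna,
                                read_length = p$read_length,
                                fragment_mean = p$fragment_mean,
                                fragment_sd = p$fragment_sd,
                                per_base_error = p$per_base_error,
                                seed = seed + 5L)

  addresses <- derive_addresses(family, address_length = p$address_length,
                                n_addresses = p$n_addresses)
  counts <- count_member_reads(reads_ecdna, addresses,
                               library_size = 2L * nrow(reads_ecdna))
  counts <- split_group_counts(counts)

  library <- build_junction_library(family, window_length = p$window_length)
  element_reads <- 2L * nrow(reads_ecdna)
  hits <- search_junctions(reads_ecdna, library, element_reads)

  motif <- ltr_start_motif(family)
  blunt <- find_blunt_ltr_reads(reads_ecdna, motif) %>%
    perfect_pair_filter(family)
  blunt_assigned <- if (nrow(blunt) > 0) assign_pair_parents(blunt, family) else NULL
  blunt_table <- if (!is.null(blunt_assigned)) tabulate_pairs(blunt_assigned) else NULL

  masked <- mask_elements(family)
  anchors <- find_discordant_pairs(reads_progeny, masked, family)
  unmapped <- unmapped_reads(reads_progeny, masked$genome)
  junc <- find_junction_reads(unmapped, family, family$genome)
  ctrl_anchors <- find_discordant_pairs(control_reads, masked, family)
  ctrl_unmapped <- unmapped_reads(control_reads, masked$genome)
  ctrl_junc <- find_junction_reads(ctrl_unmapped, family, family$genome)
  calls <- call_insertions(anchors, junc, ctrl_anchors, ctrl_junc,
                           masked_intervals = masked$intervals)

  truth <- progeny$truth
  matched <- match_calls_to_truth(calls, truth)

  painted <- lapply(truth$molecule, function(mid) {
    paint_parentage(burst$ecdna$sequence[burst$ecdna$molecule == mid], family)
  })
  names(painted) <- paste0("ins_mol", truth$molecule)
  scores <- contribution_scores(painted, members = cfg$labels)

  recovery <- tibble(
    stage = c("insertion_calling_recall", "insertion_calling_precision"),
    value = c(matched$recall, matched$precision)
  )

  params_flat <- c(list(seed = seed), p)
  manifest <- tibble(
    component = c("parameters", "burst", "calls", "library"),
    hash = c(rlang::hash(params_flat), rlang::hash(burst$ecdna),
             rlang::hash(as.data.frame(calls)), rlang::hash(library$sequence))
  )

  structure(list(
    burst = burst, progeny = progeny,
    reads_progeny = reads_progeny, reads_ecdna = reads_ecdna,
    addresses = addresses, counts = counts,
    library = library, junction_hits = hits,
    blunt_pairs = blunt_assigned, blunt_table = blunt_table,
    calls = calls, painted = painted, scores = scores,
    recovery = recovery, manifest = manifest,
    seed = seed, config = p
  ), class = "burst_pipeline")
}

# Reads (both mates) without any exact hit on the masked genome.
unmapped_reads <- function(pairs, masked_genome) {
  reads <- c(pairs$mate1, pairs$mate2)
  hits <- map_reads_exact(reads, masked_genome)
  reads[setdiff(seq_along(reads), unique(hits$read))]
}

# Recall/precision of insertion calls against simulator truth.
match_calls_to_truth <- function(calls, truth, tol = 20L) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_,
                precision = if (nrow(calls) == 0) 1 else 0))
  }
  hit <- vapply(truth$start, function(s) {
    nrow(calls) > 0 && any(abs(calls$start - s) <= tol)
  }, logical(1))
  fp <- if (nrow(calls) == 0) 0L else
    sum(!vapply(calls$start, function(s) any(abs(truth$start - s) <= tol), logical(1)))
  list(recall = mean(hit),
       precision = if (nrow(calls) == 0) NA_real_ else 1 - fp / nrow(calls))
}

#' @export
print.burst_pipeline <- function(x, ...) {
  cat(sprintf("<burst_pipeline> seed %d: %d ecDNA molecules, %d insertions planted, %d called\n",
              x$seed, nrow(x$burst$ecdna), nrow(x$progeny$truth), nrow(x$calls)))
  print(x$recovery)
  invisible(x)
}
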