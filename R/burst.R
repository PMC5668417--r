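#' Simulate a transposition burst with intra-family recombination
#'
#' Each extrachromosomal DNA (ecDNA) molecule is reverse-transcribed from two
#' co-packaged transcripts drawn independently in proportion to the family's
#' expression weights (the retroviral "pseudodiploid" rule; drawing the same
#' member twice yields a single-parent molecule). Recombination enters in two
#' ways:
#'
#' * With probability `r_transfer_recomb_prob` the first strand transfer,
#'   which relies on R-region homology between the LTR ends of the template,
#'   lands on the co-packaged partner. The annealing happens within the R
#'   homology, but the minus-strand strong stop already carries R+U5 copied
#'   from the starting template's 5' LTR, so the observable sequence
#'   junction of the reconstituted LTR sits at the U3/R boundary: U3 from
#'   the partner's 3' LTR, R/U5 from the starting template's 5' LTR.
#'   Without the transfer-recombination the same chimera is formed within
#'   one parent.
#' * Internal copy-choice switches between the two templates are placed as a
#'   Poisson process at `switch_rate` per kb of internal (CDS) sequence.
#'
#' Both LTRs of a molecule are identical copies of the reconstituted LTR, as
#' dictated by the reverse-transcription mechanism. Reverse-transcriptase
#' substitution errors are placed uniformly at `rt_error_rate` per bp.
#'
#' @param family A `family_model`.
#' @param n_molecules Number of ecDNA molecules to synthesise.
#' @param switch_rate Internal template switches per kb of CDS sequence.
#' @param r_transfer_recomb_prob Probability that the first strand transfer
#'   uses the co-packaged partner's template.
#' @param rt_error_rate Substitutions per bp introduced by reverse
#'   transcriptase (default back-calculated from ~10 polymorphisms per
#'   160 kb of new insertions).
#' @param seed Integer seed.
#' @return A list of class `burst` with `ecdna` (tibble: `molecule`,
#'   `sequence`) and `truth` (class `burst_truth`: `molecules`,
#'   `switches`, `rt_errors` tibbles). `molecules` records the ordered
#'   parent pair (`parent_first` = template on which reverse transcription
#'   initiates, `parent_second` = co-packaged partner), the R-region
#'   junction column (`r_switch`, NA when the first transfer stayed on the
#'   starting template), the internal switch count and a `recombinant` flag
#'   (structurally hetero-parental molecule).
#' @export
simulate_burst <- function(family, n_molecules,
                           switch_rate = 0.2,
                           r_transfer_recomb_prob = 0.8,
                           rt_error_rate = 6.25e-5,
                           seed = 1L) {
  stopifnot(inherits(family, "family_model"))
  if (switch_rate < 0 || r_transfer_recomb_prob < 0 || r_transfer_recomb_prob > 1 ||
      rt_error_rate < 0) {
    abort("rates must be non-negative (and probabilities in [0, 1])")
  }
  cfg <- family$config
  w <- cfg$expression_weights
  if (sum(w) <= 0) abort("total expression weight is zero; no transcripts to package")
  set.seed(seed)

  L <- cfg$element_length
  ltr <- cfg$ltr_length
  u3 <- cfg$u3_length
  internal_cols <- (ltr + 1L):(L - ltr)
  internal_kb <- length(internal_cols) / 1000

  labels <- cfg$labels
  seq_chars <- lapply(family$alignment, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  mol_rows <- vector("list", n_molecules)
  switch_rows <- list()
  err_rows <- list()
  seqs <- character(n_molecules)

  for (i in seq_len(n_molecules)) {
    pair <- sample.int(cfg$n_members, 2L, replace = TRUE, prob = w)
    p1 <- pair[1]; p2 <- pair[2] # p1: template where RT initiates
    r_recomb <- runif(1) < r_transfer_recomb_prob
    after_transfer <- if (r_recomb) p2 else p1

    # reconstituted LTR: the minus-strand strong stop already carries R+U5
    # copied from p1's 5' LTR before the transfer anneals within the R
    # homology, so the sequence junction sits at the U3/R boundary: U3 from
    # the post-transfer template's 3' LTR, R/U5 from p1's 5' LTR
    j <- u3 + 1L
    ltr_chars <- c(
      seq_chars[[after_transfer]][(L - ltr + 1L):(L - ltr + u3)],
      seq_chars[[p1]][j:ltr]
    )

    # internal mosaic: Poisson switches alternate between the two templates
    n_sw <- rpois(1L, switch_rate * internal_kb)
    sw_cols <- if (p1 != p2 && n_sw > 0) sort(sample(internal_cols, min(n_sw, length(internal_cols)))) else integer(0)
    cur <- after_transfer
    internal_chars <- character(length(internal_cols))
    seg_start <- internal_cols[1]
    bounds <- c(sw_cols, L - ltr + 1L)
    for (b in bounds) {
      if (b > seg_start) {
        idx <- seg_start:(b - 1L)
        internal_chars[idx - ltr] <- seq_chars[[cur]][idx]
      }
      cur <- if (cur == p1) p2 else p1
      seg_start <- b
    }

    mol <- c(ltr_chars, internal_chars, ltr_chars)

    # RT substitution errors, uniform over the molecule
    n_err <- rbinom(1L, length(mol), rt_error_rate)
    err_pos <- if (n_err > 0) sort(sample.int(length(mol), n_err)) else integer(0)
    if (n_err > 0) {
      ref <- mol[err_pos]
      alt <- other_base(ref)
      mol[err_pos] <- alt
      err_rows[[length(err_rows) + 1L]] <- tibble(
        molecule = i, position = err_pos, ref = ref, alt = alt
      )
    }

    seqs[i] <- paste(mol, collapse = "")
    hetero <- p1 != p2 && ((r_recomb && j > 1L) || length(sw_cols) > 0)
    mol_rows[[i]] <- tibble(
      molecule = i,
      parent_first = labels[p1],
      parent_second = labels[p2],
      r_transfer_recombined = r_recomb && p1 != p2,
      r_switch = if (r_recomb && p1 != p2) j else NA_integer_,
      n_internal_switches = length(sw_cols),
      recombinant = hetero
    )
    if (length(sw_cols) > 0) {
      switch_rows[[length(switch_rows) + 1L]] <- tibble(molecule = i, column = sw_cols)
    }
  }

  truth <- structure(list(
    molecules = bind_rows(mol_rows),
    switches = if (length(switch_rows)) bind_rows(switch_rows) else
      tibble(molecule = integer(0), column = integer(0)),
    rt_errors = if (length(err_rows)) bind_rows(err_rows) else
      tibble(molecule = integer(0), position = integer(0),
             ref = character(0), alt = character(0)),
    seed = seed
  ), class = "burst_truth")

  structure(list(
    ecdna = tibble(molecule = seq_len(n_molecules), sequence = seqs),
    truth = truth,
    family = family
  ), class = "burst")
}

#' Ground-truth parental source intervals of one ecDNA molecule
#'
#' Reconstructs, from the recorded switch positions, which parent donated
#' each interval of the molecule (in molecule coordinates, 1-based
#' inclusive). Useful as an oracle for painting.
#'
#' @param burst A `burst`.
#' @param molecule Molecule id.
#' @return Tibble with `start`, `end`, `parent` (label) and `region`
#'   (`ltr5`, `internal`, `ltr3`).
#' @export
truth_source_intervals <- function(burst, molecule) {
  fam <- burst$family
  cfg <- fam$config
  L <- cfg$element_length
  ltr <- cfg$ltr_length
  mol <- burst$truth$molecules %>% filter(.data$molecule == !!molecule)
  if (nrow(mol) == 0) abort("unknown molecule id")
  sw <- burst$truth$switches %>% filter(.data$molecule == !!molecule) %>% pull("column")
  p1 <- mol$parent_first; p2 <- mol$parent_second
  after <- if (isTRUE(mol$r_transfer_recombined)) p2 else p1
  j <- mol$r_switch

  ltr_iv <- if (!is.na(j) && j > 1L) {
    tibble(start = c(1L, j), end = c(j - 1L, ltr), parent = c(after, p1))
  } else {
    tibble(start = 1L, end = ltr, parent = p1)
  }
  # internal
  bounds <- c(ltr + 1L, sw, L - ltr + 1L)
  cur <- after
  rows <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    rows[[k]] <- tibble(start = bounds[k], end = bounds[k + 1L] - 1L, parent = cur)
    cur <- if (cur == p1) p2 else p1
  }
  internal_iv <- bind_rows(rows)
  bind_rows(
    ltr_iv %>% mutate(region = "ltr5"),
    internal_iv %>% mutate(region = "internal"),
    ltr_iv %>% mutate(start = .data$start + (L - ltr), end = .data$end + (L - ltr),
                      region = "ltr3")
  )
}

#' Integrate ecDNA molecules into a host genome
#'
#' Inserts molecules at random host positions outside existing element
#' copies, duplicating `tsd_length` host bases at the target site (the
#' target-site duplication left by integrase). Insertion points are recorded
#' in the coordinates of the input genome as 0-based half-open intervals
#' covering the duplicated target site.
#'
#' @param burst A `burst` (or a tibble like its `$ecdna`).
#' @param family A `family_model`; its `genome` is the integration target.
#' @param n_insertions Number of molecules to integrate (without
#'   replacement).
#' @param tsd_length Target-site duplication length in bp.
#' @param min_spacing Minimum distance between insertion points.
#' @param element_margin Minimum distance between an insertion point and an
#'   existing element copy.
#' @param seed Integer seed.
#' @return List of class `progeny`: `genome` (progeny sequence), `truth`
#'   (tibble: `chrom`, `start`, `end` 0-based half-open, `molecule`,
#'   `strand`, `tsd_length`).
#' @export
integrate_ecdna <- function(burst, family = burst$family, n_insertions,
                            tsd_length = 5L, min_spacing = 2000L,
                            element_margin = 1200L, seed = 1L) {
  ecdna <- if (inherits(burst, "burst")) burst$ecdna else burst
  if (n_insertions > nrow(ecdna)) {
    abort("n_insertions exceeds the number of ecDNA molecules")
  }
  set.seed(seed)
  genome <- family$genome
  glen <- nchar(genome)

  forbidden <- family$genome_map %>%
    mutate(start = .data$start - element_margin, end = .data$end + element_margin)
  margin <- 1500L
  ok <- rep(TRUE, glen)
  ok[seq_len(min(margin, glen))] <- FALSE
  ok[max(1L, glen - margin):glen] <- FALSE
  for (k in seq_len(nrow(forbidden))) {
    a <- max(1L, forbidden$start[k]); b <- min(glen, forbidden$end[k])
    ok[a:b] <- FALSE
  }
  sites <- place_insertion_sites(ok, n_insertions, min_spacing)

  mols <- sample(ecdna$molecule, n_insertions)
  strands <- sample(c("+", "-"), n_insertions, replace = TRUE)

  truth <- tibble(
    chrom = "chr1",
    start = sites,            # 0-based: site p means insertion after base p
    end = sites + tsd_length, # duplicated target interval [p, p + tsd)
    molecule = mols,
    strand = strands,
    tsd_length = tsd_length
  )

  # apply insertions right-to-left so earlier coordinates stay valid
  prog <- genome
  ord <- order(sites, decreasing = TRUE)
  for (k in ord) {
    p <- sites[k]
    seq_in <- ecdna$sequence[ecdna$molecule == mols[k]]
    if (strands[k] == "-") seq_in <- revcomp(seq_in)
    prog <- paste0(
      substr(prog, 1L, p + tsd_length),
      seq_in,
      substr(prog, p + 1L, nchar(prog))
    )
  }

  structure(list(genome = prog, truth = truth, family = family,
                 seed = seed), class = "progeny")
}

# Distribute insertion sites over the admissible intervals (runs of TRUE in
# `ok`) proportionally to interval width, sampling inside each interval with
# the requested spacing and keeping clear of the interval edges.
place_insertion_sites <- function(ok, n, min_spacing, edge = 200L) {
  if (n == 0) return(integer(0))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values]) %>%
    mutate(start = .data$start + edge, end = .data$end - edge,
           width = .data$end - .data$start + 1L) %>%
    filter(.data$width >= min_spacing %/% 2L)
  if (nrow(runs) == 0) abort("genome too short for the requested number of insertions")
  cap <- pmax(1L, (runs$width %/% min_spacing) + 1L)
  if (sum(cap) < n) abort("genome too short for the requested number of insertions")
  alloc <- integer(nrow(runs))
  frac <- runs$width / sum(runs$width) * n
  alloc <- pmin(floor(frac), cap)
  while (sum(alloc) < n) {
    room <- which(alloc < cap)
    pick <- room[which.max(frac[room] - alloc[room])]
    alloc[pick] <- alloc[pick] + 1L
  }
  sites <- integer(0)
  for (k in seq_len(nrow(runs))) {
    if (alloc[k] == 0) next
    spacing_k <- min(min_spacing, runs$width[k] %/% max(alloc[k], 1L))
    sites <- c(sites, sample_spaced(runs$start[k]:runs$end[k], alloc[k],
                                    min_dist = max(spacing_k, 500L)))
  }
  sort(sites)
}
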