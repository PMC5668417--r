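# Small families and hand-built fixtures shared across tests.

# A compact 3-member family for fast unit tests.
toy_family <- function(seed = 42, ...) {
  make_family(family_config(
    n_members = 3,
    element_length = 1600L,
    ltr_length = 220L,
    u3_length = 150L,
    r_length = 40L,
    target_ltr_identities = c(1, 0.99, 0.97),
    inter_member_divergence = 0.003,
    expression_weights = c(2, 1, 1),
    labels = c("a", "b", "c"),
    flank_length = 1200L,
    seed = seed,
    ...
  ))
}

# A mid-size 4-member family for pipeline-level tests.
small_family <- function(seed = 7, ...) {
  make_family(family_config(
    n_members = 4,
    element_length = 2400L,
    ltr_length = 220L,
    u3_length = 150L,
    r_length = 40L,
    target_ltr_identities = c(1, 1, 0.98, 0.97),
    inter_member_divergence = 0.0021,
    expression_weights = c(3, 3, 2, 1),
    labels = c("m1", "m2", "m3", "m4"),
    flank_length = 5000L,
    seed = seed,
    ...
  ))
}

# Hand-built family-model stub from explicit member sequences (equal length,
# ungapped). Only the fields used by the function under test are guaranteed.
stub_family <- function(seqs, ltr_length, u3_length, r_length,
                        genome = NULL, flank = 400L) {
  n <- length(seqs)
  labels <- names(seqs) %||% paste0("s", seq_len(n))
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  if (is.null(genome)) {
    set.seed(99)
    pieces <- character(2L * n + 1L)
    pieces[1] <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    starts <- integer(n)
    off <- flank
    for (i in seq_len(n)) {
      starts[i] <- off + 1L
      pieces[2L * i] <- seqs[i]
      pieces[2L * i + 1L] <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
      off <- off + L + flank
    }
    genome <- paste(pieces, collapse = "")
  } else {
    starts <- rep(NA_integer_, n)
  }
  cfg <- list(
    n_members = n, element_length = L, ltr_length = as.integer(ltr_length),
    u3_length = as.integer(u3_length), r_length = as.integer(r_length),
    u5_length = as.integer(ltr_length - u3_length - r_length),
    labels = labels, expression_weights = rep(1, n),
    target_ltr_identities = rep(1, n), conserved_ltr_ends = 0L
  )
  class(cfg) <- "family_config"
  structure(list(
    members = tibble::tibble(id = seq_len(n), label = labels, sequence = unname(seqs)),
    alignment = stats::setNames(unname(seqs), labels),
    genome = genome,
    genome_map = tibble::tibble(label = labels, chrom = "chr1",
                                start = starts, end = starts + L - 1L),
    config = cfg
  ), class = "family_model")
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force junction-library oracle: every mosaic window (all combinations
# of observed variants at polymorphic columns), minus parental windows, minus
# genome occurrences on either strand. Independent of enumerate_fragments.
oracle_junction_library <- function(alignment, genome, window_length) {
  mat <- do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
  n_col <- ncol(mat)
  out <- character(0)
  for (s in seq_len(n_col - window_length + 1L)) {
    cols <- s:(s + window_length - 1L)
    variant_sets <- lapply(cols, function(j) unique(mat[, j]))
    grid <- expand.grid(variant_sets, stringsAsFactors = FALSE)
    frags <- apply(as.matrix(grid), 1, function(ch) {
      ch <- ch[ch != "-"]
      if (length(ch) < window_length) return(NA_character_)
      paste(ch, collapse = "")
    })
    out <- c(out, frags[!is.na(frags)])
  }
  out <- unique(out)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(out)))
  in_genome <- vapply(seq_along(out), function(i) {
    grepl(out[i], genome, fixed = TRUE) || grepl(rc[i], genome, fixed = TRUE)
  }, logical(1))
  sort(out[!in_genome])
}

# Minimal painted_element stub for scoring tests.
stub_painted <- function(parents, len = 100L) {
  structure(list(
    intervals = tibble::tibble(start = 1L, end = len,
                               members = list(parents), n_informative = 1L),
    assignment = tibble::tibble(
      start = seq_along(parents), end = seq_along(parents),
      parent = parents),
    novel = tibble::tibble(position = integer(0), base = character(0)),
    n_parents_minimal = length(unique(parents)),
    n_switches = max(length(unique(parents)) - 1L, 0L),
    length = len
  ), class = "painted_element")
}
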