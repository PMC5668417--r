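#' Simulate paired-end reads from linear templates
#'
#' Emulates PCR-free paired-end sequencing of a mixture of linear DNA
#' templates (a chromosome and/or ecDNA molecules). Each template copy is
#' fragmented by tiling from its 5' terminus with fragment lengths drawn
#' from a normal distribution, so linear ecDNA molecules naturally produce
#' read starts exactly at their blunt LTR extremities, while long
#' chromosomal templates yield effectively uniform fragment starts. Each
#' fragment is sequenced from both ends (forward/reverse orientation
#' assigned at random), and substitution errors are placed independently at
#' `per_base_error` per base.
#'
#' @param templates Named character vector of template sequences. Template
#'   copy number is proportional to `coverage`, identical for every
#'   template.
#' @param coverage Mean fold coverage per template.
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Fragment size distribution in bp.
#' @param per_base_error Substitution error probability per sequenced base
#'   (default 1/1060, i.e. about one mismatch per seven 150-bp reads).
#' @param seed Integer seed.
#' @return Tibble of class `read_pairs`: `pair_id`, `template`, `frag_start`
#'   (1-based on the template), `frag_end`, `strand` (orientation of mate 1),
#'   `mate1`, `mate2`. Mate 2 is reverse-complemented, as delivered by the
#'   sequencer.
#' @export
sequence_reads <- function(templates, coverage,
                           read_length = 150L,
                           fragment_mean = 500, fragment_sd = 60,
                           per_base_error = 1 / 1060,
                           seed = 1L) {
  if (coverage <= 0) abort("coverage must be positive")
  if (fragment_mean < read_length) abort("fragment_mean must be >= read_length")
  if (is.null(names(templates)) || any(!nzchar(names(templates)))) {
    abort("templates must be a named character vector")
  }
  set.seed(seed)

  # one tiling pass sequences 2 * read_length bases per fragment_mean bp
  passes_exact <- coverage * fragment_mean / (2 * read_length)
  rows <- list()
  for (tn in names(templates)) {
    tpl <- templates[[tn]]
    tlen <- nchar(tpl)
    if (tlen < fragment_mean) next
    n_passes <- floor(passes_exact) + (runif(1) < passes_exact %% 1)
    for (p in seq_len(n_passes)) {
      # expected fragments per pass, generous margin
      n_exp <- ceiling(tlen / max(fragment_mean - 3 * fragment_sd, read_length)) + 5L
      lens <- pmax(round(rnorm(n_exp, fragment_mean, fragment_sd)), read_length)
      ends <- cumsum(lens)
      keep <- which(ends <= tlen)
      if (length(keep) == 0) next
      starts <- c(1L, head(ends[keep], -1) + 1L)
      rows[[length(rows) + 1L]] <- tibble(
        template = tn,
        frag_start = as.integer(starts),
        frag_end = as.integer(ends[keep])
      )
    }
  }
  frags <- bind_rows(rows)
  if (nrow(frags) == 0) abort("no fragments produced; templates shorter than fragment size?")

  frags <- frags %>%
    mutate(
      pair_id = paste0("pair", row_number()),
      strand = sample(c("+", "-"), n(), replace = TRUE),
      fwd = substring(templates[.data$template], .data$frag_start,
                      .data$frag_start + read_length - 1L),
      rev = revcomp(substring(templates[.data$template],
                              .data$frag_end - read_length + 1L, .data$frag_end)),
      mate1 = unname(if_else(.data$strand == "+", .data$fwd, .data$rev)),
      mate2 = unname(if_else(.data$strand == "+", .data$rev, .data$fwd))
    ) %>%
    select("pair_id", "template", "frag_start", "frag_end", "strand", "mate1", "mate2")

  if (per_base_error > 0) {
    frags$mate1 <- add_read_errors(frags$mate1, per_base_error)
    frags$mate2 <- add_read_errors(frags$mate2, per_base_error)
  }
  class(frags) <- c("read_pairs", class(frags))
  frags
}

# Independent substitution errors at rate p per base.
add_read_errors <- function(reads, p) {
  n_err <- rbinom(length(reads), nchar(reads), p)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    chars[pos] <- other_base(chars[pos])
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Flatten read pairs to a single vector of read sequences
#'
#' @param x A `read_pairs` tibble, a character vector (returned as is), or a
#'   tibble with a `seq` column.
#' @return Character vector of read sequences.
#' @export
read_seqs <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if (all(c("mate1", "mate2") %in% names(x))) return(c(x$mate1, x$mate2))
    if ("seq" %in% names(x)) return(x$seq)
  }
  abort("cannot extract read sequences; expected read_pairs, character vector or tibble with `seq`")
}

#' Write paired reads to FASTQ files
#'
#' Placeholder Phred-33 qualities ("I") are emitted; the simulator does not
#' model quality scores.
#'
#' @param pairs A `read_pairs` tibble.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  write_one(pairs$mate1, paste0(pairs$pair_id, "/1"), r1_path)
  write_one(pairs$mate2, paste0(pairs$pair_id, "/2"), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1_path,r2_path FASTQ paths with mates in matching order.
#' @return Tibble with `pair_id`, `mate1`, `mate2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2)) abort("mate files differ in read count")
  tibble(
    pair_id = sub("/1$", "", names(r1)),
    mate1 = unname(as.character(r1)),
    mate2 = unname(as.character(r2))
  )
}
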