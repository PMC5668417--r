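#' Read and write FASTA
#'
#' Wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning/consuming named character
#' vectors.
#'
#' @param x Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x)
  names(s) <- names(x)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Read and write BED intervals
#'
#' Minimal BED3+ support with 0-based half-open intervals; zero-length
#' intervals are rejected.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional further
#'   columns (written as BED columns 4+).
#' @param path File path.
#' @return `read_bed()` returns a tibble `chrom`, `start`, `end`, `name`
#'   (when present).
#' @export
write_bed <- function(x, path) {
  if (any(x$end <= x$start)) abort("BED intervals must have end > start (half-open, non-empty)")
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  base_names <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6L))] <- base_names[seq_len(min(ncol(x), 6L))]
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)
    abort(sprintf("BED interval of non-positive length at line %s",
                  paste(bad, collapse = ", ")))
  }
  as_tibble(x)
}

#' Read SAM alignments into a tibble
#'
#' Converts a text SAM file with [Rsamtools::asBam()] and imports the core
#' alignment fields; soft-clips are preserved in the CIGAR string.
#'
#' @param path Path to a SAM file (with header).
#' @return Tibble: `qname`, `flag`, `rname`, `pos` (1-based), `mapq`,
#'   `cigar`, `seq`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")))[[1]]
  tibble(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq)
  )
}

#' Write alignments to a text SAM file
#'
#' @param x Tibble as returned by [read_sam()].
#' @param path Output path.
#' @param seqinfo Named integer vector of reference lengths for the header.
#' @export
write_sam <- function(x, path, seqinfo) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo), seqinfo))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  x$qname, x$flag, x$rname, x$pos, x$mapq, x$cigar, x$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}
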