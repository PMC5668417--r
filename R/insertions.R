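#' Mask element copies in a reference genome
#'
#' Replaces every chromosomal member copy with `N`s so that element-derived
#' reads cannot map and insertion evidence concentrates at junctions.
#'
#' @param family A `family_model`.
#' @return List: `genome` (masked sequence), `intervals` (tibble of masked
#'   1-based inclusive intervals).
#' @export
mask_elements <- function(family) {
  genome <- family$genome
  for (k in seq_len(nrow(family$genome_map))) {
    s <- family$genome_map$start[k]
    e <- family$genome_map$end[k]
    substr(genome, s, e) <- strrep("N", e - s + 1L)
  }
  list(genome = genome, intervals = family$genome_map)
}

#' Map fixed-length reads to a genome by exact matching
#'
#' Minimal built-in mapper for synthetic genomes: exact full-length matching
#' of every read on both strands via a pattern dictionary. Reads with
#' sequencing errors do not map (they are "unmapped"), which is the
#' behaviour the insertion-calling contracts rely on for synthetic data; a
#' production SAM from any external aligner can be supplied instead via
#' [read_sam()].
#'
#' @param reads Character vector of equal-length reads.
#' @param genome Genome sequence (character scalar).
#' @return Tibble: `read` (index), `pos` (1-based start of the match on the
#'   forward strand), `strand`, `n_hits` (total hits across both strands;
#'   rows are emitted only for mapped reads, one per hit).
#' @export
map_reads_exact <- function(reads, genome) {
  if (length(reads) == 0) {
    return(tibble(read = integer(0), pos = integer(0),
                  strand = character(0), n_hits = integer(0)))
  }
  widths <- unique(nchar(reads))
  if (length(widths) != 1) abort("reads must have equal length for the exact mapper")
  subj <- Biostrings::DNAString(genome)
  glen <- nchar(genome)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(reads)))
  res <- list()
  fwd <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
  n_fwd <- lengths(fwd)
  if (sum(n_fwd) > 0) {
    res$f <- tibble(read = rep(seq_along(reads), n_fwd),
                    pos = unlist(fwd), strand = "+")
  }
  rc <- Biostrings::startIndex(
    Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj)))
  n_rc <- lengths(rc)
  if (sum(n_rc) > 0) {
    res$r <- tibble(read = rep(seq_along(reads), n_rc),
                    pos = glen - (unlist(rc) + widths - 1L) + 1L, strand = "-")
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(read = integer(0), pos = integer(0),
                  strand = character(0), n_hits = integer(0)))
  }
  out %>% group_by(.data$read) %>% mutate(n_hits = n()) %>% ungroup()
}

#' Find discordant read pairs anchoring new element insertions
#'
#' Recovers pairs in which exactly one mate maps uniquely to the
#' element-masked genome while the other is unmapped yet matches an element
#' LTR (exact substring of a member overlapping an LTR interval, either
#' strand). The mapped mate anchors the putative insertion; its strand
#' tells on which side of the anchor the insertion lies.
#'
#' @param pairs A `read_pairs` tibble.
#' @param masked Output of [mask_elements()].
#' @param family A `family_model`.
#' @return Tibble: `pair_id`, `chrom`, `anchor_pos` (1-based start of the
#'   mapped mate), `anchor_strand`, `side` (`right`/`left`: insertion
#'   expected downstream/upstream of the anchor), `element_mate` (sequence
#'   of the element-side mate).
#' @export
find_discordant_pairs <- function(pairs, masked, family) {
  n <- nrow(pairs)
  if (n == 0) {
    return(tibble(pair_id = character(0), chrom = character(0),
                  anchor_pos = integer(0), anchor_strand = character(0),
                  side = character(0), element_mate = character(0)))
  }
  reads <- c(pairs$mate1, pairs$mate2)
  hits <- map_reads_exact(reads, masked$genome)
  uniq <- hits %>% filter(.data$n_hits == 1L)
  mapped_unique <- logical(2L * n)
  mapped_unique[uniq$read] <- TRUE
  mapped_any <- logical(2L * n)
  mapped_any[unique(hits$read)] <- TRUE

  pos_of <- rep(NA_integer_, 2L * n)
  strand_of <- rep(NA_character_, 2L * n)
  pos_of[uniq$read] <- uniq$pos
  strand_of[uniq$read] <- uniq$strand

  idx1 <- seq_len(n); idx2 <- n + idx1
  one_mapped <- (mapped_unique[idx1] & !mapped_any[idx2]) |
    (mapped_unique[idx2] & !mapped_any[idx1])
  cand <- which(one_mapped)
  if (length(cand) == 0) {
    return(tibble(pair_id = character(0), chrom = character(0),
                  anchor_pos = integer(0), anchor_strand = character(0),
                  side = character(0), element_mate = character(0)))
  }
  anchor_is_m1 <- mapped_unique[idx1][cand]
  anchor_idx <- ifelse(anchor_is_m1, idx1[cand], idx2[cand])
  elem_mate <- ifelse(anchor_is_m1, pairs$mate2[cand], pairs$mate1[cand])

  ltr_hit <- mate_matches_ltr(elem_mate, family)

  out <- tibble(
    pair_id = pairs$pair_id[cand],
    chrom = "chr1",
    anchor_pos = pos_of[anchor_idx],
    anchor_strand = strand_of[anchor_idx],
    side = if_else(strand_of[anchor_idx] == "+", "right", "left"),
    element_mate = elem_mate
  )
  out[ltr_hit, ]
}

# TRUE where the mate carries element LTR sequence: a terminal segment of
# the mate (either end, either strand) occurs verbatim inside a member LTR.
# Terminal segments make boundary-spanning mates (part flank, part LTR)
# detectable, as a local aligner would.
mate_matches_ltr <- function(mates, family, seed_length = 60L) {
  cfg <- family$config
  L <- cfg$element_length
  ltr <- cfg$ltr_length
  ltr_text <- unlist(lapply(family$members$sequence, function(s) {
    c(substr(s, 1L, ltr), substr(s, L - ltr + 1L, L))
  }))
  ltr_text <- paste(c(ltr_text, revcomp(ltr_text)), collapse = "NNNN")
  n <- nchar(mates)
  segs <- cbind(substr(mates, 1L, seed_length),
                substr(mates, n - seed_length + 1L, n))
  stringr::str_detect(ltr_text, stringr::fixed(segs[, 1])) |
    stringr::str_detect(ltr_text, stringr::fixed(segs[, 2]))
}

#' Find element/genome junction reads
#'
#' Recognises reads (unmapped on the masked genome) that carry an LTR
#' extremity -- the element's first or last `motif_length` bases -- at an
#' internal offset, trims away the element part, and exactly re-maps the
#' residual genomic fragment. The junction coordinate is the genomic base
#' adjacent to the element edge, so 5'-side and 3'-side junctions of one
#' insertion differ by exactly the target-site duplication length.
#'
#' @param reads Character vector of unmapped reads.
#' @param family A `family_model`.
#' @param genome Unmasked reference genome to re-map flanks against.
#' @param motif_length LTR extremity seed length in bp.
#' @param min_flank Minimum mappable genomic residual in bp.
#' @return Tibble: `read` (index), `side` (`left`: genome then element
#'   start; `right`: element end then genome), `chrom`, `coord` (1-based
#'   genomic base adjacent to the element edge), `flank_len`. Reads whose
#'   residual is shorter than `min_flank` are counted in attribute
#'   `n_discarded_short`.
#' @export
find_junction_reads <- function(reads, family, genome, motif_length = 20L,
                                min_flank = 25L) {
  L <- family$config$element_length
  start_motif <- substr(family$members$sequence[1], 1L, motif_length)
  end_motif <- substr(family$members$sequence[1], L - motif_length + 1L, L)

  rows <- list()
  n_short <- 0L
  add_junction <- function(i, flank, element_side) {
    # element_side: "start" (flank precedes the element start motif in the
    # oriented read) or "end" (flank follows the element end motif). A flank
    # mapping on the minus strand means the element was inserted in reverse
    # orientation: the genomic side of the junction flips.
    if (nchar(flank) < min_flank) {
      n_short <<- n_short + 1L
      return()
    }
    loc <- locate_unique_stranded(genome, flank)
    if (is.null(loc)) return()
    if (element_side == "start") {
      side <- if (loc$strand == "+") "left" else "right"
      coord <- if (loc$strand == "+") loc$end else loc$start
    } else {
      side <- if (loc$strand == "+") "right" else "left"
      coord <- if (loc$strand == "+") loc$start else loc$end
    }
    rows[[length(rows) + 1L]] <<- tibble(
      read = i, side = side, chrom = "chr1",
      coord = coord, flank_len = nchar(flank))
  }
  for (i in seq_along(reads)) {
    for (orient in 1:2) {
      r <- if (orient == 1) reads[i] else revcomp(reads[i])
      rl <- nchar(r)
      # genome | element-start
      p <- stringr::str_locate(r, stringr::fixed(start_motif))[1, "start"]
      if (!is.na(p) && p > 1L) add_junction(i, substr(r, 1L, p - 1L), "start")
      # element-end | genome
      q <- stringr::str_locate(r, stringr::fixed(end_motif))[1, "end"]
      if (!is.na(q) && q < rl) add_junction(i, substr(r, q + 1L, rl), "end")
    }
  }
  out <- if (length(rows)) bind_rows(rows) %>% distinct() else
    tibble(read = integer(0), side = character(0), chrom = character(0),
           coord = integer(0), flank_len = integer(0))
  attr(out, "n_discarded_short") <- n_short
  out
}

# Unique exact occurrence on either strand: list(start, end, strand) in
# forward coordinates, or NULL when absent/ambiguous.
locate_unique_stranded <- function(genome, pattern) {
  fwd <- stringr::str_locate_all(genome, stringr::fixed(pattern))[[1]]
  rev <- stringr::str_locate_all(genome, stringr::fixed(revcomp(pattern)))[[1]]
  if (nrow(fwd) + nrow(rev) != 1L) return(NULL)
  if (nrow(fwd) == 1L) {
    list(start = unname(fwd[1, "start"]), end = unname(fwd[1, "end"]), strand = "+")
  } else {
    list(start = unname(rev[1, "start"]), end = unname(rev[1, "end"]), strand = "-")
  }
}

#' Call new element insertions
#'
#' Clusters discordant-pair anchors and junction reads along the genome,
#' requires both evidence classes (at least `min_discordant` anchors and
#' `min_junction_per_edge` junction reads on each edge), intersects the
#' treated sample against an identically processed control, and removes
#' clusters at pre-existing chromosomal element copies (the positive
#' controls of the approach). Calls are reported as 0-based half-open
#' intervals covering the duplicated target site, so `end - start` is the
#' resolved TSD length.
#'
#' @param anchors Discordant anchors from [find_discordant_pairs()].
#' @param junctions Junction records from [find_junction_reads()].
#' @param control_anchors,control_junctions The same for the control sample
#'   (empty tibbles for none).
#' @param masked_intervals Tibble of pre-existing element intervals (from
#'   [mask_elements()]`$intervals`).
#' @param cluster_width Maximum gap between evidence positions within one
#'   cluster, in bp.
#' @param min_discordant Minimum discordant-pair anchors per call.
#' @param min_junction_per_edge Minimum junction reads per edge per call.
#' @return Tibble of class `insertion_calls`: `chrom`, `start`, `end`
#'   (0-based half-open), `tsd_length`, `n_discordant`, `n_junction_left`,
#'   `n_junction_right`, `present_in_control`. Control-positive and
#'   evidence-poor clusters are dropped from the returned calls.
#' @export
call_insertions <- function(anchors, junctions,
                            control_anchors = NULL, control_junctions = NULL,
                            masked_intervals = NULL,
                            cluster_width = 500L,
                            min_discordant = 2L,
                            min_junction_per_edge = 1L) {
  clusters <- cluster_evidence(anchors, junctions, cluster_width)
  empty <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                  tsd_length = integer(0), n_discordant = integer(0),
                  n_junction_left = integer(0), n_junction_right = integer(0),
                  present_in_control = logical(0))
  if (nrow(clusters) == 0) {
    return(structure(empty, class = c("insertion_calls", class(empty))))
  }

  ctrl <- cluster_evidence(control_anchors, control_junctions, cluster_width)

  calls <- clusters %>%
    filter(.data$n_discordant >= min_discordant,
           .data$n_junction_left >= min_junction_per_edge,
           .data$n_junction_right >= min_junction_per_edge,
           !is.na(.data$left_coord), !is.na(.data$right_coord))
  if (nrow(calls) == 0) {
    return(structure(empty, class = c("insertion_calls", class(empty))))
  }

  calls <- calls %>%
    mutate(
      start = .data$right_coord - 1L, # 0-based first base of the target site
      end = .data$left_coord,         # half-open: one past the last TSD base
      tsd_length = .data$end - .data$start,
      present_in_control = purrr::map_lgl(.data$start, function(s) {
        nrow(ctrl) > 0 && any(abs(ctrl$mid - s) <= cluster_width)
      })
    )

  if (!is.null(masked_intervals) && nrow(masked_intervals) > 0) {
    near_element <- purrr::map_lgl(calls$start, function(s) {
      any(s >= masked_intervals$start - cluster_width &
            s <= masked_intervals$end + cluster_width)
    })
    calls <- calls[!near_element, ]
  }

  out <- calls %>%
    filter(!.data$present_in_control, .data$tsd_length > 0L) %>%
    arrange(.data$start) %>%
    select("chrom", "start", "end", "tsd_length", "n_discordant",
           "n_junction_left", "n_junction_right", "present_in_control")
  structure(out, class = c("insertion_calls", class(out)))
}

# Merge anchors + junctions into positional clusters; per cluster, modal
# left/right junction coordinates define the insertion point.
cluster_evidence <- function(anchors, junctions, cluster_width) {
  ev <- list()
  if (!is.null(anchors) && nrow(anchors) > 0) {
    ev$a <- anchors %>%
      mutate(kind = "discordant", coord = NA_integer_, side = .data$side,
             pos = .data$anchor_pos) %>%
      select("chrom", "pos", "kind", "side", "coord")
  }
  if (!is.null(junctions) && nrow(junctions) > 0) {
    ev$j <- junctions %>%
      mutate(kind = "junction", pos = .data$coord) %>%
      select("chrom", "pos", "kind", "side", "coord")
  }
  ev <- bind_rows(ev)
  if (is.null(ev) || nrow(ev) == 0) {
    return(tibble(chrom = character(0), mid = double(0),
                  n_discordant = integer(0), n_junction_left = integer(0),
                  n_junction_right = integer(0), left_coord = integer(0),
                  right_coord = integer(0)))
  }
  ev <- ev %>% arrange(.data$pos) %>%
    mutate(cluster = cumsum(c(1L, as.integer(diff(.data$pos) > cluster_width))))
  ev %>%
    group_by(.data$chrom, .data$cluster) %>%
    summarise(
      mid = stats::median(.data$pos),
      n_discordant = sum(.data$kind == "discordant"),
      n_junction_left = sum(.data$kind == "junction" & .data$side == "left"),
      n_junction_right = sum(.data$kind == "junction" & .data$side == "right"),
      left_coord = mode_int(.data$coord[.data$kind == "junction" & .data$side == "left"]),
      right_coord = mode_int(.data$coord[.data$kind == "junction" & .data$side == "right"]),
      .groups = "drop"
    )
}

mode_int <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Reconstruct the LTR of a called insertion
#'
#' Greedy exact-overlap assembly of element-side mates anchored near the
#' insertion point (plus element portions of junction reads), seeded at the
#' family-shared LTR start motif. Because both LTRs of an integrated element
#' are identical, the 5'-edge assembly reconstructs the element's LTR.
#'
#' @param call One row of an `insertion_calls` tibble.
#' @param anchors Discordant anchors (with `element_mate` sequences).
#' @param junction_reads Character vector of the junction-read sequences
#'   near the call (optional extra evidence).
#' @param family A `family_model`.
#' @param window Anchor window around the insertion point in bp.
#' @param min_overlap Minimum exact suffix/prefix overlap for extension.
#' @return List of class `ltr_reconstruction`: `sequence` (assembled LTR,
#'   trimmed to the family LTR length), `complete` (reached full LTR
#'   length), `n_reads_used`.
#' @export
reconstruct_ltr <- function(call, anchors, junction_reads = character(0),
                            family, window = 1200L, min_overlap = 40L) {
  ltr_len <- family$config$ltr_length
  motif <- ltr_start_motif(family)

  near <- anchors %>%
    filter(.data$anchor_pos >= call$start - window,
           .data$anchor_pos <= call$end + window)
  pool <- unique(c(near$element_mate, revcomp(near$element_mate),
                   junction_reads, revcomp(junction_reads)))
  if (length(pool) == 0) {
    return(structure(list(sequence = "", complete = FALSE, n_reads_used = 0L),
                     class = "ltr_reconstruction"))
  }

  starts_with_motif <- stringr::str_starts(pool, stringr::fixed(motif))
  seeds <- pool[starts_with_motif]
  contig <- if (length(seeds)) seeds[which.max(nchar(seeds))] else {
    # fall back: trim a junction read at the motif
    with_motif <- pool[stringr::str_detect(pool, stringr::fixed(motif))]
    if (length(with_motif) == 0) {
      return(structure(list(sequence = "", complete = FALSE, n_reads_used = 0L),
                       class = "ltr_reconstruction"))
    }
    p <- stringr::str_locate(with_motif[1], stringr::fixed(motif))[1, "start"]
    substr(with_motif[1], p, nchar(with_motif[1]))
  }

  used <- 1L
  repeat {
    if (nchar(contig) >= ltr_len) break
    best_ext <- 0L
    best_seq <- NULL
    for (s in pool) {
      ov <- overlap_len(contig, s, min_overlap)
      ext <- nchar(s) - ov
      if (ov >= min_overlap && ext > best_ext) {
        best_ext <- ext
        best_seq <- s
        best_ov <- ov
      }
    }
    if (is.null(best_seq)) break
    contig <- paste0(contig, substr(best_seq, best_ov + 1L, nchar(best_seq)))
    used <- used + 1L
  }

  structure(list(
    sequence = substr(contig, 1L, ltr_len),
    complete = nchar(contig) >= ltr_len,
    n_reads_used = used
  ), class = "ltr_reconstruction")
}

# Longest exact overlap (suffix of a, prefix of b), at least min_ov, else 0.
overlap_len <- function(a, b, min_ov) {
  max_ov <- min(nchar(a), nchar(b))
  if (max_ov < min_ov) return(0L)
  for (ov in max_ov:min_ov) {
    if (substr(a, nchar(a) - ov + 1L, nchar(a)) == substr(b, 1L, ov)) return(ov)
  }
  0L
}
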