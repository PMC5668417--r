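#' Configure a synthetic LTR retrotransposon family
#'
#' Describes the family to be realised by [make_family()]: how many members,
#' the element architecture (LTR subdivided into U3 and R/U5, flanking a
#' central coding sequence), the per-member 5'/3' LTR identity targets that
#' encode member age, the inter-member divergence accumulated since the
#' common ancestral insertion, and per-member expression weights used when
#' transcripts are co-packaged during a burst.
#'
#' Inter-member polymorphisms are placed partly in paired clusters (two
#' substitutions within a short distance) and partly as isolated sites,
#' emulating the polymorphic hotspots of real retroelement families. Paired
#' clusters guarantee that a read covering one member-distinguishing site
#' usually covers a second one nearby, which is the regime assumed by the
#' closed-form sequencing-error model (see the methods vignette).
#'
#' @param n_members Number of family members.
#' @param element_length Full element length in bp (5' LTR + internal + 3' LTR).
#' @param ltr_length LTR length in bp.
#' @param u3_length Length of the U3 sub-domain of the LTR in bp.
#' @param r_length Length of the R sub-domain in bp; U5 takes the remainder.
#' @param target_ltr_identities Numeric vector of length `n_members`; target
#'   5' vs 3' LTR identity per member as a fraction in `[0, 1]`. 1 means a
#'   young member with identical LTRs.
#' @param inter_member_divergence Substitutions per bp separating each member
#'   lineage from the common ancestor (applied over the element's unique
#'   sequence; LTR mutations predate LTR aging and appear in both copies).
#' @param expression_weights Non-negative per-member weights; relative
#'   transcript/ecDNA abundance during a burst.
#' @param labels Optional member labels (default `member1..n`).
#' @param twin_pair Optional length-2 vector of member indices realised as a
#'   near-identical pair: the second twin shares the first twin's lineage and
#'   differs by exactly one distinguishing substitution placed next to a
#'   shared polymorphic cluster.
#' @param u3_sites_per_lineage Member-specific polymorphic sites placed in
#'   the U3 sub-domain of each young lineage's LTR (members with target
#'   identity 1; old members carry LTR-distinguishing sites through their
#'   aging mutations already). U3 is the fastest-diverging part of
#'   retroelement LTRs, and at least one LTR-borne site per member is what
#'   makes blunt-end ecDNA reads assignable to members.
#' @param conserved_ltr_ends Number of bp at each LTR extremity protected
#'   from all mutations (terminal inverted motifs are strongly conserved in
#'   Ty1/copia elements); also guarantees a family-shared LTR start motif for
#'   blunt-end ecDNA detection.
#' @param flank_length Host sequence length between consecutive chromosomal
#'   member copies (and at both genome ends).
#' @param seed Integer seed driving all randomness in [make_family()].
#' @return A `family_config` list.
#' @seealso [onsen_like_family_config()] for the default 8-member burst setup.
#' @export
family_config <- function(n_members,
                          element_length = 5500L,
                          ltr_length = 220L,
                          u3_length = 150L,
                          r_length = 40L,
                          target_ltr_identities = rep(1, n_members),
                          inter_member_divergence = 0.00076,
                          expression_weights = rep(1, n_members),
                          labels = paste0("member", seq_len(n_members)),
                          twin_pair = NULL,
                          u3_sites_per_lineage = 1L,
                          conserved_ltr_ends = 20L,
                          flank_length = 8000L,
                          seed = 1L) {
  u5_length <- ltr_length - u3_length - r_length
  if (u5_length <= 0) {
    abort("ltr_length must exceed u3_length + r_length (U3 + R/U5 must tile the LTR)")
  }
  if (2L * ltr_length >= element_length) {
    abort("element_length must exceed twice ltr_length")
  }
  if (length(target_ltr_identities) != n_members) {
    abort("target_ltr_identities must have one entry per member")
  }
  if (any(target_ltr_identities > 1 | target_ltr_identities < 0)) {
    abort("target_ltr_identities must lie in [0, 1]; identities above 100% are impossible")
  }
  if (length(expression_weights) != n_members || any(expression_weights < 0)) {
    abort("expression_weights must be non-negative, one per member")
  }
  if (sum(expression_weights) <= 0) {
    abort("expression_weights must sum to a positive value")
  }
  if (inter_member_divergence < 0) abort("inter_member_divergence must be >= 0")
  if (!is.null(twin_pair) &&
      (length(twin_pair) != 2 || any(twin_pair > n_members) || twin_pair[1] == twin_pair[2])) {
    abort("twin_pair must name two distinct member indices")
  }
  structure(list(
    n_members = as.integer(n_members),
    element_length = as.integer(element_length),
    ltr_length = as.integer(ltr_length),
    u3_length = as.integer(u3_length),
    r_length = as.integer(r_length),
    u5_length = as.integer(u5_length),
    target_ltr_identities = target_ltr_identities,
    inter_member_divergence = inter_member_divergence,
    expression_weights = expression_weights,
    labels = labels,
    twin_pair = if (is.null(twin_pair)) NULL else as.integer(twin_pair),
    u3_sites_per_lineage = as.integer(u3_sites_per_lineage),
    conserved_ltr_ends = as.integer(conserved_ltr_ends),
    flank_length = as.integer(flank_length),
    seed = as.integer(seed)
  ), class = "family_config")
}

#' Default 8-member heat-burst family configuration
#'
#' An eight-member family mirroring a heat-activated Ty1/copia family in
#' Arabidopsis: three young members with identical LTRs, two members at 99%
#' 5'/3' LTR identity, one at 98% and two at 97%; the two most homologous
#' young members form a near-identical twin pair separated by a single
#' distinguishing polymorphism. Expression weights follow the qualitative
#' heat-induced ecDNA pattern of such a family: young members dominate, two
#' mid-aged members contribute, one old member is strongly reactivated, and
#' one member produces no ecDNA at all (weight 0).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [family_config()].
#' @return A `family_config`.
#' @export
onsen_like_family_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_members = 8L,
    target_ltr_identities = c(1, 1, 1, 0.99, 0.99, 0.98, 0.97, 0.97),
    expression_weights = c(20, 15, 20, 8, 6, 1, 0, 15),
    labels = c("red", "yellow", "grey", "violet", "blue", "orange", "white", "green"),
    twin_pair = c(1L, 2L),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(family_config, args)
}

# Lineage mutation positions in unique-sequence coordinates. Polymorphic
# regions of all lineages are allocated jointly with a global minimum
# spacing, so each lineage's sites sit in regions independent of every
# other lineage's (no cross-lineage hotspot collisions); each lineage gets
# paired clusters (two substitutions within a short distance) for ~2/3 of
# its sites plus isolated singletons.
place_all_lineage_mutations <- function(n_lineages, n_mut, candidates) {
  if (n_mut == 0 || n_lineages == 0) {
    return(replicate(n_lineages, integer(0), simplify = FALSE))
  }
  n_pairs <- n_mut %/% 3L
  n_single <- n_mut - 2L * n_pairs
  n_regions <- n_pairs + n_single
  n_anchors <- n_lineages * n_regions
  spacing <- max(60L, min(200L, (max(candidates) - min(candidates)) %/% (n_anchors + 1L)))
  anchors <- sample_spaced(candidates, n_anchors, min_dist = spacing)
  anchors <- sample(anchors) # shuffle before dealing out to lineages
  out <- vector("list", n_lineages)
  k <- 0L
  for (m in seq_len(n_lineages)) {
    pos <- integer(0)
    for (i in seq_len(n_regions)) {
      k <- k + 1L
      if (i <= n_pairs) {
        pos <- c(pos, anchors[k], anchors[k] + sample(20:50, 1))
      } else {
        pos <- c(pos, anchors[k])
      }
    }
    out[[m]] <- sort(unique(pos))
  }
  out
}

#' Realise a synthetic retrotransposon family
#'
#' Generates member element sequences from a common random ancestor, applies
#' per-lineage polymorphisms and per-member LTR aging so that realised 5'/3'
#' LTR identities match their targets to within 0.5 percentage points, and
#' embeds exactly one chromosomal copy of every member in a random host
#' genome with unique flanks. Because divergence is modelled as substitutions
#' only, member sequences are mutually aligned position-by-position and the
#' family multiple alignment is gap-free.
#'
#' @param config A [family_config()].
#' @return A `family_model`: list with `members` (tibble of id, label,
#'   sequence), `alignment` (named character vector, here equal to the member
#'   sequences), `genome` (host chromosome containing one copy of each
#'   member), `genome_map` (tibble of member copy coordinates, 1-based
#'   inclusive), `domains` (tibble tiling the element into U3/R-U5/CDS
#'   domains for both LTRs) and the `config`.
#' @examples
#' fam <- make_family(family_config(n_members = 3, element_length = 1200,
#'   ltr_length = 200, u3_length = 80, r_length = 40, seed = 42))
#' ltr_identity(fam)
#' @export
make_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  L <- config$element_length
  ltr <- config$ltr_length
  ce <- config$conserved_ltr_ends
  unique_len <- L - ltr # LTR counted once + internal

  ancestor <- random_dna(unique_len)

  # conserved LTR extremities are excluded from all mutation processes;
  # lineage sites live in the internal (CDS) region so every member-private
  # site is single-copy (LTR diversity comes from aging and the U3 sites)
  ltr_ok <- setdiff(seq_len(ltr), c(seq_len(ce), (ltr - ce + 1L):ltr))
  internal_ok <- (ltr + 1L):unique_len
  candidates <- internal_ok

  n_lin <- round(config$inter_member_divergence * unique_len)

  twin <- config$twin_pair
  lineage_of <- seq_len(config$n_members)
  if (!is.null(twin)) lineage_of[twin[2]] <- twin[1]

  lineage_pos <- vector("list", config$n_members)
  lineage_base <- vector("list", config$n_members)
  anc_chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  founders <- which(lineage_of == seq_len(config$n_members))
  placed <- place_all_lineage_mutations(length(founders), n_lin, candidates)
  # member-specific U3 sites for young lineages (old members are already
  # LTR-distinguishable through aging)
  young <- config$target_ltr_identities[founders] >= 1
  n_u3 <- config$u3_sites_per_lineage
  u3_sites <- stats::setNames(vector("list", length(founders)), NULL)
  if (n_u3 > 0 && any(young)) {
    pool <- sample((ce + 1L):config$u3_length)
    need <- which(young)
    for (k in seq_along(need)) {
      u3_sites[[need[k]]] <- pool[seq.int((k - 1L) * n_u3 + 1L, k * n_u3)]
    }
  }
  for (fi in seq_along(founders)) {
    m <- founders[fi]
    pos <- sort(unique(c(placed[[fi]], u3_sites[[fi]])))
    lineage_pos[[m]] <- pos
    lineage_base[[m]] <- other_base(anc_chars[pos])
  }
  # twin: shared lineage plus exactly one distinguishing substitution placed
  # next to a shared cluster so both allele windows are twin-specific
  if (!is.null(twin)) {
    src <- twin[1]
    lineage_pos[[twin[2]]] <- lineage_pos[[src]]
    lineage_base[[twin[2]]] <- lineage_base[[src]]
    anchor_pool <- lineage_pos[[src]]
    if (length(anchor_pool) > 0) {
      anchor <- sample(anchor_pool, 1)
      dpos <- anchor + sample(c(-15:-5, 5:15), 1)
      dpos <- min(max(dpos, min(candidates)), max(candidates))
    } else {
      dpos <- sample(candidates, 1)
    }
    while (dpos %in% lineage_pos[[src]]) dpos <- dpos + 1L
    lineage_pos[[twin[2]]] <- sort(c(lineage_pos[[twin[2]]], dpos))
    ins <- match(dpos, lineage_pos[[twin[2]]])
    lineage_base[[twin[2]]] <- append(lineage_base[[src]],
                                      other_base(anc_chars[dpos]), after = ins - 1L)
  }

  # LTR aging: exact number of 5'-vs-3' differences per member, pair-clustered
  members <- vector("list", config$n_members)
  for (m in seq_len(config$n_members)) {
    uniq <- mutate_bases(ancestor, lineage_pos[[m]], lineage_base[[m]])
    ltr_seq <- substr(uniq, 1L, ltr)
    internal <- substr(uniq, ltr + 1L, unique_len)

    n_age <- round((1 - config$target_ltr_identities[m]) * ltr)
    age_pos <- if (n_age > 0) {
      n_pairs <- n_age %/% 2L
      anchors <- sample_spaced(ltr_ok[ltr_ok <= ltr - ce - 50L],
                               max(n_pairs, 1L), min_dist = 45L)
      pos <- integer(0)
      for (a in seq_len(n_pairs)) pos <- c(pos, anchors[a], anchors[a] + sample(20:40, 1))
      if (n_age %% 2L == 1L) pos <- c(pos, anchors[length(anchors)] + 44L)
      sort(unique(pos))[seq_len(n_age)]
    } else integer(0)
    ltr_chars <- strsplit(ltr_seq, "", fixed = TRUE)[[1]]
    to5 <- if (length(age_pos)) as.logical(rbinom(length(age_pos), 1, 0.5)) else logical(0)
    ltr5 <- ltr_chars; ltr3 <- ltr_chars
    ltr5[age_pos[to5]] <- other_base(ltr_chars[age_pos[to5]])
    ltr3[age_pos[!to5]] <- other_base(ltr_chars[age_pos[!to5]])
    members[[m]] <- list(
      ltr5 = paste(ltr5, collapse = ""),
      ltr3 = paste(ltr3, collapse = ""),
      internal = internal
    )
  }

  seqs <- vapply(members, function(x) paste0(x$ltr5, x$internal, x$ltr3), character(1))
  names(seqs) <- config$labels

  if (config$inter_member_divergence > 0 || any(config$target_ltr_identities < 1)) {
    if (anyDuplicated(seqs)) {
      abort("realised members are not mutually distinguishable; use a different seed or higher divergence")
    }
  }

  flank <- config$flank_length
  pieces <- character(2L * config$n_members + 1L)
  pieces[1] <- random_dna(flank)
  starts <- integer(config$n_members)
  offset <- flank
  for (m in seq_len(config$n_members)) {
    starts[m] <- offset + 1L
    pieces[2L * m] <- seqs[m]
    pieces[2L * m + 1L] <- random_dna(flank)
    offset <- offset + L + flank
  }
  genome <- paste(pieces, collapse = "")

  u3 <- config$u3_length
  domains <- tibble(
    domain = c("u3_5", "r_u5_5", "cds", "u3_3", "r_u5_3"),
    start = c(1L, u3 + 1L, ltr + 1L, L - ltr + 1L, L - ltr + u3 + 1L),
    end = c(u3, ltr, L - ltr, L - ltr + u3, L)
  )

  fam <- structure(list(
    members = tibble(
      id = seq_len(config$n_members),
      label = config$labels,
      sequence = unname(seqs)
    ),
    alignment = seqs,
    genome = genome,
    genome_map = tibble(
      label = config$labels,
      chrom = "chr1",
      start = starts,
      end = starts + L - 1L
    ),
    domains = domains,
    config = config
  ), class = "family_model")
  fam
}

#' Realised 5' vs 3' LTR identity of each member
#'
#' @param family A `family_model`.
#' @return Tibble with `label`, `identity` (fraction of identical LTR
#'   positions) and `n_diff`.
#' @export
ltr_identity <- function(family) {
  cfg <- family$config
  L <- cfg$element_length
  ltr <- cfg$ltr_length
  family$members %>%
    mutate(
      ltr5 = substr(.data$sequence, 1L, ltr),
      ltr3 = substr(.data$sequence, L - ltr + 1L, L),
      n_diff = purrr::map2_int(.data$ltr5, .data$ltr3, function(a, b) {
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      }),
      identity = 1 - .data$n_diff / ltr
    ) %>%
    select("label", "identity", "n_diff")
}

#' Reconstituted LTR of a single parental member
#'
#' During reverse transcription the new element's two identical LTRs are
#' assembled from the template's 3' LTR (U3 portion) and 5' LTR (R/U5
#' portion). For young members with identical LTRs this equals either LTR;
#' for old members it is a within-member chimera of the two LTR copies.
#'
#' @param family A `family_model`.
#' @param label Member label.
#' @return Single LTR sequence (character).
#' @export
reconstituted_ltr <- function(family, label) {
  cfg <- family$config
  seq <- family$alignment[[label]]
  if (is.null(seq)) abort(sprintf("unknown member '%s'", label))
  L <- cfg$element_length
  ltr <- cfg$ltr_length
  u3 <- cfg$u3_length
  u3_from_3 <- substr(seq, L - ltr + 1L, L - ltr + u3)
  ru5_from_5 <- substr(seq, u3 + 1L, ltr)
  paste0(u3_from_3, ru5_from_5)
}

#' @export
print.family_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<family_model> %d members, element %d bp (LTR %d bp), genome %d bp\n",
              cfg$n_members, cfg$element_length, cfg$ltr_length, nchar(x$genome)))
  ids <- ltr_identity(x)
  cat(paste(sprintf("  %-8s 5'/3' LTR identity %.1f%%", ids$label, 100 * ids$identity),
            collapse = "\n"), "\n")
  invisible(x)
}
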