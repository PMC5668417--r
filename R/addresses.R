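#' Derive member-specific address sequences
#'
#' Scans the family for fixed-length windows ("addresses") that occur in
#' exactly one member's sequence (exact match, either strand, single copy),
#' and selects per member `n_addresses` of them anchored in independent
#' regions (selected windows are non-overlapping and separated by at least
#' one address length). Members without enough unique windows are pooled
#' into near-identical groups that share group addresses (windows present in
#' all and only the group members) plus one distinguishing-polymorphism
#' address per group member, mirroring the pool-then-split treatment of
#' highly homologous member pairs. Members that can neither be resolved nor
#' grouped are reported as unassignable.
#'
#' @param family A `family_model`.
#' @param address_length Address length in bp.
#' @param n_addresses Addresses per member (or group).
#' @return An `address_set`: list with `addresses` (tibble: `address_id`,
#'   `owner`, `scope` = member/group/distinguishing, `member`, `sequence`,
#'   `start`), `groups` (tibble: `group`, `members` list-column) and
#'   `unassignable` (character).
#' @export
derive_addresses <- function(family, address_length = 70L, n_addresses = 3L) {
  members <- family$members
  win_tbl <- purrr::map2_dfr(members$label, members$sequence, function(lab, seq) {
    w <- sliding_windows(seq, address_length)
    tibble(member = lab, start = seq_along(w), window = w)
  })
  if (nrow(win_tbl) == 0) abort("member sequences shorter than address_length")
  rc <- revcomp(win_tbl$window)
  win_tbl$canonical <- pmin(win_tbl$window, rc)

  occ <- win_tbl %>%
    group_by(.data$canonical) %>%
    summarise(
      members = list(unique(.data$member)),
      n_occ = n(),
      .groups = "drop"
    )
  occ_members <- setNames(occ$members, occ$canonical)
  occ_n <- setNames(occ$n_occ, occ$canonical)

  win_tbl <- win_tbl %>%
    mutate(
      n_members = lengths(occ_members[.data$canonical]),
      n_occ = unname(occ_n[.data$canonical])
    )

  # greedy selection of independent (well-separated) windows
  pick_independent <- function(starts, gap) {
    sel <- integer(0)
    last <- -Inf
    for (i in seq_along(starts)) {
      if (starts[i] >= last + gap) {
        sel <- c(sel, i)
        last <- starts[i]
      }
    }
    sel
  }
  gap <- 2L * address_length

  unique_windows <- win_tbl %>% filter(.data$n_members == 1L, .data$n_occ == 1L)

  addr_rows <- list()
  groups <- list()
  unassignable <- character(0)
  deficient <- character(0)

  for (lab in members$label) {
    uw <- unique_windows %>% filter(.data$member == lab) %>% arrange(.data$start)
    sel <- pick_independent(uw$start, gap)
    if (length(sel) >= n_addresses) {
      # spread the chosen addresses across the available regions
      take <- sel[round(seq(1, length(sel), length.out = n_addresses))]
      addr_rows[[length(addr_rows) + 1L]] <- tibble(
        owner = lab, scope = "member", member = lab,
        sequence = uw$window[take], start = uw$start[take]
      )
    } else {
      deficient <- c(deficient, lab)
    }
  }

  # try to resolve deficient members as near-identical pairs
  if (length(deficient) >= 2) {
    combos <- utils::combn(deficient, 2, simplify = FALSE)
    for (pr in combos) {
      if (!all(pr %in% deficient)) next
      pair_windows <- win_tbl %>%
        filter(.data$member == pr[1], .data$n_occ == 2L) %>%
        filter(purrr::map_lgl(occ_members[.data$canonical],
                              ~ setequal(.x, pr))) %>%
        arrange(.data$start)
      sel <- pick_independent(pair_windows$start, gap)
      identical_pair <- family$alignment[[pr[1]]] == family$alignment[[pr[2]]]
      d1 <- unique_windows %>% filter(.data$member == pr[1])
      d2 <- unique_windows %>% filter(.data$member == pr[2])
      has_distinguishing <- nrow(d1) >= 1 && nrow(d2) >= 1
      if (length(sel) >= n_addresses && (has_distinguishing || identical_pair)) {
        gid <- paste(pr, collapse = "+")
        take <- sel[round(seq(1, length(sel), length.out = n_addresses))]
        addr_rows[[length(addr_rows) + 1L]] <- tibble(
          owner = gid, scope = "group", member = NA_character_,
          sequence = pair_windows$window[take], start = pair_windows$start[take]
        )
        if (has_distinguishing) {
          mid1 <- d1$start[which.min(abs(d1$start - stats::median(d1$start)))][1]
          mid2 <- d2$start[which.min(abs(d2$start - stats::median(d2$start)))][1]
          addr_rows[[length(addr_rows) + 1L]] <- bind_rows(
            d1 %>% filter(.data$start == mid1) %>% slice(1) %>%
              mutate(owner = gid, scope = "distinguishing") %>%
              select("owner", "scope", "member", sequence = "window", "start"),
            d2 %>% filter(.data$start == mid2) %>% slice(1) %>%
              mutate(owner = gid, scope = "distinguishing") %>%
              select("owner", "scope", "member", sequence = "window", "start")
          )
        } else {
          warn(sprintf("group '%s' has no distinguishing polymorphism; counts cannot be split",
                       gid))
        }
        groups[[length(groups) + 1L]] <- tibble(group = gid, members = list(pr))
        deficient <- setdiff(deficient, pr)
      }
    }
  }

  # leftover deficient members: individual with fewer addresses, or unassignable
  for (lab in deficient) {
    uw <- unique_windows %>% filter(.data$member == lab) %>% arrange(.data$start)
    sel <- pick_independent(uw$start, gap)
    if (length(sel) >= 1) {
      warn(sprintf("member '%s' has only %d independent unique windows (requested %d)",
                   lab, length(sel), n_addresses))
      addr_rows[[length(addr_rows) + 1L]] <- tibble(
        owner = lab, scope = "member", member = lab,
        sequence = uw$window[sel], start = uw$start[sel]
      )
    } else {
      unassignable <- c(unassignable, lab)
    }
  }

  addresses <- bind_rows(addr_rows)
  if (nrow(addresses) > 0) {
    addresses <- addresses %>%
      mutate(address_id = paste0("addr", row_number())) %>%
      select("address_id", "owner", "scope", "member", "sequence", "start")
  } else {
    addresses <- tibble(address_id = character(0), owner = character(0),
                        scope = character(0), member = character(0),
                        sequence = character(0), start = integer(0))
  }

  structure(list(
    addresses = addresses,
    groups = if (length(groups)) bind_rows(groups) else
      tibble(group = character(0), members = list()),
    unassignable = unassignable,
    address_length = address_length,
    n_addresses = n_addresses
  ), class = "address_set")
}

#' Count reads per family member by perfect address matching
#'
#' A read increments an address count iff the address occurs as an exact
#' substring of the read or of its reverse complement. The per-member raw
#' count is the arithmetic mean over that member's addresses; pooled groups
#' are counted on their shared group addresses and reported as one row
#' (split them with [split_group_counts()]). Counts are normalised per
#' million reads of `library_size`.
#'
#' @param reads Reads: a `read_pairs` tibble, character vector, or tibble
#'   with a `seq` column.
#' @param addresses An `address_set`.
#' @param library_size Mapped-library size used for normalisation (e.g. the
#'   number of genome-mapped reads).
#' @return Tibble of class `member_counts`: `member`, `is_group`,
#'   `raw_mean`, `normalized`, `library_size`. Per-address and
#'   distinguishing-address counts are attached as attributes
#'   `address_counts`.
#' @export
count_member_reads <- function(reads, addresses, library_size) {
  stopifnot(inherits(addresses, "address_set"))
  if (library_size <= 0) abort("library_size must be positive")
  seqs <- read_seqs(reads)

  addr <- addresses$addresses
  hit_count <- vapply(addr$sequence, function(a) {
    if (length(seqs) == 0) return(0L)
    sum(stringr::str_detect(seqs, stringr::fixed(a)) |
          stringr::str_detect(seqs, stringr::fixed(revcomp(a))))
  }, integer(1), USE.NAMES = FALSE)
  addr_counts <- addr %>% mutate(count = hit_count)

  counts <- addr_counts %>%
    filter(.data$scope %in% c("member", "group")) %>%
    group_by(member = .data$owner) %>%
    summarise(raw_mean = mean(.data$count),
              is_group = first(.data$scope) == "group", .groups = "drop") %>%
    mutate(normalized = .data$raw_mean * 1e6 / library_size,
           library_size = library_size) %>%
    select("member", "is_group", "raw_mean", "normalized", "library_size")

  structure(counts, class = c("member_counts", class(counts)),
            address_counts = addr_counts, groups = addresses$groups)
}

#' Split pooled group counts by distinguishing polymorphisms
#'
#' Apportions each pooled group count between the group members using the
#' ratio of reads observed at the members' distinguishing-polymorphism
#' addresses. With zero coverage at the distinguishing site the pooled
#' count is reported unsplit and flagged.
#'
#' @param counts A `member_counts` from [count_member_reads()].
#' @return Tibble of class `member_counts` with one row per member;
#'   `split_flag` marks groups that could not be split.
#' @export
split_group_counts <- function(counts) {
  addr_counts <- attr(counts, "address_counts")
  groups <- attr(counts, "groups")
  out <- counts %>% filter(!.data$is_group) %>%
    mutate(split_flag = NA_character_)
  for (k in seq_len(nrow(groups))) {
    gid <- groups$group[k]
    mem <- groups$members[[k]]
    pooled <- counts %>% filter(.data$member == gid)
    if (nrow(pooled) == 0) next
    disc <- addr_counts %>%
      filter(.data$owner == gid, .data$scope == "distinguishing")
    tot <- sum(disc$count)
    if (tot == 0) {
      out <- bind_rows(out, pooled %>%
        mutate(split_flag = "unsplit: no coverage at distinguishing site"))
      next
    }
    frac <- setNames(disc$count / tot, disc$member)
    for (m in mem) {
      out <- bind_rows(out, pooled %>%
        mutate(member = m, is_group = FALSE,
               raw_mean = .data$raw_mean * frac[[m]],
               normalized = .data$normalized * frac[[m]],
               split_flag = NA_character_))
    }
  }
  structure(out, class = c("member_counts", class(tibble())),
            address_counts = addr_counts, groups = groups)
}

#' Heat-minus-control differential member abundance
#'
#' Subtracts control normalised counts from heat-sample normalised counts
#' member by member; with DNA-seq inputs this estimates the heat-induced
#' extrachromosomal DNA abundance of each member over its chromosomal
#' baseline.
#'
#' @param heat_counts,control_counts `member_counts` tibbles normalised on
#'   their own library sizes.
#' @return Tibble: `member`, `heat`, `control`, `differential`.
#' @export
ecdna_abundance <- function(heat_counts, control_counts) {
  left_join(
    heat_counts %>% select("member", heat = "normalized"),
    control_counts %>% select("member", control = "normalized"),
    by = "member"
  ) %>%
    mutate(control = dplyr::coalesce(.data$control, 0),
           differential = .data$heat - .data$control)
}
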