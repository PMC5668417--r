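test_that("identical members collapse into an unsplittable group", {
  fam <- make_family(family_config(
    n_members = 2, element_length = 1600, ltr_length = 220,
    u3_length = 150, r_length = 40,
    inter_member_divergence = 0, u3_sites_per_lineage = 0, seed = 1))
  expect_identical(fam$alignment[[1]], fam$alignment[[2]])
  ad <- suppressWarnings(derive_addresses(fam))
  expect_equal(nrow(ad$groups), 1)
  expect_setequal(ad$groups$members[[1]], fam$members$label)
  expect_false(any(ad$addresses$scope == "member"))
  expect_false(any(ad$addresses$scope == "distinguishing"))
  expect_length(ad$unassignable, 0)
})

test_that("a member's addresses are anchored at its private polymorphisms", {
  fam <- toy_family()
  ad <- derive_addresses(fam)
  own <- ad$addresses[ad$addresses$scope == "member", ]
  expect_true(nrow(own) > 0)
  for (k in seq_len(nrow(own))) {
    in_members <- vapply(fam$members$sequence, function(s) {
      grepl(own$sequence[k], s, fixed = TRUE) ||
        grepl(revcomp(own$sequence[k]), s, fixed = TRUE)
    }, logical(1))
    expect_identical(fam$members$label[in_members], own$member[k])
  }
})

test_that("the 8-member default family mirrors the pool-then-split address pattern", {
  fam <- make_family(onsen_like_family_config(seed = 3))
  ad <- derive_addresses(fam)
  own <- table(ad$addresses$owner[ad$addresses$scope == "member"])
  expect_length(own, 6) # six individually resolvable members
  expect_true(all(own == 3))
  expect_equal(ad$groups$group, "red+yellow")
  grp <- ad$addresses[ad$addresses$owner == "red+yellow", ]
  expect_equal(sum(grp$scope == "group"), 3)
  expect_setequal(grp$member[grp$scope == "distinguishing"], c("red", "yellow"))
  expect_length(ad$unassignable, 0)
})

test_that("address counting is exact, strand-symmetric and mean-based", {
  fam <- toy_family()
  ad <- derive_addresses(fam)
  addr_a <- ad$addresses[ad$addresses$owner == "a" & ad$addresses$scope == "member", ]
  # one read per address of member a, one of them reverse-complemented
  reads <- addr_a$sequence
  reads[2] <- revcomp(reads[2])
  counts <- count_member_reads(reads, ad, library_size = 1e6)
  expect_equal(counts$raw_mean[counts$member == "a"], 1)
  expect_equal(counts$raw_mean[counts$member != "a"], rep(0, sum(counts$member != "a")))
  expect_equal(counts$normalized[counts$member == "a"], 1)

  # strand symmetry: reverse-complementing every read changes nothing
  counts_rc <- count_member_reads(revcomp(reads), ad, library_size = 1e6)
  expect_equal(counts$raw_mean, counts_rc$raw_mean)

  # normalisation: doubling the library size halves normalised counts
  half <- count_member_reads(reads, ad, library_size = 2e6)
  expect_equal(half$normalized, counts$normalized / 2)

  # empty read set: zero counts, not an error
  zero <- count_member_reads(character(0), ad, library_size = 10)
  expect_true(all(zero$raw_mean == 0))
})

test_that("error-free reads from one member never count toward another", {
  fam <- toy_family()
  ad <- derive_addresses(fam)
  tpl <- c(a = fam$alignment[["a"]])
  rp <- sequence_reads(tpl, coverage = 10, per_base_error = 0, seed = 5)
  counts <- count_member_reads(rp, ad, library_size = 2 * nrow(rp))
  expect_gt(counts$raw_mean[counts$member == "a"], 0)
  expect_equal(counts$raw_mean[counts$member %in% c("b", "c")], c(0, 0))
})

test_that("group counts split by the distinguishing-polymorphism ratio", {
  fam <- make_family(onsen_like_family_config(seed = 3))
  ad <- derive_addresses(fam)
  grp <- ad$addresses[ad$addresses$owner == "red+yellow", ]
  g_addr <- grp$sequence[grp$scope == "group"]
  d_red <- grp$sequence[grp$scope == "distinguishing" & grp$member == "red"]
  d_yellow <- grp$sequence[grp$scope == "distinguishing" & grp$member == "yellow"]

  reads <- c(rep(g_addr, each = 4), rep(d_red, 3), rep(d_yellow, 1))
  counts <- count_member_reads(reads, ad, library_size = 1e6)
  split <- split_group_counts(counts)
  red <- split$raw_mean[split$member == "red"]
  yellow <- split$raw_mean[split$member == "yellow"]
  expect_equal(red / (red + yellow), 0.75)
  expect_equal(red + yellow, counts$raw_mean[counts$member == "red+yellow"])

  # no coverage at the distinguishing site: pooled, flagged
  counts0 <- count_member_reads(rep(g_addr, 2), ad, library_size = 1e6)
  split0 <- split_group_counts(counts0)
  expect_true(any(grepl("unsplit", split0$split_flag)))
})

test_that("differential abundance subtracts normalised controls", {
  heat <- tibble::tibble(member = c("a", "b"), normalized = c(10, 4))
  ctrl <- tibble::tibble(member = c("a", "b"), normalized = c(10, 1))
  d <- ecdna_abundance(heat, ctrl)
  expect_equal(d$differential, c(0, 3))
  d2 <- ecdna_abundance(heat, tibble::tibble(member = character(0), normalized = numeric(0)))
  expect_equal(d2$differential, c(10, 4))
})

test_that("a simulated heat induction is recovered by subtraction", {
  fam <- toy_family()
  ad <- derive_addresses(fam)
  # control: genomic copies only; heat: genome + strong ecDNA burst of member a
  ctrl_rp <- sequence_reads(c(g = fam$genome), coverage = 20, per_base_error = 0, seed = 6)
  b <- simulate_burst(fam, 12, switch_rate = 0, r_transfer_recomb_prob = 0,
                      rt_error_rate = 0, seed = 7)
  mols <- b$ecdna$sequence[b$truth$molecules$parent_first == "a"]
  heat_genomic <- sequence_reads(c(g = fam$genome), coverage = 20,
                                 per_base_error = 0, seed = 8)
  heat_rp <- rbind(
    heat_genomic,
    sequence_reads(stats::setNames(mols, paste0("m", seq_along(mols))),
                   coverage = 30, per_base_error = 0, seed = 9))
  # library size = genome-mapped reads, so ecDNA gain is not self-diluting
  ctrl <- count_member_reads(ctrl_rp, ad, library_size = 2 * nrow(ctrl_rp))
  heat <- count_member_reads(heat_rp, ad, library_size = 2 * nrow(heat_genomic))
  d <- ecdna_abundance(heat, ctrl)
  expect_gt(d$differential[d$member == "a"],
            3 * max(abs(d$differential[d$member %in% c("b", "c")])))
})
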