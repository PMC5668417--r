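test_that("the LTR start motif must be family-shared", {
  fam <- toy_family()
  motif <- ltr_start_motif(fam)
  expect_equal(nchar(motif), 20)
  expect_true(all(startsWith(fam$members$sequence, motif)))

  divergent <- stub_family(c(a = paste0("AAAA", rand_dna(96, seed = 1)),
                             b = paste0("CCCC", rand_dna(96, seed = 2))),
                           ltr_length = 30, u3_length = 20, r_length = 5)
  expect_error(ltr_start_motif(divergent), "shared")
})

test_that("blunt candidates require the motif at position zero", {
  fam <- toy_family()
  motif <- ltr_start_motif(fam)
  elem <- fam$alignment[[1]]
  good5 <- substr(elem, 1, 150)
  inner <- substr(elem, 301, 450)
  offset <- paste0("G", substr(elem, 1, 149)) # one extra upstream base
  pairs <- tibble::tibble(
    pair_id = c("p1", "p2", "p3"),
    mate1 = c(good5, offset, revcomp(inner)),
    mate2 = c(revcomp(inner), revcomp(inner), good5))
  out <- find_blunt_ltr_reads(pairs, motif)
  expect_setequal(out$pair_id, c("p1", "p3"))
  expect_true(all(out$mate5 == good5))
  expect_true(all(out$mate3 == inner))
})

test_that("the perfect-pair filter removes any mismatching mate", {
  fam <- toy_family()
  elem <- fam$alignment[[1]]
  cand <- tibble::tibble(
    pair_id = c("ok", "bad"),
    mate5 = rep(substr(elem, 1, 150), 2),
    mate3 = c(substr(elem, 301, 450), substr(elem, 301, 450)))
  substr(cand$mate3[2], 75, 75) <- "N"
  kept <- perfect_pair_filter(cand, fam)
  expect_equal(kept$pair_id, "ok")
})

test_that("a recombinant pair with the junction between the mates is retained", {
  fam <- toy_family()
  a <- fam$alignment[["a"]]; c_ <- fam$alignment[["c"]]
  chim <- paste0(substr(a, 1, 400), substr(c_, 401, nchar(c_)))
  cand <- tibble::tibble(pair_id = "chimera",
                         mate5 = substr(chim, 1, 150),
                         mate3 = substr(chim, 401, 550))
  kept <- perfect_pair_filter(cand, fam)
  expect_equal(nrow(kept), 1)
})

test_that("parental assignment classifies disjoint member sets as discriminatory", {
  fam <- toy_family()
  a <- fam$alignment[["a"]]; c_ <- fam$alignment[["c"]]
  # pick internal windows private to each member (ecDNA-form compatible)
  ad <- suppressWarnings(derive_addresses(fam, address_length = 150, n_addresses = 3))
  cfg <- fam$config
  own <- ad$addresses[ad$addresses$scope == "member" &
                        ad$addresses$start > cfg$ltr_length &
                        ad$addresses$start + 150 <= cfg$element_length - cfg$ltr_length, ]
  win_a <- own$sequence[own$member == "a"][1]
  win_c <- own$sequence[own$member == "c"][1]
  expect_false(is.na(win_a) || is.na(win_c))
  pairs <- tibble::tibble(
    pair_id = c("same", "cross"),
    mate5 = c(win_a, win_a),
    mate3 = c(win_a, win_c))
  asg <- assign_pair_parents(pairs, fam)
  expect_equal(asg$classification, c("non-discriminatory", "discriminatory"))
  expect_equal(asg$members5[[1]], "a")
  expect_equal(asg$members3[[2]], "c")

  tab <- tabulate_pairs(asg)
  expect_equal(tab$n_discriminatory, 1)
  expect_equal(tab$n_non_discriminatory, 1)
  expect_equal(tab$n_total, 2)
  empty <- tabulate_pairs(asg[0, ])
  expect_equal(empty$n_total, 0)
})

test_that("classification partitions pairs and ignores member order", {
  fam <- toy_family()
  b <- simulate_burst(fam, 20, rt_error_rate = 0, seed = 4)
  tpl <- stats::setNames(b$ecdna$sequence, paste0("m", b$ecdna$molecule))
  rp <- sequence_reads(tpl, coverage = 10, fragment_mean = 320, fragment_sd = 40,
                       per_base_error = 0, seed = 5)
  blunt <- perfect_pair_filter(find_blunt_ltr_reads(rp, ltr_start_motif(fam)), fam)
  asg <- assign_pair_parents(blunt, fam)
  expect_equal(sum(asg$classification == "discriminatory") +
                 sum(asg$classification == "non-discriminatory"), nrow(asg))

  fam_rev <- fam
  fam_rev$members <- fam$members[rev(seq_len(nrow(fam$members))), ]
  asg_rev <- assign_pair_parents(blunt, fam_rev)
  expect_equal(asg$classification, asg_rev$classification)
  expect_equal(lapply(asg$members5, sort), lapply(asg_rev$members5, sort))
})

test_that("reads from element-free sequence never qualify as blunt", {
  fam <- toy_family()
  flank_only <- substr(fam$genome, 1, 1000) # leading flank, no element
  rp <- sequence_reads(c(f = flank_only), coverage = 20, per_base_error = 0, seed = 6)
  out <- find_blunt_ltr_reads(rp, ltr_start_motif(fam))
  expect_equal(nrow(out), 0)
})

test_that("discriminatory pairs arise only from hetero-parental molecules", {
  fam <- make_family(onsen_like_family_config(seed = 3))
  b <- simulate_burst(fam, 30, rt_error_rate = 0, seed = 11)
  tpl <- stats::setNames(b$ecdna$sequence, paste0("ecDNA", b$ecdna$molecule))
  rp <- sequence_reads(tpl, coverage = 15, fragment_mean = 320, fragment_sd = 40,
                       per_base_error = 0, seed = 12)
  blunt <- perfect_pair_filter(find_blunt_ltr_reads(rp, ltr_start_motif(fam)), fam)
  asg <- assign_pair_parents(blunt, fam)
  mol <- as.integer(sub("ecDNA", "", rp$template[match(asg$pair_id, rp$pair_id)]))
  recomb <- b$truth$molecules$recombinant[mol]
  expect_gt(sum(asg$classification == "discriminatory"), 0)
  expect_equal(sum(asg$classification == "discriminatory" & !recomb), 0)
})
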