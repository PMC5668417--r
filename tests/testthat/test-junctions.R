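test_that("consensus collapsing marks exactly the polymorphic columns", {
  al <- c(x = "ACGTACGT", y = "ACGTACGT")
  cp <- build_consensus(al)
  expect_equal(nrow(cp$wildcards), 0)

  al2 <- c(x = "ACGTACGT", y = "ACGTGCGT")
  cp2 <- build_consensus(al2)
  expect_equal(cp2$wildcards$column, 5L)
  expect_equal(cp2$wildcards$variants[[1]], c("A", "G"))

  # indel polymorphism contributes a gap variant
  al3 <- c(x = "ACGTACGT", y = "ACG--CGT")
  cp3 <- build_consensus(al3)
  expect_equal(cp3$wildcards$column, c(4L, 5L))
  expect_true(all(vapply(cp3$wildcards$variants, function(v) "-" %in% v, logical(1))))

  expect_error(build_consensus(character(0)), "empty")
})

test_that("a toy two-wildcard window enumerates and purges as expected", {
  # two members, two biallelic sites inside a 10-bp window
  x <- "AAAACAAAGA"
  y <- "AAAATAAACA"
  genome <- paste0(rand_dna(30, seed = 1), x, rand_dna(25, seed = 2),
                   y, rand_dna(30, seed = 3))
  cp <- build_consensus(c(x = x, y = y))
  lib <- enumerate_fragments(cp, genome, window_length = 10)
  cnt <- attr(lib, "counts")
  expect_equal(unname(cnt["raw"]), 4)      # 2 x 2 combinations
  expect_equal(nrow(lib), 2)               # parental two purged by the genome
  expect_setequal(lib$sequence, c("AAAACAAACA", "AAAATAAAGA"))
})

test_that("per-window combination counts follow the product rule", {
  # variant lists of sizes 3 and 2 -> 6 raw combinations
  al <- c(a = "AAACAAAGAA", b = "AAATAAACAA", c = "AAAGAAACAA")
  cp <- build_consensus(al)
  expect_equal(sort(lengths(cp$wildcards$variants)), c(2L, 3L))
  lib <- enumerate_fragments(cp, genome = paste0(al, collapse = ""), window_length = 10)
  expect_equal(unname(attr(lib, "counts")["raw"]), 6)
})

test_that("the combinatorial budget guards dense windows", {
  set.seed(1)
  base <- rand_dna(160)
  alt <- base
  for (p in seq(5, 155, by = 6)) substr(alt, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[substr(base, p, p)]
  cp <- build_consensus(c(a = base, b = alt))
  expect_error(enumerate_fragments(cp, genome = base, window_length = 145,
                                   max_combinations = 1000),
               "combinations")
})

test_that("the library equals the brute-force mosaic oracle on toy families", {
  for (s in 1:3) {
    fam <- make_family(family_config(
      n_members = 3, element_length = 700, ltr_length = 150,
      u3_length = 80, r_length = 30,
      target_ltr_identities = c(1, 0.99, 0.98),
      inter_member_divergence = 0.006, flank_length = 500, seed = s))
    wl <- 40L
    lib <- enumerate_fragments(build_consensus(fam$alignment), fam$genome,
                               window_length = wl)
    oracle <- oracle_junction_library(fam$alignment, fam$genome, wl)
    expect_setequal(lib$sequence, oracle)
  }
})

test_that("no library fragment occurs in the reference genome", {
  fam <- toy_family()
  lib <- build_junction_library(fam, window_length = 60)
  expect_gt(nrow(lib), 0)
  g <- Biostrings::DNAString(fam$genome)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(lib$sequence))
  expect_equal(sum(Biostrings::countPDict(pd, g)), 0)
  expect_equal(sum(Biostrings::countPDict(pd, Biostrings::reverseComplement(g))), 0)
})

test_that("error-free parental reads give a recombination rate of zero", {
  fam <- toy_family()
  lib <- build_junction_library(fam, window_length = 60)
  rp <- sequence_reads(c(g = fam$genome), coverage = 4, per_base_error = 0, seed = 4)
  hits <- search_junctions(rp, lib, element_mapping_read_count = 1000)
  expect_equal(hits$n_recombination_reads, 0)
  expect_equal(hits$rate_per_1000, 0)
})

test_that("planted junctions are detected and match a direct truth scan", {
  fam <- toy_family()
  wl <- 60L
  lib <- build_junction_library(fam, window_length = wl)
  b <- simulate_burst(fam, 30, rt_error_rate = 0, seed = 9)
  tpl <- stats::setNames(b$ecdna$sequence, paste0("m", b$ecdna$molecule))
  rp <- sequence_reads(tpl, coverage = 8, per_base_error = 0, seed = 10)
  reads <- read_seqs(rp)
  hits <- search_junctions(rp, lib, element_mapping_read_count = length(reads))
  # oracle: a read is recombination-positive iff one of its windows is a
  # library member -- recomputed by direct substring scan against the library
  lib_set <- c(lib$sequence, revcomp(lib$sequence))
  oracle_hit <- vapply(reads, function(r) {
    any(vapply(seq_len(nchar(r) - wl + 1), function(s) {
      substr(r, s, s + wl - 1) %in% lib_set
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(sort(unique(hits$matches$read)), which(oracle_hit))
  expect_gt(hits$n_recombination_reads, 0)

  # a single consensus-padded fragment is found exactly once
  frag <- lib$sequence[1]
  padded <- paste0(frag, substr(fam$alignment[[1]], 1, 90 - 0))
  one <- search_junctions(substr(padded, 1, 150), lib, 1000)
  expect_equal(one$n_recombination_reads, 1)
})

test_that("library construction is deterministic", {
  fam <- toy_family()
  l1 <- build_junction_library(fam, window_length = 60)
  l2 <- build_junction_library(fam, window_length = 60)
  expect_identical(l1$sequence, l2$sequence)
  expect_identical(l1$fragment_id, l2$fragment_id)
})

test_that("gap-containing combinations are re-windowed to full length", {
  al <- c(x = "ACGTACGTACGTACGTACGT",
          y = "ACGTAC--ACGTACGTACGT")
  genome <- paste0(rand_dna(20, seed = 4), gsub("-", "", al["x"]),
                   rand_dna(20, seed = 5), gsub("-", "", al["y"]))
  lib <- enumerate_fragments(build_consensus(al), genome, window_length = 10)
  expect_true(all(nchar(lib$sequence) == 10))
})
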