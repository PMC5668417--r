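test_that("the exact mapper reports positions on both strands", {
  g <- rand_dna(3000, seed = 1)
  r_fwd <- substr(g, 501, 650)
  r_rev <- revcomp(substr(g, 1201, 1350))
  r_absent <- rand_dna(150, seed = 2)
  hits <- map_reads_exact(c(r_fwd, r_rev, r_absent), g)
  expect_equal(hits$pos[hits$read == 1], 501)
  expect_equal(hits$strand[hits$read == 1], "+")
  expect_equal(hits$pos[hits$read == 2], 1201)
  expect_equal(hits$strand[hits$read == 2], "-")
  expect_false(3 %in% hits$read)
})

test_that("concordant genomic pairs are not discordant anchors", {
  fam <- toy_family()
  masked <- mask_elements(fam)
  flank <- substr(fam$genome, 1, 1100)
  pairs <- tibble::tibble(pair_id = "p1",
                          mate1 = substr(flank, 101, 250),
                          mate2 = revcomp(substr(flank, 301, 450)))
  anchors <- find_discordant_pairs(pairs, masked, fam)
  expect_equal(nrow(anchors), 0)
})

test_that("pairs straddling pre-existing element copies anchor as positive controls", {
  fam <- toy_family()
  masked <- mask_elements(fam)
  s <- fam$genome_map$start[1]
  pairs <- tibble::tibble(
    pair_id = "ctrl",
    mate1 = substr(fam$genome, s - 200, s - 51),       # pure flank
    mate2 = revcomp(substr(fam$genome, s + 20, s + 169))) # inside the LTR
  anchors <- find_discordant_pairs(pairs, masked, fam)
  expect_equal(nrow(anchors), 1)
  expect_equal(anchors$anchor_pos, s - 200)
  expect_equal(anchors$side, "right")
})

test_that("junction reads resolve the genomic base adjacent to the element edge", {
  fam <- toy_family()
  elem <- fam$alignment[[1]]
  g <- fam$genome
  # constructed read: 80 bp flank then 70 bp of element start
  flank_end <- 900L
  jr <- paste0(substr(g, flank_end - 79, flank_end), substr(elem, 1, 70))
  out <- find_junction_reads(jr, fam, g)
  expect_equal(out$side, "left")
  expect_equal(out$coord, flank_end)
  # read entirely inside the LTR: no junction
  out2 <- find_junction_reads(substr(elem, 10, 159), fam, g)
  expect_equal(nrow(out2), 0)
  # short residual flank is discarded and counted
  jr_short <- paste0(substr(g, 891, 900), substr(elem, 1, 140))
  out3 <- find_junction_reads(jr_short, fam, g)
  expect_equal(nrow(out3), 0)
  expect_gte(attr(out3, "n_discarded_short"), 1)
})

test_that("insertion calling recovers planted insertions with exact TSDs", {
  fam <- small_family()
  b <- simulate_burst(fam, 12, rt_error_rate = 0, seed = 2)
  prog <- integrate_ecdna(b, fam, 5, tsd_length = 5, seed = 3)
  rp <- sequence_reads(c(p = prog$genome), coverage = 30, fragment_mean = 320,
                       fragment_sd = 40, per_base_error = 0, seed = 4)
  masked <- mask_elements(fam)
  anchors <- find_discordant_pairs(rp, masked, fam)
  unm <- rp$mate1 # placeholder; recompute below
  reads <- c(rp$mate1, rp$mate2)
  hits <- map_reads_exact(reads, masked$genome)
  unm <- reads[setdiff(seq_along(reads), unique(hits$read))]
  junc <- find_junction_reads(unm, fam, fam$genome)
  calls <- call_insertions(anchors, junc, masked_intervals = masked$intervals)
  expect_equal(nrow(calls), 5)
  expect_equal(calls$start, sort(prog$truth$start))
  expect_equal(calls$end, sort(prog$truth$end))
  expect_true(all(calls$tsd_length == 5))

  # TSD consistency: left and right junction coordinates differ by TSD
  expect_true(all(calls$end - calls$start == 5))

  # no insertions planted: no calls
  rp0 <- sequence_reads(c(p = fam$genome), coverage = 10, fragment_mean = 320,
                        fragment_sd = 40, per_base_error = 0, seed = 5)
  a0 <- find_discordant_pairs(rp0, masked, fam)
  reads0 <- c(rp0$mate1, rp0$mate2)
  h0 <- map_reads_exact(reads0, masked$genome)
  unm0 <- reads0[setdiff(seq_along(reads0), unique(h0$read))]
  j0 <- find_junction_reads(unm0, fam, fam$genome)
  calls0 <- call_insertions(a0, j0, masked_intervals = masked$intervals)
  expect_equal(nrow(calls0), 0)

  # an insertion present in the control as well is subtracted
  calls_ctrl <- call_insertions(anchors, junc, anchors, junc,
                                masked_intervals = masked$intervals)
  expect_equal(nrow(calls_ctrl), 0)
})

test_that("reconstructed LTRs equal the integrated molecules' LTRs", {
  fam <- small_family()
  b <- simulate_burst(fam, 12, rt_error_rate = 0, seed = 6)
  prog <- integrate_ecdna(b, fam, 4, seed = 7)
  rp <- sequence_reads(c(p = prog$genome), coverage = 30, fragment_mean = 320,
                       fragment_sd = 40, per_base_error = 0, seed = 8)
  masked <- mask_elements(fam)
  anchors <- find_discordant_pairs(rp, masked, fam)
  reads <- c(rp$mate1, rp$mate2)
  h <- map_reads_exact(reads, masked$genome)
  unm <- reads[setdiff(seq_along(reads), unique(h$read))]
  junc <- find_junction_reads(unm, fam, fam$genome)
  calls <- call_insertions(anchors, junc, masked_intervals = masked$intervals)
  expect_equal(nrow(calls), 4)
  ltr <- fam$config$ltr_length
  for (k in seq_len(nrow(calls))) {
    call <- calls[k, ]
    tr <- prog$truth[which.min(abs(prog$truth$start - call$start)), ]
    true_ltr <- substr(b$ecdna$sequence[b$ecdna$molecule == tr$molecule], 1, ltr)
    near_junc <- junc$read[junc$coord >= call$start - 50 & junc$coord <= call$end + 50]
    rec <- reconstruct_ltr(call, anchors, junction_reads = unm[unique(near_junc)],
                           family = fam)
    expect_true(rec$complete)
    expect_identical(rec$sequence, true_ltr)
  }
})

test_that("insufficient coverage yields a flagged partial reconstruction", {
  fam <- small_family()
  call <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10005L)
  rec <- reconstruct_ltr(call,
                         anchors = tibble::tibble(anchor_pos = integer(0),
                                                  element_mate = character(0)),
                         family = fam)
  expect_false(rec$complete)
  expect_equal(rec$sequence, "")
})
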