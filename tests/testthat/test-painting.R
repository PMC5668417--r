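# Brute-force oracle over all parent assignments: minimal switches, then
# fewest distinct parents, then lexicographically smallest path.
oracle_assignment <- function(sets) {
  grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    path <- as.integer(unlist(grid[r, ]))
    sw <- sum(diff(path) != 0)
    key <- list(path = path, sw = sw, k = length(unique(path)))
    if (is.null(best) || key$sw < best$sw ||
        (key$sw == best$sw && key$k < best$k) ||
        (key$sw == best$sw && key$k == best$k &&
           paste(key$path, collapse = ",") < paste(best$path, collapse = ","))) {
      best <- key
    }
  }
  best
}

test_that("the minimal-switch assignment matches exhaustive search", {
  set.seed(11)
  for (rep in 1:40) {
    n_mem <- sample(2:4, 1)
    m <- sample(1:6, 1)
    sets <- replicate(m, sort(sample(seq_len(n_mem), sample(seq_len(n_mem), 1))),
                      simplify = FALSE)
    got <- retroburst:::minimal_switch_assignment(sets, n_mem)
    want <- oracle_assignment(sets)
    expect_equal(got$switches, want$sw)
    expect_equal(got$path, want$path)
  }
})

test_that("a pure member sequence paints as a single parent", {
  fam <- toy_family()
  p <- paint_parentage(fam$alignment[["b"]], fam)
  expect_equal(p$n_parents_minimal, 1)
  expect_equal(p$n_switches, 0)
  expect_equal(unique(p$assignment$parent), "b")
  expect_equal(nrow(p$novel), 0)
  # intervals tile the sequence and adjacent sets differ
  expect_equal(p$intervals$start[1], 1L)
  expect_equal(p$intervals$end[nrow(p$intervals)], p$length)
  if (nrow(p$intervals) > 1) {
    expect_true(all(p$intervals$start[-1] == head(p$intervals$end, -1) + 1L))
  }
})

test_that("a two-parent chimera paints as two intervals with both parents", {
  fam <- toy_family()
  a <- fam$alignment[["a"]]; c_ <- fam$alignment[["c"]]
  L <- fam$config$element_length
  cut <- 800L
  chim <- paste0(substr(a, 1, cut), substr(c_, cut + 1, L))
  p <- paint_parentage(chim, fam)
  expect_equal(p$n_parents_minimal, 2)
  expect_setequal(unique(p$assignment$parent), c("a", "c"))
  # the switch lies between the last a-informative and first c-informative site
  switch_at <- p$assignment$start[min(which(p$assignment$parent == "c"))]
  expect_gt(switch_at, 1)
})

test_that("bases incompatible with every member are flagged as novel", {
  fam <- toy_family()
  seq_b <- fam$alignment[["b"]]
  # pick a monomorphic position and force a base no member carries
  mat <- do.call(rbind, strsplit(unname(fam$alignment), ""))
  mono <- which(apply(mat, 2, function(col) length(unique(col)) == 1))
  cfg <- fam$config
  mono <- mono[mono > cfg$ltr_length & mono <= cfg$element_length - cfg$ltr_length]
  pos <- mono[500]
  cur <- substr(seq_b, pos, pos)
  substr(seq_b, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  p <- paint_parentage(seq_b, fam)
  expect_equal(p$novel$position, pos)
  expect_equal(p$n_parents_minimal, 1)
})

test_that("painting respects the two LTR copies of old members", {
  fam <- toy_family()
  # the reconstituted LTR of an old member mixes its 3' U3 with its 5' R/U5;
  # painting must still accept the member at every LTR position
  mol <- simulate_burst(fam, 1, switch_rate = 0, r_transfer_recomb_prob = 0,
                        rt_error_rate = 0, seed = 30)
  while (mol$truth$molecules$parent_first != "c") {
    mol <- simulate_burst(fam, 1, switch_rate = 0, r_transfer_recomb_prob = 0,
                          rt_error_rate = 0, seed = mol$truth$seed + 1)
  }
  p <- paint_parentage(mol$ecdna$sequence[1], fam)
  expect_equal(unique(p$assignment$parent), "c")
  expect_equal(nrow(p$novel), 0)
})

test_that("true parents are always compatible with their painted intervals", {
  fam <- toy_family()
  b <- simulate_burst(fam, 15, rt_error_rate = 0, seed = 13)
  for (mid in b$ecdna$molecule) {
    p <- paint_parentage(b$ecdna$sequence[b$ecdna$molecule == mid], fam)
    iv <- truth_source_intervals(b, mid)
    for (k in seq_len(nrow(p$intervals))) {
      mid_pos <- (p$intervals$start[k] + p$intervals$end[k]) %/% 2
      src <- iv$parent[iv$start <= mid_pos & iv$end >= mid_pos][1]
      seg <- iv[iv$start <= p$intervals$start[k] & iv$end >= p$intervals$end[k], ]
      if (nrow(seg) == 1) { # interval fully inside one truth segment
        expect_true(seg$parent %in% p$intervals$members[[k]])
      }
    }
  }
})

test_that("novel polymorphism reporting aggregates painted molecules", {
  fam <- toy_family()
  b <- simulate_burst(fam, 10, rt_error_rate = 0, seed = 14)
  painted <- lapply(b$ecdna$sequence, paint_parentage, family = fam)
  names(painted) <- paste0("mol", b$ecdna$molecule)
  tab <- report_novel_polymorphisms(painted)
  expect_equal(nrow(tab), 0) # no RT errors planted
  # one planted private substitution yields exactly one entry
  s <- b$ecdna$sequence[1]
  mat <- do.call(rbind, strsplit(unname(fam$alignment), ""))
  mono <- which(apply(mat, 2, function(col) length(unique(col)) == 1))
  cfg <- fam$config
  mono <- mono[mono > cfg$ltr_length & mono <= cfg$element_length - cfg$ltr_length]
  pos <- mono[400]
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), substr(s, pos, pos))[1]
  tab2 <- report_novel_polymorphisms(list(x = paint_parentage(s, fam)))
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$position, pos)
})

test_that("contribution scores split 12 points among the minimal parents", {
  painted <- list(
    one = stub_painted("a"),
    two = stub_painted(c("a", "b")),
    three = stub_painted(c("a", "b", "c"))
  )
  ct <- contribution_scores(painted, members = c("a", "b", "c", "d"))
  per <- ct$per_insertion
  expect_equal(per$score[per$id == "one"], 12)
  expect_equal(per$score[per$id == "two"], c(6, 6))
  expect_equal(per$score[per$id == "three"], c(4, 4, 4))
  sums <- tapply(per$score, per$id, sum)
  expect_true(all(sums == 12))
  expect_equal(ct$totals$total[ct$totals$member == "d"], 0)
  expect_equal(sum(ct$totals$relative), 1)
  # property: k parents each get 12 / k, for k up to 6
  for (k in 1:6) {
    p <- list(x = stub_painted(letters[1:k]))
    ps <- contribution_scores(p)$per_insertion$score
    expect_equal(ps, rep(12 / k, k))
    expect_equal(sum(ps), 12)
  }
})
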