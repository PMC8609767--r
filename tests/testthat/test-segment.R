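test_that("cumulative-deviation candidates land on level changes", {
  cb <- candidate_breakpoints(c(0, 0, 0, 1, 1, 1))
  # hand-computed running sums: -0.5 -1 -1.5 -1 -0.5 0 -> minimum at the
  # third element, i.e. the boundary between elements 3 and 4
  expect_equal(cb$index_min, 3)
  expect_true(cb$informative)
  cb2 <- candidate_breakpoints(c(1, 1, 1, 0, 0, 0))
  expect_equal(cb2$index_max, 3)
  const <- candidate_breakpoints(rep(2.5, 4))
  expect_false(const$informative)
})

test_that("noiseless two-level signals split exactly at the boundary", {
  x <- c(rep(0.55, 200), rep(0.75, 200))
  tree <- segment_chromosome(x)
  expect_equal(tree_breakpoints(tree), 200)
  # oracle: exhaustive single-split SSE minimization
  expect_equal(sse_optimal_breakpoints(x, 1, 10)$breakpoints, 200)
  # constant signal -> single leaf
  flat <- segment_chromosome(rep(0.5, 300))
  expect_equal(nrow(segmentation_leaves(flat)), 1)
})

test_that("noisy three-level staircases recover breakpoints within 3 bins", {
  set.seed(11)
  x <- c(rnorm(150, 0.55, 0.02), rnorm(150, 0.70, 0.02),
         rnorm(150, 0.90, 0.02))
  bp <- tree_breakpoints(segment_chromosome(x))
  expect_equal(length(bp), 2)
  expect_true(all(abs(bp - c(150, 300)) <= 3))
  oracle <- sse_optimal_breakpoints(x, 2, 10)$breakpoints
  expect_true(all(abs(oracle - c(150, 300)) <= 3))
})

test_that("segmentation is deterministic and leaves partition the input", {
  set.seed(3)
  x <- c(rnorm(120, 0.5, 0.03), rnorm(80, 0.8, 0.03), rnorm(100, 0.6, 0.03))
  t1 <- segment_chromosome(x)
  t2 <- segment_chromosome(x)
  expect_identical(tree_breakpoints(t1), tree_breakpoints(t2))
  leaves <- segmentation_leaves(t1)
  expect_equal(leaves$from[1], 1)
  expect_equal(leaves$to[nrow(leaves)], length(x))
  expect_true(all(leaves$from[-1] == head(leaves$to, -1) + 1))
})

test_that("KDE merging combines same-distribution neighbors only", {
  set.seed(21)
  # same distribution: merged (two-sample KS agrees they are alike)
  x <- rnorm(200, 0.6, 0.02)
  seg <- data.frame(from = c(1, 101), to = c(100, 200))
  expect_gt(ks.test(x[1:100], x[101:200])$p.value, 0.05)
  merged <- merge_segments(seg, x)
  expect_equal(nrow(merged), 1)

  # well-separated means: kept apart (KS rejects)
  y <- c(rnorm(100, 0.55, 0.02), rnorm(100, 0.90, 0.02))
  expect_lt(ks.test(y[1:100], y[101:200])$p.value, 0.05)
  kept <- merge_segments(seg, y)
  expect_equal(nrow(kept), 2)

  # single segment passes through; merging is a contraction
  one <- merge_segments(data.frame(from = 1, to = 200), x)
  expect_equal(one, data.frame(from = 1, to = 200))
  set.seed(22)
  z <- rnorm(300, 0.6, 0.02)
  many <- data.frame(from = seq(1, 281, by = 20), to = seq(20, 300, by = 20))
  out <- merge_segments(many, z)
  expect_lte(nrow(out), nrow(many))
  expect_equal(sum(out$to - out$from + 1), 300)
})

test_that("union of segmentations pools breakpoints and dissolves slivers", {
  ann <- toy_annotation()
  n <- 90
  baf_tr <- bin_track(rep("1", n), seq(0, by = 1e6, length.out = n),
                      seq(1e6, by = 1e6, length.out = n),
                      c(rep(0.55, 50), rep(0.65, 40)), rep(0, n), ann)
  lrr_tr <- bin_track(rep("1", n), seq(0, by = 1e6, length.out = n),
                      seq(1e6, by = 1e6, length.out = n),
                      rep(0.5, n), c(rep(0, 80), rep(1, 10)), ann)
  out <- union_segmentations(data.frame(start = c(0, 5e7), end = c(5e7, 9e7)),
                             data.frame(start = c(0, 8e7), end = c(8e7, 9e7)),
                             baf_tr, lrr_tr)
  expect_equal(out$start, c(0, 5e7, 8e7))
  expect_equal(out$end, c(5e7, 8e7, 9e7))
  expect_equal(out$baf, c(0.55, 0.65, 0.65))
  expect_equal(out$n_bins, c(50, 30, 10))

  # identical break sets: unchanged
  same <- union_segmentations(data.frame(start = 0, end = 9e7),
                              data.frame(start = 0, end = 9e7),
                              baf_tr, lrr_tr)
  expect_equal(nrow(same), 1)

  # a 5-bin sliver is dissolved into the closer-BAF neighbor
  sliver <- union_segmentations(
    data.frame(start = c(0, 5e7), end = c(5e7, 9e7)),
    data.frame(start = c(0, 5.5e7), end = c(5.5e7, 9e7)),
    baf_tr, lrr_tr)
  expect_equal(nrow(sliver), 2)
  expect_equal(sum(sliver$n_bins), 90)
})

test_that("segments flanking the centromere merge only when alike", {
  ann <- toy_annotation()
  mk_chr_track <- function(p_val, q_val, col) {
    p_starts <- seq(0, 94e6, by = 1e6)
    q_starts <- seq(105e6, 199e6, by = 1e6)
    starts <- c(p_starts, q_starts)
    vals <- c(rep(p_val, length(p_starts)), rep(q_val, length(q_starts)))
    if (col == "baf") {
      bin_track(rep("1", length(starts)), starts, starts + 1e6, vals,
                rep(0, length(starts)), ann)
    } else {
      bin_track(rep("1", length(starts)), starts, starts + 1e6,
                rep(0.5, length(starts)), vals, ann)
    }
  }
  p_seg <- data.frame(start = 0, end = 95e6, n_bins = 95, baf = 0.5,
                      baf_frac = 1, lrr = 0)
  q_seg <- data.frame(start = 105e6, end = 200e6, n_bins = 95, baf = 0.5,
                      baf_frac = 1, lrr = 0)
  set.seed(5)
  baf_same <- mk_chr_track(0.5, 0.5, "baf")
  baf_same$baf <- pmin(pmax(baf_same$baf + rnorm(nrow(baf_same), 0, 0.02), 0), 1)
  lrr_tr <- mk_chr_track(0, 0, "lrr")
  lrr_tr$lrr <- lrr_tr$lrr + rnorm(nrow(lrr_tr), 0, 0.05)
  merged <- merge_across_centromere(p_seg, q_seg, baf_same, lrr_tr)
  expect_equal(nrow(merged$segments), 1)
  expect_true(merged$segments$crosses_cen)
  expect_equal(merged$segments$start, 0)
  expect_equal(merged$segments$end, 200e6)

  # different q-arm BAF level: kept separate (KS would reject)
  baf_diff <- mk_chr_track(0.5, 0.67, "baf")
  baf_diff$baf <- pmin(pmax(baf_diff$baf + rnorm(nrow(baf_diff), 0, 0.02), 0), 1)
  q_seg2 <- q_seg; q_seg2$baf <- 0.67
  kept <- merge_across_centromere(p_seg, q_seg2, baf_diff, lrr_tr)
  expect_equal(nrow(kept$segments), 2)
  expect_false(any(kept$segments$crosses_cen))

  # no q-arm coverage: unchanged
  none <- merge_across_centromere(p_seg, q_seg[0, ], baf_same, lrr_tr)
  expect_equal(nrow(none$segments), 1)
})

test_that("segment_track partitions each covered chromosome", {
  ann <- grch37_annotation()
  prof <- identifiable_profile(0.5)
  tr <- simulate_track(prof, sim_config(baf_sd = 0, lrr_sd = 0, seed = 2), ann)
  seg <- segment_track(tr, ann)$segments
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) {
      gaps <- s$start[-1] - head(s$end, -1)
      expect_true(all(gaps >= 0))  # ordered, non-overlapping
    }
  }
  # total span equals covered extent per chromosome
  for (chrom in unique(tr$chrom)) {
    s <- seg[seg$chrom == chrom, ]
    b <- tr[tr$chrom == chrom, ]
    expect_equal(min(s$start), min(b$start))
    expect_equal(max(s$end), max(b$end))
  }
})
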