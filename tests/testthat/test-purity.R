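test_that("measured copy number follows 2^LRR * 2", {
  expect_equal(theoretical_cn(0), 2)
  expect_equal(theoretical_cn(1), 4)
  expect_equal(theoretical_cn(-1), 1)
})

test_that("expected BAF reproduces the admixture model", {
  expect_equal(expected_baf(1, 1, 2), 2 / 3)
  expect_equal(expected_baf(0.5, 1, 2), 0.6)   # (1-0.5+1)/(1.5+1)
  for (p in c(0.1, 0.5, 0.9)) expect_equal(expected_baf(p, 1, 1), 0.5)
  expect_error(expected_baf(1, 0, 0), class = "gscar_homdel_error")
})

test_that("cluster purity inverts the admixture model", {
  expect_equal(as.numeric(purity_from_cluster(0.6, 3, 2 / 3)), 0.5)
  expect_equal(as.numeric(purity_from_cluster(0.75, 2, 1)), 0.5)
  expect_equal(as.numeric(purity_from_cluster(2 / 3, 3, 2 / 3)), 1)
  expect_error(purity_from_cluster(0.6, 2, 0.5),
               class = "gscar_balanced_error")
  flagged <- purity_from_cluster(0.95, 2, 1)
  expect_true(attr(flagged, "out_of_range") || as.numeric(flagged) <= 1)
})

test_that("expected_baf and purity_from_cluster are mutual inverses", {
  for (p in seq(0.05, 1, by = 0.05)) {
    for (n_a in 0:4) {
      for (n_b in n_a:8) {
        if (n_a + n_b == 0 || n_a + n_b > 8 || n_a == n_b) next
        cn <- n_a + n_b
        b <- expected_baf(p, n_a, n_b)
        expect_equal(as.numeric(purity_from_cluster(b, cn, n_b / cn)), p,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("fractional percentile ranks handle ties and singletons", {
  expect_equal(rank_percentiles(c(1, 2, 3, 4)),
               c(0.125, 0.375, 0.625, 0.875))
  expect_equal(rank_percentiles(rep(7, 5)), rep(0.5, 5))
  expect_equal(rank_percentiles(3), 0.5)
})

test_that("DBSCAN clustering matches the neighborhood-graph oracle", {
  set.seed(13)
  eps <- 0.1; minpts <- 3
  two <- rbind(cbind(rnorm(20, 0.2, 0.02), rnorm(20, 0.2, 0.02)),
               cbind(rnorm(20, 0.8, 0.02), rnorm(20, 0.8, 0.02)))
  got <- gscar:::dbscan_labels(two, eps, minpts)
  want <- oracle_dbscan(two, eps, minpts)
  expect_equal(length(unique(got[got > 0])), 2)
  expect_true(same_partition(got, want))

  # isolated point among a cluster stays noise
  iso <- rbind(cbind(rnorm(20, 0.2, 0.01), rnorm(20, 0.2, 0.01)),
               c(0.9, 0.9))
  got2 <- gscar:::dbscan_labels(iso, eps, minpts)
  expect_equal(got2[21], 0L)
  expect_true(same_partition(got2, oracle_dbscan(iso, eps, minpts)))

  # random configurations
  for (i in 1:20) {
    pts <- cbind(runif(30), runif(30))
    expect_true(same_partition(gscar:::dbscan_labels(pts, eps, minpts),
                               oracle_dbscan(pts, eps, minpts)))
  }

  # identical points form one cluster
  same <- matrix(0.4, nrow = 5, ncol = 2)
  expect_equal(unique(gscar:::dbscan_labels(same, eps, minpts)), 1L)
})

test_that("cluster_genotypes recovers recurrent genotype groups", {
  set.seed(17)
  # a diploid background plus two event genotypes recurring on several
  # chromosomes, as in a scarred tumor genome
  n_bg <- 24
  seg <- data.frame(
    chrom = rep("1", n_bg + 8),
    start = seq(0, by = 6e6, length.out = n_bg + 8),
    end = seq(6e6, by = 6e6, length.out = n_bg + 8),
    baf = c(rnorm(n_bg, 0.515, 0.003),
            rnorm(4, 0.62, 0.003),    # single-copy gain (ABB)
            rnorm(4, 0.71, 0.003)),   # hemizygous loss (B)
    cn_star = c(rnorm(n_bg, 2.0, 0.02),
                rnorm(4, 2.6, 0.02),
                rnorm(4, 1.4, 0.02)))
  cl <- cluster_genotypes(seg)
  abb <- cl[which.min(abs(cl$baf_star - 0.62)), ]
  b <- cl[which.min(abs(cl$baf_star - 0.71)), ]
  # both event groups come out whole and are not merged with each other
  expect_gte(abb$n_members, 4)
  expect_equal(b$n_members, 4)
  expect_false(abb$cluster == b$cluster)
  expect_lt(abs(abb$cn_star - 2.6), 0.1)
  expect_lt(abs(b$cn_star - 1.4), 0.1)

  # all segments identical: a single cluster
  same <- seg[1:5, ]
  same$baf <- 0.5; same$cn_star <- 2
  expect_equal(nrow(cluster_genotypes(same)), 1)
})

test_that("purity and scale factor are recovered from clean clusters", {
  # genotypes ABB (60% genome), ABB-like imbalance A (10%), AB (30%)
  p_true <- 0.6
  mk <- function(n_a, n_b, frac) {
    cn <- n_a + n_b
    data.frame(baf_star = expected_baf(p_true, n_a, n_b),
               cn_star = p_true * cn + 2 * (1 - p_true),
               baf_frac = 1, length = frac * 3e9, n_members = 3)
  }
  clusters <- rbind(mk(1, 2, 0.6), mk(0, 1, 0.1), mk(1, 1, 0.3))
  clusters$cluster <- seq_len(3)
  fit <- fit_purity_ploidy(clusters)
  expect_equal(fit$purity, p_true, tolerance = 0.02)
  expect_equal(fit$scale_factor, 1, tolerance = 0.02)
  expect_false(fit$low_confidence)

  # all-balanced sample: purity undefined and flagged
  bal <- rbind(mk(1, 1, 0.7), mk(2, 2, 0.3))
  bal$cluster <- 1:2
  flat <- fit_purity_ploidy(bal)
  expect_true(is.na(flat$purity))
  expect_true(flat$low_confidence)

  # low purity flagged
  lowp <- rbind(mk(1, 2, 0.5), mk(0, 1, 0.2))
  lowp$baf_star <- vapply(seq_len(2), function(i)
    expected_baf(0.15, c(1, 0)[i], c(2, 1)[i]), numeric(1))
  lowp$cn_star <- 0.15 * c(3, 1) + 2 * 0.85
  lowp$cluster <- 1:2
  lf <- fit_purity_ploidy(lowp)
  expect_true(lf$low_confidence)
})

test_that("integer copy-number assignment inverts the forward model", {
  fit1 <- structure(list(purity = 1, scale_factor = 1),
                    class = "purity_ploidy_fit")
  seg <- data.frame(chrom = "1", start = 0, end = 1e7,
                    cn_star = 3, baf = 2 / 3)
  out <- assign_integer_cn(seg, fit1)
  expect_equal(c(out$n_a, out$n_b), c(1L, 2L))

  fit05 <- structure(list(purity = 0.5, scale_factor = 1),
                     class = "purity_ploidy_fit")
  seg2 <- data.frame(chrom = "1", start = 0, end = 1e7,
                     cn_star = 2.5, baf = 0.6)
  out2 <- assign_integer_cn(seg2, fit05)
  expect_equal(c(out2$n_a, out2$n_b), c(1L, 2L))

  # measured BAF 0.67 with 3 copies is ABB; BAF 1.00 with 2 copies is BB
  seg3 <- data.frame(chrom = "1", start = c(0, 2e7), end = c(2e7, 4e7),
                     cn_star = c(3, 2), baf = c(0.67, 1.00))
  out3 <- assign_integer_cn(seg3, fit1)
  expect_equal(out3$n_a, c(1L, 0L))
  expect_equal(out3$n_b, c(2L, 2L))

  # noiseless random segments for p >= 0.2 invert exactly
  set.seed(29)
  for (i in 1:50) {
    p <- runif(1, 0.2, 1)
    n_a <- sample(0:3, 1); n_b <- sample(n_a:4, 1)
    if (n_a + n_b == 0) next
    cn <- n_a + n_b
    fit <- structure(list(purity = p, scale_factor = 1),
                     class = "purity_ploidy_fit")
    seg <- data.frame(chrom = "1", start = 0, end = 1e7,
                      cn_star = p * cn + 2 * (1 - p),
                      baf = expected_baf(p, n_a, n_b))
    got <- assign_integer_cn(seg, fit)
    expect_equal(c(got$n_a, got$n_b), c(n_a, n_b))
  }
})

test_that("ploidy is the genome-proportion-weighted mean copy number", {
  ann <- toy_annotation()
  total <- sum(ann$length)
  full <- data.frame(chrom = c("1", "2"), start = c(0, 0),
                     end = ann$length, cn = c(2L, 2L))
  expect_equal(compute_ploidy(full, ann), 2)
  part <- data.frame(chrom = "1", start = 0, end = 0.1 * total, cn = 4L)
  expect_equal(compute_ploidy(part, ann), 0.1 * 4 + 0.9 * 2)
  sym <- data.frame(chrom = c("1", "1"), start = c(0, 0.5 * total),
                    end = c(0.5 * total, total), cn = c(3L, 1L))
  expect_equal(compute_ploidy(sym, ann), 2)
  # linear in any single segment's copy number
  p1 <- compute_ploidy(data.frame(chrom = "1", start = 0, end = 0.2 * total,
                                  cn = 3L), ann)
  p2 <- compute_ploidy(data.frame(chrom = "1", start = 0, end = 0.2 * total,
                                  cn = 4L), ann)
  p3 <- compute_ploidy(data.frame(chrom = "1", start = 0, end = 0.2 * total,
                                  cn = 5L), ann)
  expect_equal(p2 - p1, p3 - p2)
})
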