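# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive expected results by routes different from
# the package implementation (dynamic programming, plain rule loops,
# igraph components), so agreement is informative.

toy_annotation <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tlength\tcen_start\tcen_end",
               "1\t200000000\t95000000\t105000000",
               "2\t150000000\t70000000\t80000000"),
             path)
  read_genome_annotation(path)
}

# Exact optimal k-breakpoint segmentation by dynamic programming over
# within-segment sums of squared errors, with a minimum segment size.
sse_optimal_breakpoints <- function(x, k, min_bins = 1) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) { # inclusive 1-based, vectorized over i
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k + 1, n)
  back <- matrix(NA_integer_, k + 1, n)
  js <- which(seq_len(n) >= min_bins)
  dp[1, js] <- sse(rep(1, length(js)), js)
  if (k >= 1) {
    for (s in 2:(k + 1)) {
      for (j in seq_len(n)) {
        if (j < s * min_bins) next
        is <- ((s - 1) * min_bins):(j - min_bins)
        v <- dp[s - 1, is] + sse(is + 1, j)
        b <- which.min(v)
        dp[s, j] <- v[b]; back[s, j] <- is[b]
      }
    }
  }
  bps <- integer(0); j <- n
  if (k >= 1) {
    for (s in (k + 1):2) {
      i <- back[s, j]; bps <- c(i, bps); j <- i
    }
  }
  list(breakpoints = bps, sse = dp[k + 1, n])
}

# breakpoints (last index of each leaf but the final one) of a tree
tree_breakpoints <- function(tree) {
  leaves <- segmentation_leaves(tree)
  utils::head(leaves$to, -1)
}

# Plain-loop re-implementation of the three scar rules, written against
# the definitions rather than sharing code with the package.
oracle_scars <- function(segments, annotation, loh_mb = 15, tai_mb = 11,
                         lst_flank_mb = 10, lst_filter_mb = 3) {
  loh <- 0L; tai <- 0L; lst <- 0L
  for (chrom in unique(segments$chrom)) {
    ss <- segments[segments$chrom == chrom, ]
    ss <- ss[order(ss$start), ]
    ai <- annotation[annotation$chrom == chrom, ]
    cov_lo <- min(ss$start); cov_hi <- max(ss$end)

    # LOH: merge consecutive minor-allele-0 segments into regions
    i <- 1
    while (i <= nrow(ss)) {
      if (ss$n_a[i] == 0 && ss$cn[i] >= 1) {
        j <- i
        while (j < nrow(ss) && ss$n_a[j + 1] == 0 && ss$cn[j + 1] >= 1) j <- j + 1
        span <- ss$end[j] - ss$start[i]
        whole <- ss$start[i] <= cov_lo && ss$end[j] >= cov_hi
        if (span > loh_mb * 1e6 && !whole) loh <- loh + 1L
        i <- j + 1
      } else i <- i + 1
    }

    # TAI: per segment
    for (i in seq_len(nrow(ss))) {
      if (ss$n_a[i] == ss$n_b[i]) next
      if (ss$end[i] - ss$start[i] <= tai_mb * 1e6) next
      if (ss$end[i] <= ai$cen_start) {          # p arm
        if (ss$start[i] <= cov_lo) tai <- tai + 1L
      } else if (ss$start[i] >= ai$cen_end) {   # q arm
        if (ss$end[i] >= cov_hi) tai <- tai + 1L
      }
    }

    # LST: per arm, clip, filter short, merge equal, count breakpoints
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 0 else ai$cen_end
      hi <- if (arm == "p") ai$cen_start else ai$length
      arm_segs <- list()
      for (i in seq_len(nrow(ss))) {
        s <- max(ss$start[i], lo); e <- min(ss$end[i], hi)
        if (e <= s) next
        arm_segs[[length(arm_segs) + 1]] <-
          list(start = s, end = e, n_a = ss$n_a[i], n_b = ss$n_b[i])
      }
      arm_segs <- Filter(function(z) z$end - z$start >= lst_filter_mb * 1e6,
                         arm_segs)
      merged <- list()
      for (z in arm_segs) {
        m <- length(merged)
        if (m > 0 && merged[[m]]$n_a == z$n_a && merged[[m]]$n_b == z$n_b) {
          merged[[m]]$end <- z$end
        } else merged[[m + 1]] <- z
      }
      if (length(merged) >= 2) {
        for (i in 1:(length(merged) - 1)) {
          l1 <- merged[[i]]$end - merged[[i]]$start
          l2 <- merged[[i + 1]]$end - merged[[i + 1]]$start
          if (l1 >= lst_flank_mb * 1e6 && l2 >= lst_flank_mb * 1e6)
            lst <- lst + 1L
        }
      }
    }
  }
  list(loh = loh, tai = tai, lst = lst)
}

# Random small allele-specific segment list on the toy annotation.
random_segment_list <- function(annotation, max_segments = 20) {
  genotypes <- list(c(0, 1), c(1, 1), c(1, 2), c(0, 2), c(2, 2), c(1, 3),
                    c(0, 3), c(2, 3))
  out <- list()
  for (ci in seq_len(nrow(annotation))) {
    n_seg <- sample(1:(max_segments %/% nrow(annotation)), 1)
    len <- annotation$length[ci]
    cuts <- sort(sample(seq(1e6, len - 1e6, by = 1e6), n_seg - 1))
    bounds <- c(0, cuts, len)
    for (i in seq_len(n_seg)) {
      g <- genotypes[[sample(length(genotypes), 1)]]
      out[[length(out) + 1]] <- data.frame(
        chrom = annotation$chrom[ci], start = bounds[i], end = bounds[i + 1],
        n_a = g[1], n_b = g[2], cn = g[1] + g[2])
    }
  }
  do.call(rbind, out)
}

# DBSCAN oracle: eps-graph connected components over core points (igraph),
# border points joined to their nearest core's component.
oracle_dbscan <- function(points, eps, minpts) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  core <- rowSums(d <= eps) >= minpts
  labels <- integer(n)
  if (any(core)) {
    adj <- (d[core, core, drop = FALSE] <= eps) * 1
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    labels[core] <- comp
    for (i in which(!core)) {
      nb <- which(core & d[i, ] <= eps)
      if (length(nb) > 0) labels[i] <- labels[nb[which.min(d[i, nb])]]
    }
  }
  labels
}

# identical partitions up to label permutation
same_partition <- function(a, b) {
  ta <- table(a, b)
  all(rowSums(ta > 0) <= 1) && all(colSums(ta > 0) <= 1)
}

# ground-truth profile whose every constant-genotype run has enough bins
# on its arm for the segmentation's minimum support, so recovery is exact
identifiable_profile <- function(purity) {
  sim_profile(data.frame(
    chrom = c("1", "2", "3", "5", "9", "4"),
    start = c(20, 120, 20, 70, 70, 70) * 1e6,
    end   = c(110, 220, 78, 160, 120, 150) * 1e6,
    n_a   = c(1, 0, 1, 0, 0, 2),
    n_b   = c(2, 1, 2, 1, 2, 2)), purity = purity)
}

profile_ploidy <- function(profile, annotation) {
  ev <- profile$events
  total <- sum(annotation$length)
  2 + sum((ev$n_a + ev$n_b - 2) * (ev$end - ev$start)) / total
}

write_toy_track <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tbaf\tlrr", lines), path)
  path
}
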