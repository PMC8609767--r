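#' Candidate breakpoints from the cumulative deviation from the mean
#'
#' For an ordered numeric vector the running sum `S_k = sum_{i<=k}(x_i - mean(x))`
#' is computed; its argmax and argmin are the candidate breakpoints. A
#' breakpoint at index `k` means the boundary between elements `k` and
#' `k + 1`. On a (numerically) constant vector the candidates are
#' uninformative.
#'
#' @param values ordered numeric vector, length >= 2.
#' @return list with `index_max`, `index_min` (integer indices into
#'   `values`) and `informative` (logical).
#' @export
candidate_breakpoints <- function(values) {
  stopifnot(length(values) >= 2)
  s <- cumsum(values - mean(values))
  scale <- max(abs(values - mean(values)))
  informative <- is.finite(scale) && scale > 1e-12
  list(index_max = which.max(s), index_min = which.min(s),
       informative = informative)
}

# Welch two-sample p-value with guards for (near-)zero variances, so that
# noiseless piecewise-constant input is handled exactly.
welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) return(1)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- if (n1 > 1) stats::var(x) else 0
  v2 <- if (n2 > 1) stats::var(y) else 0
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 1e-24) return(if (abs(m1 - m2) > 1e-12) 0 else 1)
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / max(n1 - 1, 1) + (v2 / n2)^2 / max(n2 - 1, 1))
  2 * stats::pt(-abs(tt), df)
}

#' Tree-recursion segmentation of one chromosome arm
#'
#' The whole input interval is the root node. At each node the candidate
#' breakpoints (argmax and argmin of the cumulative deviation, see
#' [candidate_breakpoints()]) are tried in order of decreasing
#' between-segment mean difference; a candidate is recorded only if both
#' resulting children have at least `min_bins` bins, span at least
#' `min_length_bp` (when positions are supplied), and their means differ at
#' Welch-test level `alpha`. Recursion descends into the children
#' depth-first, then across siblings, and stops when no candidate is
#' acceptable. The leaves of the final tree are a partition of the input.
#'
#' @param values ordered numeric vector (mirrored BAF or LRR of one arm).
#' @param config configuration list, see [gscar_config()].
#' @param starts,ends optional bp coordinates of the bins carrying `values`;
#'   required for the minimum-length criterion.
#' @return nested list of class `segmentation_node` with fields `lo`, `hi`
#'   (bin index range), `breakpoint` (index of the last bin of the left
#'   child, or `NULL` for a leaf) and `children`.
#' @seealso [segmentation_leaves()] to enumerate the emitted segments.
#' @export
segment_chromosome <- function(values, config = gscar_config(),
                               starts = NULL, ends = NULL) {
  n <- length(values)
  if (n == 0) {
    return(structure(list(lo = integer(0), hi = integer(0),
                          breakpoint = NULL, children = list()),
                     class = "segmentation_node"))
  }
  cfg <- config$segmentation
  acceptable <- function(lo, k, hi) {
    n_left <- k - lo + 1; n_right <- hi - k
    if (n_left < cfg$min_bins || n_right < cfg$min_bins) return(FALSE)
    if (!is.null(starts)) {
      if (ends[k] - starts[lo] < cfg$min_length_bp) return(FALSE)
      if (ends[hi] - starts[k + 1] < cfg$min_length_bp) return(FALSE)
    }
    welch_p(values[lo:k], values[(k + 1):hi]) < cfg$alpha
  }
  build <- function(lo, hi) {
    node <- structure(list(lo = lo, hi = hi, breakpoint = NULL,
                           children = list()),
                      class = "segmentation_node")
    if (hi - lo + 1 < 2 * cfg$min_bins) return(node)
    cand <- candidate_breakpoints(values[lo:hi])
    if (!cand$informative) return(node)
    ks <- unique(c(cand$index_max, cand$index_min))
    ks <- ks[ks < hi - lo + 1]           # boundary after the last bin is no split
    if (length(ks) == 0) return(node)
    ks <- lo + ks - 1                    # to absolute indices
    if (length(ks) == 2) {
      gap <- vapply(ks, function(k)
        abs(mean(values[lo:k]) - mean(values[(k + 1):hi])), numeric(1))
      ks <- ks[order(-gap)]
    }
    for (k in ks) {
      if (acceptable(lo, k, hi)) {
        node$breakpoint <- k
        node$children <- list(build(lo, k), build(k + 1, hi))
        return(node)
      }
    }
    node
  }
  build(1L, n)
}

#' Enumerate the leaf segments of a segmentation tree
#'
#' @param node a `segmentation_node` from [segment_chromosome()].
#' @return data.frame with columns `from`, `to` (inclusive bin index ranges
#'   partitioning the input).
#' @export
segmentation_leaves <- function(node) {
  if (length(node$lo) == 0) {
    return(data.frame(from = integer(0), to = integer(0)))
  }
  if (length(node$children) == 0) {
    return(data.frame(from = node$lo, to = node$hi))
  }
  do.call(rbind, lapply(node$children, segmentation_leaves))
}

# Overlap coefficient of the Gaussian KDEs of two samples, evaluated on a
# common grid with a common bandwidth. 1 = same distribution, 0 = disjoint.
kde_overlap <- function(x, y, n_grid = 256) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  bw <- max(safe_bw(x), safe_bw(y))
  lo <- min(x, y) - 3 * bw; hi <- max(x, y) + 3 * bw
  grid <- seq(lo, hi, length.out = n_grid)
  dx <- kde_at(x, grid, bw = bw)
  dy <- kde_at(y, grid, bw = bw)
  sum(pmin(dx, dy)) * (grid[2] - grid[1])
}

#' Merge adjacent segments with similar value distributions
#'
#' Iteratively finds the adjacent pair of segments whose bin-value kernel
#' density estimates have the largest overlap coefficient; if that overlap
#' is at least `config$merge$kde_overlap` the pair is combined and
#' statistics recomputed, otherwise the loop stops. The output remains an
#' ordered partition and never has more segments than the input.
#'
#' @param segments data.frame with columns `from`, `to` (bin index ranges,
#'   ordered, contiguous).
#' @param values the numeric vector the indices refer to.
#' @param config configuration list.
#' @return data.frame with columns `from`, `to` after merging.
#' @export
merge_segments <- function(segments, values, config = gscar_config()) {
  threshold <- config$merge$kde_overlap
  from <- segments$from; to <- segments$to
  while (length(from) > 1) {
    ov <- vapply(seq_len(length(from) - 1), function(i) {
      kde_overlap(values[from[i]:to[i]], values[from[i + 1]:to[i + 1]])
    }, numeric(1))
    best <- which.max(ov)
    if (length(best) == 0 || !is.finite(ov[best]) || ov[best] < threshold) break
    to[best] <- to[best + 1]
    from <- from[-(best + 1)]; to <- to[-(best + 1)]
  }
  data.frame(from = from, to = to)
}

# bp boundaries of index segments: the breakpoint after bin k is the end of
# bin k; segment extent snaps to member-bin coordinates.
segments_to_bp <- function(segments, starts, ends) {
  data.frame(start = starts[segments$from], end = ends[segments$to])
}

#' Union of the BAF and LRR segmentations of one chromosome arm
#'
#' The breakpoint sets of the two segmentations (in bp) are pooled and the
#' pooled partition re-evaluated on both tracks. Segments left with too few
#' bins or too short a span are iteratively dissolved into the neighbor
#' whose mean BAF (mean LRR when BAF is unavailable) is closer. Each output
#' segment carries recomputed mean mirrored BAF, mean LRR and bin counts.
#'
#' @param baf_bp,lrr_bp data.frames with `start`, `end` bp columns (either
#'   may have zero rows when a track has no coverage on the arm).
#' @param baf_track preprocessed (homozygous-filtered, mirrored) BAF bins of
#'   the arm.
#' @param lrr_track preprocessed LRR bins of the arm.
#' @param config configuration list.
#' @return data.frame with columns `start`, `end`, `n_bins`, `baf`, `lrr`.
#' @export
union_segmentations <- function(baf_bp, lrr_bp, baf_track, lrr_track,
                                config = gscar_config()) {
  cfg <- config$segmentation
  bin_starts <- sort(unique(c(baf_track$start, lrr_track$start)))
  if (length(bin_starts) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_bins = integer(0), baf = numeric(0),
                      baf_frac = numeric(0), lrr = numeric(0)))
  }
  extent <- c(min(baf_track$start, lrr_track$start, Inf),
              max(baf_track$end, lrr_track$end, -Inf))
  inner <- sort(unique(c(utils::head(baf_bp$end, -1),
                         utils::head(lrr_bp$end, -1))))
  inner <- inner[inner > extent[1] & inner < extent[2]]
  cuts <- c(extent[1], inner, extent[2])
  seg <- data.frame(start = utils::head(cuts, -1), end = cuts[-1])

  stat_segment <- function(s, e) {
    in_baf <- baf_track$start >= s & baf_track$start < e
    in_lrr <- lrr_track$start >= s & lrr_track$start < e
    n_bins <- length(unique(c(baf_track$start[in_baf],
                              lrr_track$start[in_lrr])))
    # when the homozygosity filter has censored most of a segment's BAF
    # bins, the surviving few are unrepresentative: report BAF as missing
    baf_ok <- sum(in_baf) >= max(3, 0.2 * n_bins)
    list(n_bins = n_bins,
         baf = if (baf_ok) mean(baf_track$baf[in_baf]) else NA_real_,
         baf_frac = if (n_bins > 0) sum(in_baf) / n_bins else 0,
         lrr = if (any(in_lrr)) mean(lrr_track$lrr[in_lrr]) else NA_real_)
  }
  recompute <- function(seg) {
    st <- lapply(seq_len(nrow(seg)), function(i)
      stat_segment(seg$start[i], seg$end[i]))
    seg$n_bins <- vapply(st, `[[`, integer(1), "n_bins")
    seg$baf <- vapply(st, `[[`, numeric(1), "baf")
    seg$baf_frac <- vapply(st, `[[`, numeric(1), "baf_frac")
    seg$lrr <- vapply(st, `[[`, numeric(1), "lrr")
    seg
  }
  seg <- recompute(seg)

  repeat {
    if (nrow(seg) <= 1) break
    offending <- which(seg$n_bins < cfg$min_bins |
                         (seg$end - seg$start) < cfg$min_length_bp)
    if (length(offending) == 0) break
    i <- offending[order(seg$n_bins[offending],
                         seg$end[offending] - seg$start[offending])][1]
    nbrs <- c(i - 1, i + 1)
    nbrs <- nbrs[nbrs >= 1 & nbrs <= nrow(seg)]
    if (length(nbrs) == 2) {
      d <- vapply(nbrs, function(j) {
        if (is.finite(seg$baf[i]) && is.finite(seg$baf[j])) {
          abs(seg$baf[i] - seg$baf[j])
        } else if (is.finite(seg$lrr[i]) && is.finite(seg$lrr[j])) {
          abs(seg$lrr[i] - seg$lrr[j])
        } else Inf
      }, numeric(1))
      j <- nbrs[which.min(d)]
    } else {
      j <- nbrs
    }
    lo <- min(i, j); hi <- max(i, j)
    seg$end[lo] <- seg$end[hi]
    seg <- seg[-hi, , drop = FALSE]
    st <- stat_segment(seg$start[lo], seg$end[lo])
    seg$n_bins[lo] <- st$n_bins; seg$baf[lo] <- st$baf
    seg$baf_frac[lo] <- st$baf_frac; seg$lrr[lo] <- st$lrr
  }
  # snap segment boundaries to the covered bins
  for (i in seq_len(nrow(seg))) {
    s <- seg$start[i]; e <- seg$end[i]
    bs <- c(baf_track$start[baf_track$start >= s & baf_track$start < e],
            lrr_track$start[lrr_track$start >= s & lrr_track$start < e])
    be <- c(baf_track$end[baf_track$start >= s & baf_track$start < e],
            lrr_track$end[lrr_track$start >= s & lrr_track$start < e])
    if (length(bs) > 0) {
      seg$start[i] <- min(bs); seg$end[i] <- max(be)
    }
  }
  rownames(seg) <- NULL
  seg
}

#' Merge the segments flanking the centromere gap when alike
#'
#' Targeted panels leave a coverage gap at the centromere, so the two arms
#' are segmented independently. When the last p-arm segment and the first
#' q-arm segment have the same value distribution (the same KDE-overlap
#' test as [merge_segments()], applied to BAF and, when available, LRR)
#' they are combined into a single segment spanning the gap.
#'
#' @param p_seg,q_seg arm segment data.frames from [union_segmentations()].
#' @param baf_track,lrr_track preprocessed chromosome tracks (both arms).
#' @param config configuration list.
#' @return list with elements `segments` (combined data.frame for the
#'   chromosome, with a logical `crosses_cen` column) — unchanged when
#'   either arm is empty or the test fails.
#' @export
merge_across_centromere <- function(p_seg, q_seg, baf_track, lrr_track,
                                    config = gscar_config()) {
  add_flag <- function(seg, flag = FALSE) {
    if (nrow(seg) > 0) seg$crosses_cen <- rep(flag, nrow(seg))
    else seg$crosses_cen <- logical(0)
    seg
  }
  if (nrow(p_seg) == 0 || nrow(q_seg) == 0) {
    return(list(segments = rbind(add_flag(p_seg), add_flag(q_seg))))
  }
  i <- nrow(p_seg)
  vals <- function(track, s, e, col) {
    track[[col]][track$start >= s & track$start < e]
  }
  p_baf <- vals(baf_track, p_seg$start[i], p_seg$end[i], "baf")
  q_baf <- vals(baf_track, q_seg$start[1], q_seg$end[1], "baf")
  p_lrr <- vals(lrr_track, p_seg$start[i], p_seg$end[i], "lrr")
  q_lrr <- vals(lrr_track, q_seg$start[1], q_seg$end[1], "lrr")
  ov_baf <- kde_overlap(p_baf, q_baf)
  ov_lrr <- kde_overlap(p_lrr, q_lrr)
  ovs <- c(ov_baf, ov_lrr)
  ovs <- ovs[is.finite(ovs)]
  same <- length(ovs) > 0 && all(ovs >= config$merge$kde_overlap)
  if (!same) {
    return(list(segments = rbind(add_flag(p_seg), add_flag(q_seg))))
  }
  n_bins_m <- p_seg$n_bins[i] + q_seg$n_bins[1]
  merged <- data.frame(
    start = p_seg$start[i], end = q_seg$end[1],
    n_bins = n_bins_m,
    baf = if (length(c(p_baf, q_baf)) > 0) mean(c(p_baf, q_baf)) else NA_real_,
    baf_frac = if (n_bins_m > 0) length(c(p_baf, q_baf)) / n_bins_m else 0,
    lrr = if (length(c(p_lrr, q_lrr)) > 0) mean(c(p_lrr, q_lrr)) else NA_real_
  )
  out <- rbind(add_flag(p_seg[-i, , drop = FALSE]),
               add_flag(merged, TRUE),
               add_flag(q_seg[-1, , drop = FALSE]))
  rownames(out) <- NULL
  list(segments = out)
}

# assign bins to the p or q arm; bins overlapping the gap go by midpoint
arm_of <- function(start, end, cen_start, cen_end) {
  mid <- (start + end) / 2
  ifelse(end <= cen_start, "p",
         ifelse(start >= cen_end, "q", ifelse(mid < cen_start, "p", "q")))
}

#' Segment a genome-wide BAF/LRR track
#'
#' Runs the full segmentation stage: homozygous-bin removal and BAF
#' mirroring, the optional LRR density filter, per-arm tree-recursion
#' segmentation of the BAF and LRR tracks separately, KDE-based merging of
#' each, the union of the two breakpoint sets with dissolution of
#' under-supported segments, and the centromere-gap merge.
#'
#' @param track `bin_track` data.frame from [read_track()].
#' @param annotation `genome_annotation`.
#' @param config configuration list.
#' @return list with `segments` (data.frame: `chrom`, `start`, `end`,
#'   `n_bins`, `baf`, `lrr`, `crosses_cen`) and `reports` (the filter
#'   reports).
#' @export
segment_track <- function(track, annotation, config = gscar_config()) {
  hom <- filter_homozygous(track, config)
  baf_all <- mirror_baf(hom$track)
  lrr_in <- track[is.finite(track$lrr), , drop = FALSE]
  lrrf <- filter_lrr_outliers(lrr_in, config)
  lrr_all <- lrrf$track

  one_arm <- function(baf_track, lrr_track) {
    seg_of <- function(tr, col) {
      if (nrow(tr) < 2) {
        if (nrow(tr) == 0) {
          return(data.frame(start = numeric(0), end = numeric(0)))
        }
        return(data.frame(start = min(tr$start), end = max(tr$end)))
      }
      tree <- segment_chromosome(tr[[col]], config,
                                 starts = tr$start, ends = tr$end)
      leaves <- segmentation_leaves(tree)
      leaves <- merge_segments(leaves, tr[[col]], config)
      segments_to_bp(leaves, tr$start, tr$end)
    }
    union_segmentations(seg_of(baf_track, "baf"), seg_of(lrr_track, "lrr"),
                        baf_track, lrr_track, config)
  }

  out <- list()
  for (ci in seq_len(nrow(annotation))) {
    chrom <- annotation$chrom[ci]
    baf_c <- baf_all[baf_all$chrom == chrom, , drop = FALSE]
    lrr_c <- lrr_all[lrr_all$chrom == chrom, , drop = FALSE]
    if (nrow(baf_c) + nrow(lrr_c) == 0) next
    arm_b <- arm_of(baf_c$start, baf_c$end,
                    annotation$cen_start[ci], annotation$cen_end[ci])
    arm_l <- arm_of(lrr_c$start, lrr_c$end,
                    annotation$cen_start[ci], annotation$cen_end[ci])
    p_seg <- one_arm(baf_c[arm_b == "p", , drop = FALSE],
                     lrr_c[arm_l == "p", , drop = FALSE])
    q_seg <- one_arm(baf_c[arm_b == "q", , drop = FALSE],
                     lrr_c[arm_l == "q", , drop = FALSE])
    merged <- merge_across_centromere(p_seg, q_seg, baf_c, lrr_c, config)
    seg <- merged$segments
    if (nrow(seg) > 0) {
      seg <- cbind(chrom = chrom, seg, stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- seg
    }
  }
  segments <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_bins = integer(0), baf = numeric(0), baf_frac = numeric(0),
               lrr = numeric(0), crosses_cen = logical(0))
  rownames(segments) <- NULL
  list(segments = segments,
       reports = list(homozygous = hom$report, lrr_outliers = lrrf$report))
}
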