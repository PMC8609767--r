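#' Count loss-of-heterozygosity scar events
#'
#' An LOH region is a maximal run of consecutive segments with minor allele
#' copy number 0 and total copy number >= 1 on one chromosome. Regions
#' longer than `loh_mb` megabases count, except a region spanning the whole
#' covered extent of its chromosome (whole-chromosome LOH reflects ploidy,
#' not scarring).
#'
#' @param segments segment data.frame with integer `n_a`, `n_b` (`n_a` the
#'   minor allele), `cn`, sorted by chromosome and start.
#' @param annotation `genome_annotation`.
#' @param config configuration list.
#' @return integer count.
#' @export
count_loh <- function(segments, annotation, config = gscar_config()) {
  min_len <- config$scars$loh_mb * 1e6
  n <- 0L
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    is_loh <- !is.na(s$n_a) & !is.na(s$cn) & s$n_a == 0 & s$cn >= 1
    r <- rle(is_loh)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      reg_start <- s$start[starts[k]]
      reg_end <- s$end[ends[k]]
      whole <- reg_start <= min(s$start) && reg_end >= max(s$end)
      if (reg_end - reg_start > min_len && !whole) n <- n + 1L
    }
  }
  n
}

#' Count telomeric allelic imbalance scar events
#'
#' A TAI event is a segment with unequal allele copy numbers that (a)
#' contains the outermost covered bin of a chromosome arm (targeted panels
#' never reach the literal telomere), (b) lies entirely within that arm
#' (does not cross the centromere), and (c) is longer than `tai_mb`
#' megabases.
#'
#' @inheritParams count_loh
#' @return integer count.
#' @export
count_tai <- function(segments, annotation, config = gscar_config()) {
  min_len <- config$scars$tai_mb * 1e6
  n <- 0L
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    ai <- annotation[annotation$chrom == chrom, , drop = FALSE]
    if (nrow(ai) == 0) next
    cov_min <- min(s$start); cov_max <- max(s$end)
    for (i in seq_len(nrow(s))) {
      if (is.na(s$n_a[i]) || is.na(s$n_b[i]) || s$n_a[i] == s$n_b[i]) next
      in_p <- s$end[i] <= ai$cen_start
      in_q <- s$start[i] >= ai$cen_end
      if (!in_p && !in_q) next                    # crosses the centromere
      telomeric <- (in_p && s$start[i] <= cov_min) ||
        (in_q && s$end[i] >= cov_max)
      if (telomeric && s$end[i] - s$start[i] > min_len) n <- n + 1L
    }
  }
  n
}

#' Count large-scale state transitions
#'
#' Per chromosome arm: segments shorter than `lst_filter_mb` megabases are
#' removed; adjacent segments with identical `(n_a, n_b)` are combined
#' (configurable via `lst_merge_equal`); every remaining breakpoint whose
#' two flanking regions both span at least `lst_flank_mb` megabases counts
#' as one transition. Segments crossing the centromere are split at the
#' centromere boundaries, and no breakpoint is counted across the gap.
#'
#' @inheritParams count_loh
#' @return integer count.
#' @export
count_lst <- function(segments, annotation, config = gscar_config()) {
  cfg <- config$scars
  n <- 0L
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    ai <- annotation[annotation$chrom == chrom, , drop = FALSE]
    if (nrow(ai) == 0) next
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 0 else ai$cen_end
      hi <- if (arm == "p") ai$cen_start else ai$length
      a <- s[s$start < hi & s$end > lo, , drop = FALSE]
      if (nrow(a) == 0) next
      a$start <- pmax(a$start, lo); a$end <- pmin(a$end, hi)
      a <- a[a$end - a$start >= cfg$lst_filter_mb * 1e6, , drop = FALSE]
      if (nrow(a) < 2) next
      if (isTRUE(cfg$lst_merge_equal)) {
        keep <- c(TRUE, !(a$n_a[-1] == a$n_a[-nrow(a)] &
                            a$n_b[-1] == a$n_b[-nrow(a)]))
        keep[is.na(keep)] <- TRUE
        grp <- cumsum(keep)
        a <- do.call(rbind, lapply(split(a, grp), function(g) {
          g$end[1] <- g$end[nrow(g)]; g[1, , drop = FALSE]
        }))
      }
      if (nrow(a) < 2) next
      len <- a$end - a$start
      flank_ok <- len[-length(len)] >= cfg$lst_flank_mb * 1e6 &
        len[-1] >= cfg$lst_flank_mb * 1e6
      state_change <- !(a$n_a[-1] == a$n_a[-nrow(a)] &
                          a$n_b[-1] == a$n_b[-nrow(a)])
      state_change[is.na(state_change)] <- TRUE
      n <- n + sum(flank_ok & state_change)
    }
  }
  as.integer(n)
}

#' Ploidy-corrected HRD score
#'
#' `HRD = LOH + TAI + LST - K * ploidy`. The correction coefficient K
#' (default 15.5) deducts the contribution of aneuploidy itself, which
#' inflates raw scar counts without reflecting repair deficiency.
#'
#' @param loh,tai,lst non-negative integer scar counts.
#' @param ploidy genome ploidy (> 0).
#' @param k correction coefficient.
#' @return the (possibly negative) HRD score.
#' @export
hrd_score <- function(loh, tai, lst, ploidy, k = 15.5) {
  stopifnot(loh >= 0, tai >= 0, lst >= 0, ploidy > 0)
  loh + tai + lst - k * ploidy
}

#' Classify an HRD score as positive or negative
#'
#' @param score HRD score.
#' @param threshold positivity cutoff (default 30); scores at or above the
#'   threshold are positive.
#' @return `"positive"` or `"negative"`.
#' @export
classify_hrd <- function(score, threshold = 30) {
  ifelse(score >= threshold, "positive", "negative")
}

#' Summary statistics of a set of HRD scores
#'
#' @param values numeric vector of HRD scores, length >= 1.
#' @return named list with `mean`, `median`, `min`, `max`.
#' @export
summarize_scores <- function(values) {
  stopifnot(length(values) >= 1)
  list(mean = mean(values), median = stats::median(values),
       min = min(values), max = max(values))
}

#' Pearson correlation between two score vectors
#'
#' Thin validated wrapper around the sample Pearson correlation, used to
#' compare scores from two platforms.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need two vectors of equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y, method = "pearson")
}
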