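#' Remove homozygous bins from the BAF track
#'
#' Bins whose BAF lies at or beyond the homozygosity bounds (default
#' BAF >= 0.95 or BAF <= 0.05) carry no allelic information in the tumor
#' and are removed from the BAF track. Bins with missing BAF are also
#' dropped here, since they cannot contribute to BAF segmentation; the LRR
#' track is left untouched by keeping the original bin set for LRR.
#'
#' @param track `bin_track` data.frame.
#' @param config configuration list, see [gscar_config()].
#' @return list with elements `track` (the filtered BAF track) and `report`
#'   (a `filter_report`, see [filter_report()]).
#' @export
filter_homozygous <- function(track, config = gscar_config()) {
  low <- config$homozygous_baf$low
  high <- config$homozygous_baf$high
  keep <- !is.na(track$baf) & track$baf > low & track$baf < high
  list(track = track[keep, , drop = FALSE],
       report = filter_report(track, keep, "homozygous_baf"))
}

#' Mirror BAF around 0.5
#'
#' Folds the allele-phase ambiguity upward: `BAF <- |BAF - 0.5| + 0.5`.
#' Applied after homozygous-bin removal, so outputs lie in [0.5, 0.95).
#' The map is idempotent.
#'
#' @param track `bin_track` data.frame with BAF values present.
#' @return the track with mirrored BAF.
#' @export
mirror_baf <- function(track) {
  track$baf <- abs(track$baf - 0.5) + 0.5
  track
}

#' Density-based LRR outlier filter
#'
#' Fits a Gaussian kernel density (Silverman bandwidth) to all LRR values
#' genome-wide, scores each bin by the density at its LRR, and removes bins
#' whose score falls strictly below the configured quantile (default the
#' 30th percentile) of all scores. Ties at the threshold are kept, so the
#' retained set is never empty. With fewer than 10 bins the filter is
#' skipped with a warning.
#'
#' @param track `bin_track` data.frame.
#' @param config configuration list, see [gscar_config()].
#' @return list with elements `track` and `report` as in
#'   [filter_homozygous()].
#' @export
filter_lrr_outliers <- function(track, config = gscar_config()) {
  if (!isTRUE(config$lrr_outlier_filter$enabled)) {
    return(list(track = track,
                report = filter_report(track, rep(TRUE, nrow(track)),
                                       "lrr_outliers")))
  }
  lrr <- track$lrr
  if (sum(is.finite(lrr)) < 10) {
    warning("fewer than 10 LRR values; outlier filter skipped")
    return(list(track = track,
                report = filter_report(track, rep(TRUE, nrow(track)),
                                       "lrr_outliers")))
  }
  score <- kde_at(lrr[is.finite(lrr)], lrr)
  cutoff <- stats::quantile(score, config$lrr_outlier_filter$quantile,
                            na.rm = TRUE, names = FALSE)
  keep <- is.na(score) | score >= cutoff
  list(track = track[keep, , drop = FALSE],
       report = filter_report(track, keep, "lrr_outliers"))
}

# Gaussian KDE fitted to `sample` evaluated at `at`; bandwidth floor keeps
# the estimate defined for (near-)constant data.
kde_at <- function(sample, at, bw = NULL) {
  if (is.null(bw)) bw <- safe_bw(sample)
  vapply(at, function(x) {
    if (!is.finite(x)) return(NA_real_)
    mean(stats::dnorm((x - sample) / bw)) / bw
  }, numeric(1))
}

safe_bw <- function(x, floor = 1e-3) {
  x <- x[is.finite(x)]
  bw <- if (length(x) >= 2 && stats::sd(x) > 0) stats::bw.nrd0(x) else 0
  max(bw, floor)
}

#' Summarize a filtering step
#'
#' @param track the input track.
#' @param keep logical vector marking retained bins.
#' @param step character label of the filtering step.
#' @return list of class `filter_report` with counts of removed and
#'   retained bins and the fraction retained per chromosome.
#' @export
filter_report <- function(track, keep, step = "filter") {
  frac <- if (nrow(track) == 0) numeric(0) else
    tapply(keep, track$chrom, mean)
  structure(
    list(step = step,
         n_input = nrow(track),
         n_removed = sum(!keep),
         n_retained = sum(keep),
         fraction_retained_per_chrom = frac),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %s> %d of %d bins removed (%.1f%%)\n",
              x$step, x$n_removed, x$n_input,
              if (x$n_input > 0) 100 * x$n_removed / x$n_input else 0))
  invisible(x)
}
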