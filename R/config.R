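#' Default analysis configuration
#'
#' Returns the nested list of tuning parameters used throughout the pipeline.
#' Any subset can be overridden by passing a list with the same structure;
#' unnamed entries keep their defaults.
#'
#' Groups:
#' \describe{
#'   \item{homozygous_baf}{`low`, `high`: BAF bounds (inclusive) beyond which
#'     a bin is considered homozygous and dropped from the BAF track.}
#'   \item{lrr_outlier_filter}{`enabled`, `quantile`: optional kernel-density
#'     outlier filter on LRR; bins whose estimated density falls below the
#'     given quantile of all per-bin densities are dropped.}
#'   \item{segmentation}{`min_bins`, `min_length_bp`, `alpha`: a candidate
#'     breakpoint is accepted only if both children have at least `min_bins`
#'     bins, span at least `min_length_bp`, and differ in mean at Welch-test
#'     level `alpha`.}
#'   \item{merge}{`kde_overlap`: adjacent segments whose kernel density
#'     estimates overlap by at least this coefficient are combined.}
#'   \item{purity}{`cn_max`, `sf_grid` (lo, hi, step), `dbscan_eps`,
#'     `dbscan_minpts`, `min_purity`, `balanced_tol`, `baf_star_max`,
#'     `baf_frac_min`: the genotype/scale-factor search space, the
#'     density-clustering parameters, the low-confidence purity cutoff, the
#'     half-width around 0.5 within which a cluster is treated as
#'     allelically balanced, and two censoring guards — the mirrored BAF
#'     above which, and the BAF-bin fraction below which, a cluster is
#'     considered censored by the homozygosity filter and excluded from
#'     purity estimation.}
#'   \item{scars}{`loh_mb`, `tai_mb`, `lst_flank_mb`, `lst_filter_mb`,
#'     `lst_merge_equal`, `k`, `threshold`: scar-event length thresholds in
#'     Mb, the ploidy correction coefficient K, and the HRD positivity
#'     threshold.}
#' }
#'
#' @param overrides optional named list (possibly read from a YAML/JSON
#'   config) replacing individual entries.
#' @return nested configuration list of class `gscar_config`.
#' @export
#' @examples
#' cfg <- gscar_config(list(scars = list(k = 15.5)))
#' cfg$segmentation$min_bins
gscar_config <- function(overrides = NULL) {
  cfg <- list(
    homozygous_baf = list(low = 0.05, high = 0.95),
    lrr_outlier_filter = list(enabled = FALSE, quantile = 0.30),
    segmentation = list(min_bins = 10, min_length_bp = 1e6, alpha = 0.01),
    merge = list(kde_overlap = 0.5),
    purity = list(
      cn_max = 8,
      sf_grid = c(0.5, 2.5, 0.01),
      dbscan_eps = 0.10,
      dbscan_minpts = 3,
      min_purity = 0.20,
      balanced_tol = 0.03,
      baf_star_max = 0.92,
      baf_frac_min = 0.7
    ),
    scars = list(
      loh_mb = 15, tai_mb = 11, lst_flank_mb = 10, lst_filter_mb = 3,
      lst_merge_equal = TRUE, k = 15.5, threshold = 30
    )
  )
  cfg <- modify_config(cfg, overrides)
  class(cfg) <- c("gscar_config", "list")
  cfg
}

# recursive list merge; `y` entries override `x`
modify_config <- function(x, y) {
  if (is.null(y)) return(x)
  stopifnot(is.list(y))
  for (nm in names(y)) {
    if (is.list(y[[nm]]) && is.list(x[[nm]])) {
      x[[nm]] <- modify_config(x[[nm]], y[[nm]])
    } else {
      x[[nm]] <- y[[nm]]
    }
  }
  x
}
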