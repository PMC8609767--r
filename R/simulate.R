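#' Ground-truth copy-number profile for simulation
#'
#' A profile lists allele-specific copy-number events on a background of
#' the normal heterozygous genotype `(1, 1)`, together with the true tumor
#' purity and scale factor used by the forward model.
#'
#' @param events data.frame with columns `chrom`, `start`, `end`, `n_a`,
#'   `n_b` (non-negative integers; intervals must not overlap within a
#'   chromosome).
#' @param purity true tumor purity in (0, 1].
#' @param scale_factor true ploidy correction factor (> 0).
#' @return list of class `sim_profile`.
#' @export
sim_profile <- function(events, purity = 1, scale_factor = 1) {
  stopifnot(is.data.frame(events),
            all(c("chrom", "start", "end", "n_a", "n_b") %in% names(events)),
            purity > 0, purity <= 1, scale_factor > 0)
  events$chrom <- normalize_chrom(events$chrom)
  stopifnot(all(events$start < events$end),
            all(events$n_a >= 0), all(events$n_b >= 0))
  for (chrom in unique(events$chrom)) {
    e <- events[events$chrom == chrom, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping events on chromosome ", chrom)
    }
  }
  structure(list(events = events, purity = purity,
                 scale_factor = scale_factor),
            class = "sim_profile")
}

#' Read a ground-truth profile from a tab-separated file
#'
#' @param path TSV with header `chrom start end n_a n_b`.
#' @param purity,scale_factor forwarded to [sim_profile()].
#' @return `sim_profile`.
#' @export
read_sim_profile <- function(path, purity = 1, scale_factor = 1) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sim_profile(df, purity = purity, scale_factor = scale_factor)
}

#' A representative tumor profile used for validation
#'
#' Arm-level events of the common genotype classes on a diploid
#' heterozygous background: single-copy gains (ABB), hemizygous deletions
#' (B), balanced double gains (AABB) and copy-neutral LOH (BB), each
#' recurring on several chromosomes as is typical of scarred tumor
#' genomes.
#'
#' @param purity true tumor purity.
#' @param scale_factor true scale factor.
#' @return `sim_profile`.
#' @export
default_tumor_profile <- function(purity = 1, scale_factor = 1) {
  events <- utils::read.delim(
    system.file("extdata", "example_profile.tsv", package = "gscar",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sim_profile(events, purity = purity, scale_factor = scale_factor)
}

#' Simulation settings
#'
#' @param bins_per_mb bin density (bins per megabase).
#' @param baf_sd Gaussian standard deviation of BAF noise.
#' @param lrr_sd Gaussian standard deviation of LRR noise.
#' @param seed integer random seed; identical settings give byte-identical
#'   tracks.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(bins_per_mb = 1, baf_sd = 0.02, lrr_sd = 0.1,
                       seed = NULL) {
  stopifnot(bins_per_mb > 0, baf_sd >= 0, lrr_sd >= 0)
  structure(list(bins_per_mb = bins_per_mb, baf_sd = baf_sd,
                 lrr_sd = lrr_sd, seed = seed),
            class = "sim_config")
}

#' Simulate a noisy BAF/LRR track from a ground-truth profile
#'
#' Bins are laid out at the configured density on every annotated
#' chromosome, skipping the centromere gap. Per bin, the true genotype is
#' looked up (background `(1, 1)`), a fair coin decides which allele is
#' read as the B allele (the unmirrored bimodal BAF pattern), and the
#' admixture model gives the expected values:
#' `BAF = (1 - p + p * n) / (p * CN + 2 * (1 - p))` for the chosen allele
#' count `n`, and `LRR = log2((p * CN + 2 * (1 - p)) / (2 * scale_factor))`.
#' Gaussian noise is added; BAF is clipped to [0, 1]. Homozygous deletions
#' at purity 1 yield missing BAF and a floored LRR.
#'
#' @param profile `sim_profile`.
#' @param config `sim_config`.
#' @param annotation `genome_annotation`.
#' @return `bin_track` data.frame.
#' @export
simulate_track <- function(profile, config = sim_config(),
                           annotation = grch37_annotation()) {
  stopifnot(inherits(profile, "sim_profile"))
  ev <- profile$events
  unknown <- setdiff(ev$chrom, annotation$chrom)
  if (length(unknown) > 0) {
    stop("profile events on unannotated chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  bad <- ev$end > annotation$length[match(ev$chrom, annotation$chrom)]
  if (any(bad)) stop("profile event outside chromosome bounds")
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- profile$purity; sf <- profile$scale_factor
  spacing <- 1e6 / config$bins_per_mb

  rows <- lapply(seq_len(nrow(annotation)), function(ci) {
    len <- annotation$length[ci]
    starts <- seq(0, len - spacing, by = spacing)
    ends <- starts + spacing
    keep <- ends <= annotation$cen_start[ci] |
      starts >= annotation$cen_end[ci]
    data.frame(chrom = annotation$chrom[ci],
               start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  mid <- (bins$start + bins$end) / 2
  n_a <- rep(1L, nrow(bins)); n_b <- rep(1L, nrow(bins))
  for (i in seq_len(nrow(ev))) {
    hit <- bins$chrom == ev$chrom[i] & mid >= ev$start[i] & mid < ev$end[i]
    n_a[hit] <- ev$n_a[i]; n_b[hit] <- ev$n_b[i]
  }
  cn <- n_a + n_b
  cn_mix <- p * cn + 2 * (1 - p)
  flip <- stats::runif(nrow(bins)) < 0.5
  n_read <- ifelse(flip, n_b, n_a)
  baf <- ifelse(cn_mix > 0, (1 - p + p * n_read) / cn_mix, NA_real_)
  lrr <- log2(pmax(cn_mix, 0.05) / (2 * sf))
  if (config$baf_sd > 0) {
    baf <- pmin(pmax(baf + stats::rnorm(nrow(bins), 0, config$baf_sd), 0), 1)
  }
  if (config$lrr_sd > 0) {
    lrr <- lrr + stats::rnorm(nrow(bins), 0, config$lrr_sd)
  }
  bin_track(bins$chrom, bins$start, bins$end, baf, lrr, annotation)
}

#' Simulate a tumor purity dilution series
#'
#' One track per requested purity, with the same profile events and an
#' independent, reproducible noise stream per track index (derived from
#' the configured seed).
#'
#' @param profile `sim_profile` (its `purity` field is overridden per
#'   track).
#' @param purities numeric vector of purities in (0, 1].
#' @param config `sim_config`.
#' @param annotation `genome_annotation`.
#' @return named list of `bin_track`s, one per purity.
#' @export
dilution_series <- function(profile, purities, config = sim_config(),
                            annotation = grch37_annotation()) {
  stopifnot(all(purities > 0), all(purities <= 1))
  out <- vector("list", length(purities))
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  for (i in seq_along(purities)) {
    pr <- profile
    pr$purity <- purities[i]
    cfg_i <- config
    cfg_i$seed <- base_seed + 977L * i
    out[[i]] <- simulate_track(pr, cfg_i, annotation)
  }
  names(out) <- as.character(purities)
  out
}

#' Cross-platform score table for 40 tumor samples
#'
#' Per sample: purity, LOH, TAI, LST, ploidy and HRD score as computed from
#' the SNP-array platform and from the targeted panel.
#'
#' @return data.frame with 40 rows and 13 columns (`sample`,
#'   `array_purity` ... `array_hrd`, `panel_purity` ... `panel_hrd`).
#' @export
load_table1_fixture <- function() {
  utils::read.delim(
    system.file("extdata", "table1_platform_scores.tsv", package = "gscar",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Scar scores of 17 ovarian and breast cancer cell lines
#'
#' @return data.frame with 17 rows: `cell_line`, `cancer_type`, `loh`,
#'   `tai`, `lst`, `ploidy`, `hrd_score`, `brca_mutation`,
#'   `brca1_methylation_pct`.
#' @export
load_table2_fixture <- function() {
  utils::read.delim(
    system.file("extdata", "table2_cell_line_scores.tsv", package = "gscar",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
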