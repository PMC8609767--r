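#' Run the full genomic scar analysis on a track
#'
#' Segments the track ([segment_track()]), converts segment LRR means to
#' measured copy numbers ([theoretical_cn()]), clusters segments into
#' genotypes ([cluster_genotypes()]), jointly fits purity and the scale
#' factor ([fit_purity_ploidy()]), assigns integer allele-specific copy
#' numbers ([assign_integer_cn()]), combines adjacent segments that ended
#' up with the same genotype, computes ploidy ([compute_ploidy()]) and the
#' scar counts, and returns the HRD score and status.
#'
#' When purity cannot be estimated (no allelically imbalanced cluster) the
#' sample is treated as diploid with purity-free copy numbers taken from
#' the measured values, and the result is flagged low-confidence; the
#' report always carries the six headline fields.
#'
#' @param track `bin_track`.
#' @param annotation `genome_annotation`.
#' @param config configuration list, see [gscar_config()].
#' @return object of class `gscar_result`: a list with `scores` (named
#'   list: `loh`, `tai`, `lst`, `ploidy`, `purity`, `k`, `hrd_score`,
#'   `hrd_status`, `low_confidence`), `segments`, `clusters`, `fit`, and
#'   `reports`.
#' @export
gscar_score <- function(track, annotation = grch37_annotation(),
                        config = gscar_config()) {
  segres <- segment_track(track, annotation, config)
  segments <- segres$segments
  segments$cn_star <- theoretical_cn(segments$lrr)
  clusters <- cluster_genotypes(segments, config)
  fit <- fit_purity_ploidy(clusters, config)
  if (is.finite(fit$purity) && is.finite(fit$scale_factor)) {
    segments <- assign_integer_cn(segments, fit)
  } else {
    # purity-free fallback: round the measured copy number directly
    segments$cn <- as.integer(pmax(round(segments$cn_star), 0))
    segments$n_b <- as.integer(pmin(pmax(round(segments$baf * segments$cn),
                                         0), segments$cn))
    segments$n_b[!is.finite(segments$baf)] <-
      as.integer(segments$cn[!is.finite(segments$baf)] -
                   floor(segments$cn[!is.finite(segments$baf)] / 2))
    segments$n_a <- segments$cn - segments$n_b
    segments$inconsistent <- FALSE
    segments$baf_missing <- !is.finite(segments$baf)
  }
  segments <- combine_equal_genotype(segments)
  fit$ploidy <- compute_ploidy(segments, annotation)
  loh <- count_loh(segments, annotation, config)
  tai <- count_tai(segments, annotation, config)
  lst <- count_lst(segments, annotation, config)
  score <- hrd_score(loh, tai, lst, fit$ploidy, config$scars$k)
  scores <- list(
    loh = loh, tai = tai, lst = lst,
    ploidy = fit$ploidy,
    purity = fit$purity,
    k = config$scars$k,
    hrd_score = score,
    hrd_status = classify_hrd(score, config$scars$threshold),
    low_confidence = isTRUE(fit$low_confidence)
  )
  structure(list(scores = scores, segments = segments, clusters = clusters,
                 fit = fit, reports = segres$reports),
            class = "gscar_result")
}

# fuse consecutive same-chromosome segments that received identical
# (n_a, n_b); means are re-weighted by bin count
combine_equal_genotype <- function(segments) {
  if (nrow(segments) < 2) return(segments)
  same <- segments$chrom[-1] == segments$chrom[-nrow(segments)] &
    segments$n_a[-1] == segments$n_a[-nrow(segments)] &
    segments$n_b[-1] == segments$n_b[-nrow(segments)]
  same[is.na(same)] <- FALSE
  grp <- cumsum(c(TRUE, !same))
  out <- lapply(split(seq_len(nrow(segments)), grp), function(idx) {
    g <- segments[idx, , drop = FALSE]
    if (nrow(g) == 1) return(g)
    w <- pmax(g$n_bins, 1)
    g$end[1] <- g$end[nrow(g)]
    g$baf[1] <- if (any(is.finite(g$baf)))
      stats::weighted.mean(g$baf, w * is.finite(g$baf), na.rm = TRUE)
    else NA_real_
    g$lrr[1] <- stats::weighted.mean(g$lrr, w, na.rm = TRUE)
    if (!is.null(g$cn_star))
      g$cn_star[1] <- stats::weighted.mean(g$cn_star, w, na.rm = TRUE)
    g$n_bins[1] <- sum(g$n_bins)
    if (!is.null(g$crosses_cen)) g$crosses_cen[1] <- any(g$crosses_cen)
    g[1, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.gscar_result <- function(x, ...) {
  s <- x$scores
  cat("<gscar_result>\n")
  cat(sprintf("  LOH %d  TAI %d  LST %d\n", s$loh, s$tai, s$lst))
  cat(sprintf("  purity %s  ploidy %.2f\n",
              if (is.na(s$purity)) "undefined" else sprintf("%.2f", s$purity),
              s$ploidy))
  cat(sprintf("  HRD score %.2f (K = %.1f): %s%s\n", s$hrd_score, s$k,
              s$hrd_status,
              if (s$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Write a JSON + TSV report of a scoring result
#'
#' @param result `gscar_result`.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, dir, prefix = "gscar") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, "_report.json"))
  tsv_path <- file.path(dir, paste0(prefix, "_segments.tsv"))
  jsonlite::write_json(result$scores, json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  write_segments(result$segments, tsv_path)
  invisible(c(json = json_path, segments = tsv_path))
}
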