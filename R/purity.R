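#' Measured total copy number from LRR
#'
#' `CN* = 2^LRR * 2`: an LRR of 0 corresponds to two copies.
#'
#' @param lrr log2 tumor/normal depth ratio.
#' @return measured (purity-uncorrected) total copy number.
#' @export
theoretical_cn <- function(lrr) 2^lrr * 2

#' Expected measured BAF of a genotype under admixture
#'
#' For a tumor fraction `p` mixed with diploid heterozygous normal cells,
#' a genotype with `n_a` copies of the A allele and `n_b` of the B allele
#' yields a measured BAF of
#' `(1 - p + p * n_b) / (p * (n_a + n_b) + 2 * (1 - p))`.
#'
#' @param p tumor purity in (0, 1].
#' @param n_a,n_b non-negative integer allele copy numbers.
#' @return expected measured BAF.
#' @export
expected_baf <- function(p, n_a, n_b) {
  denom <- p * (n_a + n_b) + 2 * (1 - p)
  if (any(denom <= 0)) {
    stop(errorCondition(
      "zero total copy number at purity 1: homozygous-deletion special case",
      class = c("gscar_homdel_error", "error", "condition")))
  }
  (1 - p + p * n_b) / denom
}

#' Purity implied by a genotype cluster
#'
#' Inverts [expected_baf()]: given the measured mean mirrored BAF of a
#' cluster (`baf_star`), the genotype's total copy number `cn` and its
#' theoretical BAF `baf = n_b / cn`, the tumor purity is
#' `(1 - 2*baf_star) / (baf_star*cn - 2*baf_star + 1 - baf*cn)`.
#' Balanced genotypes (`baf == 0.5`) make the denominator vanish and are
#' uninformative for purity.
#'
#' @param baf_star measured mean mirrored BAF of the cluster.
#' @param cn genotype total copy number.
#' @param baf theoretical BAF of the genotype.
#' @return purity clipped to [0, 1]; the attribute `out_of_range` flags a
#'   raw estimate outside that interval.
#' @export
purity_from_cluster <- function(baf_star, cn, baf) {
  if (abs(baf - 0.5) < 1e-9) {
    stop(errorCondition(
      "balanced genotype: cluster is uninformative for purity",
      class = c("gscar_balanced_error", "error", "condition")))
  }
  p <- purity_raw(baf_star, cn, baf)
  out <- pmin(pmax(p, 0), 1)
  attr(out, "out_of_range") <- p < 0 | p > 1
  out
}

purity_raw <- function(baf_star, cn, baf) {
  (1 - 2 * baf_star) / (baf_star * cn - 2 * baf_star + 1 - baf * cn)
}

#' Fractional percentile ranks
#'
#' Maps values to `(rank - 0.5) / n` with ties receiving the mean rank, so
#' ranks lie in (0, 1) and a constant vector maps to 0.5.
#'
#' @param values numeric vector.
#' @return numeric vector of ranks in (0, 1).
#' @export
rank_percentiles <- function(values) {
  stopifnot(length(values) >= 1)
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

# Plain DBSCAN on a small point set (distance-matrix implementation).
# Returns an integer cluster label per point; 0 marks noise. The
# eps-neighborhood includes the point itself, so a core point has at least
# `minpts` points within `eps`.
dbscan_labels <- function(points, eps, minpts) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(points))
  nbrs <- d <= eps
  core <- rowSums(nbrs) >= minpts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (!core[j]) next
      reach <- which(nbrs[j, ] & labels == 0L)
      labels[reach] <- cl
      queue <- c(queue, reach[core[reach]])
    }
  }
  labels
}

#' Cluster segments into genotype groups
#'
#' Segments of the same genotype occupy the same region of the
#' (mean mirrored BAF, measured CN) plane. Both quantities are converted to
#' fractional percentile ranks (see [rank_percentiles()]) and clustered
#' with DBSCAN; noise points become singleton clusters. Cluster summary
#' statistics are genome-length-weighted medians over members, which keeps
#' a single mischained member from dragging the summary.
#'
#' @param segments segment data.frame with columns `chrom`, `start`, `end`,
#'   `baf` (mean mirrored BAF) and `cn_star` (measured CN). Segments
#'   without a BAF mean are returned as singleton clusters with `baf_star`
#'   `NA`.
#' @param config configuration list (`purity$dbscan_eps`,
#'   `purity$dbscan_minpts`).
#' @return data.frame with one row per cluster: `cluster`, `n_members`,
#'   `baf_star`, `cn_star`, `length`, and a list-column `members` of row
#'   indices into `segments`.
#' @export
cluster_genotypes <- function(segments, config = gscar_config()) {
  len <- segments$end - segments$start
  with_baf <- which(is.finite(segments$baf) & is.finite(segments$cn_star))
  labels <- integer(nrow(segments))
  if (length(with_baf) >= 2) {
    pts <- cbind(rank_percentiles(segments$baf[with_baf]),
                 rank_percentiles(segments$cn_star[with_baf]))
    lab <- dbscan_labels(pts, config$purity$dbscan_eps,
                         config$purity$dbscan_minpts)
    labels[with_baf] <- lab
  } else if (length(with_baf) == 1) {
    labels[with_baf] <- 1L
  }
  # noise points and BAF-less segments become singleton clusters
  nxt <- max(labels) + 1L
  for (i in seq_len(nrow(segments))) {
    if (labels[i] == 0L) { labels[i] <- nxt; nxt <- nxt + 1L }
  }
  baf_frac <- if (is.null(segments$baf_frac)) rep(1, nrow(segments)) else
    segments$baf_frac
  ids <- sort(unique(labels))
  rows <- lapply(seq_along(ids), function(k) {
    m <- which(labels == ids[k])
    w <- len[m]
    has_baf <- is.finite(segments$baf[m])
    has_cn <- is.finite(segments$cn_star[m])
    # length-weighted medians: a single mischained member cannot drag the
    # cluster's summary the way a weighted mean would
    data.frame(
      cluster = k,
      n_members = length(m),
      baf_star = if (any(has_baf))
        weighted_median(segments$baf[m][has_baf], w[has_baf])
      else NA_real_,
      cn_star = if (any(has_cn))
        weighted_median(segments$cn_star[m][has_cn], w[has_cn])
      else NA_real_,
      baf_frac = weighted_median(baf_frac[m], w),
      length = sum(w)
    )
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(seq_along(ids), function(k) which(labels == ids[k]))
  out
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

genotype_grid <- function(cn_max, balanced = FALSE) {
  g <- expand.grid(n_a = 0:cn_max, n_b = 0:cn_max)
  g <- g[g$n_a <= g$n_b & g$n_a + g$n_b >= 1 & g$n_a + g$n_b <= cn_max, ]
  if (balanced) g <- g[g$n_a == g$n_b, ] else g <- g[g$n_a != g$n_b, ]
  g$cn <- g$n_a + g$n_b
  g$baf <- g$n_b / g$cn
  rownames(g) <- NULL
  g
}

#' Joint estimation of tumor purity and the scale factor
#'
#' Grid search over candidate scale factors. For each scale factor every
#' allelically imbalanced cluster is assigned a small-integer genotype:
#' each candidate genotype implies a purity through
#' [purity_from_cluster()], and candidates whose implied purity reproduces
#' the cluster's measured CN are retained; because genotypes of different
#' total copy number can predict nearly the same measured CN for the same
#' BAF, the assignment among near-minimal-residual candidates is refined
#' to agree with the weighted-median purity consensus across clusters.
#' Balanced clusters take the balanced genotype most consistent with the
#' consensus purity; clusters without usable BAF may take any genotype.
#' The winning scale factor minimizes the genome-length-weighted median
#' absolute deviation of the per-cluster purity estimates, plus half the
#' weighted mean CN residual, plus a small penalty (0.01 per copy) on the
#' mean assigned copy number — a uniformly genome-doubled assignment at
#' half purity reproduces BAF and CN exactly, and the penalty resolves
#' that degeneracy toward the lower-ploidy reading. The sample purity is
#' the genome-length-weighted mean of the per-cluster estimates.
#'
#' Clusters with mean mirrored BAF within `balanced_tol` of 0.5 are treated
#' as balanced; clusters above `baf_star_max`, or with fewer than
#' `baf_frac_min` of their bins carrying BAF, are excluded from purity
#' estimation because the homozygosity filter censors their BAF
#' distribution.
#'
#' @param clusters data.frame from [cluster_genotypes()].
#' @param config configuration list.
#' @return object of class `purity_ploidy_fit`: a list with `purity`,
#'   `scale_factor`, `ploidy` (`NA` until segments are assigned, see
#'   [compute_ploidy()]), `clusters` (per-cluster genotype, purity and
#'   residual), `objective`, and `low_confidence` (set when purity is
#'   undefined or below `min_purity`).
#' @export
fit_purity_ploidy <- function(clusters, config = gscar_config()) {
  cfg <- config$purity
  ok <- is.finite(clusters$cn_star)
  cl <- clusters[ok, , drop = FALSE]
  baf_frac <- if (is.null(cl$baf_frac)) rep(1, nrow(cl)) else cl$baf_frac
  # clusters that lost a sizable share of BAF bins to the homozygosity
  # filter have censored (downward-biased) BAF and cannot inform purity
  usable_baf <- is.finite(cl$baf_star) & cl$baf_star <= cfg$baf_star_max &
    baf_frac >= cfg$baf_frac_min
  imb <- usable_baf & abs(cl$baf_star - 0.5) > cfg$balanced_tol
  if (!any(imb)) {
    fit <- list(purity = NA_real_, scale_factor = NA_real_, ploidy = NA_real_,
                clusters = cl, objective = NA_real_, low_confidence = TRUE,
                reason = "no allelically imbalanced cluster")
    class(fit) <- "purity_ploidy_fit"
    return(fit)
  }
  g_imb <- genotype_grid(cfg$cn_max, balanced = FALSE)
  g_bal <- genotype_grid(cfg$cn_max, balanced = TRUE)
  g_all <- rbind(g_bal, g_imb)
  sfs <- seq(cfg$sf_grid[1], cfg$sf_grid[2], by = cfg$sf_grid[3])

  # candidate purities per imbalanced cluster are scale-factor independent
  idx_imb <- which(imb)
  cand <- lapply(idx_imb, function(i) {
    p <- purity_raw(cl$baf_star[i], g_imb$cn, g_imb$baf)
    keep <- is.finite(p) & p > 0.01 & p <= 1 + 1e-9
    list(p = pmin(p[keep], 1), cn = g_imb$cn[keep],
         n_a = g_imb$n_a[keep], n_b = g_imb$n_b[keep])
  })
  idx_bal <- which(!imb)

  best <- NULL
  for (sf in sfs) {
    p_i <- numeric(length(idx_imb)); r_i <- numeric(length(idx_imb))
    pick <- integer(length(idx_imb))
    res_k <- vector("list", length(idx_imb))
    bad <- FALSE
    for (k in seq_along(idx_imb)) {
      cc <- cand[[k]]
      if (length(cc$p) == 0) { bad <- TRUE; break }
      res <- abs((cc$p * cc$cn + 2 * (1 - cc$p)) / sf -
                   cl$cn_star[idx_imb[k]])
      res_k[[k]] <- res
      j <- order(round(res, 9), cc$cn)[1]
      p_i[k] <- cc$p[j]; r_i[k] <- res[j]; pick[k] <- j
    }
    if (bad) next
    w_i <- cl$length[idx_imb]
    # genotypes of different total CN can predict almost the same CN* for
    # the same BAF, so the residual alone cannot identify the genotype;
    # re-pick among near-minimal-residual candidates for consistency with
    # the purity consensus, and iterate
    for (it in 1:2) {
      p_med <- weighted_median(p_i, w_i)
      for (k in seq_along(idx_imb)) {
        cc <- cand[[k]]; res <- res_k[[k]]
        adm <- which(res <= min(res) + 0.1)
        j <- adm[order(round(abs(cc$p[adm] - p_med), 9), cc$cn[adm], res[adm])[1]]
        p_i[k] <- cc$p[j]; r_i[k] <- res[j]; pick[k] <- j
      }
    }
    p_hat <- stats::weighted.mean(p_i, w_i)
    r_b <- numeric(length(idx_bal)); pick_b <- integer(length(idx_bal))
    for (k in seq_along(idx_bal)) {
      # balanced clusters choose among balanced genotypes; clusters whose
      # BAF is missing or censored may take any genotype
      g_k <- if (usable_baf[idx_bal[k]]) g_bal else g_all
      res <- abs((p_hat * g_k$cn + 2 * (1 - p_hat)) / sf -
                   cl$cn_star[idx_bal[k]])
      j <- order(round(res, 9), g_k$cn)[1]
      r_b[k] <- res[j]; pick_b[k] <- j
    }
    disp <- weighted_median(abs(p_i - weighted_median(p_i, w_i)), w_i)
    resid <- stats::weighted.mean(c(r_i, r_b),
                                  c(w_i, cl$length[idx_bal]))
    # a uniformly genome-doubled assignment at half purity reproduces BAF
    # and CN* exactly; prefer the lower-ploidy reading of such ties
    cn_assigned <- c(vapply(seq_along(idx_imb),
                            function(k) cand[[k]]$cn[pick[k]], numeric(1)),
                     vapply(seq_along(idx_bal), function(k) {
                       g_k <- if (usable_baf[idx_bal[k]]) g_bal else g_all
                       g_k$cn[pick_b[k]]
                     }, numeric(1)))
    mean_cn <- stats::weighted.mean(cn_assigned,
                                    c(w_i, cl$length[idx_bal]))
    obj <- disp + 0.5 * resid + 0.01 * mean_cn
    if (is.null(best) || obj < best$obj) {
      best <- list(obj = obj, sf = sf, p = p_hat, p_i = p_i, r_i = r_i,
                   pick = pick, r_b = r_b, pick_b = pick_b)
    }
  }
  if (is.null(best)) {
    fit <- list(purity = NA_real_, scale_factor = NA_real_, ploidy = NA_real_,
                clusters = cl, objective = NA_real_, low_confidence = TRUE,
                reason = "no admissible genotype for any imbalanced cluster")
    class(fit) <- "purity_ploidy_fit"
    return(fit)
  }
  cl$genotype_n_a <- NA_integer_; cl$genotype_n_b <- NA_integer_
  cl$purity <- NA_real_; cl$residual <- NA_real_
  for (k in seq_along(idx_imb)) {
    cc <- cand[[k]]; j <- best$pick[k]
    cl$genotype_n_a[idx_imb[k]] <- cc$n_a[j]
    cl$genotype_n_b[idx_imb[k]] <- cc$n_b[j]
    cl$purity[idx_imb[k]] <- best$p_i[k]
    cl$residual[idx_imb[k]] <- best$r_i[k]
  }
  for (k in seq_along(idx_bal)) {
    j <- best$pick_b[k]
    g_k <- if (usable_baf[idx_bal[k]]) g_bal else g_all
    cl$genotype_n_a[idx_bal[k]] <- g_k$n_a[j]
    cl$genotype_n_b[idx_bal[k]] <- g_k$n_b[j]
    cl$residual[idx_bal[k]] <- best$r_b[k]
  }
  fit <- list(purity = best$p, scale_factor = best$sf, ploidy = NA_real_,
              clusters = cl, objective = best$obj,
              low_confidence = best$p < cfg$min_purity,
              reason = if (best$p < cfg$min_purity)
                sprintf("purity %.3f below validated operating range", best$p)
              else NA_character_)
  class(fit) <- "purity_ploidy_fit"
  fit
}

#' @export
print.purity_ploidy_fit <- function(x, ...) {
  cat("<purity_ploidy_fit>\n")
  cat(sprintf("  purity: %s\n",
              if (is.na(x$purity)) "undefined" else sprintf("%.3f", x$purity)))
  cat(sprintf("  scale_factor: %s\n",
              if (is.na(x$scale_factor)) "undefined"
              else sprintf("%.2f", x$scale_factor)))
  if (!is.na(x$ploidy)) cat(sprintf("  ploidy: %.2f\n", x$ploidy))
  if (isTRUE(x$low_confidence))
    cat(sprintf("  low confidence: %s\n", x$reason))
  invisible(x)
}

#' Assign integer allele-specific copy numbers to segments
#'
#' Inverts the admixture model per segment: the corrected total copy
#' number is `(CN* * scale_factor - 2 * (1 - p)) / p` rounded to the
#' nearest non-negative integer, and the B-allele copy number is
#' `(BAF* * CN* * scale_factor - (1 - p)) / p` rounded and clipped to
#' `[0, CN]`; `n_a = CN - n_b`, with the mirrored convention `n_b >= n_a`.
#' Segments whose pre-rounding copy number falls below -0.5 are flagged
#' inconsistent. Segments without a BAF mean receive the most balanced
#' split of their copy number and are flagged.
#'
#' @param segments segment data.frame with `cn_star` and mirrored `baf`.
#' @param fit a `purity_ploidy_fit` with valid purity and scale factor.
#' @return `segments` with added integer columns `cn`, `n_a`, `n_b` and
#'   logical columns `inconsistent`, `baf_missing`.
#' @export
assign_integer_cn <- function(segments, fit) {
  p <- fit$purity; sf <- fit$scale_factor
  stopifnot(is.finite(p), is.finite(sf), p > 0)
  cn_raw <- (segments$cn_star * sf - 2 * (1 - p)) / p
  segments$inconsistent <- cn_raw < -0.5
  cn <- pmax(round(cn_raw), 0)
  nb_raw <- (segments$baf * segments$cn_star * sf - (1 - p)) / p
  n_b <- pmin(pmax(round(nb_raw), 0), cn)
  segments$baf_missing <- !is.finite(segments$baf)
  n_b[segments$baf_missing] <- cn[segments$baf_missing] -
    floor(cn[segments$baf_missing] / 2)
  n_a <- cn - n_b
  # mirrored convention
  swap <- which(n_a > n_b)
  tmp <- n_a[swap]; n_a[swap] <- n_b[swap]; n_b[swap] <- tmp
  segments$cn <- as.integer(cn)
  segments$n_a <- as.integer(n_a)
  segments$n_b <- as.integer(n_b)
  segments
}

#' Genome ploidy as the proportion-weighted mean copy number
#'
#' `Ploidy = sum(Segs_i * CN_i) + (1 - sum(Segs_i)) * 2`, where `Segs_i`
#' is the fraction of the annotated genome covered by segment `i`; genome
#' not covered by any segment is assumed diploid.
#'
#' @param segments segment data.frame with integer `cn`.
#' @param annotation `genome_annotation` providing the total genome length.
#' @return the ploidy (a positive real number).
#' @export
compute_ploidy <- function(segments, annotation) {
  total <- sum(annotation$length)
  if (nrow(segments) == 0) return(2)
  prop <- (segments$end - segments$start) / total
  sum(prop * segments$cn) + (1 - sum(prop)) * 2
}
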