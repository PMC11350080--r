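#' Mann-Whitney U test
#'
#' `U = sum over pairs [x > y] + 1/2 [x = y]`. In `exact` mode the p-value
#' comes from the full permutation distribution of U (used automatically
#' when `n_x + n_y <= 16` and the data are tie-free); `normal` mode uses
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric samples (nonempty).
#' @param mode "auto", "exact" or "normal".
#' @return tibble with `U`, `p` (two-sided), `n_x`, `n_y`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("mann_whitney: empty sample", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    auto = length(x) + length(y) <= 16 && !ties,
    exact = {
      if (ties) stop("exact Mann-Whitney is undefined with ties; ",
                     "use mode = 'normal'", call. = FALSE)
      TRUE
    },
    normal = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  tibble(U = U, p = min(1, wt$p.value), n_x = length(x),
         n_y = length(y),
         method = if (use_exact) "exact" else "normal")
}

#' Divergence effect size (standardized mean difference)
#'
#' `D = |mean(x) - mean(y)| / s_pooled` with the pooled standard
#' deviation `s_pooled = sqrt(((n_x-1) s_x^2 + (n_y-1) s_y^2) /
#' (n_x + n_y - 2))` — Cohen's d, matching the conventional small/medium/
#' strong thresholds 0.2/0.5/0.8. The robust variant uses medians and the
#' analogously pooled QAD.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param robust if TRUE, medians and pooled [qad()] replace means and SDs.
#' @return nonnegative number; `Inf` (with a warning) when the pooled
#'   spread is zero but the centres differ, 0 when both are equal.
#' @examples
#' effect_size_d(c(2, 4, 6), c(3, 5, 7))  # 0.5
#' @export
effect_size_d <- function(x, y, robust = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("effect_size_d needs n >= 2 per sample", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  if (robust) {
    cx <- median(x); cy <- median(y)
    sx <- qad(x); sy <- qad(y)
  } else {
    cx <- mean(x); cy <- mean(y)
    sx <- sd(x); sy <- sd(y)
  }
  sp <- sqrt(((nx - 1) * sx^2 + (ny - 1) * sy^2) / (nx + ny - 2))
  delta <- abs(cx - cy)
  if (sp == 0) {
    if (delta == 0) return(0)
    warning("zero pooled spread with unequal centres: D = Inf")
    return(Inf)
  }
  delta / sp
}

#' R-squared of the divergence effect size
#'
#' `R^2_D = D^2 / (D^2 + 4)`, the variance-explained form of a
#' standardized mean difference (equal-n convention). Strictly increasing
#' in D; D = 2 maps to exactly 0.5.
#'
#' @param d nonnegative effect size(s).
#' @return value(s) in \[0, 1).
#' @export
r2_from_d <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("D must be >= 0", call. = FALSE)
  d^2 / (d^2 + 4)
}

#' Quantile absolute difference (QAD)
#'
#' Median of absolute deviations from the median (unscaled MAD): a robust
#' spread measure used as error bars on per-cluster boxplots.
#'
#' @param x numeric sample (n >= 1).
#' @return nonnegative number.
#' @examples
#' qad(c(1, 2, 3))      # 1
#' qad(c(1, 1, 1, 9))   # 0
#' @export
qad <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("qad: empty sample", call. = FALSE)
  median(abs(x - median(x)))
}

#' Signed relative difference in percent of a reference value
#'
#' `100 * (value_a - value_b) / value_b` — e.g. "+77%" means group A is
#' 77% above reference group B (B taken as 100%).
#'
#' @param value_a value of interest.
#' @param value_b reference value (nonzero).
#' @return signed percentage.
#' @export
relative_difference_pct <- function(value_a, value_b) {
  if (any(value_b == 0)) {
    stop("relative_difference_pct: zero reference value", call. = FALSE)
  }
  100 * (value_a - value_b) / value_b
}

#' Area-weighted mean across clusters
#'
#' `sum(value_i * area_i) / sum(area_i)` — used to aggregate per-cluster
#' intensities over merged clusters taking the clusters' areas into
#' account.
#'
#' @param values per-cluster means.
#' @param areas per-cluster pixel areas (positive, same length).
#' @return weighted mean.
#' @export
area_weighted_mean <- function(values, areas) {
  if (length(values) != length(areas)) {
    stop("values and areas must have equal length", call. = FALSE)
  }
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  sum(values * areas) / sum(areas)
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y numeric samples, n >= 3, both non-constant.
#' @return tibble with `r`, `p` (two-sided, from
#'   `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df), `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("pearson_cor needs n >= 3", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("pearson_cor: constant input, correlation undefined",
         call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-cluster, per-component two-group comparison
#'
#' For every (cluster, component) pair, compares the pixel distributions
#' of the two genotype maps with descriptive statistics (median, IQR,
#' QAD), a Mann-Whitney test, the divergence effect size D and its R^2,
#' and the signed relative difference of medians (group B as 100%
#' reference). Verdict rule: `significant` iff
#' `p < p_thresh AND (D > d_thresh OR R^2_D > r2_thresh)`; imaging-scale
#' defaults (0.001, 0.8, 0.5). Degenerate pixels are excluded. A cluster
#' absent (or with < 2 pixels) in either group yields an NA verdict with
#' a warning.
#'
#' @param maps_a,maps_b `component_maps` of the two genotypes (shared
#'   component set).
#' @param clusters_a,clusters_b [hcluster()] results giving the (shared)
#'   cluster scheme on each cube; `clusters_b` defaults to `clusters_a`
#'   when both maps live on the same geometry.
#' @param p_thresh,d_thresh,r2_thresh verdict thresholds.
#' @param mw_mode passed to [mann_whitney()].
#' @param robust_d use the robust effect-size variant.
#' @param p_adjust if TRUE, adds Benjamini-Hochberg adjusted p-values and
#'   bases the verdict on them (off by default, matching the unadjusted
#'   convention of imaging comparisons).
#' @return tibble of class `cluster_comparison`, one row per
#'   (cluster, component).
#' @export
compare_clusters <- function(maps_a, maps_b, clusters_a,
                             clusters_b = NULL, p_thresh = 0.001,
                             d_thresh = 0.8, r2_thresh = 0.5,
                             mw_mode = "auto", robust_d = FALSE,
                             p_adjust = FALSE) {
  stopifnot(inherits(maps_a, "component_maps"),
            inherits(maps_b, "component_maps"),
            inherits(clusters_a, "tissue_clusters"))
  if (is.null(clusters_b)) clusters_b <- clusters_a
  if (!identical(maps_a$components, maps_b$components)) {
    stop("the two maps have different component sets", call. = FALSE)
  }
  if (clusters_a$k != clusters_b$k) {
    stop("cluster schemes disagree on k", call. = FALSE)
  }
  k <- clusters_a$k
  comps <- maps_a$components
  pick <- function(maps, clusters, cl, j) {
    sel <- clusters$labels == cl & !is.na(maps$degenerate) &
      !maps$degenerate
    v <- maps$rel_abs[, , j][sel]
    v[is.finite(v)]
  }
  rows <- list()
  warned <- FALSE
  for (cl in seq_len(k)) {
    for (j in seq_along(comps)) {
      va <- pick(maps_a, clusters_a, cl, j)
      vb <- pick(maps_b, clusters_b, cl, j)
      if (length(va) < 2 || length(vb) < 2) {
        warned <- TRUE
        rows[[length(rows) + 1]] <- tibble(
          cluster = cl, component = comps[j],
          n_a = length(va), n_b = length(vb),
          median_a = NA_real_, median_b = NA_real_,
          iqr_a = NA_real_, iqr_b = NA_real_,
          qad_a = NA_real_, qad_b = NA_real_,
          U = NA_real_, p = NA_real_, D = NA_real_, r2_d = NA_real_,
          rel_diff_pct = NA_real_, verdict = NA_character_)
        next
      }
      mw <- mann_whitney(va, vb, mode = mw_mode)
      D <- effect_size_d(va, vb, robust = robust_d)
      med_a <- median(va)
      med_b <- median(vb)
      rows[[length(rows) + 1]] <- tibble(
        cluster = cl, component = comps[j],
        n_a = length(va), n_b = length(vb),
        median_a = med_a, median_b = med_b,
        iqr_a = IQR(va), iqr_b = IQR(vb),
        qad_a = qad(va), qad_b = qad(vb),
        U = mw$U, p = mw$p, D = D, r2_d = r2_from_d(D),
        rel_diff_pct = if (med_b != 0)
          relative_difference_pct(med_a, med_b) else NA_real_,
        verdict = NA_character_)
    }
  }
  if (warned) {
    warning("cluster(s) absent or too small in one group: ",
            "verdict undefined for those records")
  }
  out <- bind_rows(rows)
  p_eff <- out$p
  if (p_adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    p_eff <- out$p_adj
  }
  out$verdict <- ifelse(
    is.na(p_eff) | is.na(out$D), NA_character_,
    ifelse(p_eff < p_thresh &
             (out$D > d_thresh | out$r2_d > r2_thresh),
           "significant", "not_significant"))
  attr(out, "thresholds") <- c(p = p_thresh, d = d_thresh, r2 = r2_thresh)
  class(out) <- c("cluster_comparison", class(out))
  out
}
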