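#' Relative percent difference between two group means
#'
#' Default ("mean") form: `100 * |a - b| / ((a + b) / 2)` — symmetric and
#' scale invariant. The "reference" variant uses
#' `100 * |a - b| / b`.
#'
#' @param mean_a,mean_b group means with `mean_a + mean_b > 0`.
#' @param mode "mean" (default) or "reference".
#' @return nonnegative percentage.
#' @examples
#' relative_percent_difference(103, 97)  # 6
#' @export
relative_percent_difference <- function(mean_a, mean_b,
                                        mode = c("mean", "reference")) {
  mode <- match.arg(mode)
  if (any(mean_a + mean_b <= 0)) {
    stop("relative_percent_difference: nonpositive mean sum",
         call. = FALSE)
  }
  if (mode == "mean") {
    100 * abs(mean_a - mean_b) / ((mean_a + mean_b) / 2)
  } else {
    if (any(mean_b == 0)) stop("zero reference mean", call. = FALSE)
    100 * abs(mean_a - mean_b) / mean_b
  }
}

#' Screen compounds for association with rooting ability
#'
#' Implements the bulk ATR decision rule on genotype-level mean relative
#' absorbances: a compound is *eligible* when its relative percent
#' difference between the easy- and difficult-to-root group means exceeds
#' `rpd_thresh` (default 3) AND its Pearson correlation (genotypes as
#' observations) with at least two of the three adventitious-rooting
#' traits is significant at `alpha`. Only eligible compounds receive a
#' Mann-Whitney test of easy vs difficult genotype-level means. Records
#' are sorted by descending RPD.
#'
#' @param rel_abs long tibble `(sample_id, component,
#'   relative_absorbance)`, e.g. from [relative_absorbance()].
#' @param meta per-sample metadata tibble with `sample_id`, `genotype`,
#'   `group` ("easy"/"difficult") and the three trait columns
#'   `trait_ar10_ibap`, `trait_ar21_ibap`, `trait_ar21_ibam` (constant
#'   within genotype).
#' @param rpd_thresh RPD eligibility threshold in percent (default 3).
#' @param alpha trait-correlation significance level (default 0.05).
#' @param rpd_mode passed to [relative_percent_difference()].
#' @param mw_mode passed to [mann_whitney()].
#' @param p_adjust if TRUE, Benjamini-Hochberg adjusts the trait
#'   correlation p-values per trait across compounds before counting
#'   significant traits (off by default).
#' @return tibble of class `compound_screening`, one row per compound:
#'   group means, `rpd`, per-trait `r_*`/`p_*`, `n_significant_traits`,
#'   `eligible`, `U`/`p_mw` (NA unless eligible), `group_difference`
#'   ("higher_in_easy"/"higher_in_difficult"/"none") and an all-NA
#'   `predictive_performance` reporting column.
#' @export
screen_compounds <- function(rel_abs, meta, rpd_thresh = 3, alpha = 0.05,
                             rpd_mode = "mean", mw_mode = "auto",
                             p_adjust = FALSE) {
  need <- c("sample_id", "component", "relative_absorbance")
  if (!all(need %in% names(rel_abs))) {
    stop("rel_abs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  meta <- normalize_meta(as_tibble(meta), nrow(meta))
  if (any(is.na(meta$genotype))) {
    stop("meta must provide a genotype for every sample", call. = FALSE)
  }
  geno <- distinct(meta, .data$genotype, .data$group,
                   across(dplyr::all_of(trait_cols)))
  if (anyDuplicated(geno$genotype)) {
    stop("group/traits are not constant within genotype", call. = FALSE)
  }
  if (any(is.na(geno[trait_cols]))) {
    stop("missing rooting traits for genotype(s): ",
         paste(geno$genotype[!stats::complete.cases(geno[trait_cols])],
               collapse = ", "), call. = FALSE)
  }
  n_easy <- sum(geno$group == "easy")
  n_diff <- sum(geno$group == "difficult")
  if (n_easy < 2 || n_diff < 2) {
    stop("need at least 2 genotypes per rooting group (got easy = ",
         n_easy, ", difficult = ", n_diff, ")", call. = FALSE)
  }
  if (n_easy < 3 || n_diff < 3) {
    warning("fewer than 3 genotypes in a group: Mann-Whitney p-values ",
            "have little resolution")
  }
  # genotype-level mean relative absorbance per compound
  gmeans <- rel_abs |>
    left_join(select(meta, "sample_id", "genotype"), by = "sample_id") |>
    group_by(.data$genotype, .data$component) |>
    summarise(mra = mean(.data$relative_absorbance), .groups = "drop") |>
    left_join(geno, by = "genotype")

  one_compound <- function(df) {
    easy <- df$mra[df$group == "easy"]
    diff <- df$mra[df$group == "difficult"]
    me <- mean(easy)
    md <- mean(diff)
    # constant relative absorbance (or constant trait) has no defined
    # correlation; treated as non-significant rather than an error
    cors <- map(trait_cols, function(tc) {
      tryCatch(pearson_cor(df$mra, df[[tc]]),
               error = function(e) tibble(r = NA_real_, p = NA_real_,
                                          n = nrow(df)))
    })
    out <- tibble(
      compound = df$component[1],
      mean_easy = me, mean_difficult = md,
      rpd = relative_percent_difference(me, md, mode = rpd_mode),
      r_ar10_ibap = cors[[1]]$r, p_ar10_ibap = cors[[1]]$p,
      r_ar21_ibap = cors[[2]]$r, p_ar21_ibap = cors[[2]]$p,
      r_ar21_ibam = cors[[3]]$r, p_ar21_ibam = cors[[3]]$p)
    out
  }
  recs <- gmeans |>
    group_by(.data$component) |>
    dplyr::group_split() |>
    map_dfr(one_compound)
  pmat <- as.matrix(recs[c("p_ar10_ibap", "p_ar21_ibap", "p_ar21_ibam")])
  if (p_adjust) {
    pmat <- apply(pmat, 2, stats::p.adjust, method = "BH")
  }
  recs$n_significant_traits <- rowSums(pmat < alpha, na.rm = TRUE)
  recs$eligible <- recs$rpd > rpd_thresh & recs$n_significant_traits >= 2
  mw_u <- mw_p <- rep(NA_real_, nrow(recs))
  gd <- rep("none", nrow(recs))
  for (i in which(recs$eligible)) {
    df <- gmeans[gmeans$component == recs$compound[i], ]
    mw <- mann_whitney(df$mra[df$group == "easy"],
                       df$mra[df$group == "difficult"], mode = mw_mode)
    mw_u[i] <- mw$U
    mw_p[i] <- mw$p
    if (mw$p < alpha) {
      gd[i] <- if (recs$mean_easy[i] > recs$mean_difficult[i])
        "higher_in_easy" else "higher_in_difficult"
    }
  }
  recs$U <- mw_u
  recs$p_mw <- mw_p
  recs$group_difference <- gd
  recs$predictive_performance <- NA_real_
  recs <- arrange(recs, desc(.data$rpd))
  class(recs) <- c("compound_screening", class(recs))
  recs
}

#' Compound x trait Pearson correlation table
#'
#' Correlates genotype-level mean relative absorbance of every compound
#' with each rooting trait (pairwise deletion of missing values).
#'
#' @inheritParams screen_compounds
#' @return tibble `(compound, trait, r, p, n)`.
#' @export
correlation_matrix <- function(rel_abs, meta) {
  meta <- normalize_meta(as_tibble(meta), nrow(meta))
  geno <- distinct(meta, .data$genotype,
                   across(dplyr::all_of(trait_cols)))
  gmeans <- rel_abs |>
    left_join(select(meta, "sample_id", "genotype"), by = "sample_id") |>
    group_by(.data$genotype, .data$component) |>
    summarise(mra = mean(.data$relative_absorbance), .groups = "drop") |>
    left_join(geno, by = "genotype")
  map_dfr(unique(gmeans$component), function(cmp) {
    df <- gmeans[gmeans$component == cmp, ]
    map_dfr(trait_cols, function(tc) {
      ct <- pearson_cor(df$mra, df[[tc]])
      tibble(compound = cmp, trait = tc, r = ct$r, p = ct$p, n = ct$n)
    })
  })
}
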