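#' Tidy an EMSC fit into one row per (sample, term)
#'
#' @param x an [emsc_fit].
#' @param ... unused.
#' @return tibble `(sample_id, term, type, estimate)` where `type` is
#'   "scatter", "baseline" or "component".
#' @export
tidy.emsc_fit <- function(x, ...) {
  p1 <- x$model$poly_order + 2
  types <- c("scatter", rep("baseline", p1 - 1),
             rep("component", ncol(x$components)))
  as_tibble(x$coefficients) |>
    mutate(sample_id = x$sample_id, .before = 1) |>
    pivot_longer(-"sample_id", names_to = "term",
                 values_to = "estimate") |>
    mutate(type = rep(types, length(x$sample_id)), .after = "term")
}

#' One-row summary of an EMSC fit
#'
#' @param x an [emsc_fit].
#' @param ... unused.
#' @return tibble with fit dimensions, solver, design condition number,
#'   degenerate count and mean residual rms.
#' @export
glance.emsc_fit <- function(x, ...) {
  tibble(n_spectra = length(x$a),
         n_components = ncol(x$components),
         poly_order = x$model$poly_order,
         solver = x$solver,
         condition_number = x$model$condition_number,
         n_degenerate = sum(x$degenerate),
         mean_residual_rms = mean(x$residual_rms))
}

#' Per-cluster summary of a tissue clustering
#'
#' @param x a [hcluster()] result.
#' @param ... unused.
#' @return tibble `(cluster, area_px, area_um2)`.
#' @export
tidy.tissue_clusters <- function(x, ...) {
  tibble(cluster = seq_len(x$k),
         area_px = x$cluster_areas,
         area_um2 = x$cluster_areas * x$pixel_size_um^2)
}

#' @rdname tidy.tissue_clusters
#' @export
glance.tissue_clusters <- function(x, ...) {
  tibble(k = x$k, linkage = x$linkage,
         n_pixels = sum(x$cluster_areas),
         largest_cluster_px = max(x$cluster_areas))
}
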