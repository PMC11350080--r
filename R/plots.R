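#' Plot a few spectra of a spectrum table
#'
#' @param table a [spectrum_table].
#' @param n number of spectra to draw (default up to 10).
#' @return a ggplot (wavenumber axis reversed, instrument convention).
#' @export
plot_spectra <- function(table, n = 10) {
  stopifnot(inherits(table, "spectrum_table"))
  idx <- seq_len(min(n, nrow(table$absorbance)))
  df <- tibble(
    sample_id = rep(table$meta$sample_id[idx], each = length(table$axis)),
    wavenumber = rep(table$axis, length(idx)),
    absorbance = as.vector(t(table$absorbance[idx, , drop = FALSE])))
  ggplot(df, aes(.data$wavenumber, .data$absorbance,
                 colour = .data$sample_id)) +
    geom_line(linewidth = 0.3, show.legend = length(idx) <= 10) +
    scale_x_reverse() +
    labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance") +
    theme_minimal()
}

#' @export
autoplot.tissue_clusters <- function(object, ...) {
  df <- as_tibble(expand.grid(row = seq_len(nrow(object$labels)),
                              col = seq_len(ncol(object$labels))))
  df$cluster <- as.vector(object$labels)
  df$cluster[df$cluster == 0] <- NA
  ggplot(df, aes(.data$col, .data$row, fill = factor(.data$cluster))) +
    geom_raster() +
    scale_y_reverse() +
    coord_equal() +
    labs(fill = "cluster", x = NULL, y = NULL,
         title = sprintf("Tissue clusters (k = %d)", object$k)) +
    theme_void()
}

#' @export
autoplot.spectra_pca <- function(object, colour = "group", ...) {
  sc <- object$scores
  ggplot(sc, aes(.data$PC1, .data$PC2,
                 colour = .data[[colour]])) +
    geom_point() +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    theme_minimal()
}

#' @export
autoplot.cluster_comparison <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$verdict))
  long <- df |>
    select("cluster", "component", "median_a", "median_b",
           "qad_a", "qad_b", "verdict") |>
    pivot_longer(c("median_a", "median_b"), names_to = "genotype",
                 values_to = "median") |>
    mutate(qad = ifelse(.data$genotype == "median_a", df$qad_a[
      match(paste(.data$cluster, .data$component),
            paste(df$cluster, df$component))], df$qad_b[
      match(paste(.data$cluster, .data$component),
            paste(df$cluster, df$component))]),
      genotype = ifelse(.data$genotype == "median_a", "A", "B"))
  stars <- dplyr::filter(df, .data$verdict == "significant")
  ggplot(long, aes(factor(.data$cluster), .data$median,
                   fill = .data$genotype)) +
    geom_col(position = "dodge") +
    geom_errorbar(aes(ymin = .data$median - .data$qad,
                      ymax = .data$median + .data$qad),
                  position = position_dodge(width = 0.9), width = 0.3,
                  linewidth = 0.3) +
    geom_point(data = stars,
               aes(factor(.data$cluster),
                   y = pmax(.data$median_a, .data$median_b) * 1.1),
               inherit.aes = FALSE, shape = 8, size = 1.5) +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "cluster", y = "median relative absorbance ± QAD") +
    theme_minimal()
}

#' @export
autoplot.compound_screening <- function(object, ...) {
  df <- mutate(object,
               compound = factor(.data$compound,
                                 levels = rev(.data$compound)))
  ggplot(df, aes(.data$rpd, .data$compound, fill = .data$eligible)) +
    geom_col() +
    geom_vline(xintercept = 3, linetype = 2) +
    labs(x = "relative percent difference (easy vs difficult)",
         y = NULL, fill = "eligible") +
    theme_minimal()
}

#' Plot one component's relative-absorbance map
#'
#' @param maps a `component_maps` object.
#' @param component component name (default: first).
#' @return a ggplot raster.
#' @export
plot_component_map <- function(maps, component = NULL) {
  stopifnot(inherits(maps, "component_maps"))
  if (is.null(component)) component <- maps$components[1]
  j <- match(component, maps$components)
  if (is.na(j)) stop("unknown component: ", component, call. = FALSE)
  img <- maps$rel_abs[, , j]
  df <- as_tibble(expand.grid(row = seq_len(nrow(img)),
                              col = seq_len(ncol(img))))
  df$value <- as.vector(img)
  ggplot(df, aes(.data$col, .data$row, fill = .data$value)) +
    geom_raster() +
    scale_y_reverse() +
    coord_equal() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(title = component, fill = "rel. abs.", x = NULL, y = NULL) +
    theme_void()
}
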