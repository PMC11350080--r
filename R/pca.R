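#' Principal component analysis of vector-normalized spectra
#'
#' Mean-centred PCA (no scaling). Loadings follow the sign convention that
#' the largest-magnitude element of each loading vector is positive.
#'
#' @param table a [spectrum_table] (conventionally vector-normalized).
#' @param n_components number of components,
#'   `<= min(n_samples - 1, n_channels)`.
#' @return object of class `spectra_pca`: `scores` (tibble with sample
#'   metadata and PC columns), `loadings` (channels x n matrix),
#'   `explained_variance` (fractions, non-increasing), `axis`.
#' @export
pca_scores <- function(table, n_components = 2) {
  stopifnot(inherits(table, "spectrum_table"))
  n_max <- min(nrow(table$absorbance) - 1L, length(table$axis))
  if (n_components < 1 || n_components > n_max) {
    stop("n_components must be in [1, ", n_max, "]", call. = FALSE)
  }
  pc <- prcomp(table$absorbance, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  L <- pc$rotation[, seq_len(n_components), drop = FALSE]
  S <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      S[, j] <- -S[, j]
    }
  }
  scores <- dplyr::bind_cols(table$meta, as_tibble(S))
  structure(
    list(scores = scores, loadings = L,
         explained_variance = ev[seq_len(n_components)], axis = table$axis),
    class = "spectra_pca"
  )
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("<spectra_pca> %d components; explained variance: %s\n",
              ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}
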