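#' Extract fingerprint spectra of unmasked pixels
#'
#' Returns the pixel x channel matrix of the fingerprint region
#' (default 1800-800 cm^-1) for all unmasked pixels, in row-major pixel
#' order. The cube should already be vector-normalized if the downstream
#' clustering is meant to compare spectral shape, not intensity.
#'
#' @param cube a [hypercube].
#' @param lo,hi fingerprint range bounds (cm^-1).
#' @return numeric matrix with attributes `pixel_idx` (linear indices into
#'   the image), `img_dim` (rows, cols), `pixel_size_um` and `axis`.
#' @export
extract_fingerprints <- function(cube, lo = 800, hi = 1800) {
  stopifnot(inherits(cube, "hypercube"))
  keep <- truncate_idx(cube$axis, lo, hi)
  d <- dim(cube$data)
  idx <- which(as.vector(cube$mask))
  if (length(idx) == 0) stop("empty mask: no pixels to extract",
                             call. = FALSE)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  fp <- flat[idx, keep, drop = FALSE]
  attr(fp, "pixel_idx") <- idx
  attr(fp, "img_dim") <- d[1:2]
  attr(fp, "pixel_size_um") <- cube$pixel_size_um
  attr(fp, "axis") <- cube$axis[keep]
  fp
}

#' Hierarchical clustering of pixel fingerprints into tissue clusters
#'
#' Ward (default), average or complete linkage on Euclidean distances.
#' When more than `max_pixels` fingerprints are present, a seeded uniform
#' subsample is clustered and the remaining pixels are assigned to the
#' nearest cluster centroid; clusters are then renumbered by descending
#' pixel area (cluster 1 = largest). Deterministic given the seed.
#'
#' @param fingerprints matrix from [extract_fingerprints()] (or any
#'   pixel x channel matrix; spatial attributes are used when present).
#' @param k number of clusters (>= 2, the study-scale default for stem
#'   sections is 7).
#' @param linkage "ward", "average" or "complete".
#' @param max_pixels subsample threshold (default 20000).
#' @param seed integer seed for the subsample.
#' @return object of class `tissue_clusters`: `labels` (rows x cols
#'   integer image, 0 = masked), `k`, `linkage_tree` (hclust object of the
#'   clustered set), `cluster_mean_spectra` (k x channels),
#'   `cluster_areas` (pixel counts), `pixel_idx`, `axis`,
#'   `pixel_size_um`.
#' @export
hcluster <- function(fingerprints, k, linkage = c("ward", "average",
                                                  "complete"),
                     max_pixels = 20000, seed = 1) {
  linkage <- match.arg(linkage)
  fp <- as.matrix(fingerprints)
  n <- nrow(fp)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the pixel count (", n, ")",
                  call. = FALSE)
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  if (n > max_pixels) {
    sub <- withr::with_seed(seed, sort(sample.int(n, max_pixels)))
  } else {
    sub <- seq_len(n)
  }
  tree <- hclust(dist(fp[sub, , drop = FALSE]), method = method)
  lab_sub <- cutree(tree, k = k)
  centroids <- rowsum(fp[sub, , drop = FALSE], lab_sub) /
    as.vector(table(lab_sub))
  labels_vec <- integer(n)
  labels_vec[sub] <- lab_sub
  rest <- setdiff(seq_len(n), sub)
  if (length(rest) > 0) {
    # nearest centroid by Euclidean distance
    G <- fp[rest, , drop = FALSE]
    d2 <- outer(rowSums(G^2), rowSums(centroids^2), "+") -
      2 * G %*% t(centroids)
    labels_vec[rest] <- max.col(-d2, ties.method = "first")
  }
  # renumber by descending area
  areas <- tabulate(labels_vec, nbins = k)
  ord <- order(areas, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels_vec <- relabel[labels_vec]
  areas <- tabulate(labels_vec, nbins = k)
  mean_spectra <- rowsum(fp, labels_vec) / areas
  rownames(mean_spectra) <- NULL
  idx <- attr(fingerprints, "pixel_idx")
  dd <- attr(fingerprints, "img_dim")
  if (is.null(idx)) {
    idx <- seq_len(n)
    dd <- c(n, 1L)
  }
  labels <- matrix(0L, dd[1], dd[2])
  labels[idx] <- labels_vec
  px <- attr(fingerprints, "pixel_size_um")
  structure(
    list(labels = labels, k = as.integer(k), linkage_tree = tree,
         cluster_mean_spectra = mean_spectra, cluster_areas = areas,
         pixel_idx = idx, axis = attr(fingerprints, "axis"),
         pixel_size_um = if (is.null(px)) NA_real_ else px,
         linkage = linkage),
    class = "tissue_clusters"
  )
}

#' @export
print.tissue_clusters <- function(x, ...) {
  cat(sprintf("<tissue_clusters> k = %d (%s linkage), areas: %s px\n",
              x$k, x$linkage, paste(x$cluster_areas, collapse = ", ")))
  invisible(x)
}

#' Pixel mask for a set of clusters
#'
#' @param result a [hcluster()] result.
#' @param clusters integer cluster ids (subset of 1..k; empty set gives an
#'   all-FALSE mask).
#' @return logical rows x cols matrix, TRUE where the pixel label is in
#'   `clusters`.
#' @export
cluster_mask <- function(result, clusters) {
  stopifnot(inherits(result, "tissue_clusters"))
  clusters <- as.integer(clusters)
  if (length(clusters) > 0 &&
      (any(clusters < 1) || any(clusters > result$k))) {
    stop("unknown cluster id(s): ",
         paste(setdiff(clusters, seq_len(result$k)), collapse = ", "),
         call. = FALSE)
  }
  matrix(result$labels %in% clusters, nrow(result$labels),
         ncol(result$labels))
}
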