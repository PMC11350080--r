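#' Spectrum table: absorbance spectra on a shared wavenumber axis
#'
#' The central container for bulk ATR-FTIR data: an n_samples x n_channels
#' absorbance matrix, a shared descending wavenumber axis, and per-sample
#' metadata (genotype, rooting group, rooting traits) as a tibble.
#'
#' @param absorbance numeric matrix (samples x channels) or a single
#'   spectrum as a numeric vector. Must be finite.
#' @param axis numeric wavenumber axis (cm^-1), strictly monotonic, within
#'   \[400, 4000\]. Ascending input is reversed to the descending
#'   instrument convention together with the matrix columns.
#' @param meta optional tibble/data.frame of per-sample metadata with at
#'   least a `sample_id` column; missing columns among `genotype`, `group`
#'   and the three rooting traits (`trait_ar10_ibap`, `trait_ar21_ibap`,
#'   `trait_ar21_ibam`, percentages in \[0, 100\]) are filled with
#'   defaults/NA. `group` must be one of "easy", "difficult", "unknown".
#' @return object of class `spectrum_table`.
#' @examples
#' st <- spectrum_table(matrix(runif(8), 2), axis = c(1800, 1400, 1000, 800))
#' st
#' @export
spectrum_table <- function(absorbance, axis, meta = NULL) {
  if (is.vector(absorbance) && is.numeric(absorbance)) {
    absorbance <- matrix(absorbance, nrow = 1)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  ca <- canonical_axis(axis)
  if (ncol(absorbance) != length(ca$axis)) {
    stop("absorbance has ", ncol(absorbance),
         " channels but the axis has ", length(ca$axis), call. = FALSE)
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance contains non-finite values", call. = FALSE)
  }
  absorbance <- absorbance[, ca$order, drop = FALSE]
  meta <- normalize_meta(meta, nrow(absorbance), rownames(absorbance))
  dimnames(absorbance) <- NULL
  structure(
    list(axis = ca$axis, absorbance = absorbance, meta = meta),
    class = "spectrum_table"
  )
}

trait_cols <- c("trait_ar10_ibap", "trait_ar21_ibap", "trait_ar21_ibam")

normalize_meta <- function(meta, n, rn = NULL) {
  if (is.null(meta)) {
    ids <- if (!is.null(rn)) rn else sprintf("S%03d", seq_len(n))
    meta <- tibble(sample_id = ids)
  }
  meta <- as_tibble(meta)
  if (nrow(meta) != n) {
    stop("meta has ", nrow(meta), " rows for ", n, " samples", call. = FALSE)
  }
  if (!"sample_id" %in% names(meta)) {
    stop("meta must contain a sample_id column", call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (!"genotype" %in% names(meta)) meta$genotype <- NA_character_
  if (!"group" %in% names(meta)) meta$group <- "unknown"
  meta$group <- as.character(meta$group)
  bad <- !meta$group %in% c("easy", "difficult", "unknown")
  if (any(bad)) {
    stop("invalid rooting group value(s): ",
         paste(unique(meta$group[bad]), collapse = ", "), call. = FALSE)
  }
  for (tc in trait_cols) {
    if (!tc %in% names(meta)) meta[[tc]] <- NA_real_
    meta[[tc]] <- as.numeric(meta[[tc]])
    v <- meta[[tc]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop(tc, " must be a percentage in [0, 100]", call. = FALSE)
    }
  }
  meta
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf(
    "<spectrum_table> %d spectra x %d channels (%.0f-%.0f cm^-1)\n",
    nrow(x$absorbance), length(x$axis), max(x$axis), min(x$axis)))
  grp <- table(x$meta$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_table <- function(x) dim(x$absorbance)

#' Subset samples of a spectrum table
#'
#' @param x a `spectrum_table`.
#' @param i sample index (integer, logical or sample_id character).
#' @param ... unused.
#' @return a `spectrum_table` with the selected samples.
#' @export
`[.spectrum_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$sample_id)
  structure(
    list(axis = x$axis,
         absorbance = x$absorbance[i, , drop = FALSE],
         meta = x$meta[i, , drop = FALSE]),
    class = "spectrum_table"
  )
}

#' Hyperspectral FTIR image cube
#'
#' A rows x cols x channels absorbance array with a shared wavenumber axis,
#' a logical tissue mask (TRUE = tissue pixel, FALSE = excluded from all
#' downstream statistics) and the spatial pixel size in micrometres.
#'
#' @param data numeric 3-d array, rows x cols x n_channels.
#' @param axis wavenumber axis (cm^-1); ascending input is reversed along
#'   with the channel dimension.
#' @param mask logical rows x cols matrix; defaults to all-TRUE.
#' @param pixel_size_um positive pixel edge length in micrometres
#'   (default 11, the instrument resolution the data model emulates).
#' @return object of class `hypercube`.
#' @export
hypercube <- function(data, axis, mask = NULL, pixel_size_um = 11) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "double"
  ca <- canonical_axis(axis)
  if (dim(data)[3] != length(ca$axis)) {
    stop("cube has ", dim(data)[3], " channels but the axis has ",
         length(ca$axis), call. = FALSE)
  }
  data <- data[, , ca$order, drop = FALSE]
  if (is.null(mask)) {
    mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  }
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !all(dim(mask) == dim(data)[1:2])) {
    stop("mask must be a logical matrix matching the spatial shape",
         call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("cube contains non-finite values", call. = FALSE)
  }
  structure(
    list(axis = ca$axis, data = data, mask = mask,
         pixel_size_um = pixel_size_um),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d pixels x %d channels (%.0f-%.0f cm^-1), %d masked, %g um/px\n",
    d[1], d[2], d[3], max(x$axis), min(x$axis), sum(!x$mask),
    x$pixel_size_um))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Restrict spectra to a wavenumber range
#'
#' Retains channels with `lo <= wavenumber <= hi` (closed interval). The
#' standard reduction to the 1800-800 cm^-1 fingerprint region before
#' normalization and decomposition.
#'
#' @param x a `spectrum_table` or `hypercube`.
#' @param lo,hi range bounds in cm^-1, `lo < hi`.
#' @return object of the same class with the restricted axis.
#' @examples
#' st <- spectrum_table(matrix(1, 1, 5), axis = seq(800, 2400, by = 400))
#' dim(truncate_range(st, 800, 1800))
#' @export
truncate_range <- function(x, lo = 800, hi = 1800) UseMethod("truncate_range")

truncate_idx <- function(axis, lo, hi) {
  if (!(lo < hi)) stop("truncate_range: lo must be < hi", call. = FALSE)
  keep <- which(axis >= lo & axis <= hi)
  if (length(keep) < 2) {
    stop(sprintf(
      "truncate_range: fewer than 2 channels remain in [%g, %g]", lo, hi),
      call. = FALSE)
  }
  keep
}

#' @export
truncate_range.spectrum_table <- function(x, lo = 800, hi = 1800) {
  keep <- truncate_idx(x$axis, lo, hi)
  spectrum_table(x$absorbance[, keep, drop = FALSE], x$axis[keep], x$meta)
}

#' @export
truncate_range.hypercube <- function(x, lo = 800, hi = 1800) {
  keep <- truncate_idx(x$axis, lo, hi)
  hypercube(x$data[, , keep, drop = FALSE], x$axis[keep], x$mask,
            x$pixel_size_um)
}

#' Vector (unit Euclidean norm) normalization
#'
#' Scales every spectrum to unit L2 norm over the current axis, the
#' conventional "vector normalization" of FTIR chemometrics. Zero-norm
#' spectra are an error naming the offending samples/pixels; for cubes only
#' unmasked pixels are normalized (masked pixels are left untouched).
#'
#' @param x a `spectrum_table` or `hypercube`.
#' @return object of the same class with unit-norm spectra.
#' @examples
#' st <- spectrum_table(matrix(c(3, 4), 1), axis = c(1800, 800))
#' vector_normalize(st)$absorbance
#' @export
vector_normalize <- function(x) UseMethod("vector_normalize")

#' @export
vector_normalize.spectrum_table <- function(x) {
  nrm <- sqrt(rowSums(x$absorbance^2))
  zero <- nrm == 0
  if (any(zero)) {
    stop("vector_normalize: zero-norm spectra: ",
         paste(x$meta$sample_id[zero], collapse = ", "), call. = FALSE)
  }
  spectrum_table(x$absorbance / nrm, x$axis, x$meta)
}

#' @export
vector_normalize.hypercube <- function(x) {
  d <- dim(x$data)
  flat <- matrix(x$data, d[1] * d[2], d[3])
  idx <- which(as.vector(x$mask))
  nrm <- sqrt(rowSums(flat[idx, , drop = FALSE]^2))
  zero <- nrm == 0
  if (any(zero)) {
    rc <- arrayInd(idx[zero], d[1:2])
    stop("vector_normalize: zero-norm pixels at (row,col): ",
         paste(sprintf("(%d,%d)", rc[, 1], rc[, 2])[seq_len(min(5, nrow(rc)))],
               collapse = " "),
         if (nrow(rc) > 5) " ..." else "", call. = FALSE)
  }
  flat[idx, ] <- flat[idx, , drop = FALSE] / nrm
  hypercube(array(flat, d), x$axis, x$mask, x$pixel_size_um)
}

#' Background mask from total fingerprint absorbance
#'
#' Flags pixels whose summed absolute absorbance over the fingerprint
#' region falls below a quantile of the image as background (mask = FALSE).
#'
#' @param cube a `hypercube`.
#' @param lo,hi fingerprint range used for the total (default 800-1800).
#' @param quantile_cut quantile in \[0, 1); pixels below it are masked out.
#' @return the cube with an updated mask (combined with the existing one).
#' @export
background_mask <- function(cube, lo = 800, hi = 1800, quantile_cut = 0.05) {
  stopifnot(inherits(cube, "hypercube"),
            quantile_cut >= 0, quantile_cut < 1)
  keep <- truncate_idx(cube$axis, lo, hi)
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  tot <- rowSums(abs(flat[, keep, drop = FALSE]))
  thr <- quantile(tot[as.vector(cube$mask)], quantile_cut, names = FALSE)
  new_mask <- cube$mask & matrix(tot >= thr, d[1], d[2])
  hypercube(cube$data, cube$axis, new_mask, cube$pixel_size_um)
}
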