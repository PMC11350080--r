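#' Validate and canonicalize a wavenumber axis
#'
#' FTIR wavenumber axes are stored in descending order (instrument
#' convention, e.g. 3900 -> 800 cm^-1). Ascending input is accepted and
#' reversed; the permutation applied is returned so data columns can be
#' reordered alongside.
#'
#' @param values numeric vector of wavenumbers in cm^-1. Must be strictly
#'   monotonic and lie within \[400, 4000\].
#' @return list with `axis` (descending numeric) and `order` (integer
#'   permutation mapping input channels to the canonical order).
#' @keywords internal
canonical_axis <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    stop("wavenumber axis must be a numeric vector of length >= 2",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("wavenumber axis contains non-finite values", call. = FALSE)
  }
  d <- diff(values)
  if (all(d > 0)) {
    ord <- rev(seq_along(values))
  } else if (all(d < 0)) {
    ord <- seq_along(values)
  } else {
    stop("wavenumber axis must be strictly monotonic", call. = FALSE)
  }
  ax <- values[ord]
  if (min(ax) < 400 || max(ax) > 4000) {
    stop("wavenumber axis must lie within [400, 4000] cm^-1", call. = FALSE)
  }
  list(axis = ax, order = ord)
}

#' Legendre polynomial basis on a wavenumber axis
#'
#' Evaluates Legendre polynomials P_0..P_p on the axis rescaled linearly to
#' \[-1, 1\]. Used as the baseline block of the EMSC design matrix (well
#' conditioned, unlike raw monomials) and as the baseline model of the
#' synthetic-data generator.
#'
#' @param axis numeric wavenumber axis (any order).
#' @param p polynomial order (>= 0).
#' @return numeric matrix, length(axis) x (p + 1), columns named "P0".."Pp".
#' @keywords internal
legendre_basis <- function(axis, p) {
  stopifnot(p >= 0, length(axis) >= 2)
  x <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  B <- matrix(0, length(x), p + 1)
  B[, 1] <- 1
  if (p >= 1) B[, 2] <- x
  if (p >= 2) {
    for (k in 2:p) {
      B[, k + 1] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1]) / k
    }
  }
  colnames(B) <- paste0("P", 0:p)
  B
}
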