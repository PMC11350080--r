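#' Build an EMSC decomposition model
#'
#' Assembles the extended multiplicative signal correction design matrix
#' `[m_bar | P_0..P_p | K_1..K_J]`: a reference spectrum `m_bar` capturing
#' multiplicative scatter, Legendre polynomial baseline terms on the
#' wavenumber axis rescaled to \[-1, 1\], and the chemical component
#' spectra of the library. Each spectrum is then modelled as
#' `s = a * m_bar + sum_i d_i P_i + sum_j c_j K_j + e`.
#'
#' The reference set defaults, for measured data, to the batch under
#' analysis (its channel-wise mean). With purely synthetic mixtures the
#' batch mean lies in the span of the components and baseline and the
#' design becomes rank deficient; use the dedicated reference spectrum the
#' generator emits (see [make_reference()]).
#'
#' @param reference a [spectrum_table] (its channel-wise mean is used) or a
#'   single numeric reference spectrum on the library axis.
#' @param library a [component_library].
#' @param poly_order baseline polynomial order `p >= 0` (default 2,
#'   quadratic).
#' @return object of class `emsc_model` with the design, its QR
#'   factorization and condition number (a warning is raised above 1e8;
#'   rank deficiency is an error).
#' @examples
#' lib <- make_library(synth_config(seed = 1))
#' m <- emsc_model(make_reference(synth_config(seed = 1)), lib)
#' m
#' @export
emsc_model <- function(reference, library, poly_order = 2) {
  stopifnot(inherits(library, "component_library"), poly_order >= 0)
  if (inherits(reference, "spectrum_table")) {
    if (!isTRUE(all.equal(reference$axis, library$axis))) {
      stop("reference axis does not match library axis", call. = FALSE)
    }
    m_bar <- colMeans(reference$absorbance)
  } else if (is.numeric(reference)) {
    if (length(reference) != length(library$axis)) {
      stop("reference spectrum length does not match library axis",
           call. = FALSE)
    }
    m_bar <- as.numeric(reference)
  } else {
    stop("reference must be a spectrum_table or a numeric spectrum",
         call. = FALSE)
  }
  P <- legendre_basis(library$axis, poly_order)
  design <- cbind(m_bar = m_bar, P, t(library$spectra))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("EMSC design is rank deficient (collinear reference/components)",
         call. = FALSE)
  }
  kp <- kappa(design, exact = TRUE)
  if (kp > 1e8) {
    warning(sprintf("EMSC design badly conditioned (kappa = %.3g)", kp))
  }
  # (D'D)^-1 diagonal for the reference column: scales the sampling
  # uncertainty of the scatter coefficient in the degenerate-fit rule
  inv_a <- chol2inv(qr.R(qrd))[1, 1]
  structure(
    list(axis = library$axis, m_bar = m_bar, poly_order = poly_order,
         library = library, design = design, qr = qrd,
         condition_number = kp, inv_a = inv_a),
    class = "emsc_model"
  )
}

#' @export
print.emsc_model <- function(x, ...) {
  cat(sprintf(
    "<emsc_model> %d channels, poly order %d, %d components, kappa %.3g\n",
    length(x$axis), x$poly_order, nrow(x$library$spectra),
    x$condition_number))
  invisible(x)
}

# NIPALS PLS1, uncentred: with ncomp = ncol(X) the regression vector
# equals the OLS solution.
pls1_beta <- function(X, y, ncomp) {
  W <- P <- matrix(0, ncol(X), ncomp)
  q <- numeric(ncomp)
  Xr <- X
  yr <- y
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      W <- W[, seq_len(k - 1), drop = FALSE]
      P <- P[, seq_len(k - 1), drop = FALSE]
      q <- q[seq_len(k - 1)]
      break
    }
    w <- w / nw
    t <- Xr %*% w
    tt <- sum(t^2)
    p <- crossprod(Xr, t) / tt
    qk <- sum(yr * t) / tt
    Xr <- Xr - t %*% t(p)
    yr <- yr - t * qk
    W[, k] <- w
    P[, k] <- p
    q[k] <- qk
  }
  drop(W %*% solve(t(P) %*% W, q))
}

# partial NNLS: components constrained >= 0, reference + baseline free.
# Projects the free block out, solves NNLS on the residual system, then
# back-substitutes the free coefficients.
fit_nnls_partial <- function(model, s) {
  p1 <- model$poly_order + 2            # m_bar + P0..Pp
  U <- model$design[, seq_len(p1), drop = FALSE]
  C <- model$design[, -seq_len(p1), drop = FALSE]
  qu <- qr(U)
  Ct <- qr.resid(qu, C)
  rt <- qr.resid(qu, s)
  cc <- pracma::lsqnonneg(Ct, rt)$x
  uu <- qr.coef(qu, s - C %*% cc)
  c(uu, cc)
}

#' Fit the EMSC model to spectra
#'
#' Decomposes each spectrum into scatter scale `a`, baseline coefficients
#' `d_0..d_p` and component coefficients `c_1..c_J` by least squares
#' (`ols`, exact), nonnegative component coefficients (`nnls`), or partial
#' least squares (`pls`, NIPALS; with `ncomp` equal to the number of
#' design columns it reproduces `ols`). Relative absorbance of component j
#' is `|c_j| / sum_j |c_j|` — the component's absorbance in relation to
#' the total fitted chemical absorbance, invariant to global rescaling of
#' the input spectrum.
#'
#' Fits with a negative scatter scale (`a < 0`) are flagged degenerate
#' (warning, not error) and are excluded from downstream cluster
#' statistics.
#'
#' @param model an [emsc_model].
#' @param x spectra: numeric vector (one spectrum), matrix (rows =
#'   spectra) or [spectrum_table] on the model axis.
#' @param solver "ols" (default), "nnls" or "pls".
#' @param ncomp number of PLS latent variables (default: all design
#'   columns).
#' @return object of class `emsc_fit`; see [tidy.emsc_fit()],
#'   [glance.emsc_fit()], [relative_absorbance()].
#' @export
emsc_fit <- function(model, x, solver = c("ols", "nnls", "pls"),
                     ncomp = NULL) {
  stopifnot(inherits(model, "emsc_model"))
  solver <- match.arg(solver)
  sample_id <- NULL
  if (inherits(x, "spectrum_table")) {
    if (!isTRUE(all.equal(x$axis, model$axis))) {
      stop("spectra are not on the model axis", call. = FALSE)
    }
    sample_id <- x$meta$sample_id
    X <- x$absorbance
  } else if (is.numeric(x) && is.null(dim(x))) {
    X <- matrix(x, nrow = 1)
  } else {
    X <- as.matrix(x)
  }
  if (ncol(X) != length(model$axis)) {
    stop("spectra have ", ncol(X), " channels; model expects ",
         length(model$axis), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("non-finite absorbance values in input spectra", call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(rownames(X))) rownames(X) else
      sprintf("S%03d", seq_len(nrow(X)))
  }
  m <- ncol(model$design)
  coefs <- switch(solver,
    ols = t(qr.coef(model$qr, t(X))),
    nnls = t(apply(X, 1, function(s) fit_nnls_partial(model, s))),
    pls = {
      if (is.null(ncomp)) ncomp <- m
      stopifnot(ncomp >= 1, ncomp <= m)
      t(apply(X, 1, function(s) pls1_beta(model$design, s, ncomp)))
    })
  coefs <- matrix(coefs, nrow = nrow(X), ncol = m,
                  dimnames = list(NULL, colnames(model$design)))
  fitted <- coefs %*% t(model$design)
  residual_rms <- sqrt(rowMeans((X - fitted)^2))
  p1 <- model$poly_order + 2
  a <- coefs[, 1]
  baseline <- coefs[, 2:p1, drop = FALSE]
  comps <- coefs[, (p1 + 1):m, drop = FALSE]
  # a significantly negative scatter scale is a physically impossible
  # fit. Spectra without reference-specific structure legitimately sit
  # at a ~ 0, so the rule compares a against its own sampling
  # uncertainty under the fitted residual noise.
  se_a <- residual_rms * sqrt(model$inv_a * ncol(X) /
                                max(1, ncol(X) - m))
  a_scale <- sqrt(rowSums(X^2)) / sqrt(sum(model$m_bar^2))
  degenerate <- a < -(3 * se_a + 1e-10 * a_scale)
  if (any(degenerate)) {
    warning(sum(degenerate),
            " degenerate fit(s) with negative scatter scale a")
  }
  tot <- rowSums(abs(comps))
  rel <- abs(comps) / ifelse(tot > 0, tot, NA_real_)
  structure(
    list(sample_id = sample_id, coefficients = coefs, a = a,
         baseline = baseline, components = comps,
         relative_absorbance = rel, residual_rms = residual_rms,
         degenerate = degenerate, spectra = X, model = model,
         solver = solver),
    class = "emsc_fit"
  )
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat(sprintf(
    "<emsc_fit> %d spectra, solver %s, %d degenerate, mean residual rms %.3g\n",
    length(x$a), x$solver, sum(x$degenerate), mean(x$residual_rms)))
  invisible(x)
}

#' EMSC-corrected spectra
#'
#' Removes the fitted baseline and divides by the scatter scale:
#' `(s - sum_i d_i P_i) / a`. The reference spectrum maps to itself.
#'
#' @param fit an [emsc_fit].
#' @return numeric matrix of corrected spectra (rows = spectra).
#' @export
emsc_correct <- function(fit) {
  stopifnot(inherits(fit, "emsc_fit"))
  zero <- abs(fit$a) < 1e-10
  if (any(zero)) {
    stop("degenerate fit: scatter scale a = 0 for ",
         paste(fit$sample_id[zero], collapse = ", "), call. = FALSE)
  }
  p1 <- fit$model$poly_order + 2
  P <- fit$model$design[, 2:p1, drop = FALSE]
  (fit$spectra - fit$baseline %*% t(P)) / fit$a
}

#' Per-sample relative absorbances as a tibble
#'
#' @param fit an [emsc_fit] or `component_maps` object.
#' @param format "long" (sample_id, component, relative_absorbance) or
#'   "wide" (one column per component).
#' @return a tibble.
#' @export
relative_absorbance <- function(fit, format = c("long", "wide")) {
  UseMethod("relative_absorbance")
}

#' @export
relative_absorbance.emsc_fit <- function(fit,
                                         format = c("long", "wide")) {
  format <- match.arg(format)
  wide <- as_tibble(fit$relative_absorbance)
  wide <- tibble(sample_id = fit$sample_id, wide)
  if (format == "wide") return(wide)
  pivot_longer(wide, -"sample_id", names_to = "component",
               values_to = "relative_absorbance")
}

#' Fit the EMSC model to every unmasked pixel of a cube
#'
#' @param model an [emsc_model].
#' @param cube a [hypercube] on the model axis.
#' @param solver passed to [emsc_fit()].
#' @return object of class `component_maps`: per-component relative
#'   absorbance images (`rel_abs`, rows x cols x J, NA outside the mask),
#'   per-pixel coefficient images for scatter scale and residual rms, a
#'   degenerate-pixel map, and a fit report (`n_pixels`, `n_degenerate`).
#' @export
emsc_fit_cube <- function(model, cube, solver = "ols") {
  stopifnot(inherits(model, "emsc_model"), inherits(cube, "hypercube"))
  if (!isTRUE(all.equal(cube$axis, model$axis))) {
    stop("cube is not on the model axis", call. = FALSE)
  }
  d <- dim(cube$data)
  idx <- which(as.vector(cube$mask))
  cn <- model$library$info$name
  J <- length(cn)
  empty <- array(NA_real_, c(d[1], d[2], J), dimnames = list(NULL, NULL, cn))
  if (length(idx) == 0) {
    warning("fully masked cube: empty component maps")
    return(structure(
      list(rel_abs = empty, coefficients = empty,
           a = matrix(NA_real_, d[1], d[2]),
           residual_rms = matrix(NA_real_, d[1], d[2]),
           degenerate = matrix(NA, d[1], d[2]), mask = cube$mask,
           components = cn, n_pixels = 0L, n_degenerate = 0L,
           pixel_size_um = cube$pixel_size_um),
      class = "component_maps"))
  }
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  fit <- emsc_fit(model, flat[idx, , drop = FALSE], solver = solver)
  rel <- empty
  cf <- empty
  for (j in seq_len(J)) {
    pl <- matrix(NA_real_, d[1], d[2])
    pl[idx] <- fit$relative_absorbance[, j]
    rel[, , j] <- pl
    pl[idx] <- fit$components[, j]
    cf[, , j] <- pl
  }
  a <- rrms <- matrix(NA_real_, d[1], d[2])
  a[idx] <- fit$a
  rrms[idx] <- fit$residual_rms
  dg <- matrix(NA, d[1], d[2])
  dg[idx] <- fit$degenerate
  structure(
    list(rel_abs = rel, coefficients = cf, a = a, residual_rms = rrms,
         degenerate = dg, mask = cube$mask, components = cn,
         n_pixels = length(idx), n_degenerate = sum(fit$degenerate),
         pixel_size_um = cube$pixel_size_um),
    class = "component_maps"
  )
}

#' @export
print.component_maps <- function(x, ...) {
  cat(sprintf(
    "<component_maps> %d components, %d fitted pixels (%d degenerate)\n",
    length(x$components), x$n_pixels, x$n_degenerate))
  invisible(x)
}

#' @export
relative_absorbance.component_maps <- function(fit,
                                               format = c("long", "wide")) {
  format <- match.arg(format)
  d <- dim(fit$rel_abs)
  idx <- which(as.vector(fit$mask))
  rc <- arrayInd(idx, d[1:2])
  flat <- matrix(fit$rel_abs, d[1] * d[2], d[3])
  wide <- as_tibble(flat[idx, , drop = FALSE], .name_repair = "minimal")
  names(wide) <- fit$components
  wide <- tibble(row = rc[, 1], col = rc[, 2], wide)
  if (format == "wide") return(wide)
  pivot_longer(wide, c(-"row", -"col"), names_to = "component",
               values_to = "relative_absorbance")
}

#' Export component maps as an ENVI band stack and a long CSV
#'
#' @param maps a `component_maps` object.
#' @param dir output directory (created if needed).
#' @param stem file stem (default "component_maps").
#' @return paths of the written files, invisibly.
#' @export
export_maps <- function(maps, dir, stem = "component_maps") {
  stopifnot(inherits(maps, "component_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  envi <- file.path(dir, paste0(stem, ".envi"))
  envi_write_array(maps$rel_abs, envi, band_names = maps$components)
  csv <- file.path(dir, paste0(stem, ".csv"))
  write.csv(relative_absorbance(maps, "long"), csv, row.names = FALSE)
  invisible(c(envi, paste0(envi, ".hdr"), csv))
}
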