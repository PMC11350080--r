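lib3 <- tiny_library()
ref3 <- tiny_reference(lib3)
mod3 <- emsc_model(ref3, lib3, poly_order = 1)

test_that("model assembly follows the reference/baseline/component layout", {
  st1 <- spectrum_table(ref3, lib3$axis)
  m <- emsc_model(st1, lib3, poly_order = 0)
  expect_equal(m$m_bar, ref3)              # single reference = its mean
  expect_equal(ncol(m$design), 2 + 3)      # m_bar + P0 + J components

  dup <- component_library(rbind(lib3$spectra[1, ], lib3$spectra[1, ]),
                           lib3$axis, names = c("a", "b"))
  expect_error(emsc_model(ref3, dup), "rank deficient")

  other <- spectrum_table(matrix(1, 1, 10),
                          axis = seq(1800, 900, length.out = 10))
  expect_error(emsc_model(other, lib3), "axis")
})

test_that("noiseless spectra built from the design are recovered exactly", {
  P <- stemspec:::legendre_basis(lib3$axis, 1)
  s <- 1.3 * ref3 + 0.2 * P[, 1] + 0.5 * lib3$spectra[1, ]
  f <- emsc_fit(mod3, s)
  expect_equal(unname(f$a), 1.3, tolerance = 1e-9)
  expect_equal(unname(f$baseline[1, ]), c(0.2, 0), tolerance = 1e-9)
  expect_equal(unname(f$components[1, ]), c(0.5, 0, 0), tolerance = 1e-9)

  f2 <- emsc_fit(mod3, ref3)               # the reference itself
  expect_equal(unname(f2$a), 1, tolerance = 1e-9)
  expect_equal(max(abs(f2$coefficients[1, -1])), 0, tolerance = 1e-9)

  # any random coefficient vector round-trips through fit (ols)
  withr::with_seed(11, {
    for (r in 1:5) {
      beta <- rnorm(ncol(mod3$design))
      s <- drop(mod3$design %*% beta)
      f_r <- suppressWarnings(emsc_fit(mod3, s))  # beta may imply a < 0
      expect_equal(unname(f_r$coefficients[1, ]), beta, tolerance = 1e-9)
    }
  })
})

test_that("EMSC correction removes baseline and scatter", {
  s <- 2 * ref3 + 0.1
  f <- emsc_fit(mod3, s)
  expect_equal(drop(emsc_correct(f)), ref3, tolerance = 1e-9)
  expect_equal(drop(emsc_correct(emsc_fit(mod3, ref3))), ref3,
               tolerance = 1e-9)
  # noiseless mixture with reference content: correction leaves the
  # a-normalized chemical part on top of the reference
  withr::with_seed(12, {
    a <- runif(1, 0.5, 2)
    cc <- runif(3)
    s <- a * ref3 + 0.3 * stemspec:::legendre_basis(lib3$axis, 1)[, 2] +
      drop(cc %*% lib3$spectra)
    f <- emsc_fit(mod3, s)
    expect_equal(drop(emsc_correct(f)),
                 ref3 + drop(cc %*% lib3$spectra) / a, tolerance = 1e-8)
  })
  f0 <- emsc_fit(mod3, drop(0.4 %*% lib3$spectra[2, , drop = FALSE]))
  expect_error(emsc_correct(f0), "a = 0")
})

test_that("relative absorbance is scale invariant and sums to one", {
  withr::with_seed(13, s <- drop(runif(3) %*% lib3$spectra) + 0.05)
  f1 <- emsc_fit(mod3, s)
  f2 <- emsc_fit(mod3, 7.3 * s)
  expect_equal(f1$relative_absorbance, f2$relative_absorbance,
               tolerance = 1e-9)
  expect_equal(unname(rowSums(f1$relative_absorbance)), 1,
               tolerance = 1e-9)
})

test_that("PLS with full latent variables equals OLS; NNLS keeps c >= 0", {
  withr::with_seed(14, {
    S <- matrix(runif(2 * 3), 2, 3) %*% lib3$spectra +
      matrix(rnorm(2 * length(lib3$axis), 0, 0.01), 2)
  })
  fo <- emsc_fit(mod3, S, solver = "ols")
  fp <- emsc_fit(mod3, S, solver = "pls")
  expect_equal(fo$coefficients, fp$coefficients, tolerance = 1e-8)

  # a mixture engineered so OLS goes negative on component 2
  s_neg <- drop(c(1, -0.4, 0.6) %*% lib3$spectra)
  fn <- suppressWarnings(emsc_fit(mod3, s_neg, solver = "nnls"))
  expect_true(all(fn$components >= -1e-12))
  # and NNLS reproduces OLS when the truth is nonnegative
  fo2 <- emsc_fit(mod3, S, solver = "ols")
  fn2 <- emsc_fit(mod3, S, solver = "nnls")
  expect_equal(fo2$components, fn2$components, tolerance = 1e-6)
})

test_that("coefficient error shrinks monotonically as noise drops", {
  lib <- make_library(synth_config(seed = 1))
  mod <- emsc_model(make_reference(synth_config(seed = 1)), lib)
  rmse <- sapply(c(20, 40, 60), function(snr) {
    mix <- make_mixture_set(lib, 60, snr_db = snr, seed = 21)
    f <- suppressWarnings(emsc_fit(mod, mix$table))
    sqrt(mean((f$components - mix$coefficients)^2))
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("cube fits map pixels and handle uniform and masked cubes", {
  withr::with_seed(15, w <- runif(3, 0.3, 1))
  s <- drop(w %*% lib3$spectra)
  arr <- array(rep(s, each = 4), c(2, 2, length(lib3$axis)))
  cube <- hypercube(arr, lib3$axis)
  maps <- emsc_fit_cube(mod3, cube)
  expect_equal(maps$n_pixels, 4L)
  for (j in 1:3) {
    expect_equal(stats::sd(maps$rel_abs[, , j]), 0, tolerance = 1e-12)
  }
  expect_equal(maps$rel_abs[1, 1, ], w / sum(w), tolerance = 1e-9,
               ignore_attr = TRUE)

  empty <- hypercube(arr, lib3$axis, mask = matrix(FALSE, 2, 2))
  expect_warning(m0 <- emsc_fit_cube(mod3, empty), "fully masked")
  expect_true(all(is.na(m0$rel_abs)))
})

test_that("two-region cube recovers planted per-region relative absorbance", {
  w1 <- c(0.8, 0.3, 0.5)
  w2 <- c(0.2, 0.9, 0.4)
  n_ch <- length(lib3$axis)
  withr::with_seed(16, {
    arr <- array(0, c(4, 6, n_ch))
    for (r in 1:4) for (cc in 1:6) {
      w <- if (cc <= 3) w1 else w2
      arr[r, cc, ] <- drop(w %*% lib3$spectra) + rnorm(n_ch, 0, 0.004)
    }
  })
  maps <- emsc_fit_cube(mod3, hypercube(arr, lib3$axis))
  for (j in 1:3) {
    m1 <- mean(maps$rel_abs[, 1:3, j])
    m2 <- mean(maps$rel_abs[, 4:6, j])
    expect_equal(m1, (w1 / sum(w1))[j], tolerance = 0.05)
    expect_equal(m2, (w2 / sum(w2))[j], tolerance = 0.05)
  }
})

test_that("PCA is mean-centred, sign-fixed and matches an eigen oracle", {
  # perfectly collinear data: PC1 explains everything
  line <- spectrum_table(outer(1:5, c(1, 2, 3)) + 1,
                         axis = c(1800, 1300, 800))
  p <- pca_scores(line, 1)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)

  st <- random_table(n = 12, n_ch = 6, seed = 17)
  p2 <- pca_scores(st, 2)
  # sign convention: dominant loading element positive
  for (j in 1:2) {
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  }
  # independent eigendecomposition oracle
  X <- scale(st$absorbance, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(X))
  ev <- eg$values / sum(eg$values)
  expect_equal(p2$explained_variance, ev[1:2], tolerance = 1e-10)
  expect_equal(abs(p2$loadings), abs(eg$vectors[, 1:2]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_scores(st, 50), "n_components")
  # explained variance fractions are non-increasing and bounded
  expect_true(all(diff(p2$explained_variance) <= 0))
  expect_lte(sum(p2$explained_variance), 1)
})
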