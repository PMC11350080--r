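test_that("generation is fully deterministic for a fixed seed", {
  cfg <- synth_config(seed = 5, dims = c(32, 32), layout = "blocks")
  expect_identical(serialize(make_library(cfg), NULL),
                   serialize(make_library(cfg), NULL))
  expect_identical(serialize(make_panel(cfg), NULL),
                   serialize(make_panel(cfg), NULL))
  expect_identical(serialize(make_cube(cfg), NULL),
                   serialize(make_cube(cfg), NULL))
  # a different seed changes the data
  expect_false(identical(make_panel(cfg)$table$absorbance,
                         make_panel(cfg, seed = 99)$table$absorbance))
})

test_that("the library satisfies its construction invariants", {
  cfg <- synth_config(seed = 1)
  lib <- make_library(cfg)
  expect_equal(unname(sqrt(rowSums(lib$spectra^2))), rep(1, 10),
               tolerance = 1e-12)
  expect_true(all(lib$spectra >= 0))
  cs <- lib$spectra %*% t(lib$spectra)
  expect_lt(max(cs[upper.tri(cs)]), 0.95)

  lib1 <- make_library(synth_config(seed = 2, n_components = 1))
  expect_equal(nrow(lib1$spectra), 1)
  expect_equal(sum(lib1$spectra^2), 1, tolerance = 1e-12)
})

test_that("noise-free panels are exact component mixtures", {
  cfg <- synth_config(seed = 4, noise_sd = 0, scatter_sd = 0,
                      baseline_coeff_sd = c(0, 0, 0),
                      panel = list(n_replicates = 2))
  pan <- make_panel(cfg)
  W <- pan$truth$sample_coefficients
  expect_equal(pan$table$absorbance, W %*% pan$library$spectra,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(pan$truth$distortions$a), rep(1, nrow(W)))

  # with no planted effect, group separation is only genotype noise
  cfg0 <- synth_config(seed = 4,
                       panel = list(effect_multiplier = 1,
                                    genotype_sd = 0.01,
                                    n_replicates = 2))
  pan0 <- make_panel(cfg0)
  br <- suppressWarnings(
    run_bulk(pan0$table, pan0$library, reference = pan0$reference))
  expect_true(all(br$screening$rpd < 3))
})

test_that("panel traits are percentages tied to the planted compound", {
  pan <- make_panel(synth_config(seed = 8))
  tr <- pan$truth$traits
  for (tc in c("trait_ar10_ibap", "trait_ar21_ibap", "trait_ar21_ibam")) {
    expect_true(all(tr[[tc]] >= 0 & tr[[tc]] <= 100))
  }
  w <- pan$truth$genotype_weights$Man_hemicellulose
  expect_gt(cor(w, tr$trait_ar21_ibap), 0.5)
  expect_equal(pan$truth$planted$multiplier, 1.4)
  # easy group carries the planted excess
  gw <- pan$truth$genotype_weights
  expect_gt(mean(gw$Man_hemicellulose[gw$group == "easy"]),
            mean(gw$Man_hemicellulose[gw$group == "difficult"]))
})

test_that("the stem-section cube paints all seven regions consistently", {
  cfg <- synth_config(seed = 1)
  sc <- make_cube(cfg)
  expect_equal(sort(unique(sc$truth$regions)), 1:7)
  expect_identical(dim(sc$truth$region_labels), dim(sc$cube$mask))
  expect_identical(sc$truth$region_labels > 0, sc$cube$mask)
  expect_equal(length(sc$truth$pixel_idx), sum(sc$cube$mask))

  # pre-distortion per-region means equal the configured profiles
  cfg0 <- synth_config(seed = 1, dims = c(48, 48), layout = "blocks",
                       pixel_sd = 0, noise_sd = 0, scatter_sd = 0,
                       baseline_coeff_sd = c(0, 0, 0))
  s0 <- make_cube(cfg0)
  for (reg in sort(unique(s0$truth$regions))) {
    expect_equal(
      colMeans(s0$truth$coefficients[s0$truth$regions == reg, ,
                                     drop = FALSE]),
      s0$truth$profiles[reg, ], tolerance = 1e-12,
      ignore_attr = TRUE)
  }

  u <- make_cube(synth_config(seed = 2, dims = c(24, 24),
                              layout = "uniform"))
  expect_equal(unique(u$truth$regions), 1)
})

test_that("planted cube effects multiply exactly the targeted region/component", {
  cfg <- synth_config(seed = 3, dims = c(64, 64), pixel_sd = 0,
                      noise_sd = 0, scatter_sd = 0,
                      baseline_coeff_sd = c(0, 0, 0))
  base <- make_cube(cfg, seed = 10, planted = FALSE)
  eff <- make_cube(cfg, seed = 10, planted = TRUE)
  jp <- match("pectin_GalARha", base$library$info$name)
  sel <- base$truth$regions == 3
  expect_equal(eff$truth$coefficients[sel, jp],
               1.5 * base$truth$coefficients[sel, jp], tolerance = 1e-12)
  expect_equal(eff$truth$coefficients[!sel, ],
               base$truth$coefficients[!sel, ], tolerance = 1e-12)
})

test_that("EMSC fitting recovers the cube's planted truth without noise", {
  cfg <- synth_config(seed = 6, dims = c(32, 32), layout = "blocks",
                      noise_sd = 0)
  sc <- make_cube(cfg)
  model <- emsc_model(sc$reference, sc$library)
  maps <- emsc_fit_cube(model, sc$cube)
  d <- dim(maps$coefficients)
  flat <- matrix(maps$coefficients, d[1] * d[2], d[3])
  est <- flat[sc$truth$pixel_idx, ]
  expect_equal(est, unname(sc$truth$coefficients), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("mixture sets honour their target signal-to-noise ratio", {
  lib <- make_library(synth_config(seed = 1))
  mix <- make_mixture_set(lib, 40, snr_db = 40, seed = 3)
  clean <- mix$coefficients %*% lib$spectra
  noise <- mix$table$absorbance - clean
  snr <- 20 * log10(sqrt(mean(clean^2)) / sqrt(mean(noise^2)))
  expect_equal(snr, 40, tolerance = 1)
  mix0 <- make_mixture_set(lib, 5, Inf, seed = 3)
  expect_equal(mix0$table$absorbance,
               mix0$coefficients %*% lib$spectra, tolerance = 1e-15,
               ignore_attr = TRUE)
})
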