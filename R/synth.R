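#' Configuration of the synthetic FTIR data generator
#'
#' Bundles every knob of the generator: the shared wavenumber axis (default
#' 1800 -> 800 cm^-1 at 6 cm^-1, the imaging spectral resolution), the
#' Gaussian-band component library, the distortion model (additive channel
#' noise, lognormal multiplicative scatter, random Legendre baseline), the
#' spatial stem-section layout (concentric rings plus primordium domes)
#' with per-region component mixing profiles and pixel-level biological
#' variability, planted imaging effects, and the bulk genotype panel
#' (5 easy- / 10 difficult-to-root genotypes with a planted discriminative
#' compound linked to three rooting traits through a noisy logistic).
#'
#' The seed fully determines every emitted artifact.
#'
#' @param seed integer master seed.
#' @param lo,hi,step axis range and spacing in cm^-1.
#' @param n_components library size (default 10; the default component
#'   names/categories cover hemicellulose monomer signatures Ara/Gal/Man/
#'   Xyl, cellulose, two lignin variants, pectin and two protein types).
#' @param bands_per_component Gaussian bands per component spectrum.
#' @param noise_sd additive channel noise sd (absorbance units).
#' @param scatter_sd lognormal sigma of the multiplicative scale a.
#' @param baseline_coeff_sd sds of the Legendre baseline coefficients
#'   d_0..d_p (length = poly order + 1).
#' @param pixel_sd lognormal sigma of pixel-level (within tissue region)
#'   component-weight variability.
#' @param layout "rings_with_primordia", "blocks" or "uniform".
#' @param dims cube spatial size (rows, cols).
#' @param n_domes number of primordium domes.
#' @param pixel_size_um pixel edge length (um).
#' @param region_profiles optional 7 x n_components matrix of region
#'   mixing weights (rows = regions); a built-in contrast pattern is used
#'   for the default 10-component library, random weights otherwise.
#' @param planted_effects list of `list(region=, component=, multiplier=)`
#'   applied by [make_cube()] when `planted = TRUE`. Default: pectin
#'   x 1.5 in the root-cap region.
#' @param panel list of genotype-panel settings: `n_easy`, `n_difficult`,
#'   `n_replicates`, `planted_compound`, `effect_multiplier` (applied to
#'   the easy group), `genotype_sd` (lognormal, genotype-level compound
#'   variability), `trait_noise_sd` (percentage points),
#'   `trait_shifts` (per-trait logistic offsets), `logistic_spread`.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, lo = 800, hi = 1800, step = 6,
                         n_components = 10, bands_per_component = 3,
                         noise_sd = 0.008, scatter_sd = 0.1,
                         baseline_coeff_sd = c(0.02, 0.01, 0.005),
                         pixel_sd = 0.12,
                         layout = c("rings_with_primordia", "blocks",
                                    "uniform"),
                         dims = c(96, 96), n_domes = 3,
                         pixel_size_um = 11, region_profiles = NULL,
                         planted_effects = NULL, panel = list()) {
  layout <- match.arg(layout)
  stopifnot(lo < hi, step > 0, n_components >= 1,
            bands_per_component >= 1, noise_sd >= 0, scatter_sd >= 0,
            all(baseline_coeff_sd >= 0), pixel_sd >= 0,
            length(dims) == 2, all(dims >= 8), n_domes >= 1)
  axis <- seq(hi, lo, by = -step)
  panel_defaults <- list(
    n_easy = 5, n_difficult = 10, n_replicates = 6,
    planted_compound = "Man_hemicellulose", effect_multiplier = 1.4,
    genotype_sd = 0.10, trait_noise_sd = 16,
    trait_shifts = c(-0.8, 0.3, -0.3), logistic_spread = 0.15)
  panel <- modifyList(panel_defaults, panel)
  if (is.null(planted_effects)) {
    planted_effects <- list(list(region = 3L,
                                 component = "pectin_GalARha",
                                 multiplier = 1.5))
  }
  cfg <- list(seed = as.integer(seed), lo = lo, hi = hi, step = step,
              axis = axis, n_components = as.integer(n_components),
              bands_per_component = as.integer(bands_per_component),
              noise_sd = noise_sd, scatter_sd = scatter_sd,
              baseline_coeff_sd = baseline_coeff_sd,
              pixel_sd = pixel_sd, layout = layout, dims = as.integer(dims),
              n_domes = as.integer(n_domes),
              pixel_size_um = pixel_size_um,
              region_profiles = region_profiles,
              planted_effects = planted_effects, panel = panel)
  class(cfg) <- "synth_config"
  cfg
}

default_component_names <- c(
  "Ara_hemicellulose", "Gal_hemicellulose", "Man_hemicellulose",
  "Xyl_hemicellulose", "cellulose", "lignin_G", "lignin_OHG",
  "pectin_GalARha", "protein_1", "protein_2")

default_component_categories <- c(
  rep("hemicellulose_monomer", 4), "cellulose", "lignin", "lignin",
  "pectin", "protein", "protein")

region_names <- c("epidermis", "cortex_shoot", "root_cap", "meristem",
                  "vasculature_root", "cortex_root", "pith_vascular_ring")

# region x component mixing weights for the default 10-component library;
# contrasts loosely follow tissue chemistry (epidermis arabinan-rich,
# woody core lignin/cellulose-rich, meristem protein-rich, ...).
default_region_profiles <- function() {
  m <- rbind(
    c(1.40, .25, .30, .35, .70, .30, .25, .70, .35, .30),  # epidermis
    c(.35, 1.20, 1.00, 1.00, .45, .30, .40, .75, .35, .35),# cortex shoot
    c(.40, .30, .95, .95, .45, .60, .30, .50, .40, .35),   # root cap
    c(.50, .40, .55, .50, .40, .25, .25, .40, 1.40, 1.00), # meristem
    c(.30, .35, .50, .90, 1.30, .55, .30, .35, .65, .45),  # root vasc.
    c(.50, .85, .35, .40, .50, .35, .35, 1.25, .40, .40),  # root cortex
    c(.30, .40, .45, .55, 1.10, 1.30, .95, .35, .35, .30)) # pith + ring
  dimnames(m) <- list(region_names, default_component_names)
  m
}

gauss_bands <- function(axis, centers, widths, heights) {
  s <- numeric(length(axis))
  for (b in seq_along(centers)) {
    s <- s + heights[b] * exp(-(axis - centers[b])^2 / (2 * widths[b]^2))
  }
  s
}

#' Generate the synthetic component library
#'
#' Each component is a sum of seeded Gaussian bands in the fingerprint
#' region; components violating the pairwise cosine-similarity bound
#' (< 0.95) are regenerated (at most 100 attempts each).
#'
#' @param config a [synth_config()].
#' @return a [component_library].
#' @export
make_library <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  J <- config$n_components
  nm <- if (J <= 10) default_component_names[seq_len(J)] else
    c(default_component_names,
      sprintf("component_%02d", 11:J))
  ct <- if (J <= 10) default_component_categories[seq_len(J)] else
    c(default_component_categories, rep("other", J - 10))
  ax <- config$axis
  lo_c <- min(ax) + 0.03 * diff(range(ax))
  hi_c <- max(ax) - 0.03 * diff(range(ax))
  withr::with_seed(config$seed + 1L, {
    spectra <- matrix(0, J, length(ax))
    for (j in seq_len(J)) {
      for (attempt in seq_len(100)) {
        nb <- config$bands_per_component
        sp <- gauss_bands(ax, runif(nb, lo_c, hi_c), runif(nb, 10, 35),
                          runif(nb, 0.4, 1))
        sp <- sp / sqrt(sum(sp^2))
        if (j == 1) break
        cs <- spectra[seq_len(j - 1), , drop = FALSE] %*% sp
        if (max(cs) < 0.95) break
        if (attempt == 100) {
          stop("could not satisfy the cosine-similarity bound in 100 ",
               "attempts for component ", j, call. = FALSE)
        }
      }
      spectra[j, ] <- sp
    }
    component_library(spectra, ax, names = nm, categories = ct)
  })
}

#' Synthetic EMSC reference spectrum
#'
#' A broad-band "mean tissue" spectrum (wide Gaussian humps plus offset)
#' with spectral structure outside the component-library span, so the
#' EMSC design stays full rank on purely synthetic mixtures.
#'
#' @param config a [synth_config()].
#' @return unit-norm numeric spectrum on the config axis.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ax <- config$axis
  withr::with_seed(config$seed + 2L, {
    s <- 0.25 + gauss_bands(ax, runif(4, min(ax), max(ax)),
                            runif(4, 80, 160), runif(4, 0.3, 0.8))
    s / sqrt(sum(s^2))
  })
}

# shared distortion forward model: rows of W are component weights
# (already including scatter? no - scatter applied here)
distort_mixtures <- function(W, K, P, config, n) {
  a <- if (config$scatter_sd > 0) rlnorm(n, 0, config$scatter_sd) else
    rep(1, n)
  nb <- length(config$baseline_coeff_sd)
  B <- matrix(rnorm(n * nb, 0, rep(config$baseline_coeff_sd, each = n)),
              n, nb)
  E <- if (config$noise_sd > 0)
    matrix(rnorm(n * ncol(K), 0, config$noise_sd), n) else
    matrix(0, n, ncol(K))
  S <- (a * W) %*% K + B %*% t(P) + E
  list(S = S, a = a, baseline = B, coefficients = a * W)
}

#' Generate the bulk genotype panel
#'
#' Emits a [spectrum_table] of replicate ATR spectra for 5 easy- and 10
#' difficult-to-root genotypes (defaults), with the panel's planted
#' compound multiplied in the easy group, genotype-level lognormal
#' compound variability, per-spectrum scatter/baseline/noise distortions,
#' and three rooting traits generated as a noisy logistic function of the
#' planted compound's genotype weight (clipped to \[0, 100\]). Ground
#' truth (genotype weights, per-spectrum coefficients and distortions,
#' traits, planted-effect table) is exported alongside.
#'
#' @param config a [synth_config()].
#' @param seed optional override of the panel seed (default
#'   `config$seed + 3`); the library and reference always derive from
#'   `config$seed`.
#' @return list of class `synth_panel`: `table`, `truth`, `library`,
#'   `reference`, `config`.
#' @export
make_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  lib <- make_library(config)
  ref <- make_reference(config)
  pc <- config$panel
  if (!pc$planted_compound %in% lib$info$name) {
    stop("panel planted_compound '", pc$planted_compound,
         "' is not in the library", call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed + 3L
  J <- nrow(lib$spectra)
  P <- legendre_basis(config$axis,
                      length(config$baseline_coeff_sd) - 1L)
  withr::with_seed(as.integer(seed), {
    base_w <- runif(J, 0.4, 1)
    names(base_w) <- lib$info$name
    # the screening target is a mid-abundance constituent: a fixed modest
    # share keeps its ground-truth trait correlation stable across seeds
    base_w[pc$planted_compound] <- 0.55
    n_g <- pc$n_easy + pc$n_difficult
    genotype <- sprintf("G%02d", seq_len(n_g))
    group <- rep(c("easy", "difficult"), c(pc$n_easy, pc$n_difficult))
    gw <- matrix(base_w, n_g, J, byrow = TRUE,
                 dimnames = list(genotype, lib$info$name))
    if (pc$genotype_sd > 0) {
      gw <- gw * exp(matrix(rnorm(n_g * J, 0, pc$genotype_sd), n_g, J))
    }
    jp <- match(pc$planted_compound, lib$info$name)
    gw[group == "easy", jp] <- gw[group == "easy", jp] *
      pc$effect_multiplier
    # traits: noisy logistic in the planted compound's genotype weight
    mult_bar <- (pc$n_easy * pc$effect_multiplier + pc$n_difficult) / n_g
    z <- (gw[, jp] - mult_bar * base_w[jp]) /
      (pc$logistic_spread * base_w[jp])
    traits <- sapply(pc$trait_shifts, function(sh) {
      pmin(100, pmax(0, 100 * plogis(z + sh) +
                       rnorm(n_g, 0, pc$trait_noise_sd)))
    })
    colnames(traits) <- trait_cols
    W <- gw[rep(seq_len(n_g), each = pc$n_replicates), , drop = FALSE]
    n <- nrow(W)
    dm <- distort_mixtures(W, lib$spectra, P, config, n)
    meta <- tibble(
      sample_id = paste0(rep(genotype, each = pc$n_replicates), "_r",
                         rep(seq_len(pc$n_replicates), n_g)),
      genotype = rep(genotype, each = pc$n_replicates),
      group = rep(group, each = pc$n_replicates))
    for (tc in trait_cols) {
      meta[[tc]] <- rep(traits[, tc], each = pc$n_replicates)
    }
    table <- spectrum_table(dm$S, config$axis, meta)
    truth <- list(
      genotype_weights = as_tibble(gw) |>
        mutate(genotype = genotype, group = group, .before = 1),
      sample_coefficients = dm$coefficients,
      distortions = tibble(sample_id = meta$sample_id, a = dm$a) |>
        dplyr::bind_cols(as_tibble(dm$baseline, .name_repair = ~
          paste0("d", seq_along(.x) - 1))),
      traits = as_tibble(traits) |>
        mutate(genotype = genotype, group = group, .before = 1),
      planted = tibble(compound = pc$planted_compound, group = "easy",
                      multiplier = pc$effect_multiplier),
      base_weights = base_w)
    structure(list(table = table, truth = truth, library = lib,
                   reference = ref, config = config),
              class = "synth_panel")
  })
}

# paint the ring-and-dome region label image; 0 = outside the section
paint_regions <- function(config) {
  nr <- config$dims[1]
  nc <- config$dims[2]
  cx <- (nc + 1) / 2
  cy <- (nr + 1) / 2
  R <- 0.46 * min(nr, nc)
  R1 <- R - max(2, 0.03 * min(nr, nc))  # epidermis inner radius
  R2 <- 0.55 * R                        # cortex inner radius
  col_i <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row_i <- matrix(rep(seq_len(nr), nc), nr, nc)
  dx <- col_i - cx
  dy <- row_i - cy
  r <- sqrt(dx^2 + dy^2)
  lab <- matrix(0L, nr, nc)
  lab[r <= R] <- 1L                      # epidermis rim
  lab[r <= R1] <- 2L                     # shoot cortex
  lab[r <= R2] <- 7L                     # pith + vascular ring
  if (config$layout == "rings_with_primordia") {
    th0 <- runif(1, 0, 2 * pi)
    thetas <- th0 + (seq_len(config$n_domes) - 1) * 2 * pi /
      config$n_domes + runif(config$n_domes, -0.25, 0.25)
    thick <- R1 - R2
    semi_r <- 0.48 * thick
    semi_t <- 0.42 * thick
    rc <- (R1 + R2) / 2
    for (th in thetas) {
      ux <- cos(th)
      uy <- sin(th)
      ox <- cx + rc * ux
      oy <- cy + rc * uy
      pr <- (col_i - ox) * ux + (row_i - oy) * uy   # radial (outward +)
      pt <- -(col_i - ox) * uy + (row_i - oy) * ux  # tangential
      re <- sqrt((pr / semi_r)^2 + (pt / semi_t)^2)
      inside <- re <= 1 & lab != 0L
      t01 <- (pr + semi_r) / (2 * semi_r)           # 0 base -> 1 apex
      lab[inside] <- 6L                                       # root cortex
      lab[inside & re <= 0.5 & t01 <= 0.55] <- 5L             # root vasc.
      lab[inside & re <= 0.75 & t01 > 0.55] <- 4L             # meristem
      lab[inside & re > 0.75 & t01 > 0.45] <- 3L              # root cap
    }
  } else if (config$layout == "blocks") {
    lab[lab > 0] <- 1L + (col_i[lab > 0] * 7L) %/% (nc + 1L)
    lab[lab > 7L] <- 7L
    lab[lab < 1L] <- 1L
  } else { # uniform
    lab[lab > 0] <- 1L
  }
  lab
}

#' Generate a synthetic stem-section hyperspectral cube
#'
#' Paints the spatial layout (default: concentric epidermis / shoot-cortex
#' / pith rings with primordium domes subdivided into root cap, meristem,
#' root vasculature and root cortex — seven tissue regions), assigns each
#' region its component mixing profile with lognormal pixel-level
#' variability, and distorts every pixel spectrum with scatter, baseline
#' and noise as in [make_panel()]. Pixels outside the section are masked.
#' Ground-truth region labels, per-pixel coefficients and distortions are
#' exported.
#'
#' @param config a [synth_config()].
#' @param seed optional override of the cube seed (default
#'   `config$seed + 4`); use different seeds for independent sections.
#' @param planted apply `config$planted_effects` (region-specific
#'   component multipliers) — the "affected genotype" cube.
#' @return list of class `synth_cube`: `cube` ([hypercube]), `truth`
#'   (region_labels image, region names, per-pixel `coefficients` matrix
#'   with `pixel_idx`, distortions, profiles, planted-effect table),
#'   `library`, `reference`, `config`.
#' @export
make_cube <- function(config, seed = NULL, planted = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  lib <- make_library(config)
  ref <- make_reference(config)
  J <- nrow(lib$spectra)
  profiles <- config$region_profiles
  if (is.null(seed)) seed <- config$seed + 4L
  withr::with_seed(as.integer(seed), {
    if (is.null(profiles)) {
      if (J == 10) {
        profiles <- default_region_profiles()
      } else {
        profiles <- matrix(runif(7 * J, 0.3, 1.2), 7, J,
                           dimnames = list(region_names, lib$info$name))
      }
    }
    if (any(profiles < 0)) stop("mixing weights must be nonnegative",
                                call. = FALSE)
    lab <- paint_regions(config)
    if (config$layout == "rings_with_primordia" &&
        length(unique(lab[lab > 0])) < 7) {
      stop("dome placement failed: fewer than 7 regions on a ",
           config$dims[1], "x", config$dims[2], " image", call. = FALSE)
    }
    idx <- which(as.vector(lab) > 0)
    regions <- as.vector(lab)[idx]
    n <- length(idx)
    W <- profiles[regions, , drop = FALSE]
    if (config$pixel_sd > 0) {
      W <- W * exp(matrix(rnorm(n * J, 0, config$pixel_sd), n, J))
    }
    planted_tab <- tibble(region = integer(), component = character(),
                          multiplier = numeric())
    if (planted) {
      for (pe in config$planted_effects) {
        jj <- match(pe$component, lib$info$name)
        if (is.na(jj)) stop("planted component '", pe$component,
                            "' not in library", call. = FALSE)
        sel <- regions == pe$region
        W[sel, jj] <- W[sel, jj] * pe$multiplier
        planted_tab <- bind_rows(planted_tab, tibble(
          region = as.integer(pe$region), component = pe$component,
          multiplier = pe$multiplier))
      }
    }
    P <- legendre_basis(config$axis,
                        length(config$baseline_coeff_sd) - 1L)
    dm <- distort_mixtures(W, lib$spectra, P, config, n)
    d <- c(config$dims, length(config$axis))
    flat <- matrix(0, d[1] * d[2], d[3])
    flat[idx, ] <- dm$S
    cube <- hypercube(array(flat, d), config$axis,
                      mask = matrix(as.vector(lab) > 0, d[1], d[2]),
                      pixel_size_um = config$pixel_size_um)
    truth <- list(
      region_labels = lab, region_names = region_names,
      pixel_idx = idx, regions = regions,
      coefficients = dm$coefficients,
      distortions = list(a = dm$a, baseline = dm$baseline),
      profiles = profiles, planted = planted_tab)
    structure(list(cube = cube, truth = truth, library = lib,
                   reference = ref, config = config),
              class = "synth_cube")
  })
}

#' Random mixture spectra with known coefficients
#'
#' Mixtures `s = sum_j c_j K_j + noise` with coefficients drawn uniform
#' (0, 1) and additive Gaussian noise scaled to a target signal-to-noise
#' ratio — the small-scale oracle input for decomposition tests.
#'
#' @param library a [component_library].
#' @param n number of spectra.
#' @param snr_db signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param seed integer seed.
#' @return list with `table` ([spectrum_table]) and the true
#'   `coefficients` matrix (n x J).
#' @export
make_mixture_set <- function(library, n, snr_db = Inf, seed = 1) {
  stopifnot(inherits(library, "component_library"), n >= 1)
  J <- nrow(library$spectra)
  withr::with_seed(as.integer(seed), {
    C <- matrix(runif(n * J), n, J,
                dimnames = list(NULL, library$info$name))
    S <- C %*% library$spectra
    if (is.finite(snr_db)) {
      sig_rms <- sqrt(mean(S^2))
      S <- S + matrix(rnorm(length(S), 0, sig_rms / 10^(snr_db / 20)),
                      n)
    }
    list(table = spectrum_table(S, library$axis), coefficients = C)
  })
}
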