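test_that("relative percent difference is symmetric and scale invariant", {
  expect_equal(relative_percent_difference(103, 97), 6)
  expect_equal(relative_percent_difference(5, 5), 0)
  expect_equal(relative_percent_difference(3, 1), 100)
  expect_equal(relative_percent_difference(1, 3),
               relative_percent_difference(3, 1))
  expect_equal(relative_percent_difference(3e-4, 1e-4),
               relative_percent_difference(3, 1))
  expect_error(relative_percent_difference(0, 0), "nonpositive")
  # reference variant
  expect_equal(relative_percent_difference(150, 100, mode = "reference"),
               50)
})

# a hand-built screening input: 8 genotypes (4 easy / 4 difficult),
# one sample each, two compounds
toy_screen_input <- function(trait_link = TRUE, seed = 51) {
  withr::with_seed(seed, {
    genotype <- sprintf("G%d", 1:8)
    group <- rep(c("easy", "difficult"), each = 4)
    a <- c(0.30, 0.28, 0.33, 0.31, 0.20, 0.22, 0.19, 0.21)
    b <- rep(0.5, 8) + rnorm(8, 0, 0.01)
    rel_abs <- tibble::tibble(
      sample_id = rep(genotype, 2),
      component = rep(c("cmpA", "cmpB"), each = 8),
      relative_absorbance = c(a, b))
    tr <- if (trait_link) 100 * a + rnorm(8, 0, 1) else
      runif(8, 40, 60)
    meta <- tibble::tibble(sample_id = genotype, genotype = genotype,
                           group = group,
                           trait_ar10_ibap = pmin(100, tr),
                           trait_ar21_ibap = pmin(100, tr + rnorm(8)),
                           trait_ar21_ibam = pmin(100, tr + rnorm(8)))
    list(rel_abs = rel_abs, meta = meta)
  })
}

test_that("the screening rule requires both the RPD and correlation gates", {
  ti <- toy_screen_input()
  sw <- suppressWarnings(screen_compounds(ti$rel_abs, ti$meta))
  recA <- sw[sw$compound == "cmpA", ]
  expect_true(recA$eligible)
  expect_gt(recA$rpd, 3)
  expect_gte(recA$n_significant_traits, 2)
  expect_false(is.na(recA$p_mw))
  expect_equal(recA$group_difference, "higher_in_easy")
  recB <- sw[sw$compound == "cmpB", ]
  expect_false(recB$eligible)
  expect_true(is.na(recB$p_mw))        # no MW unless eligible
  # records sorted by descending RPD
  expect_true(all(diff(sw$rpd) <= 0))

  # large RPD but shuffled traits: the AND-rule rejects
  ti2 <- toy_screen_input(trait_link = FALSE)
  s2 <- suppressWarnings(screen_compounds(ti2$rel_abs, ti2$meta))
  expect_gt(s2$rpd[s2$compound == "cmpA"], 3)
  expect_false(any(s2$eligible))
})

test_that("identical genotypes produce zero RPD and no eligibility", {
  rel_abs <- tibble::tibble(
    sample_id = rep(sprintf("G%d", 1:6), 2),
    component = rep(c("cmpA", "cmpB"), each = 6),
    relative_absorbance = rep(c(0.4, 0.6), each = 6))
  meta <- tibble::tibble(sample_id = sprintf("G%d", 1:6),
                         genotype = sprintf("G%d", 1:6),
                         group = rep(c("easy", "difficult"), each = 3),
                         trait_ar10_ibap = 50, trait_ar21_ibap = 60,
                         trait_ar21_ibam = 40)
  sw <- suppressWarnings(screen_compounds(rel_abs, meta))
  expect_equal(sw$rpd, c(0, 0))
  expect_false(any(sw$eligible))
})

test_that("screening validates its inputs", {
  ti <- toy_screen_input()
  meta_bad <- ti$meta
  meta_bad$trait_ar21_ibam[2] <- NA
  expect_error(suppressWarnings(
    screen_compounds(ti$rel_abs, meta_bad)), "missing rooting traits")
  meta_small <- ti$meta
  meta_small$group <- c("easy", rep("difficult", 7))
  expect_error(suppressWarnings(
    screen_compounds(ti$rel_abs, meta_small)), "at least 2 genotypes")
})

test_that("correlation matrix is consistent with the pearson operation", {
  ti <- toy_screen_input()
  cm <- correlation_matrix(ti$rel_abs, ti$meta)
  expect_equal(nrow(cm), 2 * 3)        # 2 compounds x 3 traits
  # element-wise recomputation
  gm <- ti$rel_abs |>
    dplyr::left_join(ti$meta, by = "sample_id")
  for (i in seq_len(nrow(cm))) {
    df <- gm[gm$component == cm$compound[i], ]
    ref <- pearson_cor(df$relative_absorbance, df[[cm$trait[i]]])
    expect_equal(cm$r[i], ref$r)
    expect_equal(cm$p[i], ref$p)
  }
  # a trait affine in the compound gives |r| = 1
  expect_equal(abs(cm$r[cm$compound == "cmpA" &
                          cm$trait == "trait_ar10_ibap"]), 1,
               tolerance = 0.05)
})

test_that("the synthetic panel's planted compound is recovered end to end", {
  cfg <- synth_config(seed = 7)
  pan <- make_panel(cfg)
  br <- suppressWarnings(
    run_bulk(pan$table, pan$library, reference = pan$reference))
  rec <- br$screening[br$screening$compound ==
                        cfg$panel$planted_compound, ]
  expect_true(rec$eligible)
  expect_lt(rec$p_mw, 0.05)
  expect_equal(rec$group_difference, "higher_in_easy")
  # structural rule: MW present iff eligible
  expect_true(all(is.na(br$screening$p_mw[!br$screening$eligible])))
  expect_true(all(!is.na(br$screening$p_mw[br$screening$eligible])))
})

test_that("eligibility frequency is monotone in the planted effect size", {
  freq <- sapply(c(1.0, 1.1, 1.4), function(mult) {
    hits <- 0
    for (r in 1:25) {
      cfg <- synth_config(seed = 300 + r,
                          panel = list(effect_multiplier = mult,
                                       n_replicates = 3))
      pan <- make_panel(cfg)
      br <- suppressWarnings(
        run_bulk(pan$table, pan$library, reference = pan$reference))
      rec <- br$screening[br$screening$compound ==
                            cfg$panel$planted_compound, ]
      if (rec$eligible) hits <- hits + 1
    }
    hits
  })
  expect_true(all(diff(freq) >= 0))
})
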