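test_that("Mann-Whitney U and exact p match hand-computable cases", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)          # 2 of 20 assignments as extreme
  expect_equal(mw$method, "exact")

  x <- c(1, 2, 3)
  mw2 <- mann_whitney(x, x)        # identical samples
  expect_equal(mw2$U, 9 / 2)       # n^2 / 2
  expect_equal(mw2$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "empty")
  expect_error(mann_whitney(c(1, 1, 2), c(1, 3), mode = "exact"),
               "ties")
})

test_that("exact enumeration and normal approximation agree for n = 8 + 8", {
  withr::with_seed(41, {
    for (r in 1:5) {
      x <- rnorm(8)
      y <- rnorm(8, 0.5)
      pe <- mann_whitney(x, y, mode = "exact")$p
      pn <- mann_whitney(x, y, mode = "normal")$p
      expect_lt(abs(pe - pn), 0.02)
    }
  })
})

test_that("exact mode equals brute-force enumeration for all n_x + n_y <= 10", {
  withr::with_seed(42, {
    for (n_tot in 4:10) {
      for (nx in 1:(n_tot - 1)) {
        z <- sample(seq_len(100), n_tot)   # tie-free
        x <- z[seq_len(nx)]
        y <- z[(nx + 1):n_tot]
        ours <- mann_whitney(x, y, mode = "exact")
        oracle <- mw_enumerate(x, y)
        expect_equal(ours$U, oracle$U)
        expect_equal(ours$p, oracle$p, tolerance = 1e-12)
      }
    }
  })
})

test_that("divergence effect size follows the pooled-SD formula", {
  expect_equal(effect_size_d(c(2, 4, 6), c(3, 5, 7)), 0.5)
  expect_equal(effect_size_d(1:5, 1:5), 0)
  # grows linearly in the planted shift
  x <- c(1, 2, 3, 4)
  s <- sd(x)
  d1 <- effect_size_d(x, x + 1 * s)
  d2 <- effect_size_d(x, x + 2 * s)
  expect_equal(d2 / d1, 2, tolerance = 1e-12)

  expect_warning(di <- effect_size_d(c(1, 1), c(2, 2)), "Inf")
  expect_identical(di, Inf)
  expect_equal(effect_size_d(c(1, 1), c(1, 1)), 0)
  expect_error(effect_size_d(1, 1:3), "n >= 2")
  # robust variant uses medians/QAD
  expect_equal(effect_size_d(c(0, 1, 2, 100), c(1, 2, 3, 101),
                             robust = TRUE), 1)
})

test_that("R^2 of D follows the closed form and its threshold identities", {
  expect_identical(r2_from_d(2), 0.5)
  expect_identical(r2_from_d(0), 0)
  expect_equal(r2_from_d(0.8), 0.64 / 4.64)
  d <- seq(0, 6, by = 0.25)
  expect_true(all(diff(r2_from_d(d)) > 0))
  expect_true(all(r2_from_d(d) >= 0 & r2_from_d(d) < 1))
  # D > 2  <=>  R^2 > 0.5, exactly at the boundary
  expect_true(r2_from_d(2 + 1e-12) > 0.5 && r2_from_d(2 - 1e-12) < 0.5)
  expect_error(r2_from_d(-1), ">= 0")
})

test_that("QAD, relative difference and area-weighted mean evaluate exactly", {
  expect_equal(qad(c(1, 2, 3)), 1)
  expect_equal(qad(rep(7, 5)), 0)
  expect_equal(qad(c(1, 1, 1, 9)), 0)

  expect_equal(relative_difference_pct(177, 100), 77)
  expect_equal(relative_difference_pct(5, 5), 0)
  expect_equal(relative_difference_pct(50, 100), -50)
  expect_error(relative_difference_pct(1, 0), "zero reference")

  expect_equal(area_weighted_mean(c(10, 20), c(1, 3)), 17.5)
  expect_equal(area_weighted_mean(c(4, 8), c(2, 2)), 6)
  expect_equal(area_weighted_mean(5, 3), 5)
  expect_error(area_weighted_mean(1:3, 1:2), "equal length")
  expect_error(area_weighted_mean(1:2, c(1, 0)), "positive")
})

test_that("Pearson helper matches perfect and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

fake_maps <- function(values) {
  # values: rows x cols x J array
  structure(list(rel_abs = values,
                 degenerate = matrix(FALSE, dim(values)[1],
                                     dim(values)[2]),
                 mask = matrix(TRUE, dim(values)[1], dim(values)[2]),
                 components = dimnames(values)[[3]],
                 n_pixels = prod(dim(values)[1:2]), n_degenerate = 0L,
                 pixel_size_um = 11),
            class = "component_maps")
}

fake_clusters <- function(labels, k) {
  structure(list(labels = labels, k = as.integer(k),
                 cluster_areas = tabulate(labels, k),
                 pixel_idx = which(labels > 0), pixel_size_um = 11),
            class = "tissue_clusters")
}

test_that("cluster comparison verdicts follow the dual-threshold rule", {
  withr::with_seed(43, {
    J <- 2
    vals <- array(rlnorm(20 * 20 * J, 0, 0.1), c(20, 20, J),
                  dimnames = list(NULL, NULL, c("man", "pectin")))
  })
  labels <- matrix(rep(1:2, each = 200), 20, 20)
  cl <- fake_clusters(labels, 2)
  m_a <- fake_maps(vals)

  # identical maps: nothing significant, all relative differences zero
  cmp0 <- compare_clusters(m_a, m_a, cl)
  expect_true(all(cmp0$verdict == "not_significant"))
  expect_true(all(cmp0$rel_diff_pct == 0))
  expect_true(all(cmp0$U == cmp0$n_a * cmp0$n_b / 2))

  # planted +50% shift of "man" in cluster 2 only
  vals_b <- vals
  vals_b[, 11:20, 1] <- vals_b[, 11:20, 1] * 1.5
  cmp1 <- compare_clusters(m_a, fake_maps(vals_b), cl)
  flagged <- cmp1[cmp1$verdict == "significant",
                  c("cluster", "component")]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$cluster, 2)
  expect_equal(flagged$component, "man")

  # swapping the groups preserves p and D and flips the sign of rel diff
  cmp2 <- compare_clusters(fake_maps(vals_b), m_a, cl)
  expect_equal(cmp2$p, cmp1$p, tolerance = 1e-12)
  expect_equal(cmp2$D, cmp1$D, tolerance = 1e-12)
  expect_equal(sign(cmp2$rel_diff_pct), -sign(cmp1$rel_diff_pct))
  expect_equal(cmp2$U, cmp1$n_a * cmp1$n_b - cmp1$U)

  # rank statistics invariant under strictly monotone rescaling
  cmp3 <- compare_clusters(fake_maps(exp(vals)), fake_maps(exp(vals_b)),
                           cl)
  expect_equal(cmp3$p, cmp1$p, tolerance = 1e-12)
  expect_equal(cmp3$U, cmp1$U)
})

test_that("clusters missing in one group yield NA verdicts with a warning", {
  withr::with_seed(44, {
    vals <- array(rlnorm(8 * 8 * 1, 0, 0.1), c(8, 8, 1),
                  dimnames = list(NULL, NULL, "man"))
  })
  la <- matrix(1L, 8, 8)
  lb <- matrix(1L, 8, 8); lb[1:4, ] <- 2L
  expect_warning(
    cmp <- compare_clusters(fake_maps(vals), fake_maps(vals),
                            fake_clusters(la, 2), fake_clusters(lb, 2)),
    "absent")
  expect_true(is.na(cmp$verdict[cmp$cluster == 2]))
})

test_that("a planted shift of D = 1.2 at n = 200 is almost always flagged", {
  hits <- 0
  withr::with_seed(45, {
    for (r in 1:100) {
      x <- rnorm(200)
      y <- rnorm(200, 1.2)
      p <- mann_whitney(x, y, mode = "normal")$p
      D <- effect_size_d(x, y)
      if (p < 0.001 && (D > 0.8 || r2_from_d(D) > 0.5)) hits <- hits + 1
    }
  })
  expect_gte(hits, 95)
})
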