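# Shared fixtures, built in code at test time.

# small deterministic library on a short axis
tiny_library <- function(J = 3, n_ch = 40, seed = 42) {
  ax <- seq(1800, 800, length.out = n_ch)
  withr::with_seed(seed, {
    sp <- matrix(0, J, n_ch)
    for (j in seq_len(J)) {
      ctr <- runif(3, 850, 1750)
      wid <- runif(3, 20, 60)
      hgt <- runif(3, 0.4, 1)
      for (b in 1:3) {
        sp[j, ] <- sp[j, ] + hgt[b] * exp(-(ax - ctr[b])^2 / (2 * wid[b]^2))
      }
    }
    component_library(sp, ax, names = paste0("K", seq_len(J)))
  })
}

# independent reference spectrum outside the tiny library span
tiny_reference <- function(lib, seed = 43) {
  ax <- lib$axis
  withr::with_seed(seed, {
    s <- 0.3 + 0.7 * exp(-(ax - runif(1, 1000, 1600))^2 / (2 * 200^2))
    s / sqrt(sum(s^2))
  })
}

random_table <- function(n = 4, n_ch = 30, seed = 1) {
  withr::with_seed(seed, {
    spectrum_table(matrix(runif(n * n_ch, 0.2, 1), n),
                   axis = seq(1790, 810, length.out = n_ch))
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force Mann-Whitney oracle: full enumeration of label assignments
mw_enumerate <- function(x, y) {
  z <- c(x, y)
  n <- length(z)
  nx <- length(x)
  u_of <- function(xi) {
    xs <- z[xi]
    ys <- z[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(utils::combn(n, nx), 2, u_of)
  u_obs <- u_of(seq_len(nx))
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# majority-vote mapping of cluster labels to ground-truth regions
cluster_region_map <- function(clusters, truth) {
  m <- table(clusters$labels[truth$pixel_idx], truth$regions)
  map <- integer(nrow(m))
  names(map) <- rownames(m)
  for (i in seq_len(nrow(m))) map[i] <- as.integer(which.max(m[i, ]))
  map[setdiff(as.character(1:clusters$k), rownames(m))] <- NA
  map[as.character(1:clusters$k)]
}
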