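# Independent oracles and fixture builders shared across tests. Everything
# here is deliberately written from first principles (closed forms, brute
# force, enumeration) and kept independent of the package's code paths.

# --- visual model -------------------------------------------------------

# independent re-implementation of the A1 pigment template (alpha band)
oracle_template <- function(lambda, lmax) {
  x <- lmax / lambda
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

# normalization used by the package: peak over the 300-700 nm 1-nm grid
oracle_template_norm <- function(lambda, lmax) {
  oracle_template(lambda, lmax) / max(oracle_template(seq(300, 700, 1), lmax))
}

# random smooth positive spectrum: mixture of Gaussian bumps, sampled on a
# 1-nm grid over 310-670 (the instrument-like representation)
random_smooth_spectrum <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  centers <- runif(k, 330, 650)
  widths <- runif(k, 40, 120)
  heights <- runif(k, 0.1, 1)
  wl <- seq(310, 670, by = 1)
  v <- rowSums(sapply(seq_len(k), function(i)
    heights[i] * exp(-((wl - centers[i]) / widths[i])^2))) + 0.01
  spectrum(wl, v, units = "energy")
}

# 0.01-nm midpoint Riemann catch of a sampled quantal spectrum: linear
# interpolation of the samples, analytic template
riemann_catch <- function(s_quantal, lmax, range = c(310, 670), h = 0.01) {
  grid <- seq(range[1] + h / 2, range[2] - h / 2, by = h)
  iq <- approx(s_quantal$wavelengths_nm, s_quantal$values, xout = grid)$y
  sum(iq * oracle_template_norm(grid, lmax)) * h
}

# --- trees and dense-MVN likelihood oracles -----------------------------

# random ultrametric tree, unit depth
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, 1, 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# root-to-tip edge paths by explicit parent walking
tip_paths <- function(tree) {
  nt <- length(tree$tip.label)
  lapply(seq_len(nt), function(i) {
    p <- integer(0); node <- i
    while (node != nt + 1L) {
      e <- which(tree$edge[, 2] == node)
      p <- c(e, p); node <- tree$edge[e, 1]
    }
    p
  })
}

# shared root-to-MRCA time of two tips from their edge paths
oracle_shared_time <- function(tree) {
  nt <- length(tree$tip.label)
  paths <- tip_paths(tree)
  S <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    shared <- intersect(paths[[i]], paths[[j]])
    S[i, j] <- sum(tree$edge.length[shared])
  }
  dimnames(S) <- list(tree$tip.label, tree$tip.label)
  S
}

# per-tip painted path segments (absolute times from the root) of a map
oracle_path_segments <- function(map) {
  nt <- length(map$tip.label)
  dep <- ape::node.depth.edgelength(map)
  paths <- tip_paths(map)
  lapply(seq_len(nt), function(i) {
    do.call(rbind, lapply(paths[[i]], function(e) {
      seg <- map$maps[[e]]
      t0 <- dep[map$edge[e, 1]] + c(0, cumsum(seg))[seq_along(seg)]
      data.frame(regime = names(seg), t0 = t0, t1 = t0 + as.numeric(seg))
    }))
  })
}

# dense OUM mean vector and covariance built from first principles
oracle_oum_moments <- function(map, alpha, sigma2, theta) {
  nt <- length(map$tip.label)
  dep <- ape::node.depth.edgelength(map)
  segs <- oracle_path_segments(map)
  S <- oracle_shared_time(map)
  mu <- vapply(seq_len(nt), function(i) {
    sg <- segs[[i]]
    Ti <- dep[i]
    w <- exp(-alpha * (Ti - sg$t1)) - exp(-alpha * (Ti - sg$t0))
    sum(w * theta[sg$regime]) + exp(-alpha * Ti) * theta[[sg$regime[1]]]
  }, numeric(1))
  V <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    tij <- S[i, j]
    dij <- dep[i] + dep[j] - 2 * tij
    V[i, j] <- sigma2 / (2 * alpha) * exp(-alpha * dij) *
      (1 - exp(-2 * alpha * tij))
  }
  list(mu = mu, V = V, tips = map$tip.label)
}

# dense BMM covariance: regime-specific rate times shared time in regime
oracle_bmm_cov <- function(map, sigma2) {
  nt <- length(map$tip.label)
  segs <- oracle_path_segments(map)
  paths <- tip_paths(map)
  V <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    shared <- intersect(paths[[i]], paths[[j]])
    for (e in shared) {
      seg <- map$maps[[e]]
      V[i, j] <- V[i, j] + sum(as.numeric(seg) * sigma2[names(seg)])
    }
  }
  dimnames(V) <- list(map$tip.label, map$tip.label)
  V
}

mvn_oracle <- function(y, mu, V) {
  mvtnorm::dmvnorm(y, mu, V, log = TRUE)
}

# small painted tree fixture
painted_tree <- function(n, seed, regimes = c("A", "B"), rate = 1.5) {
  tr <- random_tree(n, seed)
  paint_regimes(tr, regimes = regimes, rate = rate, mode = "mk",
                seed = seed + 1)
}

# --- images -------------------------------------------------------------

# uniform-scatter fisheye image with an exact in-disc sky count
uniform_sky_image <- function(frac, size = 201, seed = 1) {
  set.seed(seed)
  img0 <- fisheye_image(matrix(0, size, size))
  inside <- photoniche:::.inside_circle(img0)
  n_in <- sum(inside)
  n_sky <- round(frac * n_in)
  px <- matrix(30, size, size)
  sky_idx <- sample(which(inside), n_sky)
  px[sky_idx] <- 225
  list(image = fisheye_image(px), frac = n_sky / n_in)
}

rotate90 <- function(m) t(m)[, nrow(m):1]
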