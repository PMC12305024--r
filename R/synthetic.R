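# Deterministic synthetic communities with full ground truth: trees,
# regime paintings, traits under BM/OU/EB, forest-shade vs gap irradiance
# spectra, fisheye and wing-silhouette images, individual records.

#' Default synthetic-community configuration
#'
#' The stated world the generator emulates: 45 species in 8 mimicry rings
#' aggregated into 3 mimetic clusters; 785 individuals with highly skewed
#' per-species sample sizes (1-65, truncated-geometric); a unit-depth
#' pure-birth tree; a strong multipeak OU process on the latent
#' light-preference variable (phylogenetic half-life 10% of depth, optimum
#' separation 3 stationary SD between gap- and shade-dwelling clusters).
#'
#' @param n_species,n_individuals Community size (defaults 45 and 785).
#' @param seed Master seed; per-module child seeds are fixed offsets of it.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_species = 45, n_individuals = 785, seed = 1) {
  alpha <- log(2) / 0.1              # half-life = 10% of unit depth
  stat_sd <- 0.25
  sigma2 <- 2 * alpha * stat_sd^2
  list(
    n_species = n_species,
    n_individuals = n_individuals,
    birth_rate = 1,
    rings = list(
      clearwing = c("eurimedia", "lerida", "aureliana", "agnosia"),
      `tiger-stripe` = c("hermias", "mamercus", "mothone"),
      confusa = "confusa"),
    mk_rate = 1.5,                   # regime painting rate (events per depth)
    trait_model = "OUM",
    alpha = alpha,
    sigma2 = sigma2,
    # latent light-preference optima: gap-dwelling tiger-stripe high,
    # shade-dwelling clearwing low, confusa shade-like but distinct
    theta = c(clearwing = -1, confusa = -0.6, `tiger-stripe` = 1),
    # cluster wing-morphology optima (area mm2, aspect ratio, loading g/mm2)
    wing = list(
      clearwing = c(area = 230, ar = 1.9, loading = 1.6e-4),
      confusa = c(area = 260, ar = 2.5, loading = 2.4e-4),
      `tiger-stripe` = c(area = 300, ar = 2.1, loading = 1.9e-4)),
    # individual-level measurement noise
    noise = c(light = 0.25, flight_height = 1.2, openness = 4,
              wing_rel = 0.06, species_intercept = 0.15,
              spectra_sdlog = 0.35, spectra_shape = 0.06),
    sample_size_range = c(1, 65),
    seed = seed
  )
}

# child seeds: fixed offsets from the master seed, kept below 2^31
.child_seed <- function(seed, offset) (seed + offset * 10007L) %% 2147483647L

#' Simulate a pure-birth tree
#'
#' Yule tree with `n_tips` tips rescaled to unit depth; ultrametric.
#'
#' @param n_tips >= 2.
#' @param birth_rate Speciation rate.
#' @param seed RNG seed.
#' @return `phylo` with tip labels `sp01, sp02, ...`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) stop("need >= 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$edge.length <- tree$edge.length / tree_depth(tree)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Paint selective regimes on a tree
#'
#' `mode = "mk"`: forward-simulates an equal-rates Markov history from a
#' uniform root state. `mode = "tip-clustered"`: draws tip clusters by the
#' same forward simulation but requires every cluster present and
#' polyphyletic (>= 2 independent origins), resampling up to 100 times,
#' then samples the full history conditionally on those tips (one
#' stochastic map under the ML rate).
#'
#' @param tree `phylo`.
#' @param regimes Character vector of regime labels.
#' @param rate Mk transition rate.
#' @param mode `"tip-clustered"` (default) or `"mk"`.
#' @param seed RNG seed.
#' @return `"regime_map"`.
#' @export
paint_regimes <- function(tree, regimes = c("clearwing", "confusa",
                                            "tiger-stripe"),
                          rate = 1.5, mode = c("tip-clustered", "mk"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  k <- length(regimes)
  forward_once <- function() {
    nt <- length(tree$tip.label)
    node_state <- integer(nt + tree$Nnode)
    node_state[nt + 1L] <- sample.int(k, 1L)
    maps <- vector("list", nrow(tree$edge))
    ord <- ape::reorder.phylo(tree, "postorder")
    pre <- rev(seq_len(nrow(ord$edge)))
    for (e in pre) {
      parent <- ord$edge[e, 1]
      child <- ord$edge[e, 2]
      t <- ord$edge.length[e]
      cur <- node_state[parent]
      pos <- 0
      states <- cur
      times <- numeric(0)
      if (k > 1L) {
        repeat {
          wait <- stats::rexp(1, (k - 1) * rate)
          if (pos + wait >= t) break
          pos <- pos + wait
          times <- c(times, pos)
          cur <- if (k == 2L) (1:2)[-cur] else sample((1:k)[-cur], 1L)
          states <- c(states, cur)
        }
      }
      seg <- diff(c(0, times, t))
      names(seg) <- regimes[states]
      orig <- which(tree$edge[, 1] == parent & tree$edge[, 2] == child)
      maps[[orig]] <- seg
      node_state[child] <- cur
    }
    regime_map(tree, maps,
               node_states = stats::setNames(regimes[node_state],
                                             seq_along(node_state)))
  }
  if (mode == "mk") return(forward_once())
  for (try in seq_len(100)) {
    m <- forward_once()
    tr <- tip_regimes(m)
    if (length(unique(tr)) < k) next
    # require >= 2 tips per cluster and no cluster forming a single clade
    ok <- vapply(regimes, function(r) {
      tips <- names(tr)[tr == r]
      length(tips) >= 2 && !ape::is.monophyletic(tree, tips)
    }, logical(1))
    if (all(ok)) {
      # resample the painting conditionally on the tips (stochastic map)
      cond <- sample_simmap(tree, tr, n_maps = 1)[[1]]
      return(cond)
    }
  }
  stop("could not paint regimes with all clusters present and polyphyletic")
}

#' Simulate a trait along a regime map
#'
#' Recursive branch-wise simulation: BM increments `N(0, sigma2 dt)`; OU
#' transitions `N(theta_k + (y - theta_k) exp(-alpha dt),
#' sigma2 (1 - exp(-2 alpha dt))/(2 alpha))` applied per painted segment;
#' EB as time-rescaled BM with rate `sigma2 exp(r t)`.
#'
#' @param map `"regime_map"` (or plain `phylo` for BM1/EB).
#' @param model `"BM"`, `"OU"`, or `"EB"`.
#' @param sigma2 Rate (scalar; for `"OU"` the stochastic variance).
#' @param alpha OU selection strength.
#' @param theta Named per-regime optima (OU).
#' @param r EB exponent.
#' @param root_state Root value; for OU defaults to the root-regime optimum.
#' @param seed RNG seed.
#' @param internal Return internal-node values too?
#' @return Named numeric of tip values (attribute `"node_values"` if
#'   `internal`).
#' @export
simulate_trait <- function(map, model = c("OU", "BM", "EB"), sigma2 = 1,
                           alpha = 1, theta = NULL, r = 0,
                           root_state = NULL, seed = NULL, internal = FALSE) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(map$tip.label)
  has_maps <- !is.null(map$maps)
  if (model == "OU" && !has_maps) stop("OU simulation requires a regime map")
  if (model == "OU" && is.null(theta)) stop("OU simulation requires theta")
  if (is.null(root_state)) {
    root_state <- if (model == "OU") {
      root_seg <- map$maps[[which(map$edge[, 1] == nt + 1L)[1]]]
      theta[[names(root_seg)[1]]]
    } else 0
  }
  depth <- ape::node.depth.edgelength(map)
  vals <- numeric(nt + map$Nnode)
  vals[nt + 1L] <- root_state
  ord <- ape::reorder.phylo(map, "postorder")
  for (e in rev(seq_len(nrow(ord$edge)))) {
    parent <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    orig <- which(map$edge[, 1] == parent & map$edge[, 2] == child)
    y <- vals[parent]
    if (model == "BM") {
      y <- y + stats::rnorm(1, 0, sqrt(sigma2 * map$edge.length[orig]))
    } else if (model == "EB") {
      t0 <- depth[parent]
      t1 <- depth[child]
      v <- if (abs(r) < 1e-12) sigma2 * (t1 - t0) else
        sigma2 * (exp(r * t1) - exp(r * t0)) / r
      y <- y + stats::rnorm(1, 0, sqrt(v))
    } else {
      seg <- map$maps[[orig]]
      for (s in seq_along(seg)) {
        th <- theta[[names(seg)[s]]]
        dt <- seg[[s]]
        m <- th + (y - th) * exp(-alpha * dt)
        v <- sigma2 * (1 - exp(-2 * alpha * dt)) / (2 * alpha)
        y <- stats::rnorm(1, m, sqrt(v))
      }
    }
    vals[child] <- y
  }
  out <- vals[seq_len(nt)]
  names(out) <- map$tip.label
  if (internal) attr(out, "node_values") <- vals
  out
}

# smooth positive bump on the wavelength grid
.bump <- function(wl, center, width, height) {
  height * exp(-((wl - center) / width)^2)
}

#' Archetype irradiance spectra for forest microhabitats
#'
#' Parametric Gaussian-bump emulations of the two canonical rainforest
#' irradiance classes: `"gap"` (bright, broad, long-wavelength rich) and
#' `"shade"` (dim, green-peaked). Energy units (W m-2 nm-1) on a
#' 310-670 nm grid.
#'
#' @param archetype `"gap"` or `"shade"`.
#' @param wl Wavelength grid (nm).
#' @return A [spectrum()].
#' @export
archetype_spectrum <- function(archetype = c("gap", "shade"),
                               wl = seq(310, 670, by = 1)) {
  archetype <- match.arg(archetype)
  v <- if (archetype == "gap") {
    .bump(wl, 480, 160, 0.55) + .bump(wl, 620, 120, 0.35) +
      .bump(wl, 360, 60, 0.12) + 0.05
  } else {
    .bump(wl, 550, 55, 0.035) + .bump(wl, 620, 80, 0.008) + 0.0012
  }
  spectrum(wl, v, units = "energy")
}

#' Simulate irradiance spectra for a microhabitat archetype
#'
#' Archetype mean curve times a lognormal intensity factor plus a smooth
#' multiplicative shape perturbation; values stay >= 0.
#'
#' @param archetype `"gap"` or `"shade"`.
#' @param n Number of spectra.
#' @param intensity_sdlog SD of the lognormal intensity factor.
#' @param shape_sd Amplitude SD of the sinusoidal shape perturbation.
#' @param seed RNG seed.
#' @return List of [spectrum()] objects.
#' @export
simulate_spectra <- function(archetype = c("gap", "shade"), n = 1,
                             intensity_sdlog = 0.35, shape_sd = 0.06,
                             seed = NULL) {
  archetype <- match.arg(archetype)
  if (!is.null(seed)) set.seed(seed)
  base <- archetype_spectrum(archetype)
  wl <- base$wavelengths_nm
  lapply(seq_len(n), function(i) {
    fac <- stats::rlnorm(1, 0, intensity_sdlog)
    a <- stats::rnorm(1, 0, shape_sd)
    phi <- stats::runif(1, 0, 2 * pi)
    shape <- 1 + a * sin(2 * pi * (wl - 310) / 360 + phi)
    spectrum(wl, pmax(base$values * fac * shape, 0), units = "energy")
  })
}

#' Simulate a hemispherical fisheye image with known gap fraction
#'
#' Sky pixels are placed by thresholding a spatially correlated Gaussian
#' random field at the in-disc quantile matching `gap_fraction_target`
#' exactly (to one pixel). Sky pixels get a bright value, canopy a dark
#' value, with mild within-class noise, so Otsu recovers the classes.
#'
#' @param gap_fraction_target Target sky fraction in \[0, 1\].
#' @param size_px Image side (square), default 241.
#' @param corr_px Correlation length (Gaussian smoothing SD, px).
#' @param seed RNG seed.
#' @return List: `image` (a `"fisheye"`), `sky_fraction` (realized, exact),
#'   `openness_true_pct`.
#' @export
simulate_fisheye <- function(gap_fraction_target, size_px = 241,
                             corr_px = 6, seed = NULL) {
  stopifnot(gap_fraction_target >= 0, gap_fraction_target <= 1)
  if (!is.null(seed)) set.seed(seed)
  field <- matrix(stats::rnorm(size_px^2), size_px, size_px)
  field <- .gauss_smooth(field, corr_px)
  img0 <- fisheye_image(field)
  inside <- .inside_circle(img0)
  n_in <- sum(inside)
  n_sky <- round(gap_fraction_target * n_in)
  vals <- field[inside]
  sky <- matrix(FALSE, size_px, size_px)
  if (n_sky > 0) {
    thr <- sort(vals, decreasing = TRUE)[n_sky]
    sky[inside] <- field[inside] >= thr
    # ties could overshoot by a pixel or two; trim deterministically
    extra <- sum(sky[inside]) - n_sky
    if (extra > 0) {
      idx <- which(sky & inside)
      sky[idx[seq_len(extra)]] <- FALSE
    }
  }
  px <- matrix(35, size_px, size_px)
  px[sky] <- 220
  px <- px + matrix(stats::runif(size_px^2, -10, 10), size_px, size_px)
  img <- fisheye_image(px)
  list(image = img, sky_mask = sky, sky_fraction = n_sky / n_in,
       openness_true_pct = .mask_openness(sky, img))
}

# ground-truth openness of the analyzed 0-70 degree cap: per-ring sky
# fraction pixel-counted on the true mask, solid-angle ring weights
.mask_openness <- function(mask, img, n_rings = 7L, zenith_max = 70) {
  d <- dim(mask)
  rr <- matrix(seq_len(d[1]), d[1], d[2]) - img$center[1]
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - img$center[2]
  zen <- 90 * sqrt(rr^2 + cc^2) / img$radius_px
  sel <- zen < zenith_max
  bounds <- seq(0, zenith_max, length.out = n_rings + 1L)
  ring <- pmin(findInterval(zen[sel], bounds, all.inside = TRUE), n_rings)
  gf <- tapply(as.numeric(mask[sel]), ring, mean)
  rb <- bounds * pi / 180
  w <- (cos(rb[-length(rb)]) - cos(rb[-1])) / (1 - cos(rb[length(rb)]))
  100 * sum(w * gf[as.character(seq_len(n_rings))])
}

# separable Gaussian smoothing with reflecting edges
.gauss_smooth <- function(m, sd_px) {
  half <- max(1L, ceiling(3 * sd_px))
  kern <- stats::dnorm(-half:half, sd = sd_px)
  kern <- kern / sum(kern)
  smooth_vec <- function(v) {
    padded <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1]))
    stats::filter(padded, kern, sides = 2)[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(t(m), 2, smooth_vec))
}

#' Simulate a wing silhouette with known area and aspect ratio
#'
#' Filled rotated ellipse with the requested area (mm^2) and major/minor
#' axis ratio at the given scale, rendered bright on dark.
#'
#' @param area_mm2 Target area.
#' @param aspect_ratio Major/minor ratio >= 1.
#' @param scale_mm_per_px Scale.
#' @param angle_deg Rotation of the major axis.
#' @param margin_px Canvas margin around the ellipse.
#' @return List: `image` (matrix, 0/255), `area_mm2`, `aspect_ratio`,
#'   `scale_mm_per_px`.
#' @export
simulate_wing <- function(area_mm2, aspect_ratio, scale_mm_per_px = 0.1,
                          angle_deg = 0, margin_px = 8) {
  if (aspect_ratio < 1) stop("aspect ratio must be >= 1")
  b_mm <- sqrt(area_mm2 / (pi * aspect_ratio))
  a_mm <- aspect_ratio * b_mm
  a_px <- a_mm / scale_mm_per_px
  b_px <- b_mm / scale_mm_per_px
  half <- ceiling(a_px) + margin_px
  n <- 2L * half + 1L
  cx <- half + 1L
  th <- angle_deg * pi / 180
  rr <- matrix(seq_len(n), n, n) - cx
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  u <- cc * cos(th) + rr * sin(th)
  v <- -cc * sin(th) + rr * cos(th)
  mask <- (u / a_px)^2 + (v / b_px)^2 <= 1
  img <- matrix(0, n, n)
  img[mask] <- 255
  list(image = img, area_mm2 = area_mm2, aspect_ratio = aspect_ratio,
       scale_mm_per_px = scale_mm_per_px)
}

# truncated-geometric per-species sample sizes adjusted to an exact total
.sample_sizes <- function(n_species, total, range = c(1, 65)) {
  p <- 1 / (total / n_species)      # geometric success prob, mean ~ total/n
  n <- pmin(pmax(stats::rgeom(n_species, p) + 1, range[1]), range[2])
  # adjust to the exact configured total
  diff <- total - sum(n)
  i <- 1L
  while (diff != 0) {
    j <- ((i - 1L) %% n_species) + 1L
    step <- sign(diff)
    if (n[j] + step >= range[1] && n[j] + step <= range[2]) {
      n[j] <- n[j] + step
      diff <- diff - step
    }
    i <- i + 1L
  }
  n
}

#' Simulate individual records for a community
#'
#' Per individual: species, sex (Bernoulli 1/2), flight height and canopy
#' openness from cluster/species-specific normals driven by the species'
#' latent light preference, a simulated irradiance spectrum (mixture of gap
#' and shade archetypes weighted by the light preference) reduced to its
#' catch set, and wing metrics. Species-level random intercepts are drawn
#' with phylogenetic covariance, so the mixed model's assumed structure is
#' literally present in the data.
#'
#' @param tree `phylo`.
#' @param clusters Named cluster labels per species.
#' @param light Named latent light preference per species (the OUM trait).
#' @param config A [synthetic_config()].
#' @param seed RNG seed.
#' @return data.frame of individual records.
#' @export
simulate_individuals <- function(tree, clusters, light, config,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- tree$tip.label
  ns <- length(sp)
  n_i <- .sample_sizes(ns, config$n_individuals, config$sample_size_range)
  rings <- .assign_rings(clusters, config$rings, sp)
  # species intercepts with phylogenetic covariance
  C <- phylo_correlation(tree, 1)$C[sp, sp]
  L <- chol(C)
  b_sp <- as.numeric(t(L) %*% stats::rnorm(ns)) * config$noise[["species_intercept"]]
  names(b_sp) <- sp
  noise <- config$noise
  # species-level targets driven by the latent light preference
  openness_mu <- 12 + 9 * light[sp] + b_sp * 10      # percent
  height_mu <- pmax(0.5, 4 + 2.2 * light[sp] + b_sp * 5) # metres
  names(openness_mu) <- names(height_mu) <- sp
  p_gap <- stats::setNames(stats::plogis(2.2 * light[sp]), sp)
  wings <- config$wing
  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    n <- n_i[s]
    cl <- clusters[[sp[s]]]
    gap_draw <- stats::runif(n) < p_gap[[sp[s]]]
    catches <- lapply(seq_len(n), function(i) {
      arch <- if (gap_draw[i]) "gap" else "shade"
      s_i <- simulate_spectra(arch, 1,
                              intensity_sdlog = noise[["spectra_sdlog"]],
                              shape_sd = noise[["spectra_shape"]])[[1]]
      catch_set(s_i, grid_step = 0.5)
    })
    w <- wings[[cl]]
    area <- w[["area"]] * exp(stats::rnorm(n, 0, noise[["wing_rel"]]))
    ar <- pmax(1.01, w[["ar"]] * exp(stats::rnorm(n, 0, noise[["wing_rel"]])))
    loading <- w[["loading"]] * exp(stats::rnorm(n, 0, noise[["wing_rel"]]))
    rows[[s]] <- data.frame(
      species = sp[s],
      mimicry_ring = rings[[sp[s]]],
      mimetic_cluster = cl,
      sex = sample(c("F", "M"), n, replace = TRUE),
      flight_height_m = pmax(0.2, stats::rnorm(n, height_mu[[sp[s]]],
                                               noise[["flight_height"]])),
      canopy_openness_pct = pmin(100, pmax(
        0.5, stats::rnorm(n, openness_mu[[sp[s]]], noise[["openness"]]))),
      q_uv = vapply(catches, `[[`, numeric(1), "q_uv"),
      q_b = vapply(catches, `[[`, numeric(1), "q_b"),
      q_lw = vapply(catches, `[[`, numeric(1), "q_lw"),
      photon_catch_lw = vapply(catches, `[[`, numeric(1), "photon_catch_lw"),
      photon_catch_mean = vapply(catches, `[[`, numeric(1),
                                 "photon_catch_mean"),
      rel_uv = vapply(catches, `[[`, numeric(1), "rel_uv"),
      rel_b = vapply(catches, `[[`, numeric(1), "rel_b"),
      rel_lw = vapply(catches, `[[`, numeric(1), "rel_lw"),
      wing_area_mm2 = area,
      aspect_ratio = ar,
      wing_loading_g_per_mm2 = loading,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# distribute ring labels within each cluster (round-robin over the
# cluster's rings in species order)
.assign_rings <- function(clusters, rings, sp) {
  out <- character(length(sp))
  names(out) <- sp
  for (cl in names(rings)) {
    members <- sp[clusters[sp] == cl]
    if (!length(members)) next
    out[members] <- rep(rings[[cl]], length.out = length(members))
  }
  out
}

#' Generate a full synthetic community
#'
#' Orchestrates the generator: pure-birth tree, polyphyletic regime
#' painting, latent light preference under the configured trait model,
#' individual records, and (a few) fisheye and wing images with known
#' truth. Fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param images Generate example image fixtures? Default TRUE.
#' @return Object of class `"synthetic_community"`: `tree`, `map`,
#'   `species` (data.frame with ring, cluster, true light optimum and
#'   value), `records`, `fisheye`, `wings`, `config`.
#' @export
simulate_community <- function(config = synthetic_config(), images = TRUE) {
  seed <- config$seed
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        seed = .child_seed(seed, 1))
  map <- paint_regimes(tree, names(config$rings), rate = config$mk_rate,
                       seed = .child_seed(seed, 2))
  clusters <- tip_regimes(map)
  light <- simulate_trait(map, "OU", sigma2 = config$sigma2,
                          alpha = config$alpha, theta = config$theta,
                          seed = .child_seed(seed, 3))
  records <- simulate_individuals(tree, clusters, light, config,
                                  seed = .child_seed(seed, 4))
  species <- data.frame(
    species = tree$tip.label,
    mimicry_ring = .assign_rings(clusters, config$rings,
                                 tree$tip.label)[tree$tip.label],
    mimetic_cluster = clusters[tree$tip.label],
    light_true = light[tree$tip.label],
    theta_true = config$theta[clusters[tree$tip.label]],
    stringsAsFactors = FALSE)
  fisheye <- wings <- NULL
  if (images) {
    targets <- c(shade = 0.08, mid = 0.25, gap = 0.55)
    fisheye <- lapply(seq_along(targets), function(i)
      simulate_fisheye(targets[[i]], seed = .child_seed(seed, 10 + i)))
    names(fisheye) <- names(targets)
    wings <- lapply(names(config$wing), function(cl) {
      w <- config$wing[[cl]]
      simulate_wing(w[["area"]], w[["ar"]], angle_deg = 25)
    })
    names(wings) <- names(config$wing)
  }
  structure(list(tree = tree, map = map, species = species,
                 records = records, fisheye = fisheye, wings = wings,
                 config = config),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d species, %d individuals, %d clusters\n",
              length(x$tree$tip.label), nrow(x$records),
              length(unique(x$species$mimetic_cluster))))
  print(table(x$species$mimetic_cluster))
  invisible(x)
}

#' Run the full analysis pipeline on a community
#'
#' Species means -> ecological-axes PCA -> EC1 -> model comparison over a
#' stochastic-map ensemble; the end-to-end analysis the package exists for.
#'
#' @param community A [simulate_community()] result (or equivalent list).
#' @param n_maps Stochastic maps for the ensemble (default 500).
#' @param seed Seed for the map ensemble.
#' @return List: `species_means`, `pca`, `ec1` (named species scores),
#'   `ensemble` (a `"map_ensemble"`), `cluster_means` (EC1 by cluster).
#' @export
run_pipeline <- function(community, n_maps = 500, seed = 42) {
  vars <- c("q_uv", "q_b", "q_lw", "flight_height_m", "canopy_openness_pct",
            "wing_area_mm2", "aspect_ratio", "wing_loading_g_per_mm2")
  sm <- species_means(community$records, vars)
  pca <- ecological_axes(sm)
  ec1 <- pca$scores[, 1]
  names(ec1) <- sm$species
  clusters <- stats::setNames(community$species$mimetic_cluster,
                              community$species$species)
  ens <- compare_over_maps(community$tree, clusters[names(ec1)], ec1,
                           n_maps = n_maps, seed = seed)
  cl_means <- tapply(ec1, clusters[names(ec1)], mean)
  list(species_means = sm, pca = pca, ec1 = ec1, ensemble = ens,
       cluster_means = cl_means)
}
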