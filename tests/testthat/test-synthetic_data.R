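# synthetic_data: generators are deterministic, honour their stated
# parameters, and carry recorded ground truth.

test_that("simulate_tree yields deterministic unit-depth ultrametric trees", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(photoniche:::tree_depth(t2), 1)
  tr <- simulate_tree(30, seed = 2)
  dep <- ape::node.depth.edgelength(tr)[1:30]
  expect_lt(diff(range(dep)), 1e-8)
  expect_identical(ape::write.tree(simulate_tree(30, seed = 2)),
                   ape::write.tree(tr))
  # Yule expectation: with birth rate b over unit depth before rescaling,
  # richer communities need more time; sanity-check lineage growth instead
  expect_error(simulate_tree(1), ">= 2")
})

test_that("paint_regimes respects rate limits and cluster constraints", {
  tr <- simulate_tree(20, seed = 3)
  m0 <- paint_regimes(tr, regimes = c("A", "B"), rate = 1e-9, mode = "mk",
                      seed = 4)
  expect_equal(length(map_regimes(m0)), 1)
  # forward transition counts per unit length approximate the rate
  # (Poisson oracle: events occur at (k-1) * rate per unit branch length)
  tr2 <- simulate_tree(40, seed = 5)
  rate <- 2
  counts <- vapply(1:30, function(i) {
    m <- paint_regimes(tr2, regimes = c("A", "B"), rate = rate, mode = "mk",
                       seed = 100 + i)
    sum(vapply(m$maps, length, integer(1)) - 1)
  }, numeric(1))
  total_len <- sum(tr2$edge.length)
  lambda <- (2 - 1) * rate * total_len
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 30))

  m <- paint_regimes(tr, seed = 6)
  trg <- tip_regimes(m)
  expect_setequal(unique(trg), c("clearwing", "confusa", "tiger-stripe"))
  for (cl in unique(trg)) {
    tips <- names(trg)[trg == cl]
    expect_false(ape::is.monophyletic(tr, tips))
  }
  # painting is internally consistent
  for (e in seq_along(m$maps)) {
    expect_equal(sum(m$maps[[e]]), m$edge.length[e], tolerance = 1e-9)
  }
})

test_that("simulate_trait honours degenerate and stationary limits", {
  tr <- simulate_tree(10, seed = 7)
  y0 <- simulate_trait(tr, "BM", sigma2 = 0, seed = 8)
  expect_true(all(y0 == 0))
  # single-lineage BM variance ~ sigma2 * depth (MC oracle)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  t2 <- read_newick(f)
  set.seed(9)
  tips <- replicate(1000, simulate_trait(t2, "BM", sigma2 = 2)[["A"]])
  expect_lt(abs(var(tips) - 2), 0.3)
  # strong OU clusters near the regime optima
  m <- paint_regimes(tr, regimes = c("lo", "hi"), rate = 1, mode = "mk",
                     seed = 10)
  if (length(map_regimes(m)) == 2) {
    al <- 25
    set.seed(11)
    reps <- replicate(100, simulate_trait(m, "OU", sigma2 = 0.1, alpha = al,
                                          theta = c(lo = -2, hi = 2)))
    trg <- tip_regimes(m)
    mu_lo <- mean(reps[trg[rownames(reps)] == "lo", ])
    expect_lt(abs(mu_lo - (-2)), 3 * sqrt(0.1 / (2 * al)))
  }
  # EB with r = 0 behaves like BM in distribution (variance check)
  set.seed(12)
  veb <- var(replicate(600, simulate_trait(t2, "EB", sigma2 = 1, r = 0)[["A"]]))
  expect_lt(abs(veb - 1), 0.25)
})

test_that("simulate_spectra honours archetype contrast and zero noise", {
  gap <- catch_set(archetype_spectrum("gap"), grid_step = 0.5)
  shade <- catch_set(archetype_spectrum("shade"), grid_step = 0.5)
  expect_gt(gap$q_lw / shade$q_lw, 5)
  expect_gt(shade$rel_lw, gap$rel_uv)
  s0 <- simulate_spectra("gap", 3, intensity_sdlog = 0, shape_sd = 0,
                         seed = 1)
  expect_equal(s0[[1]]$values, s0[[2]]$values)
  expect_equal(s0[[1]]$values, archetype_spectrum("gap")$values)
  s1 <- simulate_spectra("shade", 2, seed = 2)
  expect_true(all(s1[[1]]$values >= 0))
  expect_false(identical(s1[[1]]$values, s1[[2]]$values))
})

test_that("simulate_fisheye hits its target fraction deterministically", {
  f1 <- simulate_fisheye(1, size_px = 101, seed = 1)
  img0 <- fisheye_image(matrix(0, 101, 101))
  inside <- photoniche:::.inside_circle(img0)
  expect_true(all(f1$sky_mask[inside]))
  f4 <- simulate_fisheye(0.4, size_px = 201, seed = 2)
  expect_lt(abs(f4$sky_fraction - 0.4), 0.005)
  f4b <- simulate_fisheye(0.4, size_px = 201, seed = 2)
  expect_identical(f4$image$pixels, f4b$image$pixels)
  expect_true(f4$openness_true_pct >= 0 && f4$openness_true_pct <= 100)
})

test_that("simulate_wing renders the requested geometry", {
  d <- simulate_wing(300, 1, scale_mm_per_px = 0.2)
  m <- segment_wing(d$image)
  expect_equal(wing_aspect_ratio(m), 1, tolerance = 0.02)
  w <- simulate_wing(200, 2, scale_mm_per_px = 0.1, angle_deg = 0)
  w2 <- simulate_wing(200, 2, scale_mm_per_px = 0.1, angle_deg = 63)
  expect_equal(wing_area(segment_wing(w$image), 0.1), 200, tolerance = 0.01)
  expect_equal(wing_aspect_ratio(segment_wing(w$image)),
               wing_aspect_ratio(segment_wing(w2$image)), tolerance = 0.02)
  expect_error(simulate_wing(100, 0.5), "aspect ratio")
})

test_that("simulate_individuals bookkeeping and noise limits hold", {
  cfg <- synthetic_config(n_species = 12, n_individuals = 80, seed = 3)
  tr <- simulate_tree(12, seed = 31)
  m <- paint_regimes(tr, seed = 32)
  light <- simulate_trait(m, "OU", sigma2 = cfg$sigma2, alpha = cfg$alpha,
                          theta = cfg$theta, seed = 33)
  rec <- simulate_individuals(tr, tip_regimes(m), light, cfg, seed = 34)
  expect_equal(nrow(rec), 80)
  expect_true(all(table(rec$species) >= 1 & table(rec$species) <= 65))
  expect_setequal(unique(rec$mimetic_cluster), unique(tip_regimes(m)))
  # ring-to-cluster consistency
  ring2cluster <- stats::setNames(
    rep(names(cfg$rings), lengths(cfg$rings)), unlist(cfg$rings))
  expect_equal(unname(ring2cluster[rec$mimicry_ring]), rec$mimetic_cluster)
  # zero noise: conspecific continuous measurements collapse
  cfg0 <- cfg
  cfg0$noise[c("flight_height", "openness", "wing_rel", "spectra_sdlog",
               "spectra_shape")] <- 0
  rec0 <- simulate_individuals(tr, tip_regimes(m), light, cfg0, seed = 35)
  per_sp <- split(rec0, rec0$species)
  for (d in per_sp) {
    expect_lt(diff(range(d$flight_height_m)), 1e-12)
    expect_lt(diff(range(d$wing_area_mm2)), 1e-12)
  }
})

test_that("simulate_community is fully deterministic with recorded truth", {
  cfg <- synthetic_config(n_species = 15, n_individuals = 60, seed = 5)
  c1 <- simulate_community(cfg, images = FALSE)
  c2 <- simulate_community(cfg, images = FALSE)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))
  expect_identical(c1$records, c2$records)
  expect_identical(c1$species, c2$species)
  # tip regimes of the painting equal the species table clusters
  expect_equal(unname(tip_regimes(c1$map)[c1$species$species]),
               c1$species$mimetic_cluster)
  expect_equal(unname(c1$species$theta_true),
               unname(cfg$theta[c1$species$mimetic_cluster]))
})
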