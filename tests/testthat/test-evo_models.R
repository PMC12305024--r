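# evo_models: Mk fitting, SIMMAP sampling, BM/BMM/OU/OUM/EB likelihoods,
# ML fitting, map-ensemble comparison, BM ancestral states.

test_that("fit_mk matches exhaustive enumeration and scales with time", {
  tr3 <- ape::read.tree(text = "((A:0.3,B:0.3):0.4,C:0.7);")
  st <- c(A = "x", B = "y", C = "x")
  q <- 0.8
  # brute force over the two internal-node states (root + one node)
  P <- function(t) {
    e <- exp(-2 * q * t)
    matrix(c((1 + e) / 2, (1 - e) / 2, (1 - e) / 2, (1 + e) / 2), 2, 2)
  }
  tip <- c(A = 1L, B = 2L, C = 1L)
  lik <- 0
  for (r in 1:2) for (n2 in 1:2) {
    lik <- lik + 0.5 * P(0.4)[r, n2] * P(0.3)[n2, tip["A"]] *
      P(0.3)[n2, tip["B"]] * P(0.7)[r, tip["C"]]
  }
  ll <- photoniche:::.mk_partials(tr3, tip, q, 2)$loglik
  expect_equal(ll, log(lik), tolerance = 1e-10)

  # time-scale invariance: q_hat rescales by 1/c
  tr <- random_tree(25, seed = 41)
  m <- paint_regimes(tr, regimes = c("A", "B"), rate = 2, mode = "mk",
                     seed = 42)
  ts <- tip_regimes(m)
  f1 <- fit_mk(tr, ts)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 3
  f2 <- fit_mk(tr2, ts)
  expect_equal(f2$q, f1$q / 3, tolerance = 1e-3)

  # single observed state: boundary with a warning
  expect_warning(fb <- fit_mk(tr, setNames(rep("A", 25), tr$tip.label)),
                 "single observed state")
  expect_lt(fb$q, 1e-8)
})

test_that("sample_simmap is deterministic, endpoint-consistent, and parity-correct", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  t2 <- read_newick(f)
  maps <- sample_simmap(t2, c(A = "p", B = "q"), n_maps = 20, seed = 5)
  for (m in maps) {
    # both states observed: at least one transition somewhere
    n_trans <- sum(vapply(m$maps, length, integer(1)) - 1)
    expect_gte(n_trans, 1)
    # segments sum to branch lengths, adjacent segments differ
    for (e in seq_along(m$maps)) {
      seg <- m$maps[[e]]
      expect_equal(sum(seg), m$edge.length[e], tolerance = 1e-9)
      if (length(seg) > 1) {
        expect_true(all(names(seg)[-1] != names(seg)[-length(seg)]))
      }
    }
    # tip-adjacent regimes equal the observed tip states
    expect_equal(unname(tip_regimes(m)), c("p", "q"))
  }
  tr <- random_tree(10, seed = 6)
  mm <- paint_regimes(tr, regimes = c("A", "B"), rate = 1.5, mode = "mk",
                      seed = 7)
  ts <- tip_regimes(mm)
  a <- sample_simmap(tr, ts, n_maps = 5, seed = 11)
  b <- sample_simmap(tr, ts, n_maps = 5, seed = 11)
  expect_identical(lapply(a, `[[`, "maps"), lapply(b, `[[`, "maps"))
})

test_that("uniformized path sampling produces valid endpoint-conditioned paths", {
  set.seed(9)
  for (i in 1:50) {
    iS <- sample(1:3, 1); jS <- sample(1:3, 1)
    seg <- photoniche:::.sample_path_uniformized(iS, jS, 0.7, 1.2, 3)
    expect_equal(sum(seg), 0.7, tolerance = 1e-9)
    expect_equal(as.integer(names(seg)[1]), iS)
    expect_equal(as.integer(names(seg)[length(seg)]), jS)
    if (length(seg) > 1) {
      expect_true(all(names(seg)[-1] != names(seg)[-length(seg)]))
    }
  }
})

test_that("continuous-trait likelihoods match dense MVN oracles on small trees", {
  skip_if_not_installed("mvtnorm")
  tr <- random_tree(5, seed = 13)
  set.seed(14)
  y <- simulate_trait(tr, "BM", sigma2 = 1)
  s2 <- 0.9; mu0 <- 0.3
  Tsh <- oracle_shared_time(tr)
  expect_equal(bm_loglik(tr, y, s2, mu0),
               mvn_oracle(y[rownames(Tsh)], rep(mu0, 5), s2 * Tsh),
               tolerance = 1e-8)
  # EB against its closed-form covariance
  r <- -1.4
  Veb <- 0.8 * (exp(r * Tsh) - 1) / r
  expect_equal(eb_loglik(tr, y, 0.8, r, mu0),
               mvn_oracle(y[rownames(Tsh)], rep(mu0, 5), Veb),
               tolerance = 1e-8)
  expect_equal(eb_loglik(tr, y, 0.8, 0, mu0), bm_loglik(tr, y, 0.8, mu0),
               tolerance = 1e-8)
  # BMM and OUM on a painting of the same tree
  m <- paint_regimes(tr, regimes = c("A", "B"), rate = 1.5, mode = "mk",
                     seed = 17)
  sig <- c(A = 0.5, B = 2)
  Vb <- oracle_bmm_cov(m, sig)
  expect_equal(bmm_loglik(m, y, sig, mu0),
               mvn_oracle(y[rownames(Vb)], rep(mu0, 5), Vb),
               tolerance = 1e-8)
  th <- c(A = -1, B = 1)
  om <- oracle_oum_moments(m, alpha = 2.5, sigma2 = 0.7, theta = th)
  expect_equal(ou_loglik(m, y, 2.5, 0.7, th),
               mvn_oracle(y[om$tips], om$mu, om$V), tolerance = 1e-8)
  # regime collapse: single-regime map equals OU1 for any parameters
  m1 <- paint_regimes(tr, regimes = "only", rate = 1, mode = "mk", seed = 1)
  om1 <- oracle_oum_moments(m1, 3, 1, c(only = 0.4))
  expect_equal(ou_loglik(m1, y, 3, 1, c(only = 0.4)),
               mvn_oracle(y[om1$tips], om1$mu, om1$V), tolerance = 1e-8)
  # alpha -> 0 limit approaches BM
  expect_equal(ou_loglik(m, y, 1e-8, s2, c(A = mu0, B = mu0)),
               bm_loglik(tr, y, s2, mu0), tolerance = 1e-3)
})

test_that("fit_model respects nesting and recovers generating parameters", {
  m <- painted_tree(40, seed = 23, rate = 2)
  tr <- ape::as.phylo(m); tr$maps <- NULL; class(tr) <- "phylo"
  set.seed(24)
  y <- simulate_trait(m, "OU", sigma2 = 1, alpha = 5,
                      theta = c(A = -1, B = 1))
  fits <- list(BM1 = fit_model("BM1", tr, y), OU1 = fit_model("OU1", tr, y),
               EB = fit_model("EB", tr, y), BMM = fit_model("BMM", m, y),
               OUM = fit_model("OUM", m, y))
  expect_gte(fits$OUM$logL, fits$OU1$logL - 1e-6)
  expect_gte(fits$BMM$logL, fits$BM1$logL - 1e-6)
  expect_gte(fits$OU1$logL, fits$BM1$logL - 1e-3)
  expect_gte(fits$EB$logL, fits$BM1$logL - 1e-8)
  expect_equal(vapply(fits, `[[`, numeric(1), "k"),
               c(BM1 = 2, OU1 = 3, EB = 3, BMM = 3, OUM = 4))
  for (f in fits) expect_equal(f$AICc, aicc(f$logL, f$k, f$n))

  # BM1 rate recovery (median over replicates)
  tr50 <- random_tree(50, seed = 25)
  set.seed(26)
  s2_hat <- replicate(30, fit_model("BM1", tr50,
                                    simulate_trait(tr50, "BM", sigma2 = 1))$sigma2)
  expect_lt(abs(median(s2_hat) - 1), 0.25)

  # OUM with all-equal optima never beats itself: AICc ordering sane
  set.seed(27)
  yb <- simulate_trait(tr, "BM", sigma2 = 1)
  f_oum <- fit_model("OUM", m, yb)
  f_ou1 <- fit_model("OU1", tr, yb)
  expect_gte(f_oum$logL, f_ou1$logL - 1e-6)
})

test_that("compare_over_maps tabulates per-map AICc deterministically", {
  m <- painted_tree(25, seed = 33, rate = 1.5)
  tr <- ape::as.phylo(m); tr$maps <- NULL; class(tr) <- "phylo"
  set.seed(34)
  y <- simulate_trait(m, "OU", sigma2 = 1, alpha = 7, theta = c(A = -1, B = 1))
  ens1 <- compare_over_maps(tr, tip_regimes(m), y, n_maps = 30, seed = 3)
  ens2 <- compare_over_maps(tr, tip_regimes(m), y, n_maps = 30, seed = 3)
  expect_identical(ens1$aicc, ens2$aicc)
  expect_equal(nrow(ens1$aicc), 30)
  expect_equal(sum(ens1$best_fraction), 1)
  expect_gt(ens1$best_fraction[["OUM"]], 0.5)
})

test_that("BM ancestral states match symmetry and the dense GLS oracle", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  t2 <- read_newick(f)
  a <- ancestral_states_bm(t2, c(A = 0, B = 2))
  expect_equal(a$value[3], 1)
  a2 <- ancestral_states_bm(t2, c(A = 5, B = 5))
  expect_equal(a2$value, rep(5, 3))

  tr6 <- random_tree(6, seed = 35)
  set.seed(36)
  y <- simulate_trait(tr6, "BM", sigma2 = 1)
  est <- ancestral_states_bm(tr6, y)
  # oracle: joint BM covariance over tips + internal nodes via shared times
  dep <- ape::node.depth.edgelength(tr6)
  M <- ape::mrca(tr6, full = TRUE)
  nall <- nrow(M)
  S <- matrix(dep[M], nall, nall)
  tips <- seq_len(6)
  nodes <- 7:nall
  Ctt <- S[tips, tips]
  one <- rep(1, 6)
  mu <- drop(solve(t(one) %*% solve(Ctt, one)) %*% t(one) %*% solve(Ctt, y[tr6$tip.label]))
  pred <- mu + S[nodes, tips] %*% solve(Ctt, y[tr6$tip.label] - mu)
  expect_lt(max(abs(est$value[nodes] - pred)), 1e-8)
})
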