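# phylo_stats: tree I/O and pruning, Pagel's-lambda correlation, PGLS,
# mixed models, AICc comparison, SMA shift tests.

test_that("read_newick parses and round-trips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(photoniche:::tree_depth(tr), 1)

  writeLines("((A:1,B:1):1,C:2):0;", f)
  tr2 <- read_newick(f)
  expect_equal(photoniche:::tree_depth(tr2), 2)

  tr3 <- random_tree(12, seed = 4)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr3, f2)
  tr3b <- read_newick(f2)
  expect_setequal(tr3b$tip.label, tr3$tip.label)
  d1 <- ape::cophenetic.phylo(tr3)
  d2 <- ape::cophenetic.phylo(tr3b)[rownames(d1), colnames(d1)]
  expect_lt(max(abs(d1 - d2)), 1e-8)

  writeLines("(A,B);", f)
  expect_error(read_newick(f), "branch lengths")
})

test_that("prune collapses paths and validates the species set", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2):0;", f)
  tr <- read_newick(f)
  same <- prune(tr, c("A", "B", "C"))
  expect_equal(sort(same$tip.label), sort(tr$tip.label))
  pr <- prune(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  expect_equal(sort(ape::node.depth.edgelength(pr)[1:2]), c(2, 2))
  expect_error(prune(tr, c("A", "Z")), "Z")
  expect_error(prune(tr, "A"), "fewer than 2")
})

test_that("phylo_correlation implements the lambda transform", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.2,B:0.2):0.8,C:1):0;", f)
  tr <- read_newick(f)
  C1 <- phylo_correlation(tr, 1)$C
  expect_equal(C1["A", "B"], 0.8)
  expect_equal(diag(C1), c(A = 1, B = 1, C = 1))
  C0 <- phylo_correlation(tr, 0)$C
  expect_equal(unname(C0), diag(3))
  Ch <- phylo_correlation(tr, 0.5)$C
  expect_equal(Ch["A", "B"], 0.4)
  # brute-force shared-path oracle on a random tree
  tr10 <- random_tree(10, seed = 31)
  C <- phylo_correlation(tr10, 1)$C
  S <- oracle_shared_time(tr10)
  expect_lt(max(abs(C - S / max(S))), 1e-10)
  expect_error(phylo_correlation(tr, 1.2), "lambda")
})

test_that("pgls_fit reduces to OLS at lambda 0 and matches the whitening oracle", {
  tr <- random_tree(10, seed = 12)
  set.seed(13)
  y <- simulate_trait(tr, "BM", sigma2 = 1)
  X <- data.frame(x = rnorm(10), row.names = names(y))
  f0 <- pgls_fit(y, X, phylo_correlation(tr, 0))
  ols <- stats::lm(yy ~ x, data = data.frame(yy = as.numeric(y), x = X$x))
  expect_lt(max(abs(f0$coefficients - coef(ols))), 1e-8)

  C <- phylo_correlation(tr, 1)
  f1 <- pgls_fit(y, X, C)
  ch <- chol(C$C[names(y), names(y)])
  Xm <- cbind(1, X$x)
  beta_oracle <- qr.solve(backsolve(ch, Xm, transpose = TRUE),
                          backsolve(ch, as.numeric(y), transpose = TRUE))
  expect_lt(max(abs(f1$coefficients - beta_oracle)), 1e-8)

  # two equal-depth tips, intercept only: the arithmetic mean
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", f)
  t2 <- read_newick(f)
  y2 <- c(A = 1, B = 3)
  f2 <- pgls_fit(y2, NULL, phylo_correlation(t2, 1))
  expect_equal(unname(f2$coefficients), 2)

  expect_error(pgls_fit(c(A = 1, B = 2, Z = 3), NULL, phylo_correlation(t2, 1)),
               "Z")
})

test_that("mixed_fit recovers variance components and matches PGLS", {
  # degenerate: no random terms equals OLS
  set.seed(2)
  y <- rnorm(30); x <- rnorm(30)
  mf <- mixed_fit(y, data.frame(x = x))
  expect_lt(max(abs(mf$coefficients - coef(lm(y ~ x)))), 1e-8)

  # intraclass correlation recovered in a balanced one-way layout
  set.seed(44)
  nrep <- 40
  icc_true <- 2 / (2 + 1)       # sigma_g2 = 2, sigma_e2 = 1
  icc_hat <- replicate(nrep, {
    g <- factor(rep(1:15, each = 6))
    yy <- rnorm(15, 0, sqrt(2))[g] + rnorm(90)
    f <- mixed_fit(yy, NULL, random = list(group = g), method = "REML")
    v <- f$varcomp
    v[["group"]] / (v[["group"]] + v[["residual"]])
  })
  expect_lt(abs(mean(icc_hat) - icc_true), 3 * sd(icc_hat) / sqrt(nrep) + 0.03)

  # equivalence oracle: one phylogenetic random term, one obs per species,
  # no other terms -> PGLS ML log-likelihood
  tr <- random_tree(12, seed = 3)
  yph <- simulate_trait(tr, "BM", sigma2 = 0.7, seed = 5)
  C <- phylo_correlation(tr, 1)
  fp <- pgls_fit(yph, NULL, C)
  fm <- mixed_fit(as.numeric(yph), NULL,
                  random = list(species = list(
                    f = factor(names(yph), levels = names(yph)), C = C$C)),
                  method = "ML", residual = FALSE)
  expect_lt(abs(fm$logLik_ml - fp$logLik_ml), 1e-6)
})

test_that("REML is invariant to fixed-effect reparameterization", {
  set.seed(6)
  g <- factor(rep(1:10, each = 4))
  x <- rnorm(40)
  y <- rnorm(10)[g] + 0.5 * x + rnorm(40, 0, 0.5)
  f1 <- mixed_fit(y, data.frame(x = x), random = list(group = g))
  f2 <- mixed_fit(y, data.frame(x = x + 100), random = list(group = g))
  expect_lt(abs(f1$logLik_reml - f2$logLik_reml), 1e-4)
})

test_that("compare_models ranks by AICc with the equivalence threshold", {
  expect_equal(aicc(-10, 3, 40), 26 + 2 * 3 * 4 / 36)
  fitA <- list(AICc = 100, n = 40)
  fitB <- list(AICc = 100, n = 40)
  fitC <- list(AICc = 104, n = 40)
  cmp <- compare_models(list(A = fitA, B = fitB, C = fitC))
  expect_equal(cmp$model[1:2], c("A", "B"))
  expect_equal(cmp$equivalent, c(TRUE, TRUE, FALSE))
  expect_error(compare_models(list(fitA, list(AICc = 1, n = 10))),
               "different numbers")
  # adding a pure-noise predictor does not improve expected AICc
  set.seed(77)
  deltas <- replicate(100, {
    x <- rnorm(25); yy <- 1 + x + rnorm(25)
    f1 <- mixed_fit(yy, data.frame(x = x))
    f2 <- mixed_fit(yy, data.frame(x = x, junk = rnorm(25)))
    f2$AICc - f1$AICc
  })
  expect_gt(mean(deltas), 0)
})

test_that("SMA slopes, tests, and the geometric-mean identity behave", {
  set.seed(8)
  x <- rnorm(40)
  y <- 2 * x + rnorm(40, 0, 0.01)
  f <- sma_fit(x, y)
  expect_equal(f$groups$slope, sd(y) / sd(x))
  # |b_SMA| = sqrt(b_yx / b_xy^{-1}) numerically
  byx <- unname(coef(lm(y ~ x))[2])
  bxy <- unname(coef(lm(x ~ y))[2])
  expect_equal(abs(f$groups$slope), sqrt(abs(byx / bxy)), tolerance = 1e-8)

  # y = x exactly in both groups: slope 1, no shifts
  x2 <- c(1:10, 2:11)
  g <- rep(c("a", "b"), each = 10)
  f2 <- sma_fit(x2, x2, g)
  expect_equal(f2$common_slope, 1, tolerance = 1e-6)
  expect_gt(f2$slope_test$p, 0.99)

  # small-scale power/type-I check (full-size runs live in acceptance)
  set.seed(15)
  res <- replicate(150, {
    n <- 30
    xa <- rnorm(n); xb <- rnorm(n)
    ya <- 0.75 * xa + rnorm(n, 0, 0.2)
    yb <- 0.5 + 0.75 * xb + rnorm(n, 0, 0.2)
    ff <- sma_fit(c(xa, xb), c(ya, yb), rep(c("a", "b"), each = n))
    c(slope_sig = ff$slope_test$p < 0.05, elev_sig = ff$elevation_test$p < 0.05)
  })
  expect_lt(mean(res["slope_sig", ]), 0.12)
  expect_gt(mean(res["elev_sig", ]), 0.9)

  expect_error(sma_fit(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(sma_fit(1:2, 1:2), "n < 3")
})
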