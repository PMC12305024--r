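# Single- and multipeak trait-evolution models on (regime-painted)
# phylogenies: BM1, BMM, OU1, OUM, EB Gaussian likelihoods, ML fitting with
# analytic profiling of optima/rates, AICc comparison over ensembles of
# stochastic character maps, and BM ancestral states for phenograms.

# ---- caches -----------------------------------------------------------

# Root-to-node path edge lists and node depths.
.path_cache <- function(tree) {
  nt <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  parent_edge <- integer(nt + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  paths <- vector("list", nt)
  for (i in seq_len(nt)) {
    p <- integer(0)
    node <- i
    while (node != nt + 1L) {
      e <- parent_edge[node]
      p <- c(e, p)
      node <- tree$edge[e, 1]
    }
    paths[[i]] <- p
  }
  list(nt = nt, depth = depth, paths = paths, parent_edge = parent_edge)
}

# Per-tip painted segments with absolute times from the root, plus per-node
# cumulative time in each regime (for BMM) and the root regime.
.map_cache <- function(map) {
  pc <- .path_cache(map)
  nt <- pc$nt
  regimes <- map_regimes(map)
  k <- length(regimes)
  # per-edge segments with absolute (t0, t1)
  edge_segs <- vector("list", nrow(map$edge))
  for (e in seq_len(nrow(map$edge))) {
    seg <- map$maps[[e]]
    t0 <- pc$depth[map$edge[e, 1]] + c(0, cumsum(seg))[seq_along(seg)]
    edge_segs[[e]] <- data.frame(regime = match(names(seg), regimes),
                                 t0 = t0, t1 = t0 + as.numeric(seg))
  }
  # tip path segments
  seg_tip <- integer(0); seg_reg <- integer(0)
  seg_t0 <- numeric(0); seg_t1 <- numeric(0)
  for (i in seq_len(nt)) {
    for (e in pc$paths[[i]]) {
      s <- edge_segs[[e]]
      seg_tip <- c(seg_tip, rep(i, nrow(s)))
      seg_reg <- c(seg_reg, s$regime)
      seg_t0 <- c(seg_t0, s$t0)
      seg_t1 <- c(seg_t1, s$t1)
    }
  }
  # cumulative regime time root -> node (preorder accumulation)
  rt <- matrix(0, nt + map$Nnode, k)
  ord <- ape::reorder.phylo(map, "postorder")
  for (e in rev(seq_len(nrow(ord$edge)))) {
    orig <- which(map$edge[, 1] == ord$edge[e, 1] &
                    map$edge[, 2] == ord$edge[e, 2])
    s <- edge_segs[[orig]]
    add <- vapply(seq_len(k), function(r) sum(s$t1[s$regime == r] -
                                                s$t0[s$regime == r]),
                  numeric(1))
    rt[ord$edge[e, 2], ] <- rt[ord$edge[e, 1], ] + add
  }
  root_regime <- edge_segs[[pc$paths[[1]][1]]]$regime[1]
  list(nt = nt, depth = pc$depth, regimes = regimes, k = k,
       seg_tip = seg_tip, seg_reg = seg_reg, seg_t0 = seg_t0,
       seg_t1 = seg_t1, rt = rt, root_regime = root_regime)
}

# Shared-time and patristic-distance matrices for the tips.
.tree_cache <- function(tree) {
  Tsh <- ape::vcv(tree)
  Ti <- diag(Tsh)
  Dm <- outer(Ti, Ti, `+`) - 2 * Tsh
  list(Tsh = Tsh, Ti = Ti, Dm = Dm, depth = max(Ti),
       tips = rownames(Tsh))
}

# GLS profile of (mean parameters, sigma2) for relative covariance R and
# design W: returns max log-likelihood and estimates.
.profile_gls <- function(y, W, R) {
  n <- length(y)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(list(logL = -Inf))
  logdetR <- 2 * sum(log(diag(ch)))
  Wi <- backsolve(ch, forwardsolve(t(ch), W))
  WtRW <- crossprod(Wi, W)
  theta <- tryCatch(solve(WtRW, crossprod(Wi, y)), error = function(e) NULL)
  if (is.null(theta)) return(list(logL = -Inf))
  r <- y - W %*% theta
  rss <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
  sigma2 <- rss / n
  if (sigma2 <= 0) return(list(logL = -Inf))
  logL <- -0.5 * (n * log(2 * pi * sigma2) + logdetR + n)
  list(logL = as.numeric(logL), theta = drop(theta), sigma2 = sigma2)
}

# ---- likelihoods (explicit-parameter forms) ---------------------------

#' Brownian-motion log-likelihood
#'
#' Gaussian log-density of the tip values with mean `root_state` and
#' covariance `sigma2 *` (shared root-to-tip path time).
#'
#' @param tree `phylo`.
#' @param trait Named tip values.
#' @param sigma2 Rate, > 0.
#' @param root_state Root (ancestral) state.
#' @return Scalar log-likelihood.
#' @export
bm_loglik <- function(tree, trait, sigma2, root_state) {
  tc <- .tree_cache(tree)
  y <- trait[tc$tips]
  .mvn_loglik(y, rep(root_state, length(y)), sigma2 * tc$Tsh)
}

#' Multi-rate Brownian-motion log-likelihood
#'
#' Covariance accumulates regime-specific rates over the shared root-to-MRCA
#' path: `V_ij = sum_k sigma2[k] * (shared time painted k)`.
#'
#' @param map `"regime_map"`.
#' @param trait Named tip values.
#' @param sigma2 Named per-regime rates.
#' @param root_state Root state.
#' @return Scalar log-likelihood.
#' @export
bmm_loglik <- function(map, trait, sigma2, root_state) {
  mc <- .map_cache(map)
  y <- trait[map$tip.label]
  sig <- sigma2[mc$regimes]
  mr <- ape::mrca(map)[seq_len(mc$nt), seq_len(mc$nt)]
  V <- matrix(0, mc$nt, mc$nt)
  for (r in seq_len(mc$k)) {
    V <- V + sig[r] * matrix(mc$rt[mr, r], mc$nt, mc$nt)
  }
  .mvn_loglik(y, rep(root_state, mc$nt), V)
}

#' Early-burst log-likelihood
#'
#' BM with exponentially time-varying rate `sigma2_0 * exp(r t)`:
#' `V_ij = sigma2_0 (exp(r t_shared) - 1)/r` (limit `sigma2_0 t_shared` as
#' `r -> 0`).
#'
#' @param tree `phylo` (ultrametric).
#' @param trait Named tip values.
#' @param sigma2_0 Initial rate.
#' @param r Rate-change exponent (negative = decelerating).
#' @param root_state Root state.
#' @return Scalar log-likelihood.
#' @export
eb_loglik <- function(tree, trait, sigma2_0, r, root_state) {
  tc <- .tree_cache(tree)
  y <- trait[tc$tips]
  R <- if (abs(r) < 1e-12) tc$Tsh else (exp(r * tc$Tsh) - 1) / r
  .mvn_loglik(y, rep(root_state, length(y)), sigma2_0 * R)
}

#' Multipeak Ornstein-Uhlenbeck log-likelihood
#'
#' Mean: `E[y_i] = exp(-a T) y0 + sum_k theta_k W_ik` where `W_ik`
#' integrates `a exp(-a (T - t))` over the root-to-tip segments painted `k`;
#' by default the root state `y0` is fixed at the root-regime optimum.
#' Covariance (ultrametric tree):
#' `sigma2/(2a) exp(-a d_ij) (1 - exp(-2a t_ij))` with `t_ij` shared time
#' and `d_ij` patristic distance.
#'
#' @param map `"regime_map"` on an ultrametric tree.
#' @param trait Named tip values.
#' @param alpha Selection strength, >= 0.
#' @param sigma2 Rate, > 0.
#' @param theta Named per-regime optima.
#' @param root `"optimum"` (root state = root-regime optimum, default) or a
#'   numeric root state.
#' @return Scalar log-likelihood.
#' @export
ou_loglik <- function(map, trait, alpha, sigma2, theta, root = "optimum") {
  mc <- .map_cache(map)
  tc <- .tree_cache(map)
  y <- trait[map$tip.label]
  th <- theta[mc$regimes]
  W <- .ou_weights(mc, alpha)
  y0 <- if (identical(root, "optimum")) th[mc$root_regime] else as.numeric(root)
  mu <- drop(W %*% th) + exp(-alpha * tc$Ti) * y0
  V <- .ou_cov(tc, alpha, sigma2)
  .mvn_loglik(y, mu, V)
}

# weight matrix W (tip x regime) at selection strength alpha
.ou_weights <- function(mc, alpha) {
  Ti <- mc$depth[seq_len(mc$nt)]
  if (alpha <= 0) {
    # BM limit: optima never pull; all weight collapses onto the root state
    return(matrix(0, mc$nt, mc$k, dimnames = list(NULL, mc$regimes)))
  }
  w <- exp(-alpha * (Ti[mc$seg_tip] - mc$seg_t1)) -
    exp(-alpha * (Ti[mc$seg_tip] - mc$seg_t0))
  idx <- (mc$seg_reg - 1L) * mc$nt + mc$seg_tip
  acc <- rowsum(w, idx)
  W <- matrix(0, mc$nt, mc$k, dimnames = list(NULL, mc$regimes))
  W[as.integer(rownames(acc))] <- acc
  W
}

.ou_cov <- function(tc, alpha, sigma2) {
  if (alpha <= 1e-12) return(sigma2 * tc$Tsh)
  sigma2 / (2 * alpha) * exp(-alpha * tc$Dm) * (1 - exp(-2 * alpha * tc$Tsh))
}

# dense Gaussian log-density (implementation route; tests use mvtnorm as the
# independent oracle)
.mvn_loglik <- function(y, mu, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite"))
  r <- y - mu
  z <- forwardsolve(t(ch), r)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# ---- fitting ----------------------------------------------------------

.k_params <- c(BM1 = 2, OU1 = 3, EB = 3)

#' Fit a trait-evolution model
#'
#' Maximum-likelihood fit of one of `BM1`, `BMM`, `OU1`, `OUM`, `EB`.
#' Optima/root and `sigma2` are profiled analytically by GLS given the shape
#' parameter (`alpha` for OU, `r` for EB, rate ratios for BMM), which is
#' optimized by bounded search: `alpha` over `[1e-6, 50]/depth` on a
#' log-spaced grid refined by `optimize()`, `r` over `[-10, 0]/depth`, BMM
#' log-ratios by quasi-Newton. Free-parameter counts: BM1 = 2, OU1 = 3,
#' EB = 3, BMM = 1 + #regimes, OUM = 2 + #regimes.
#'
#' @param model `"BM1"`, `"BMM"`, `"OU1"`, `"OUM"`, `"EB"`.
#' @param tree `phylo` for BM1/OU1/EB, `"regime_map"` for BMM/OUM.
#' @param trait Named tip values (complete).
#' @param root OU root handling: `"optimum"` (default; root state fixed at
#'   the root-regime optimum) or `"estimated"` (extra free parameter; only
#'   identifiable for OUM).
#' @return Object of class `"evo_fit"` / `"model_fit"`: `model`, `sigma2`,
#'   `alpha`, `theta`, `r`, `root_state`, `logL`, `k`, `AICc`, `n`,
#'   `boundary` flag.
#' @export
fit_model <- function(model = c("BM1", "BMM", "OU1", "OUM", "EB"),
                      tree, trait, root = c("optimum", "estimated")) {
  model <- match.arg(model)
  root <- match.arg(root)
  if (is.null(names(trait))) stop("trait must be named by species")
  if (anyNA(trait[tree$tip.label])) stop("trait missing for some tips")
  tc <- .tree_cache(tree)
  y <- as.numeric(trait[tc$tips])
  n <- length(y)
  ones <- matrix(1, n, 1)
  depth <- tc$depth
  out <- list(model = model, n = n, boundary = FALSE)

  if (model == "BM1") {
    pr <- .profile_gls(y, ones, tc$Tsh)
    out$sigma2 <- pr$sigma2
    out$root_state <- pr$theta
    out$logL <- pr$logL
    out$k <- 2
  } else if (model == "EB") {
    fr <- function(r) {
      R <- if (abs(r) < 1e-12) tc$Tsh else (exp(r * tc$Tsh) - 1) / r
      .profile_gls(y, ones, R)$logL
    }
    opt <- stats::optimize(fr, lower = -10 / depth, upper = 0, maximum = TRUE)
    r_hat <- if (fr(0) >= opt$objective) 0 else opt$maximum
    R <- if (abs(r_hat) < 1e-12) tc$Tsh else (exp(r_hat * tc$Tsh) - 1) / r_hat
    pr <- .profile_gls(y, ones, R)
    out$sigma2 <- pr$sigma2
    out$r <- r_hat
    out$root_state <- pr$theta
    out$logL <- pr$logL
    out$k <- 3
    out$boundary <- r_hat <= -9.99 / depth
  } else if (model == "OU1") {
    fa <- function(a) .profile_gls(y, ones, .ou_cov(tc, a, 1))$logL
    sol <- .optimize_alpha(fa, depth)
    pr <- .profile_gls(y, ones, .ou_cov(tc, sol$alpha, 1))
    out$alpha <- sol$alpha
    out$sigma2 <- pr$sigma2
    out$theta <- pr$theta
    out$root_state <- pr$theta
    out$logL <- pr$logL
    out$k <- 3
    out$boundary <- sol$boundary
  } else if (model == "BMM") {
    mc <- .map_cache(tree)
    mr <- ape::mrca(tree)[seq_len(n), seq_len(n)]
    RT <- lapply(seq_len(mc$k), function(r)
      matrix(mc$rt[mr, r], n, n))
    fx <- function(x) {
      cs <- c(1, exp(x))
      R <- Reduce(`+`, Map(`*`, cs, RT))
      .profile_gls(y, ones, R)$logL
    }
    if (mc$k == 1L) {
      pr <- .profile_gls(y, ones, RT[[1]])
      cs <- 1
    } else {
      opt <- stats::optim(rep(0, mc$k - 1L), function(x) -fx(x),
                          method = "BFGS", control = list(maxit = 300))
      cs <- c(1, exp(opt$par))
      pr <- .profile_gls(y, ones, Reduce(`+`, Map(`*`, cs, RT)))
    }
    out$sigma2 <- stats::setNames(pr$sigma2 * cs, mc$regimes)
    out$root_state <- pr$theta
    out$logL <- pr$logL
    out$k <- 1 + mc$k
  } else { # OUM
    mc <- .map_cache(tree)
    design <- function(a) {
      W <- .ou_weights(mc, a)
      if (root == "optimum") {
        W[, mc$root_regime] <- W[, mc$root_regime] + exp(-a * tc$Ti)
        W
      } else {
        cbind(W, root = exp(-a * tc$Ti))
      }
    }
    fa <- function(a) .profile_gls(y, design(a), .ou_cov(tc, a, 1))$logL
    sol <- .optimize_alpha(fa, depth)
    pr <- .profile_gls(y, design(sol$alpha), .ou_cov(tc, sol$alpha, 1))
    theta <- pr$theta[seq_len(mc$k)]
    names(theta) <- mc$regimes
    out$alpha <- sol$alpha
    out$sigma2 <- pr$sigma2
    out$theta <- theta
    out$root_state <- if (root == "optimum") theta[[mc$root_regime]] else
      pr$theta[["root"]]
    out$logL <- pr$logL
    out$k <- 2 + mc$k + (root == "estimated")
    out$boundary <- sol$boundary
  }
  out$AICc <- aicc(out$logL, out$k, n)
  structure(out, class = c("evo_fit", "model_fit"))
}

# coarse log-spaced grid + local refinement for the OU selection strength
.optimize_alpha <- function(f, depth, lower = 1e-6, upper = 50, n_grid = 24) {
  grid <- exp(seq(log(lower / depth), log(upper / depth), length.out = n_grid))
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(function(la) f(exp(la)), lower = log(lo),
                         upper = log(hi), maximum = TRUE)
  alpha <- exp(opt$maximum)
  if (opt$objective < vals[i]) alpha <- grid[i]
  list(alpha = alpha, boundary = i %in% c(1L, n_grid))
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("<evo_fit> %s: logL = %.4f, k = %d, AICc = %.4f\n",
              x$model, x$logL, x$k, x$AICc))
  if (!is.null(x$alpha)) cat(sprintf("  alpha = %.4g\n", x$alpha))
  if (!is.null(x$theta)) {
    cat("  theta:", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                          collapse = ", "), "\n")
  }
  if (!is.null(x$r)) cat(sprintf("  r = %.4g\n", x$r))
  cat("  sigma2:", paste(sprintf("%.4g", x$sigma2), collapse = ", "), "\n")
  invisible(x)
}

#' Model comparison over a stochastic-map ensemble
#'
#' Samples `n_maps` stochastic character maps of the tip regimes (ER Mk),
#' fits the regime-dependent models (BMM, OUM) on every map and the
#' regime-independent models (BM1, OU1, EB) once on the tree, and tabulates
#' per-map AICc, the best model per map, and the fraction of maps on which
#' each model wins.
#'
#' @param tree `phylo` (ultrametric).
#' @param tip_regimes Regime labels named by species.
#' @param trait Named tip values.
#' @param n_maps Number of maps (default 500).
#' @param models Subset of `c("BM1","BMM","OU1","OUM","EB")`.
#' @param seed RNG seed for the map ensemble.
#' @param root Passed to [fit_model()] for OU models.
#' @return Object of class `"map_ensemble"`: `aicc` (map x model
#'   data.frame), `best` (per-map winner), `best_fraction`, `fixed_fits`,
#'   `failures` (per-map fit failures, excluded with a census).
#' @export
compare_over_maps <- function(tree, tip_regimes, trait, n_maps = 500,
                              models = c("BM1", "BMM", "OU1", "OUM", "EB"),
                              seed = NULL, root = "optimum") {
  models <- match.arg(models, several.ok = TRUE)
  maps <- sample_simmap(tree, tip_regimes, n_maps = n_maps, seed = seed)
  fixed <- intersect(models, c("BM1", "OU1", "EB"))
  permap <- intersect(models, c("BMM", "OUM"))
  fixed_fits <- lapply(stats::setNames(fixed, fixed), function(m)
    fit_model(m, tree, trait, root = root))
  aicc_tab <- matrix(NA_real_, n_maps, length(models),
                     dimnames = list(NULL, models))
  for (m in fixed) aicc_tab[, m] <- fixed_fits[[m]]$AICc
  failures <- 0L
  for (i in seq_len(n_maps)) {
    for (m in permap) {
      fit <- tryCatch(fit_model(m, maps[[i]], trait, root = root),
                      error = function(e) NULL)
      if (is.null(fit)) failures <- failures + 1L else
        aicc_tab[i, m] <- fit$AICc
    }
  }
  ok <- stats::complete.cases(aicc_tab)
  best <- colnames(aicc_tab)[apply(aicc_tab[ok, , drop = FALSE], 1, which.min)]
  structure(list(
    aicc = as.data.frame(aicc_tab), best = best,
    best_fraction = vapply(stats::setNames(models, models),
                           function(m) mean(best == m), numeric(1)),
    fixed_fits = fixed_fits, n_maps = n_maps, n_used = sum(ok),
    failures = failures
  ), class = "map_ensemble")
}

#' @export
print.map_ensemble <- function(x, ...) {
  cat(sprintf("<map_ensemble> %d maps (%d used, %d fit failures)\n",
              x$n_maps, x$n_used, x$failures))
  cat("fraction of maps won:\n")
  print(round(x$best_fraction, 3))
  invisible(x)
}

#' BM ancestral state estimates
#'
#' GLS/ML estimates of internal-node states under single-rate Brownian
#' motion, for phenogram (traitgram) drawing.
#'
#' @param tree `phylo`.
#' @param trait Named tip values.
#' @return data.frame: `node` (ape numbering), `time` (depth from root),
#'   `value` (tip values for tips, estimates for internal nodes).
#' @export
ancestral_states_bm <- function(tree, trait) {
  tc <- .tree_cache(tree)
  y <- as.numeric(trait[tc$tips])
  n <- length(y)
  if (stats::var(y) == 0) {
    nn0 <- n + tree$Nnode
    return(data.frame(node = seq_len(nn0),
                      time = ape::node.depth.edgelength(tree),
                      value = rep(y[1], nn0)))
  }
  pr <- .profile_gls(y, matrix(1, n, 1), tc$Tsh)
  mu <- pr$theta
  nt <- n
  nn <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  # shared time of node a with tip i = depth of their MRCA
  anc <- numeric(nt + nn)
  anc[seq_len(nt)] <- y
  Ctt_inv_r <- solve(tc$Tsh, y - mu)
  for (a in (nt + 1L):(nt + nn)) {
    cv <- depth[M[a, seq_len(nt)]]
    anc[a] <- mu + sum(cv * Ctt_inv_r)
  }
  data.frame(node = seq_len(nt + nn), time = depth, value = anc)
}
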