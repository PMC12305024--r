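# Equal-rates Mk model for discrete regimes: pruning likelihood, ML rate
# estimation, marginal ancestral states, and stochastic character mapping
# (SIMMAP) with rejection sampling plus a uniformization fallback.

# ER transition probability matrix: k states, off-diagonal rate q each.
# P_ii(t) = 1/k + (1 - 1/k) e^{-k q t}; P_ij(t) = 1/k - (1/k) e^{-k q t}.
.er_pmat <- function(q, t, k) {
  e <- exp(-k * q * t)
  off <- (1 - e) / k
  P <- matrix(off, k, k)
  diag(P) <- off + e
  P
}

# Postorder partial likelihoods; tip_states is an integer vector (1..k)
# named by tip label. Returns list(L = (Nnode+Ntip) x k matrix, loglik at
# rate q with a flat root prior, scaled).
.mk_partials <- function(tree, tip_states, q, k) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  L <- matrix(0, nt + nn, k)
  L[cbind(seq_len(nt), tip_states[tree$tip.label])] <- 1
  logscale <- 0
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1]
    child <- ord$edge[i, 2]
    P <- .er_pmat(q, ord$edge.length[i], k)
    msg <- P %*% L[child, ]
    if (all(L[parent, ] == 0)) L[parent, ] <- 1
    L[parent, ] <- L[parent, ] * msg
    mx <- max(L[parent, ])
    if (mx > 0 && (mx < 1e-280 || mx > 1e280)) {
      L[parent, ] <- L[parent, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- nt + 1L
  lik <- sum(L[root, ] / k)
  list(L = L, loglik = log(lik) + logscale, root = root)
}

#' Fit an equal-rates Mk model
#'
#' Maximum-likelihood transition rate for the equal-rates (ER) Markov model
#' of a discrete character, via Felsenstein pruning with a flat root prior.
#'
#' @param tree `phylo`.
#' @param tip_states Character/factor of states named by species, or aligned
#'   to `tree$tip.label`.
#' @return Object of class `"mk_fit"`: `q` (ML rate), `loglik`, `states`
#'   (level labels), `partials` (node x state conditional likelihoods),
#'   `tip_states` (integer codes).
#' @export
fit_mk <- function(tree, tip_states) {
  if (is.null(names(tip_states))) names(tip_states) <- tree$tip.label
  tip_states <- tip_states[tree$tip.label]
  if (anyNA(tip_states)) stop("tip states missing for some tips")
  f <- factor(as.character(tip_states))
  states <- levels(f)
  k <- length(states)
  codes <- as.integer(f)
  names(codes) <- names(tip_states)
  depth <- tree_depth(tree)
  if (k < 2L) {
    warning("single observed state: rate estimated at the lower boundary")
    q <- 1e-10 / depth
    pr <- .mk_partials(tree, codes, q, max(k, 2L))
    return(structure(list(q = q, loglik = pr$loglik, states = states,
                          partials = pr$L, tip_states = codes, tree = tree,
                          k = max(k, 2L)),
                     class = "mk_fit"))
  }
  nll <- function(logq) -.mk_partials(tree, codes, exp(logq), k)$loglik
  opt <- stats::optimize(nll, lower = log(1e-8 / depth),
                         upper = log(500 / depth))
  q <- exp(opt$minimum)
  pr <- .mk_partials(tree, codes, q, k)
  structure(list(q = q, loglik = -opt$objective, states = states,
                 partials = pr$L, tip_states = codes, tree = tree, k = k),
            class = "mk_fit")
}

#' Marginal ancestral state probabilities under the ER Mk model
#'
#' Standard up-down (outside-inside) algorithm with a flat root prior.
#'
#' @param fit A [fit_mk()] result (or supply `tree`, `tip_states`, `q`).
#' @return Matrix (internal node x state) of marginal posterior
#'   probabilities; rows ordered as ape node numbers `Ntip+1 ...`.
#' @export
mk_marginals <- function(fit) {
  tree <- fit$tree
  k <- fit$k
  q <- fit$q
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  D <- fit$partials
  # up messages: U[node, ] for every node; root gets the prior
  U <- matrix(NA_real_, nt + nn, k)
  U[nt + 1L, ] <- rep(1 / k, k)
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  # precompute per-edge messages M_child(parent state) = sum_j P_ij D_child(j)
  msg <- function(child, t) .er_pmat(q, t, k) %*% D[child, ]
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]
    child <- edges[i, 2]
    t <- elen[i]
    sibs <- setdiff(tree$edge[children[[as.character(parent)]], 2], child)
    up <- U[parent, ]
    for (s in sibs) {
      ts <- tree$edge.length[which(tree$edge[, 2] == s)]
      up <- up * as.numeric(msg(s, ts))
    }
    P <- .er_pmat(q, t, k)
    U[child, ] <- as.numeric(t(P) %*% up)
  }
  post <- D * U
  post <- post / rowSums(post)
  nodes <- (nt + 1L):(nt + nn)
  out <- post[nodes, , drop = FALSE]
  dimnames(out) <- list(nodes, fit$states)
  out
}

# Sample a CTMC path of the ER chain between endpoint states over duration t
# via rejection sampling (cap attempts), falling back to uniformization.
# Returns a named numeric vector of segment durations (names = state codes
# as character), ordered from the parent end to the child end.
.sample_path <- function(i, j, t, q, k, cap = 1e4) {
  rate <- (k - 1) * q
  for (attempt in seq_len(cap)) {
    cur <- i
    pos <- 0
    path_states <- cur
    path_times <- numeric(0)
    repeat {
      wait <- stats::rexp(1, rate)
      if (pos + wait >= t) break
      pos <- pos + wait
      path_times <- c(path_times, pos)
      cur <- sample((1:k)[-cur], 1L)
      path_states <- c(path_states, cur)
    }
    if (cur == j) {
      bounds <- c(0, path_times, t)
      seg <- diff(bounds)
      names(seg) <- as.character(path_states)
      return(.collapse_segments(seg))
    }
    # quick exit: i == j and no forced change needed happens fast anyway
  }
  .sample_path_uniformized(i, j, t, q, k)
}

# Uniformization: dominating rate L = (k-1) q, R = I + Q/L has zero diagonal
# and 1/(k-1) off-diagonal. Draw the number of (true) jumps conditional on
# the endpoints, then the intermediate states by forward-backward, then
# uniform jump times.
.sample_path_uniformized <- function(i, j, t, q, k) {
  L <- (k - 1) * q
  R <- matrix(1 / (k - 1), k, k)
  diag(R) <- 0
  Pij <- .er_pmat(q, t, k)[i, j]
  # P(N = n | i -> j) prop. to pois(n; L t) * (R^n)_ij
  nmax <- max(20, ceiling(L * t + 12 * sqrt(L * t + 1)))
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1]] <- diag(k)
  for (m in seq_len(nmax)) Rpow[[m + 1]] <- Rpow[[m]] %*% R
  wts <- vapply(0:nmax, function(n) {
    stats::dpois(n, L * t) * Rpow[[n + 1]][i, j]
  }, numeric(1))
  if (sum(wts) <= 0) stop("uniformization failure for branch endpoint pair")
  n <- sample(0:nmax, 1L, prob = wts)
  states <- integer(n + 1L)
  states[1] <- i
  states[n + 1L] <- j
  if (n >= 2L) {
    for (m in seq_len(n - 1L)) {
      w <- R[states[m], ] * vapply(1:k, function(s)
        Rpow[[n - m + 1L]][s, j], numeric(1))
      states[m + 1L] <- sample(1:k, 1L, prob = w)
    }
  }
  if (n == 0L) {
    seg <- t
    names(seg) <- as.character(i)
    return(seg)
  }
  times <- sort(stats::runif(n, 0, t))
  bounds <- c(0, times, t)
  seg <- diff(bounds)
  names(seg) <- as.character(states)
  .collapse_segments(seg)
}

# Merge adjacent segments with equal state; drop zero-length segments.
.collapse_segments <- function(seg) {
  keep_states <- names(seg)
  out_s <- character(0)
  out_d <- numeric(0)
  for (m in seq_along(seg)) {
    if (length(out_s) && out_s[length(out_s)] == keep_states[m]) {
      out_d[length(out_d)] <- out_d[length(out_d)] + seg[m]
    } else {
      out_s <- c(out_s, keep_states[m])
      out_d <- c(out_d, seg[m])
    }
  }
  pos <- out_d > 0 | seq_along(out_d) == 1
  out_d <- out_d[pos]
  names(out_d) <- out_s[pos]
  out_d
}

#' Sample stochastic character maps
#'
#' Draws full regime histories consistent with the tip states under the
#' fitted ER Mk model: node states by stochastic traceback from the pruning
#' conditionals (flat root prior), branch interiors by endpoint-conditioned
#' path sampling (rejection sampling capped at 1e4 attempts, then
#' uniformization).
#'
#' @param tree `phylo`.
#' @param tip_states Discrete states named by species.
#' @param q Transition rate; default the [fit_mk()] ML estimate.
#' @param n_maps Number of maps (default 500).
#' @param seed Optional RNG seed for reproducibility.
#' @return List of `"regime_map"` objects (see [regime_map()]).
#' @export
sample_simmap <- function(tree, tip_states, q = NULL, n_maps = 500,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_mk(tree, tip_states)
  if (is.null(q)) q <- fit$q
  k <- fit$k
  nt <- length(tree$tip.label)
  D <- fit$partials
  ord <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(ord$edge)))
  edges <- ord$edge[pre, , drop = FALSE]
  elen <- ord$edge.length[pre]
  lapply(seq_len(n_maps), function(m) {
    node_state <- integer(nt + tree$Nnode)
    root <- nt + 1L
    wr <- D[root, ] / k
    node_state[root] <- sample(1:k, 1L, prob = wr)
    maps <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]
      child <- edges[e, 2]
      t <- elen[e]
      P <- .er_pmat(q, t, k)
      w <- P[node_state[parent], ] * D[child, ]
      node_state[child] <- sample(1:k, 1L, prob = w)
      orig_e <- which(tree$edge[, 1] == parent & tree$edge[, 2] == child)
      seg <- .sample_path(node_state[parent], node_state[child], t, q, k)
      names(seg) <- fit$states[as.integer(names(seg))]
      maps[[orig_e]] <- seg
    }
    regime_map(tree, maps,
               node_states = stats::setNames(fit$states[node_state],
                                             seq_along(node_state)))
  })
}

#' Construct a regime map
#'
#' A regime map is a tree plus a piecewise-constant painting of discrete
#' selective regimes along every branch: per edge an ordered named numeric
#' vector of segment durations (names = regimes, ordered from the rootward
#' end), summing to the branch length.
#'
#' @param tree `phylo`.
#' @param maps List (one per row of `tree$edge`) of named duration vectors.
#' @param node_states Optional vector of node regimes.
#' @return `"regime_map"` object (a `phylo` with `$maps`).
#' @export
regime_map <- function(tree, maps, node_states = NULL) {
  stopifnot(length(maps) == nrow(tree$edge))
  for (e in seq_along(maps)) {
    if (abs(sum(maps[[e]]) - tree$edge.length[e]) >
        1e-9 * max(1, tree$edge.length[e])) {
      stop("segment durations do not sum to branch length on edge ", e)
    }
  }
  tree$maps <- maps
  tree$node.states <- node_states
  class(tree) <- c("regime_map", "phylo")
  tree
}

#' Regimes present in a map
#' @param map A `"regime_map"`.
#' @return Character vector of regime labels (sorted).
#' @export
map_regimes <- function(map) {
  sort(unique(unlist(lapply(map$maps, names))))
}

#' Tip regimes of a map
#' @param map A `"regime_map"`.
#' @return Character vector named by tip label: the regime at each tip.
#' @export
tip_regimes <- function(map) {
  nt <- length(map$tip.label)
  out <- character(nt)
  for (i in seq_len(nt)) {
    e <- which(map$edge[, 2] == i)
    seg <- map$maps[[e]]
    out[i] <- names(seg)[length(seg)]
  }
  names(out) <- map$tip.label
  out
}
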