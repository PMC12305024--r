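# Phylogenetic regression machinery: tree I/O, pruning, Pagel's-lambda
# correlation structure, PGLS, and AICc model comparison.

#' Read a Newick tree
#'
#' @param path Newick file; branch lengths required.
#' @return An `ape::phylo` tree (polytomies allowed).
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("parse error: not a valid Newick file: ", path)
  if (is.null(tree$edge.length)) stop("parse error: tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("parse error: missing branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Prune a tree to a species set
#'
#' Induced subtree on `keep`; degree-2 nodes collapsed with branch lengths
#' summed (ape's standard behaviour).
#'
#' @param tree `phylo`.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return Pruned `phylo`.
#' @export
prune <- function(tree, keep) {
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("cannot prune to fewer than 2 tips")
  ape::keep.tip(tree, keep)
}

# Tree depth (max root-to-tip distance).
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= tol * max(d)
}

#' Phylogenetic correlation matrix with Pagel's lambda
#'
#' For an ultrametric tree, `C_ij` is the shared root-to-tip path length of
#' tips i and j divided by tree depth, with off-diagonals multiplied by
#' `lambda`; the diagonal is 1. For non-ultrametric trees with `lambda < 1`
#' the covariance form (shared path length, off-diagonals scaled) is used
#' with a warning.
#'
#' @param tree `phylo`.
#' @param lambda Pagel's lambda in \[0, 1\]; default 1.
#' @return List of class `"phylo_correlation"`: `C` (species x species),
#'   `lambda`.
#' @export
phylo_correlation <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  V <- ape::vcv(tree)
  if (is_ultrametric(tree)) {
    C <- V / tree_depth(tree)
  } else {
    if (lambda < 1) {
      warning("non-ultrametric tree: using covariance (not correlation) form")
    }
    C <- V / max(diag(V))
  }
  od <- row(C) != col(C)
  C[od] <- C[od] * lambda
  structure(list(C = C, lambda = lambda), class = "phylo_correlation")
}

# Shared log-likelihood pieces for GLS with V = sigma2 * C.
.gls_core <- function(y, X, C) {
  n <- length(y)
  p <- ncol(X)
  ch <- tryCatch(chol(C), error = function(e)
    stop("correlation matrix not positive definite"))
  logdetC <- 2 * sum(log(diag(ch)))
  w <- backsolve(ch, forwardsolve(t(ch), cbind(y, X)))
  yt <- w[, 1]
  Xt <- w[, -1, drop = FALSE]
  # whitened OLS
  XtX <- crossprod(Xt, X)      # X' C^-1 X
  Xty <- crossprod(Xt, y)      # X' C^-1 y
  qrX <- qr(XtX)
  if (qrX$rank < p) stop("rank-deficient design matrix")
  beta <- solve(qrX, Xty)
  resid <- y - X %*% beta
  rC <- backsolve(ch, forwardsolve(t(ch), resid))
  rss <- sum(resid * rC)       # r' C^-1 r
  sigma2_ml <- rss / n
  sigma2_reml <- rss / (n - p)
  logdetXtX <- determinant(XtX, logarithm = TRUE)$modulus
  logLik_ml <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  # REML: -0.5 [ (n-p) log(2 pi s2) + log|C| + log|X' C^-1 X| + (n-p) ]
  logLik_reml <- -0.5 * ((n - p) * log(2 * pi * sigma2_reml) + logdetC +
                           logdetXtX + (n - p))
  vcov_beta <- sigma2_reml * solve(XtX)
  list(beta = drop(beta), vcov = vcov_beta, sigma2_ml = sigma2_ml,
       sigma2_reml = sigma2_reml, logLik_ml = as.numeric(logLik_ml),
       logLik_reml = as.numeric(logLik_reml), rss = rss, n = n, p = p)
}

#' Phylogenetic generalized least squares
#'
#' GLS with residual covariance `sigma2 * C`, `C` a phylogenetic correlation
#' matrix (Pagel's lambda fixed, default 1). Coefficients, t-statistics,
#' ML/REML sigma2 and log-likelihoods, and AICc are returned; nested models
#' can be compared with [mixed_lrt()] on the ML log-likelihoods.
#'
#' @param y Named numeric response (names = species) or numeric vector
#'   aligned with `rownames(C)`.
#' @param X Design matrix or data.frame of fixed effects (intercept added if
#'   absent); rows aligned to species.
#' @param corr A [phylo_correlation()], or a correlation matrix.
#' @return Object of class `"pgls_fit"` (also `"model_fit"`).
#' @export
pgls_fit <- function(y, X = NULL, corr) {
  C <- if (inherits(corr, "phylo_correlation")) corr$C else as.matrix(corr)
  sp <- rownames(C)
  if (!is.null(names(y)) && !is.null(sp)) {
    missing_sp <- setdiff(names(y), sp)
    if (length(missing_sp)) {
      stop("species in data not in tree: ", paste(missing_sp, collapse = ", "))
    }
    C <- C[names(y), names(y)]
  }
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- stats::model.matrix(~., data = as.data.frame(X))
  }
  core <- .gls_core(as.numeric(y), X, C)
  k <- core$p + 1L  # + sigma2
  tval <- core$beta / sqrt(diag(core$vcov))
  pval <- 2 * stats::pt(-abs(tval), df = n - core$p)
  structure(list(
    coefficients = core$beta, se = sqrt(diag(core$vcov)), t = tval, p = pval,
    sigma2_ml = core$sigma2_ml, sigma2_reml = core$sigma2_reml,
    logLik_ml = core$logLik_ml, logLik_reml = core$logLik_reml,
    AICc = aicc(core$logLik_ml, k, n), n = n, k = k, df_residual = n - core$p
  ), class = c("pgls_fit", "model_fit"))
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<pgls_fit>\n")
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p))
  cat(sprintf("sigma2 (ML) = %.4g, logLik (ML) = %.4f, AICc = %.4f\n",
              x$sigma2_ml, x$logLik_ml, x$AICc))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size.
#' @return Scalar AICc (`Inf` when `n <= k + 1`).
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank model fits by AICc
#'
#' @param fits Named list of fits, each with `AICc` and `n` fields (e.g.
#'   [pgls_fit()], [mixed_fit()], [fit_model()] results).
#' @param threshold Fits within `threshold` AICc of the best are flagged
#'   equivalent (default 2).
#' @return data.frame sorted by AICc with `delta_AICc` and `equivalent`.
#' @export
compare_models <- function(fits, threshold = 2) {
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) as.numeric(f$n), numeric(1))
  if (length(unique(ns)) != 1L) stop("fits use different numbers of observations")
  a <- vapply(fits, function(f) as.numeric(f$AICc), numeric(1))
  out <- data.frame(model = names(fits), AICc = a,
                    delta_AICc = a - min(a))
  out$equivalent <- out$delta_AICc < threshold
  out[order(out$AICc), , drop = FALSE]
}
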