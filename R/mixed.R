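# Gaussian mixed models with optional level correlations (phylogenetic
# random effects), estimated by ML or REML over log-variances.

# Build the n x n covariance contribution Z K Z' of one random term.
.term_cov <- function(f, K, n) {
  f <- as.factor(f)
  Z <- stats::model.matrix(~ f - 1)
  if (is.null(K)) {
    tcrossprod(Z)
  } else {
    K <- as.matrix(K)
    lev <- levels(f)
    if (!is.null(rownames(K))) {
      missing_lev <- setdiff(lev, rownames(K))
      if (length(missing_lev)) {
        stop("levels missing from correlation matrix: ",
             paste(missing_lev, collapse = ", "))
      }
      K <- K[lev, lev]
    }
    Z %*% K %*% t(Z)
  }
}

#' Gaussian mixed model with correlated random effects
#'
#' Fits `y = X beta + sum_u b_u + e` where each random term `u` contributes
#' `b_u ~ N(0, sigma2_u * Z_u K_u Z_u')` (with `K_u` an optional
#' level-correlation matrix, e.g. the phylogenetic correlation for species)
#' and, optionally, `e ~ N(0, sigma2_e I)`. Variance components are
#' estimated by maximizing the ML or REML Gaussian likelihood over
#' log-variances (bounded quasi-Newton, multi-start on failure); fixed
#' effects are profiled by GLS.
#'
#' @param y Numeric response, one element per observation.
#' @param X Fixed-effect design (matrix or data.frame; intercept added for
#'   data.frames); `NULL` for intercept-only.
#' @param random Named list of random terms: each either a grouping factor,
#'   or a list `list(f = factor, C = correlation matrix)`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param residual Include an iid residual variance? Default TRUE. With
#'   `FALSE`, the last random term's covariance absorbs the residual
#'   structure (e.g. a pure phylogenetic GLS).
#' @param n_starts Extra random restarts if the first optimization fails to
#'   improve (default 3).
#' @return Object of class `"mixed_fit"` / `"model_fit"`: coefficients with
#'   standard errors, `varcomp` (named variances incl. `residual`),
#'   `logLik_ml`, `logLik_reml`, `AICc`, `n`, `k`, `convergence`.
#' @export
mixed_fit <- function(y, X = NULL, random = list(), method = c("REML", "ML"),
                      residual = TRUE, n_starts = 3) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) {
    Xm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (is.matrix(X)) {
    Xm <- X
  } else {
    Xm <- stats::model.matrix(~., data = as.data.frame(X))
  }
  p <- ncol(Xm)
  if (!length(random) && residual) {
    # plain OLS via the GLS core
    core <- .gls_core(y, Xm, diag(n))
    vc <- c(residual = if (method == "REML") core$sigma2_reml else core$sigma2_ml)
    k <- p + 1
    return(structure(list(
      coefficients = core$beta, se = sqrt(diag(core$vcov)),
      varcomp = vc, logLik_ml = core$logLik_ml,
      logLik_reml = core$logLik_reml, AICc = aicc(core$logLik_ml, k, n),
      n = n, k = k, method = method, convergence = 0L
    ), class = c("mixed_fit", "model_fit")))
  }
  if (!length(random)) stop("residual = FALSE requires at least one random term")
  covs <- lapply(random, function(term) {
    if (is.list(term)) .term_cov(term$f, term$C, n) else .term_cov(term, NULL, n)
  })
  if (residual) covs <- c(covs, list(diag(n)))
  nv <- length(covs)
  vnames <- c(names(random), if (residual) "residual")

  obj <- function(logv) {
    v <- exp(pmax(logv, -20))
    V <- Reduce(`+`, Map(`*`, v, covs))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    W <- backsolve(ch, forwardsolve(t(ch), cbind(y, Xm)))
    XtVX <- crossprod(W[, -1, drop = FALSE], Xm)
    XtVy <- crossprod(W[, -1, drop = FALSE], y)
    beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    r <- y - Xm %*% beta
    rVr <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
    if (method == "ML") {
      0.5 * (n * log(2 * pi) + logdetV + rVr)
    } else {
      ld2 <- determinant(XtVX, logarithm = TRUE)$modulus
      0.5 * ((n - p) * log(2 * pi) + logdetV + as.numeric(ld2) + rVr)
    }
  }

  vy <- stats::var(y)
  start0 <- rep(log(vy / nv), nv)
  best <- NULL
  set_starts <- list(start0)
  for (i in seq_len(n_starts)) {
    set_starts[[i + 1]] <- start0 + (i - 2) * 1.5
  }
  for (st in set_starts) {
    opt <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B",
                   lower = rep(-20, nv), upper = rep(20, nv),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(best) && best$convergence == 0 && st[1] == start0[1]) break
  }
  if (is.null(best)) stop("mixed-model optimization failed on all starts")
  v <- exp(pmax(best$par, -20))
  names(v) <- vnames

  # final fixed-effect solve and both likelihoods at the optimum
  V <- Reduce(`+`, Map(`*`, v, covs))
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  W <- backsolve(ch, forwardsolve(t(ch), cbind(y, Xm)))
  XtVX <- crossprod(W[, -1, drop = FALSE], Xm)
  beta <- solve(XtVX, crossprod(W[, -1, drop = FALSE], y))
  r <- y - Xm %*% beta
  rVr <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
  ld2 <- as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
  logLik_ml <- -0.5 * (n * log(2 * pi) + logdetV + rVr)
  logLik_reml <- -0.5 * ((n - p) * log(2 * pi) + logdetV + ld2 + rVr)
  vcov_beta <- solve(XtVX)
  k <- p + nv
  structure(list(
    coefficients = drop(beta), se = sqrt(diag(vcov_beta)),
    varcomp = v, logLik_ml = logLik_ml, logLik_reml = logLik_reml,
    AICc = aicc(logLik_ml, k, n), n = n, k = k, method = method,
    convergence = best$convergence
  ), class = c("mixed_fit", "model_fit"))
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> (", x$method, ")\n", sep = "")
  print(data.frame(estimate = x$coefficients, se = x$se))
  cat("variance components:\n")
  print(x$varcomp)
  cat(sprintf("logLik ML = %.4f, REML = %.4f, AICc = %.4f\n",
              x$logLik_ml, x$logLik_reml, x$AICc))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' Uses the ML log-likelihoods of two nested fits (same observations).
#'
#' @param full,reduced Fits with `logLik_ml`, `k` and `n` fields.
#' @return List: `chisq`, `df`, `p`.
#' @export
mixed_lrt <- function(full, reduced) {
  if (full$n != reduced$n) stop("fits use different numbers of observations")
  df <- full$k - reduced$k
  if (df <= 0) stop("'full' must have more parameters than 'reduced'")
  chisq <- 2 * (full$logLik_ml - reduced$logLik_ml)
  list(chisq = chisq, df = df,
       p = stats::pchisq(max(chisq, 0), df, lower.tail = FALSE))
}
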