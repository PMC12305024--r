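# Standardized major axis (SMA) allometry: per-group line fits plus the
# three between-group shift tests (common slope / elevation a.k.a. grade
# shift / shift along the common axis), following Warton et al. (2006).

# Per-group SMA line: slope = sign(r) * sd(y)/sd(x), elevation through the
# centroid.
.sma_group <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("n < 3 in a group")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in a group")
  r <- stats::cor(x, y)
  b <- sign(r) * sy / sx
  if (b == 0) b <- sy / sx
  a <- mean(y) - b * mean(x)
  # large-sample SE of the SMA slope (Warton et al. 2006)
  se_b <- abs(b) * sqrt((1 - r^2) / n) / max(abs(r), 1e-12)
  list(n = n, slope = b, elevation = a, r = r, se_slope = se_b,
       mean_x = mean(x), mean_y = mean(y), var_x = sx^2, var_y = sy^2)
}

# Correlation between residual (y - b x) and fitted (y + b x) scores within
# one group, as a function of the candidate common slope b. A degenerate
# (perfectly collinear) group has zero residual variance at the true slope:
# treat as correlation 0 (perfect fit of the common slope).
.rrf <- function(x, y, b) {
  rs <- y - b * x
  fs <- y + b * x
  if (stats::var(rs) < 1e-24 * max(stats::var(fs), 1e-300)) return(0)
  stats::cor(rs, fs)
}

#' Standardized major axis fits and shift tests
#'
#' Fits an SMA line per group and, for multiple groups, tests for (i) a
#' common slope (likelihood-ratio statistic on residual-vs-fitted score
#' correlations, chi-square with g-1 df), then assuming the common slope
#' (ii) elevation (grade) shifts via a Wald test on group means of residual
#' scores `y - b x`, and (iii) shifts along the common axis via a Wald test
#' on group means of fitted scores `y + b x`.
#'
#' @param x,y Numeric vectors.
#' @param groups Factor/character of group labels (`NULL` for a single
#'   group).
#' @return Object of class `"sma_fit"`: `groups` (per-group data.frame),
#'   `common_slope`, `slope_test`, `elevation_test`, `shift_test` (each a
#'   list with `stat`, `df`, `p`).
#' @export
sma_fit <- function(x, y, groups = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(groups)) groups <- rep("all", length(x)) else groups <- groups[ok]
  g <- split(seq_along(x), as.character(groups))
  fits <- lapply(g, function(i) .sma_group(x[i], y[i]))
  per_group <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(group = nm, n = f$n, slope = f$slope, elevation = f$elevation,
               r = f$r, se_slope = f$se_slope)
  }))
  out <- list(groups = per_group, common_slope = NULL, slope_test = NULL,
              elevation_test = NULL, shift_test = NULL)
  if (length(g) < 2L) {
    out$common_slope <- per_group$slope[1]
    class(out) <- "sma_fit"
    return(out)
  }
  # common-slope estimate: minimize the LR statistic over b (all group
  # slopes share a sign here; search on log|b|)
  signs <- sign(per_group$slope)
  s <- if (all(signs > 0)) 1 else if (all(signs < 0)) -1 else
    sign(sum(per_group$n * per_group$slope))
  lr_stat <- function(logb) {
    b <- s * exp(logb)
    sum(vapply(g, function(i) {
      ni <- length(i)
      r2 <- min(.rrf(x[i], y[i], b)^2, 1 - 1e-15)
      -(ni - 2.5) * log(1 - r2)
    }, numeric(1)))
  }
  df_slope <- length(g) - 1L
  if (diff(range(per_group$slope)) < 1e-10 &&
      all(abs(per_group$r) > 1 - 1e-9)) {
    # perfectly collinear groups with identical slopes: exact common slope
    b_com <- per_group$slope[1]
    stat <- 0
  } else {
    rng <- log(range(abs(per_group$slope)))
    opt <- stats::optimize(lr_stat, lower = rng[1] - 2, upper = rng[2] + 2)
    b_com <- s * exp(opt$minimum)
    stat <- opt$objective
  }
  out$common_slope <- b_com
  out$slope_test <- list(stat = stat, df = df_slope,
                         p = stats::pchisq(stat, df_slope,
                                           lower.tail = FALSE))
  # variance of the common slope: inverse-variance pooling of group slopes
  var_b <- 1 / sum(1 / vapply(fits, function(f) f$se_slope^2, numeric(1)))
  wald <- function(score_fun, slope_term_sign) {
    m <- vapply(g, function(i) mean(score_fun(x[i], y[i])), numeric(1))
    v <- vapply(g, function(i) {
      stats::var(score_fun(x[i], y[i])) / length(i)
    }, numeric(1))
    # slope uncertainty propagates through the group mean of x
    mx <- vapply(g, function(i) mean(x[i]), numeric(1))
    v <- pmax(v + mx^2 * var_b, 1e-20)
    mbar <- sum(m / v) / sum(1 / v)
    stat <- sum((m - mbar)^2 / v)
    list(stat = stat, df = length(g) - 1L,
         p = stats::pchisq(stat, length(g) - 1L, lower.tail = FALSE))
  }
  out$elevation_test <- wald(function(xx, yy) yy - b_com * xx, -1)
  out$shift_test <- wald(function(xx, yy) yy + b_com * xx, +1)
  class(out) <- "sma_fit"
  out
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("<sma_fit>\n")
  print(x$groups)
  if (!is.null(x$slope_test)) {
    cat(sprintf("common slope %.4f; slope test p = %.4g; elevation p = %.4g; shift p = %.4g\n",
                x$common_slope, x$slope_test$p, x$elevation_test$p,
                x$shift_test$p))
  }
  invisible(x)
}
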