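# Canopy-openness estimation from upward-facing 180-degree hemispherical
# photographs: blue-channel extraction, Otsu thresholding inside the fisheye
# circle, zenith-ring x azimuth-segment gap fractions, solid-angle-weighted
# openness over the 0-70 degree cap.

#' Wrap a pixel grid as a fisheye image
#'
#' @param pixels Numeric matrix (grayscale, rows x cols) or 3-d array
#'   (rows x cols x 3, RGB). Values on any consistent scale (0-1 or 0-255).
#' @param center Circle center `c(row, col)`; default image center.
#' @param radius_px Fisheye circle radius in pixels; default the largest
#'   inscribed radius.
#' @param projection Radial mapping to zenith angle; only `"equidistant"`
#'   (zenith proportional to radial distance, 90 deg at `radius_px`) is
#'   implemented.
#' @return Object of class `"fisheye"`.
#' @export
fisheye_image <- function(pixels, center = NULL, radius_px = NULL,
                          projection = "equidistant") {
  d <- dim(pixels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop("pixels must be a matrix or rows x cols x 3 array")
  }
  projection <- match.arg(projection, "equidistant")
  nr <- d[1]; nc <- d[2]
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  if (is.null(radius_px)) radius_px <- min(nr, nc) / 2
  if (radius_px <= 0) stop("radius must be > 0")
  structure(list(pixels = pixels, center = center, radius_px = radius_px,
                 projection = projection),
            class = "fisheye")
}

#' Read a PNG file as a fisheye image
#'
#' @param path PNG file.
#' @param ... Passed to [fisheye_image()].
#' @return A `"fisheye"` object; RGB kept as a 3-channel array.
#' @export
read_fisheye_png <- function(path, ...) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG requires the png package")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L) px <- px[, , 1:3]
  fisheye_image(px, ...)
}

#' Extract the blue channel
#'
#' Sky/canopy contrast is best in the blue plane; geometry is unchanged.
#' A grayscale input is passed through with a warning.
#'
#' @param img A `"fisheye"` image.
#' @return Grayscale `"fisheye"` image.
#' @export
extract_blue <- function(img) {
  stopifnot(inherits(img, "fisheye"))
  px <- img$pixels
  if (length(dim(px)) == 2L) {
    warning("input already grayscale; passing through")
    return(img)
  }
  img$pixels <- px[, , 3]
  img
}

# Logical mask of pixels inside the fisheye circle (optionally only the
# zenith <= zenith_max part of it).
.inside_circle <- function(img, zenith_max = 90) {
  d <- dim(img$pixels)
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  dist <- sqrt((rr - img$center[1])^2 + (cc - img$center[2])^2)
  dist <= img$radius_px * (zenith_max / 90)
}

#' Otsu threshold of a grayscale vector
#'
#' Exhaustive search over a 256-bin histogram for the threshold maximizing
#' between-class variance.
#'
#' @param values Numeric vector of pixel intensities.
#' @return The threshold (on the input scale); pixels strictly above it are
#'   classed as sky.
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) stop("degenerate-histogram error: constant image")
  nbins <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(values, breaks, all.inside = TRUE), nbins),
                nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nbins])
  breaks[k + 1L]
}

#' Binarize a fisheye image by Otsu's method
#'
#' The threshold is computed over pixels inside the fisheye circle only;
#' pixels above it become sky (1), the rest canopy (0).
#'
#' @param img Grayscale `"fisheye"` image.
#' @return `"fisheye"` image whose pixels are 0/1 (outside-circle pixels NA),
#'   with the threshold stored in `$threshold`.
#' @export
binarize_otsu <- function(img) {
  stopifnot(inherits(img, "fisheye"))
  if (length(dim(img$pixels)) != 2L) stop("binarize_otsu expects grayscale")
  inside <- .inside_circle(img)
  thr <- otsu_threshold(img$pixels[inside])
  bin <- matrix(NA_real_, nrow(img$pixels), ncol(img$pixels))
  bin[inside] <- as.numeric(img$pixels[inside] > thr)
  img$pixels <- bin
  img$threshold <- thr
  img
}

#' Gap fractions on a zenith-ring by azimuth-segment grid
#'
#' Tabulates the sky fraction of a binary fisheye image in (by default) seven
#' 10-degree zenith rings over 0-70 degrees crossed with eight 45-degree
#' azimuth segments, using the equidistant projection (zenith angle
#' proportional to radial pixel distance, 90 degrees at the circle radius).
#'
#' @param bin Binarized `"fisheye"` image from [binarize_otsu()] (or any
#'   0/1 pixel grid wrapped by [fisheye_image()]).
#' @param n_rings,n_segments Grid dimensions.
#' @param zenith_max_deg Outer zenith bound of the analyzed cap (degrees).
#' @return Object of class `"gap_grid"`: a `n_rings x n_segments` matrix of
#'   gap fractions with ring/segment bounds and pixel counts attached.
#' @export
gap_fraction_grid <- function(bin, n_rings = 7L, n_segments = 8L,
                              zenith_max_deg = 70) {
  stopifnot(inherits(bin, "fisheye"))
  px <- bin$pixels
  if (length(dim(px)) != 2L) stop("binary grayscale image required")
  vals <- unique(px[is.finite(px)])
  if (!all(vals %in% c(0, 1))) stop("image is not binary")
  d <- dim(px)
  rr <- matrix(seq_len(d[1]), d[1], d[2]) - bin$center[1]
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - bin$center[2]
  dist <- sqrt(rr^2 + cc^2)
  zen <- 90 * dist / bin$radius_px
  if (bin$radius_px * (zenith_max_deg / 90) < n_rings) {
    stop("resolution error: analyzed cap spans fewer pixels than rings")
  }
  az <- (atan2(cc, -rr) * 180 / pi) %% 360  # 0 = up, clockwise; convention only
  sel <- is.finite(px) & zen < zenith_max_deg
  ring_bounds <- seq(0, zenith_max_deg, length.out = n_rings + 1L)
  seg_bounds <- seq(0, 360, length.out = n_segments + 1L)
  ri <- pmin(findInterval(zen[sel], ring_bounds, all.inside = TRUE), n_rings)
  si <- pmin(findInterval(az[sel], seg_bounds, all.inside = TRUE), n_segments)
  idx <- (si - 1L) * n_rings + ri
  npix <- tabulate(idx, n_rings * n_segments)
  sky <- rowsum(px[sel], idx)
  gf <- matrix(NA_real_, n_rings, n_segments)
  gf[as.integer(rownames(sky))] <- sky / npix[as.integer(rownames(sky))]
  gf[matrix(npix == 0L, n_rings, n_segments)] <- NA_real_
  structure(gf,
            ring_bounds_deg = ring_bounds, segment_bounds_deg = seg_bounds,
            n_pixels = matrix(npix, n_rings, n_segments),
            class = c("gap_grid", "matrix"))
}

#' Canopy openness from a gap-fraction grid
#'
#' Averages gap fraction over azimuth within each zenith ring, then combines
#' rings. With `weighting = "solid_angle"` (default) ring r gets weight
#' \eqn{(\cos\theta_{lo} - \cos\theta_{hi})/(1 - \cos\theta_{max})}, i.e. the
#' fraction of the analyzed spherical cap it subtends; `"mean"` weights rings
#' equally.
#'
#' @param g A `"gap_grid"`.
#' @param weighting `"solid_angle"` or `"mean"`.
#' @return Openness in percent (0-100).
#' @export
canopy_openness <- function(g, weighting = c("solid_angle", "mean")) {
  stopifnot(inherits(g, "gap_grid"))
  weighting <- match.arg(weighting)
  ring_gf <- rowMeans(unclass(g), na.rm = TRUE)
  if (any(!is.finite(ring_gf))) {
    stop("estimation error: ring(s) with no pixels: ",
         paste(which(!is.finite(ring_gf)), collapse = ", "))
  }
  rb <- attr(g, "ring_bounds_deg") * pi / 180
  if (weighting == "solid_angle") {
    w <- (cos(rb[-length(rb)]) - cos(rb[-1])) / (1 - cos(rb[length(rb)]))
  } else {
    w <- rep(1 / length(ring_gf), length(ring_gf))
  }
  100 * sum(w * ring_gf)
}

#' Canopy openness for a whole image
#'
#' Convenience wrapper: blue channel (if RGB), Otsu binarization, gap
#' fractions, openness.
#'
#' @param img A `"fisheye"` image.
#' @param ... Passed to [gap_fraction_grid()] / [canopy_openness()].
#' @param weighting See [canopy_openness()].
#' @return List: `openness_pct`, `threshold`, `gap_grid`.
#' @export
estimate_openness <- function(img, weighting = "solid_angle", ...) {
  if (length(dim(img$pixels)) == 3L) img <- extract_blue(img)
  bin <- binarize_otsu(img)
  g <- gap_fraction_grid(bin, ...)
  list(openness_pct = canopy_openness(g, weighting = weighting),
       threshold = bin$threshold, gap_grid = g)
}
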