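# Flight-related wing morphometrics from dorsal silhouettes: segmentation,
# surface area, moment-ellipse aspect ratio, wing loading.

#' Segment a wing silhouette
#'
#' Otsu-thresholds a grayscale image, keeps the largest connected foreground
#' component (4-connectivity) and fills interior holes. The wing is assumed
#' lighter than the background by default.
#'
#' @param img Numeric matrix (grayscale) or rows x cols x 3 RGB array
#'   (averaged to grayscale).
#' @param foreground `"light"` (default) or `"dark"`: which Otsu class is
#'   the wing.
#' @return Logical matrix mask.
#' @export
segment_wing <- function(img, foreground = c("light", "dark")) {
  foreground <- match.arg(foreground)
  if (length(dim(img)) == 3L) img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  thr <- otsu_threshold(as.numeric(img))
  fg <- if (foreground == "light") img > thr else img <= thr
  if (!any(fg)) stop("segmentation error: no foreground component")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  fill_holes(mask)
}

#' Label connected components of a binary mask
#'
#' Iterative BFS flood fill, 4-connectivity.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (d in 1:4) {
        rr <- r + c(-1L, 1L, 0L, 0L)[d]
        cc <- cl + c(0L, 0L, -1L, 1L)[d]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        nb <- (cc[ok] - 1L) * nr + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Fill interior holes of a binary mask
#'
#' Background connected to the image border stays background; enclosed
#' background becomes foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- !mask
  # flood the border-connected background by labelling bg components and
  # keeping those that touch the border
  lab <- label_components(bg)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0L]
  mask | !(lab %in% border_labs & lab > 0L) & bg
}

#' Wing surface area
#'
#' @param mask Logical matrix from [segment_wing()].
#' @param scale_mm_per_px Image scale (mm per pixel), > 0.
#' @return Area in mm^2 (pixel count times scale squared).
#' @export
wing_area <- function(mask, scale_mm_per_px) {
  if (scale_mm_per_px <= 0) stop("scale must be > 0")
  n <- sum(mask)
  if (n == 0L) stop("empty mask")
  n * scale_mm_per_px^2
}

#' Wing aspect ratio
#'
#' Ratio of the major to minor axis lengths of the ellipse with the same
#' second central moments as the mask (default), or of the axis-aligned
#' bounding box (`method = "bbox"`). Always >= 1; invariant to rotation and
#' uniform scaling (moment method).
#'
#' @param mask Logical matrix.
#' @param method `"moments"` (default) or `"bbox"`.
#' @return Scalar aspect ratio.
#' @export
wing_aspect_ratio <- function(mask, method = c("moments", "bbox")) {
  method <- match.arg(method)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("degenerate mask")
  if (method == "bbox") {
    ext <- c(diff(range(idx[, 1])) + 1, diff(range(idx[, 2])) + 1)
    return(max(ext) / min(ext))
  }
  xy <- sweep(idx, 2, colMeans(idx))
  # + 1/12: each pixel is a unit square, not a point
  cv <- crossprod(xy) / nrow(xy) + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) stop("degenerate (collinear) mask")
  sqrt(ev[1] / ev[2])
}

#' Wing loading
#'
#' Body mass divided by forewing area.
#'
#' @param mass_g Body mass (g), >= 0.
#' @param area_mm2 Forewing area (mm^2), > 0.
#' @return Wing loading in g mm^-2.
#' @export
wing_loading <- function(mass_g, area_mm2) {
  if (any(area_mm2 <= 0)) stop("area must be > 0")
  if (any(mass_g < 0)) stop("mass must be >= 0")
  mass_g / area_mm2
}

#' Wing metrics for one specimen
#'
#' @param img Image (matrix or RGB array) of a single dorsal forewing.
#' @param scale_mm_per_px Scale, mm per pixel.
#' @param mass_g Optional body mass (g) for wing loading.
#' @param damaged Logical flag; damaged wings return NA metrics.
#' @param ... Passed to [segment_wing()].
#' @return data.frame: `area_mm2`, `aspect_ratio`, `wing_loading_g_per_mm2`.
#' @export
wing_metrics <- function(img, scale_mm_per_px, mass_g = NA_real_,
                         damaged = FALSE, ...) {
  if (isTRUE(damaged)) {
    return(data.frame(area_mm2 = NA_real_, aspect_ratio = NA_real_,
                      wing_loading_g_per_mm2 = NA_real_))
  }
  mask <- segment_wing(img, ...)
  area <- wing_area(mask, scale_mm_per_px)
  data.frame(
    area_mm2 = area,
    aspect_ratio = wing_aspect_ratio(mask),
    wing_loading_g_per_mm2 = if (is.na(mass_g)) NA_real_ else
      wing_loading(mass_g, area))
}
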