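#' Neighborhood distance of every pixel to an intensity level
#'
#' For each pixel i, computes the rough-set distance
#' \deqn{d_i(g) = \sum_{m \in \partial_i} \|x_m - g\|^2 / (n (J_{max}-J_{min}))}
#' over the 3 x 3 neighborhood \eqn{\partial_i} (n = 9, replicate padding at
#' the borders). For multichannel images the squared term is the squared
#' Euclidean norm over channels and the intensity span is taken over all
#' channels.
#'
#' @param image numeric matrix (h x w) or h x w x D array.
#' @param level intensity level g: scalar, or vector of length D.
#' @param pixel optional single pixel index (column-major); if `NULL` the full
#'   h x w distance field is returned.
#' @return numeric h x w matrix of distances, or a single value when `pixel`
#'   is given.
#' @examples
#' img <- matrix(0, 3, 3); img[2, 2] <- 1
#' distance_to_level(img, 0.5, pixel = 5)  # center pixel
#' @export
distance_to_level <- function(image, level, pixel = NULL) {
  pm <- as_pixmat(image)
  span <- intensity_span(image)
  if (span <= 0) stop("degenerate intensity scale: J_max = J_min", call. = FALSE)
  level <- rep_len(as.numeric(level), pm$d)
  dmat <- box9(sqdist_field(pm, level)) / (9 * span)
  if (is.null(pixel)) dmat else dmat[pixel]
}

#' Adaptive rough-set thresholds of an image
#'
#' Computes the two thresholds that bound the rough regions:
#' t1 is the mean over pixels of the minimum neighborhood distance to any
#' intensity level, t2 the mean over pixels of the mean distance over levels.
#' By construction t1 <= t2.
#'
#' Levels default to the integer levels spanning the intensity range for
#' integer-valued images (8-bit convention, at most 256), and to 64 uniformly
#' spaced values between the global minimum and maximum otherwise; for
#' multichannel images the scalar levels are replicated across channels.
#'
#' @param image numeric matrix or h x w x D array.
#' @param levels optional numeric vector of scalar intensity levels.
#' @return object of class `threshold_pair`: named list with `t1`, `t2`.
#' @export
compute_thresholds <- function(image, levels = NULL) {
  pm <- as_pixmat(image)
  span <- intensity_span(image)
  if (span <= 0) stop("degenerate intensity scale: J_max = J_min", call. = FALSE)
  if (is.null(levels)) levels <- default_levels(image)
  levels <- as.numeric(levels)
  if (length(levels) == 0L) stop("empty level set", call. = FALSE)

  # d_i(g) expands to [B2 - 2 g B1 + 9 D g^2] / (9 span) with box sums of x, x^2
  b1 <- matrix(0, pm$h, pm$w); b2 <- matrix(0, pm$h, pm$w)
  for (c in seq_len(pm$d)) {
    xc <- field(pm$x[, c], pm$h, pm$w)
    b1 <- b1 + box9(xc)
    b2 <- b2 + box9(xc * xc)
  }
  dmin <- NULL; dsum <- matrix(0, pm$h, pm$w)
  for (g in levels) {
    dg <- (b2 - 2 * g * b1 + 9 * pm$d * g * g) / (9 * span)
    dsum <- dsum + dg
    dmin <- if (is.null(dmin)) dg else pmin(dmin, dg)
  }
  out <- list(t1 = mean(dmin), t2 = mean(dsum) / length(levels))
  class(out) <- "threshold_pair"
  out
}

default_levels <- function(image) {
  v <- as.numeric(image)
  rng <- range(v, finite = TRUE)
  if (all(v == round(v)) && (rng[2L] - rng[1L]) <= 255) {
    seq(rng[1L], rng[2L], by = 1)
  } else {
    seq(rng[1L], rng[2L], length.out = 64L)
  }
}

#' Graded bounded-support indicator
#'
#' Piecewise-linear membership in a cluster's bounded support: 1 at or below
#' t1 (positive region), a linear ramp (t2 - d)/(t2 - t1) between the
#' thresholds (boundary region), 0 beyond t2 (negative region). Non-increasing
#' and continuous in the distance.
#'
#' @param distance numeric vector/matrix of rough-set distances.
#' @param thresholds a `threshold_pair` (or list with `t1`, `t2`).
#' @return values in `[0, 1]`, same shape as `distance`.
#' @export
bounded_indicator <- function(distance, thresholds) {
  t1 <- thresholds$t1; t2 <- thresholds$t2
  if (t1 > t2) stop("t1 > t2", call. = FALSE)
  if (t1 == t2) {
    warning("t1 == t2: boundary band collapsed to a hard indicator")
    return(ifelse(distance <= t1, 1, 0) * 1)
  }
  h <- (t2 - distance) / (t2 - t1)
  pmin(pmax(h, 0), 1)
}

#' Bounded indicator for a point off the pixel lattice
#'
#' Evaluates the bounded-support indicator for arbitrary intensity vectors
#' (e.g. Monte-Carlo samples), using the neighborhood-free (n = 1) form of the
#' rough-set distance \eqn{\|x - \mu_k\|^2 / (J_{max}-J_{min})}.
#'
#' @param x numeric vector (one point, length D) or n x D matrix of points.
#' @param mean cluster mean vector (length D).
#' @param thresholds a `threshold_pair`.
#' @param scale intensity span J_max - J_min (> 0).
#' @return indicator values in `[0, 1]`, one per point.
#' @export
point_indicator <- function(x, mean, thresholds, scale) {
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  dd <- sweep(x, 2L, mean)
  d <- rowSums(dd * dd) / scale
  bounded_indicator(d, thresholds)
}

#' Assign per-cluster rough regions
#'
#' Labels every pixel, for every cluster k, as positive (Po: d_i(mu_k) <= t1),
#' boundary (Bo: t1 < d <= t2) or negative (Ne: d > t2) from the neighborhood
#' distance to the cluster mean. If a pixel falls in the positive region of
#' several clusters, only the minimum-distance cluster keeps it (ties to the
#' lowest cluster index); the others are demoted to the boundary region. The
#' graded indicator is the pure distance ramp of [bounded_indicator()] and is
#' not altered by the demotion.
#'
#' @param image numeric matrix or h x w x D array.
#' @param means K x D matrix of cluster means (a vector is taken as K means of
#'   a single-channel image).
#' @param thresholds a `threshold_pair` from [compute_thresholds()].
#' @return object of class `rough_partition`: list with `region` (N x K
#'   integer, 1 = Po, 2 = Bo, 3 = Ne), `distance` (N x K), `indicator`
#'   (N x K), `thresholds`, `dim`.
#' @export
assign_rough_regions <- function(image, means, thresholds) {
  pm <- as_pixmat(image)
  if (!is.matrix(means)) means <- matrix(means, ncol = pm$d)
  K <- nrow(means)
  N <- pm$h * pm$w
  dist <- matrix(0, N, K)
  for (k in seq_len(K)) {
    dist[, k] <- as.numeric(distance_to_level(image, means[k, ]))
  }
  t1 <- thresholds$t1; t2 <- thresholds$t2
  region <- matrix(3L, N, K)
  region[dist <= t2] <- 2L
  region[dist <= t1] <- 1L
  # Po exclusivity: keep Po only for the argmin-distance cluster
  if (K > 1L) {
    npo <- rowSums(region == 1L)
    multi <- which(npo > 1L)
    if (length(multi)) {
      keep <- max.col(-dist[multi, , drop = FALSE], ties.method = "first")
      for (j in seq_along(multi)) {
        i <- multi[j]
        po <- which(region[i, ] == 1L)
        region[i, setdiff(po, keep[j])] <- 2L
      }
    }
  }
  indicator <- if (t1 == t2) {
    suppressWarnings(bounded_indicator(dist, thresholds))
  } else {
    bounded_indicator(dist, thresholds)
  }
  structure(
    list(region = region, distance = dist, indicator = indicator,
         thresholds = thresholds, dim = c(pm$h, pm$w), K = K),
    class = "rough_partition")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("rough-set thresholds: t1 = %.6g, t2 = %.6g\n", x$t1, x$t2))
  invisible(x)
}

#' @export
print.rough_partition <- function(x, ...) {
  cat(sprintf("rough partition: %d x %d pixels, K = %d clusters\n",
              x$dim[1L], x$dim[2L], x$K))
  for (k in seq_len(x$K)) {
    cat(sprintf("  cluster %d: Po %d | Bo %d | Ne %d\n", k,
                sum(x$region[, k] == 1L), sum(x$region[, k] == 2L),
                sum(x$region[, k] == 3L)))
  }
  invisible(x)
}
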