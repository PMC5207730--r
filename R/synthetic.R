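#' Generate a piecewise-constant phantom image
#'
#' Builds the synthetic test images used throughout the package: a
#' piecewise-constant label layout whose labels carry strictly increasing
#' luminance values in `[0, 1]`. Layouts: `"concentric"` (nested circles over
#' a background), `"quadrant"` (2 x 2 blocks, exactly 4 labels) and
#' `"stripes"` (equal horizontal bands). Every label occupies at least 1% of
#' the pixels.
#'
#' @param size image side length (scalar) or `c(h, w)`; default 128.
#' @param luminances strictly increasing label values in `[0, 1]`.
#' @param layout one of `"concentric"`, `"quadrant"`, `"stripes"`.
#' @return object of class `phantom`: list with `image` (h x w numeric) and
#'   `labels` (h x w integer ground truth, 1-based).
#' @examples
#' ph <- make_phantom(luminances = c(0, 1/3, 2/3, 1))
#' sort(unique(as.numeric(ph$image)))
#' @export
make_phantom <- function(size = 128L, luminances = c(0, 1/3, 2/3, 1),
                         layout = c("concentric", "quadrant", "stripes")) {
  layout <- match.arg(layout)
  size <- rep_len(as.integer(size), 2L)
  h <- size[1L]; w <- size[2L]
  nl <- length(luminances)
  if (nl < 2L) stop("need at least two luminance values", call. = FALSE)
  if (any(diff(luminances) <= 0)) {
    stop("luminances must be strictly increasing", call. = FALSE)
  }
  labels <- matrix(1L, h, w)
  if (layout == "concentric") {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    rmax <- 0.40625 * min(h, w)  # 52 px at 128
    r <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
    for (j in 2L:nl) {
      rj <- rmax * (nl - j + 1L) / (nl - 1L)
      labels[r <= rj] <- j
    }
  } else if (layout == "quadrant") {
    if (nl != 4L) stop("quadrant layout needs exactly 4 labels", call. = FALSE)
    top <- seq_len(h) <= h %/% 2
    left <- seq_len(w) <= w %/% 2
    labels[top, left] <- 1L; labels[top, !left] <- 2L
    labels[!top, left] <- 3L; labels[!top, !left] <- 4L
  } else {
    if (nl > h) stop("too many labels for stripes layout", call. = FALSE)
    band <- as.integer(cut(seq_len(h), breaks = nl, labels = FALSE))
    labels <- matrix(band, h, w)
  }
  counts <- tabulate(labels, nbins = nl)
  if (any(counts < 0.01 * h * w)) {
    stop("a label occupies less than 1% of the pixels", call. = FALSE)
  }
  image <- matrix(luminances[labels], h, w)
  structure(list(image = image, labels = labels, luminances = luminances,
                 layout = layout), class = "phantom")
}

#' Add additive Gaussian noise to an image
#'
#' x + n with n ~ Normal(mean, variance), i.i.d. per pixel. Unclipped by
#' default (the model is built for unbounded noisy intensities); set
#' `clip = TRUE` to clamp to `[0, 1]`.
#'
#' @param image numeric matrix or array.
#' @param mean,variance noise mean and variance (variance >= 0).
#' @param seed optional seed applied locally (the caller's RNG state is
#'   restored afterwards).
#' @param clip clamp the result to `[0, 1]`?
#' @return noisy image, same shape.
#' @export
add_gaussian_noise <- function(image, mean = 0, variance = 0.07, seed = NULL,
                               clip = FALSE) {
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  out <- with_local_seed(seed, {
    image + stats::rnorm(length(image), mean = mean, sd = sqrt(variance))
  })
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Add multiplicative speckle noise to an image
#'
#' x + x * n with n ~ Normal(0, variance): the multiplicative speckle
#' convention of MATLAB's imnoise. Zero-valued pixels are unchanged.
#'
#' @param image numeric matrix or array.
#' @param variance noise variance (>= 0).
#' @param seed optional seed applied locally.
#' @param clip clamp the result to `[0, 1]`?
#' @return noisy image, same shape.
#' @export
add_speckle_noise <- function(image, variance = 0.04, seed = NULL,
                              clip = FALSE) {
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  out <- with_local_seed(seed, {
    image + image * stats::rnorm(length(image), sd = sqrt(variance))
  })
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d, %d labels (%s layout), luminances %s\n",
              nrow(x$image), ncol(x$image), length(x$luminances), x$layout,
              paste(signif(x$luminances, 3), collapse = ", ")))
  invisible(x)
}
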