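#' Read an image into a pixel grid
#'
#' Reads PNG/TIFF (8/16-bit gray or RGB) or NIfTI (.nii/.nii.gz) images.
#' Grayscale images come back as an h x w matrix in `[0, 1]`; RGB images are
#' either collapsed to luma (`color_space = "gray"`) or converted to the Lab
#' color space (`color_space = "lab"`, D = 3) with each channel rescaled to
#' `[0, 1]` (L by /100, a and b by a fixed `[-110, 110]` span). For 3-D NIfTI
#' volumes a 2-D axial `slice` index is required; NIfTI intensities are
#' rescaled to `[0, 1]` over the slice.
#'
#' @param path file path (.png, .tif/.tiff, .nii, .nii.gz).
#' @param color_space `"gray"` or `"lab"` (only relevant for RGB inputs).
#' @param slice slice index for 3-D NIfTI volumes.
#' @return numeric matrix (D = 1) or h x w x 3 array (Lab).
#' @export
read_image <- function(path, color_space = c("gray", "lab"), slice = NULL) {
  color_space <- match.arg(color_space)
  ext <- tolower(sub("^.*?(\\.[A-Za-z0-9.]+)$", "\\1", basename(path)))
  if (grepl("\\.png$", ext)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", ext)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", ext)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the 'RNifti' package", call. = FALSE)
    }
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) >= 3L && dim(arr)[3L] > 1L) {
      if (is.null(slice)) {
        stop("3-D NIfTI volume: a 2-D `slice` index is required",
             call. = FALSE)
      }
      arr <- arr[, , slice]
    } else if (length(dim(arr)) == 3L) {
      arr <- arr[, , 1L]
    }
    img <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
    rng <- range(img, finite = TRUE)
    if (rng[2L] > rng[1L]) img <- (img - rng[1L]) / (rng[2L] - rng[1L])
    return(img)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(img)) == 2L) return(img)
  if (dim(img)[3L] >= 4L) img <- img[, , 1:3]  # drop alpha
  if (dim(img)[3L] == 2L) return(img[, , 1L])  # gray + alpha
  if (dim(img)[3L] == 1L) return(img[, , 1L])
  if (color_space == "gray") {
    0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  } else {
    rgb_to_lab01(img)
  }
}

# sRGB [0,1] h x w x 3 -> Lab rescaled per channel to [0,1]
rgb_to_lab01 <- function(img) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  rgb <- cbind(as.numeric(img[, , 1L]), as.numeric(img[, , 2L]),
               as.numeric(img[, , 3L]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  out <- array(0, dim = c(h, w, 3L))
  out[, , 1L] <- lab[, 1L] / 100
  out[, , 2L] <- (lab[, 2L] + 110) / 220
  out[, , 3L] <- (lab[, 3L] + 110) / 220
  out
}

#' Write segmentation results to a directory
#'
#' Writes the label map as a PNG (gray value k/255 encodes cluster k, so the
#' labels decode back exactly), one posterior-probability PNG per cluster,
#' and a JSON metadata file with the run configuration, iteration count,
#' convergence flag and objective trace. When `nifti = TRUE` (and RNifti is
#' available) the label map is additionally written as NIfTI.
#'
#' @param result an `rsbgmm` fit.
#' @param dir output directory (created if missing).
#' @param nifti also write a NIfTI label map?
#' @return invisibly, the vector of files written.
#' @export
write_result <- function(result, dir, nifti = FALSE) {
  stopifnot(inherits(result, "rsbgmm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  K <- result$config$K
  f <- file.path(dir, "labels.png")
  png::writePNG(result$labels / 255, f)
  files <- c(files, f)
  h <- result$dim[1L]; w <- result$dim[2L]
  for (k in seq_len(K)) {
    f <- file.path(dir, sprintf("posterior_%d.png", k))
    png::writePNG(pmin(pmax(matrix(result$z_tilde[, k], h, w), 0), 1), f)
    files <- c(files, f)
  }
  meta <- list(config = result$config, n_iter = result$n_iter,
               converged = result$converged,
               objective_trace = result$objective_trace,
               thresholds = list(t1 = result$thresholds$t1,
                                 t2 = result$thresholds$t2))
  f <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      warning("RNifti not available; skipping NIfTI output")
    } else {
      f <- file.path(dir, "labels.nii.gz")
      RNifti::writeNifti(RNifti::asNifti(result$labels * 1), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Export per-cluster rough-region maps as PNG label images
#'
#' One PNG per cluster, rendering the positive region bright (255), the
#' boundary region gray (128) and the negative region dark (0).
#'
#' @param rough a `rough_partition`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_region_maps <- function(rough, dir) {
  stopifnot(inherits(rough, "rough_partition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- rough$dim[1L]; w <- rough$dim[2L]
  shade <- c(255, 128, 0) / 255
  files <- character(0)
  for (k in seq_len(rough$K)) {
    f <- file.path(dir, sprintf("region_%d.png", k))
    png::writePNG(matrix(shade[rough$region[, k]], h, w), f)
    files <- c(files, f)
  }
  invisible(files)
}
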