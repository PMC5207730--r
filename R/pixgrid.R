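# Internal pixel-grid helpers.
#
# Images are numeric matrices (h x w, single channel) or h x w x D arrays
# (D channels). Internally pixels are flattened column-major into an N x D
# matrix, so pixel i = (col - 1) * h + row; all neighborhood operations work
# on h x w fields with replicate padding (3 x 3 window, n = 9 everywhere).

as_pixmat <- function(image) {
  if (is.matrix(image) && is.numeric(image)) {
    list(x = matrix(as.numeric(image), ncol = 1L),
         h = nrow(image), w = ncol(image), d = 1L)
  } else if (is.array(image) && length(dim(image)) == 3L && is.numeric(image)) {
    dm <- dim(image)
    list(x = matrix(as.numeric(image), nrow = dm[1L] * dm[2L], ncol = dm[3L]),
         h = dm[1L], w = dm[2L], d = dm[3L])
  } else {
    stop("`image` must be a numeric matrix or an h x w x D array", call. = FALSE)
  }
}

# global intensity range over all pixels and channels
intensity_span <- function(image) {
  r <- range(image, finite = TRUE)
  r[2L] - r[1L]
}

field <- function(v, h, w) matrix(v, nrow = h, ncol = w)

# value of the neighbor at offset (dr, dc), replicate padding at borders
shift_pad <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin.int(pmax.int(seq_len(h) + dr, 1L), h)
  ci <- pmin.int(pmax.int(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# sum over the 3 x 3 window (9 terms incl. center)
box9 <- function(m) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) acc <- acc + shift_pad(m, dr, dc)
  acc
}

# directional 3-pixel sums through the window center:
# 1 horizontal (W,C,E), 2 vertical (N,C,S), 3 diagonal NW-C-SE, 4 diagonal NE-C-SW
dir_offsets <- list(
  list(c(0L, -1L), c(0L, 0L), c(0L, 1L)),
  list(c(-1L, 0L), c(0L, 0L), c(1L, 0L)),
  list(c(-1L, -1L), c(0L, 0L), c(1L, 1L)),
  list(c(-1L, 1L), c(0L, 0L), c(1L, -1L))
)

dir_sum <- function(m, s) {
  off <- dir_offsets[[s]]
  shift_pad(m, off[[1L]][1L], off[[1L]][2L]) + m +
    shift_pad(m, off[[3L]][1L], off[[3L]][2L])
}

# per-pixel squared Euclidean distance to a level/mean vector, as an h x w field
sqdist_field <- function(pm, v) {
  sq <- pm$x[, 1L] - v[1L]
  sq <- sq * sq
  if (pm$d > 1L) {
    for (c in 2L:pm$d) {
      dd <- pm$x[, c] - v[c]
      sq <- sq + dd * dd
    }
  }
  field(sq, pm$h, pm$w)
}

# row-wise max of an N x K matrix (K small)
row_max <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) for (k in 2L:ncol(m)) mx <- pmax(mx, m[, k])
  mx
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
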