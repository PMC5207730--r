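#' Select the best-aligned neighborhood direction for a cluster
#'
#' For every pixel, picks the direction s (1 horizontal, 2 vertical,
#' 3 diagonal NW-SE, 4 diagonal NE-SW) whose 3 collinear window pixels have
#' the smallest summed Euclidean distance to the cluster mean. This is the
#' edge-preserving mechanism of the directional spatial prior: along an edge
#' the along-edge direction wins. Ties go to the lowest direction index.
#'
#' @param image numeric matrix or h x w x D array.
#' @param mean cluster mean vector (length D).
#' @return h x w integer matrix of direction indices in 1..4.
#' @export
select_direction <- function(image, mean) {
  pm <- as_pixmat(image)
  dist <- sqrt(sqdist_field(pm, mean))
  dsums <- vapply(1:4, function(s) as.numeric(dir_sum(dist, s)),
                  numeric(pm$h * pm$w))
  field(max.col(-dsums, ties.method = "first"), pm$h, pm$w)
}

# directional 3-pixel average of a per-pixel field, using a per-pixel
# direction map
dir_average <- function(vfield, dirmap) {
  sums <- vapply(1:4, function(s) as.numeric(dir_sum(vfield, s)),
                 numeric(length(vfield)))
  sums[cbind(seq_along(dirmap), as.integer(dirmap))] / 3
}

row_softmax <- function(a) {
  mx <- row_max(a)
  e <- exp(a - mx)
  e / rowSums(e)
}

#' Between-cluster spatial prior factor
#'
#' The factor E_ik: a softmax over clusters of the direction-averaged sum of
#' posterior and prior probabilities, \eqn{\sum_{m \in \partial_i^{S^*_k}}
#' (z_{mk} + \pi_{mk}) / N_i^{S^*_k}}, with the direction selected per pixel
#' and cluster by [select_direction()]. Rows sum to 1 over clusters.
#'
#' @param z N x K posterior probabilities.
#' @param pi N x K prior probabilities.
#' @param image the image (for direction selection).
#' @param means K x D matrix of cluster means.
#' @return list with `E` (N x K, rows summing to 1) and `direction`
#'   (N x K integer matrix of selected directions).
#' @export
prior_factor_between <- function(z, pi, image, means) {
  pm <- as_pixmat(image)
  if (!is.matrix(means)) means <- matrix(means, ncol = pm$d)
  K <- nrow(means)
  arg <- matrix(0, nrow(z), K)
  dirm <- matrix(1L, nrow(z), K)
  for (k in seq_len(K)) {
    dk <- select_direction(image, means[k, ])
    dirm[, k] <- as.integer(dk)
    arg[, k] <- dir_average(field(z[, k] + pi[, k], pm$h, pm$w), dk)
  }
  list(E = row_softmax(arg), direction = dirm)
}

#' Within-cluster spatial prior factor
#'
#' The factor F_ikl: for each cluster k, a softmax over its L components of
#' the direction-averaged sum of the within-cluster posterior and weight,
#' \eqn{\sum_{m \in \partial_i^{S^*_l}} (y_{mkl} + \eta_{mkl}) / N_i^{S^*_l}},
#' with the direction selected per component from its mean. Sums to 1 over l.
#'
#' @param y N x K x L within-cluster posteriors.
#' @param eta N x K x L component weights.
#' @param image the image.
#' @param mu K x L x D array of component means.
#' @return N x K x L array `F`, summing to 1 over the last margin.
#' @export
prior_factor_within <- function(y, eta, image, mu) {
  pm <- as_pixmat(image)
  K <- dim(mu)[1L]; L <- dim(mu)[2L]
  N <- dim(y)[1L]
  Fw <- array(0, dim = c(N, K, L))
  for (k in seq_len(K)) {
    arg <- matrix(0, N, L)
    for (l in seq_len(L)) {
      dl <- select_direction(image, mu[k, l, ])
      arg[, l] <- dir_average(field(y[, k, l] + eta[, k, l], pm$h, pm$w), dl)
    }
    Fw[, k, ] <- row_softmax(arg)
  }
  Fw
}
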