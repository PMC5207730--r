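DENSITY_FLOOR <- 1e-300
NORMALIZER_FLOOR <- 1e-8

#' Multivariate Gaussian density
#'
#' Evaluates the D-dimensional Gaussian density, in log space internally
#' (Cholesky factorization of the covariance).
#'
#' @param x numeric vector (one point) or n x D matrix of points.
#' @param mean mean vector (length D).
#' @param cov D x D symmetric positive-definite covariance.
#' @param log return log-density?
#' @return numeric vector of (log-)densities, one per point.
#' @export
gaussian_pdf <- function(x, mean, cov, log = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, ncol = length(mean))
  cov <- as.matrix(cov)
  D <- length(mean)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    # regularization path: lift eigenvalues to a small positive floor
    cov <- ensure_spd(cov, max(diag(cov)) * 1e-10 + 1e-12)
    ch <- chol(cov)
  }
  xc <- sweep(x, 2L, mean)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  q <- colSums(z * z)
  lp <- -0.5 * q - sum(log(diag(ch))) - 0.5 * D * log(2 * pi)
  if (log) lp else exp(lp)
}

# symmetrize and clip eigenvalues into [floor, ceiling] so the matrix is SPD
# and bounded: the ceiling stops the variance runaway of a truncated-Gaussian
# component whose within-support data look uniform (its variance MLE diverges)
ensure_spd <- function(m, floor, ceiling = Inf) {
  m <- (m + t(m)) / 2
  if (nrow(m) == 1L) {
    return(matrix(min(max(m[1L, 1L], floor), ceiling), 1L, 1L))
  }
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor && max(e$values) <= ceiling) return(m)
  v <- pmin(pmax(e$values, floor), ceiling)
  e$vectors %*% (v * t(e$vectors))
}

#' Monte-Carlo normalizer of a bounded component
#'
#' Estimates the truncation constant of a bounded Gaussian component,
#' \eqn{\int \Phi(x|\mu,\Sigma)\tilde H(x) dx \approx M^{-1}\sum_m \tilde H(s_m)}
#' with samples \eqn{s_m \sim \Phi(\cdot|\mu,\Sigma)}. The estimate is clamped
#' below at a small floor before use as a divisor; a vanished support
#' (all-zero indicator) triggers a warning.
#'
#' @param mean component mean vector.
#' @param cov component covariance.
#' @param indicator function mapping an n x D matrix of points to values in
#'   `[0, 1]`.
#' @param M number of Monte-Carlo samples (>= 1).
#' @param samples optional pre-drawn M x D sample matrix (overrides drawing).
#' @param floor lower clamp for the estimate.
#' @return scalar in `(0, 1]`.
#' @export
mc_normalizer <- function(mean, cov, indicator, M = 10000L, samples = NULL,
                          floor = NORMALIZER_FLOOR) {
  if (is.null(samples)) samples <- draw_mc_samples(mean, cov, M)
  hv <- indicator(samples)
  est <- sum(hv) / nrow(samples)
  if (est <= 0) {
    warning("component support vanished: all Monte-Carlo indicators are zero")
    return(floor)
  }
  max(est, floor)
}

draw_mc_samples <- function(mean, cov, M, z = NULL) {
  D <- length(mean)
  if (is.null(z)) z <- matrix(stats::rnorm(M * D), M, D)
  ch <- tryCatch(chol(as.matrix(cov)),
                 error = function(e) chol(ensure_spd(as.matrix(cov), 1e-12)))
  sweep(z %*% ch, 2L, mean, `+`)
}

#' Bounded Gaussian component density
#'
#' The truncated (indicator-masked, renormalized) Gaussian density
#' \eqn{\tilde\Psi(x) = \Phi(x|\mu,\Sigma) \tilde H(x) / Z} with Z the
#' Monte-Carlo normalizer; zero wherever the indicator is zero.
#'
#' @param x point(s) at which to evaluate (vector or n x D matrix).
#' @param mean,cov component parameters.
#' @param indicator_value indicator value(s) at `x`, in `[0, 1]`.
#' @param normalizer truncation constant (> 0), see [mc_normalizer()].
#' @return nonnegative densities.
#' @export
bounded_pdf <- function(x, mean, cov, indicator_value, normalizer) {
  stopifnot(normalizer > 0)
  gaussian_pdf(x, mean, cov) * indicator_value / normalizer
}

#' Cluster component density (asymmetric mixture of bounded Gaussians)
#'
#' \eqn{p(x_i|\Omega_k) = \sum_l \eta_{ikl} \tilde\Psi(x_i|\mu_{kl},\Sigma_{kl})}:
#' the convex combination over the L within-cluster bounded components.
#'
#' @param x N x D matrix of pixel intensities.
#' @param k cluster index.
#' @param params a `mixture_params` object (see [init_kmeans()]).
#' @param indicator length-N vector of bounded-indicator values for cluster k.
#' @return length-N nonnegative density vector.
#' @export
component_density <- function(x, k, params, indicator) {
  if (!is.matrix(x)) x <- matrix(x, ncol = dim(params$mu)[3L])
  N <- nrow(x)
  dens <- numeric(N)
  for (l in seq_len(params$L)) {
    psi <- bounded_pdf(x, params$mu[k, l, ], params$sigma[k, l, , ],
                       indicator, params$normalizer[k, l])
    dens <- dens + params$eta[, k, l] * psi
  }
  dens
}

# Core E-step in log space. logH: N x K matrix of log indicator values.
# Returns z (N x K), y (N x K x L), loglik contribution per pixel (N).
estep_core <- function(x, params, logH) {
  N <- nrow(x); K <- params$K; L <- params$L
  a <- array(-Inf, dim = c(N, K, L))
  for (k in seq_len(K)) {
    for (l in seq_len(L)) {
      lphi <- gaussian_pdf(x, params$mu[k, l, ], params$sigma[k, l, , ],
                           log = TRUE)
      a[, k, l] <- log(params$eta[, k, l]) + lphi + logH[, k] -
        log(params$normalizer[k, l])
    }
  }
  # log p(x|Omega_k) and y via log-sum-exp over l
  logpk <- matrix(-Inf, N, K)
  y <- array(1 / L, dim = c(N, K, L))
  for (k in seq_len(K)) {
    ak <- a[, k, , drop = FALSE]; dim(ak) <- c(N, L)
    mx <- row_max(ak)
    s <- rowSums(exp(ak - mx))
    lse <- mx + log(s)
    lse[!is.finite(mx)] <- -Inf
    logpk[, k] <- lse
    ok <- is.finite(lse)
    if (any(ok)) {
      yk <- exp(ak[ok, , drop = FALSE] - lse[ok])
      y[which(ok), k, ] <- yk
    }
  }
  b <- log(params$pi) + logpk
  mxb <- row_max(b)
  dead <- !is.finite(mxb)
  z <- matrix(1 / K, N, K)
  if (any(!dead)) {
    bo <- b[!dead, , drop = FALSE]
    lseb <- mxb[!dead] + log(rowSums(exp(bo - mxb[!dead])))
    z[!dead, ] <- exp(bo - lseb)
  }
  loglik_pix <- numeric(N)
  if (any(!dead)) {
    bo <- b[!dead, , drop = FALSE]
    loglik_pix[!dead] <- mxb[!dead] + log(rowSums(exp(bo - mxb[!dead])))
  }
  loglik_pix[dead] <- log(DENSITY_FLOOR)
  if (any(dead)) {
    warning(sprintf(
      "%d pixel(s) had zero density under every cluster; uniform fallback",
      sum(dead)))
  }
  list(z = z, y = y, loglik_pix = loglik_pix, dead = dead)
}

#' Between- and within-cluster posterior probabilities
#'
#' Computes the posterior responsibilities z_ik (pixel-to-cluster) and y_ikl
#' (pixel-to-component within cluster), with log-sum-exp stabilization.
#' Pixels with zero density under every cluster fall back to uniform 1/K and
#' 1/L with a warning.
#'
#' @param image numeric matrix or h x w x D array.
#' @param params a `mixture_params` object.
#' @param indicator N x K matrix of bounded-indicator values (e.g. the
#'   `indicator` field of a `rough_partition`), or a `rough_partition`.
#' @return list with `z` (N x K, rows sum to 1) and `y` (N x K x L, slices
#'   sum to 1 over l).
#' @export
mixture_posteriors <- function(image, params, indicator) {
  pm <- as_pixmat(image)
  H <- if (inherits(indicator, "rough_partition")) indicator$indicator
       else indicator
  est <- estep_core(pm$x, params, log(H))
  list(z = est$z, y = est$y)
}

#' Negative penalized log-likelihood of the model
#'
#' The objective J = -L traced across EM iterations: the mixture log-likelihood
#' of the bounded asymmetric model plus the spatial prior terms
#' \eqn{\sum E_{ik}\log\pi_{ik} + \sum F_{ikl}\log\eta_{ikl}}, negated.
#' Logs are floored so degenerate densities never produce -Inf.
#'
#' @param image numeric matrix or array.
#' @param params a `mixture_params` object.
#' @param indicator N x K indicator matrix or `rough_partition`.
#' @param E N x K between-cluster prior factors (default uniform 1/K, whose
#'   log-prior term is then constant).
#' @param F_within N x K x L within-cluster prior factors (default uniform).
#' @return scalar objective value (lower is better).
#' @export
mixture_objective <- function(image, params, indicator, E = NULL,
                              F_within = NULL) {
  pm <- as_pixmat(image)
  H <- if (inherits(indicator, "rough_partition")) indicator$indicator
       else indicator
  est <- suppressWarnings(estep_core(pm$x, params, log(H)))
  ll <- sum(est$loglik_pix)
  if (!is.null(E)) ll <- ll + sum(E * log(pmax(params$pi, DENSITY_FLOOR)))
  if (!is.null(F_within)) {
    ll <- ll + sum(F_within * log(pmax(params$eta, DENSITY_FLOOR)))
  }
  -ll
}
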