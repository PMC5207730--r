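# k-means that tolerates fewer distinct points than centers
safe_kmeans <- function(x, centers, nstart = 10L) {
  ux <- unique(x)
  if (nrow(ux) <= centers) {
    ctr <- ux[rep_len(seq_len(nrow(ux)), centers), , drop = FALSE]
    d2 <- vapply(seq_len(centers), function(k) {
      rowSums(sweep(x, 2L, ctr[k, ])^2)
    }, numeric(nrow(x)))
    cl <- max.col(-d2, ties.method = "first")
    return(list(centers = ctr, cluster = cl))
  }
  km <- tryCatch(
    stats::kmeans(x, centers = centers, nstart = nstart, iter.max = 100L),
    error = function(e) NULL)
  if (is.null(km)) {
    # farthest-point re-seed: deterministic greedy spread of initial centers
    ctr <- x[which.min(rowSums(x)), , drop = FALSE]
    while (nrow(ctr) < centers) {
      d2 <- apply(ctr, 1L, function(c0) rowSums(sweep(x, 2L, c0)^2))
      ctr <- rbind(ctr, x[which.max(apply(as.matrix(d2), 1L, min)), ])
    }
    km <- stats::kmeans(x, centers = ctr, iter.max = 100L)
  }
  km
}

#' Initialize mixture parameters with (nested) k-means
#'
#' Top-level k-means on the pixel intensities gives the K cluster means;
#' a second k-means with L centers inside each cluster gives the component
#' means mu_kl; component covariances come from the within-component scatter
#' (floored to be positive definite). Per-pixel priors start uniform:
#' pi_ik = 1/K, eta_ikl = 1/L. Clusters are ordered by increasing mean
#' intensity so the initialization is deterministic up to the RNG seed.
#'
#' @param image numeric matrix or h x w x D array.
#' @param K number of clusters (>= 2).
#' @param L number of bounded components per cluster (>= 1).
#' @param seed optional RNG seed (uses the current RNG state when `NULL`).
#' @return object of class `mixture_params`: list with `pi` (N x K), `eta`
#'   (N x K x L), `mu` (K x L x D), `sigma` (K x L x D x D), `normalizer`
#'   (K x L, initialized to 1), `cluster_means` (K x D), `K`, `L`, `D`.
#' @export
init_kmeans <- function(image, K, L = 1L, seed = NULL) {
  pm <- as_pixmat(image)
  N <- nrow(pm$x); D <- pm$d
  span <- intensity_span(image)
  reg <- 1e-6 * span^2
  run <- function() {
    km <- safe_kmeans(pm$x, K)
    ord <- order(rowMeans(matrix(km$centers, ncol = D)))
    mu <- array(0, dim = c(K, L, D))
    sigma <- array(0, dim = c(K, L, D, D))
    for (kk in seq_len(K)) {
      k <- ord[kk]
      xk <- pm$x[km$cluster == k, , drop = FALSE]
      if (nrow(xk) == 0L) xk <- matrix(km$centers[k, ], 1L, D)
      if (L == 1L) {
        mu[kk, 1L, ] <- colMeans(xk)
        sub <- list(centers = matrix(colMeans(xk), 1L, D),
                    cluster = rep(1L, nrow(xk)))
      } else {
        sub <- safe_kmeans(xk, L, nstart = 5L)
        mu[kk, , ] <- matrix(sub$centers, L, D)
      }
      for (l in seq_len(L)) {
        xl <- xk[sub$cluster == l, , drop = FALSE]
        s <- if (nrow(xl) > 1L) stats::cov(xl) else matrix(0, D, D)
        sigma[kk, l, , ] <- ensure_spd(matrix(s, D, D), reg)
      }
    }
    structure(
      list(pi = matrix(1 / K, N, K), eta = array(1 / L, dim = c(N, K, L)),
           mu = mu, sigma = sigma, normalizer = matrix(1, K, L),
           cluster_means = cluster_level_means(mu,
                                               array(1 / L, dim = c(N, K, L))),
           K = K, L = L, D = D),
      class = "mixture_params")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# cluster-level mean mu_k as the eta-bar-weighted average of component means
cluster_level_means <- function(mu, eta) {
  K <- dim(mu)[1L]; L <- dim(mu)[2L]; D <- dim(mu)[3L]
  etabar <- apply(eta, c(2L, 3L), mean)  # K x L
  cm <- matrix(0, K, D)
  for (k in seq_len(K)) {
    w <- etabar[k, ] / sum(etabar[k, ])
    cm[k, ] <- colSums(matrix(mu[k, , ], L, D) * w)
  }
  cm
}

#' Override posteriors with the rough regions
#'
#' Replaces the soft posteriors by their rough-set versions: in a cluster's
#' positive region the pixel is certainly a member (z-tilde = 1, y-tilde = 1),
#' in the boundary region the soft value is kept, and in the negative region
#' membership is 0. No renormalization is applied (the prior-update
#' denominators absorb unnormalized rows). A pixel lying in the negative
#' region of every cluster keeps its soft posteriors (with a warning), so it
#' is not erased from every update.
#'
#' @param post list with `z` (N x K) and `y` (N x K x L), as returned by
#'   [mixture_posteriors()].
#' @param rough a `rough_partition` for the same image and clusters.
#' @return list with `z_tilde` and `y_tilde` added.
#' @export
apply_rough_overrides <- function(post, rough) {
  z <- post$z; y <- post$y
  region <- rough$region
  K <- ncol(z); L <- dim(y)[3L]
  zt <- z; yt <- y
  zt[region == 1L] <- 1
  zt[region == 3L] <- 0
  for (l in seq_len(L)) {
    yl <- yt[, , l]
    yl[region == 1L] <- 1
    yl[region == 3L] <- 0
    yt[, , l] <- yl
  }
  allne <- rowSums(region == 3L) == K
  if (any(allne)) {
    warning(sprintf(
      "%d pixel(s) fell in the negative region of every cluster; soft posteriors kept",
      sum(allne)))
    zt[allne, ] <- z[allne, ]
    yt[allne, , ] <- y[allne, , ]
  }
  post$z_tilde <- zt
  post$y_tilde <- yt
  post
}

#' Mean update of the bounded components
#'
#' One fixed-point application of the bounded-EM mean update: the
#' responsibility-weighted data mean minus the Monte-Carlo bias-correction
#' term \eqn{\sum_m (\mu_{kl} - s_m)\tilde H(s_m) / \sum_m \tilde H(s_m)}
#' evaluated at the previous mean. A component with vanishing responsibility
#' mass keeps its previous mean (warning).
#'
#' @param x N x D matrix of pixel intensities.
#' @param z_tilde,y_tilde rough-overridden posteriors.
#' @param mu_old K x L x D array of previous means.
#' @param samples list of lists: `samples[[k]][[l]]` an M x D matrix drawn
#'   from the (k, l) component.
#' @param sample_ind list of lists of indicator values at those samples.
#' @return K x L x D array of updated means.
#' @export
update_means <- function(x, z_tilde, y_tilde, mu_old, samples, sample_ind) {
  K <- dim(mu_old)[1L]; L <- dim(mu_old)[2L]; D <- dim(mu_old)[3L]
  mu <- mu_old
  for (k in seq_len(K)) {
    for (l in seq_len(L)) {
      w <- z_tilde[, k] * y_tilde[, k, l]
      sw <- sum(w)
      if (sw <= .Machine$double.eps * length(w)) {
        warning(sprintf(
          "component (%d,%d): vanishing responsibility mass; mean kept", k, l))
        next
      }
      dmean <- as.numeric(crossprod(w, x)) / sw
      hv <- sample_ind[[k]][[l]]
      hs <- sum(hv)
      corr <- if (hs > 0) {
        mu_old[k, l, ] - as.numeric(crossprod(hv, samples[[k]][[l]])) / hs
      } else rep(0, D)
      mu[k, l, ] <- dmean - corr
    }
  }
  mu
}

#' Covariance update of the bounded components
#'
#' One fixed-point application of the bounded-EM covariance update: the
#' responsibility-weighted scatter minus the Monte-Carlo correction
#' \eqn{\sum_m ((s_m-\mu)(s_m-\mu)^T - \Sigma_{kl})\tilde H(s_m)/\sum_m \tilde H(s_m)}
#' (previous covariance inside the bracket). The result is symmetrized and
#' eigenvalue-floored at `1e-6 * span^2` so it stays positive definite.
#'
#' @inheritParams update_means
#' @param mu K x L x D array of (updated) means.
#' @param sigma_old K x L x D x D array of previous covariances.
#' @param span intensity span of the image (sets the regularization floor).
#' @return K x L x D x D array of updated covariances.
#' @export
update_covariances <- function(x, z_tilde, y_tilde, mu, sigma_old,
                               samples, sample_ind, span) {
  K <- dim(mu)[1L]; L <- dim(mu)[2L]; D <- dim(mu)[3L]
  reg <- 1e-6 * span^2
  sigma <- sigma_old
  for (k in seq_len(K)) {
    for (l in seq_len(L)) {
      w <- z_tilde[, k] * y_tilde[, k, l]
      sw <- sum(w)
      if (sw <= .Machine$double.eps * length(w)) next
      xc <- sweep(x, 2L, mu[k, l, ])
      scat <- crossprod(xc * sqrt(w)) / sw
      hv <- sample_ind[[k]][[l]]
      hs <- sum(hv)
      if (hs > 0) {
        sc <- sweep(samples[[k]][[l]], 2L, mu[k, l, ])
        mc_scat <- crossprod(sc * sqrt(hv)) / hs
        corr <- mc_scat - matrix(sigma_old[k, l, , ], D, D)
      } else corr <- matrix(0, D, D)
      sigma[k, l, , ] <- ensure_spd(scat - corr, reg, ceiling = span^2)
    }
  }
  sigma
}

#' Prior probability updates
#'
#' pi_ik = (z-tilde_ik + E_ik) / sum_h (z-tilde_ih + E_ih) and the analogous
#' eta update with (y-tilde, F). Rows sum to 1 by construction; since the
#' prior factors sum to 1 over their margin the denominators never vanish.
#'
#' @param z_tilde N x K rough-overridden posteriors.
#' @param y_tilde N x K x L rough-overridden within-cluster posteriors.
#' @param E N x K between-cluster prior factors.
#' @param F_within N x K x L within-cluster prior factors.
#' @return list with `pi` (N x K) and `eta` (N x K x L).
#' @export
update_priors <- function(z_tilde, y_tilde, E, F_within) {
  num <- z_tilde + E
  pi <- num / rowSums(num)
  K <- ncol(z_tilde); L <- dim(y_tilde)[3L]
  eta <- y_tilde + F_within
  den <- apply(eta, c(1L, 2L), sum)
  for (l in seq_len(L)) eta[, , l] <- eta[, , l] / den
  list(pi = pi, eta = eta)
}

#' Fit the rough-set bounded asymmetric Gaussian mixture segmentation
#'
#' Runs the full EM pipeline: adaptive rough-set thresholds, k-means
#' initialization, then iterations of (rough-region assignment from the
#' current cluster means; Monte-Carlo normalization of the bounded
#' components; E-step with rough overrides; directional spatial prior
#' factors; M-step updates of means, covariances and per-pixel priors) until
#' the summed displacement of the component means drops below `tol` or
#' `max_iter` is reached. Labels are the argmax over clusters of the final
#' rough-overridden posteriors (ties to the lowest cluster index).
#'
#' @param image numeric matrix (h x w) or h x w x D array.
#' @param K number of clusters (>= 2).
#' @param L number of bounded Gaussian components per cluster.
#' @param mc_samples Monte-Carlo sample count M per component per iteration.
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the total mean displacement.
#' @param seed RNG seed; identical seeds give bit-identical label maps.
#' @param recompute_regions recompute the rough regions from the current
#'   cluster means at every iteration (the printed algorithm loop); if
#'   `FALSE` the initial regions are kept.
#' @param frozen_samples reuse the same standard-normal draws every iteration
#'   (transformed by the current parameters); useful for objective
#'   monotonicity checks. Default redraws fresh samples each iteration.
#' @param levels optional intensity levels for [compute_thresholds()].
#' @param verbose print per-iteration objective values.
#' @return object of class `rsbgmm`: list with `labels` (h x w integer
#'   matrix), `z_tilde`, `params`, `rough`, `thresholds`, `objective_trace`,
#'   `n_iter`, `converged`, `config`.
#' @examples
#' ph <- make_phantom(size = 32, luminances = c(0, 1), layout = "stripes")
#' fit <- fit_rsbgmm(ph$image, K = 2, L = 1, mc_samples = 500,
#'                   max_iter = 5, seed = 1)
#' table(fit$labels, ph$labels)
#' @export
fit_rsbgmm <- function(image, K, L = 3L, mc_samples = 10000L, max_iter = 100L,
                       tol = 1e-5, seed = 1L, recompute_regions = TRUE,
                       frozen_samples = FALSE, levels = NULL,
                       verbose = FALSE) {
  stopifnot(K >= 2L, L >= 1L, tol > 0, mc_samples >= 1L)
  pm <- as_pixmat(image)
  span <- intensity_span(image)
  thr <- compute_thresholds(image, levels = levels)
  set.seed(seed)
  params <- init_kmeans(image, K, L)
  M <- as.integer(mc_samples)
  frozen_z <- NULL
  if (frozen_samples) {
    frozen_z <- lapply(seq_len(K), function(k)
      lapply(seq_len(L), function(l) matrix(stats::rnorm(M * pm$d), M, pm$d)))
  }
  E <- matrix(1 / K, nrow(pm$x), K)
  Fw <- array(1 / L, dim = c(nrow(pm$x), K, L))
  trace <- numeric(0)
  converged <- FALSE
  rough <- NULL
  post <- NULL
  n_iter <- 0L

  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    if (is.null(rough) || recompute_regions) {
      rough <- assign_rough_regions(image, params$cluster_means, thr)
    }
    # Monte-Carlo samples and normalizers for every (k, l)
    samples <- vector("list", K); sample_ind <- vector("list", K)
    for (k in seq_len(K)) {
      samples[[k]] <- vector("list", L); sample_ind[[k]] <- vector("list", L)
      for (l in seq_len(L)) {
        z0 <- if (frozen_samples) frozen_z[[k]][[l]] else NULL
        s <- draw_mc_samples(params$mu[k, l, ],
                             matrix(params$sigma[k, l, , ], pm$d, pm$d),
                             M, z = z0)
        hv <- point_indicator(s, params$cluster_means[k, ], thr, span)
        samples[[k]][[l]] <- s
        sample_ind[[k]][[l]] <- hv
        est <- sum(hv) / M
        params$normalizer[k, l] <- max(est, NORMALIZER_FLOOR)
      }
    }
    # E-step (with the objective traced under the factors that produced the
    # current priors)
    est <- suppressWarnings(estep_core(pm$x, params, log(rough$indicator)))
    obj <- -(sum(est$loglik_pix) +
               sum(E * log(pmax(params$pi, DENSITY_FLOOR))) +
               sum(Fw * log(pmax(params$eta, DENSITY_FLOOR))))
    trace <- c(trace, obj)
    if (verbose) message(sprintf("iter %3d  J = %.6f", iter, obj))
    post <- suppressWarnings(
      apply_rough_overrides(list(z = est$z, y = est$y), rough))

    # M-step 4.1: prior factors from the current posteriors and priors
    pf <- prior_factor_between(est$z, params$pi, image, params$cluster_means)
    E <- pf$E
    Fw <- prior_factor_within(est$y, params$eta, image, params$mu)
    # 4.2 means, 4.3 covariances, 4.4 priors
    mu_new <- suppressWarnings(
      update_means(pm$x, post$z_tilde, post$y_tilde, params$mu,
                   samples, sample_ind))
    params$sigma <- update_covariances(pm$x, post$z_tilde, post$y_tilde,
                                       mu_new, params$sigma,
                                       samples, sample_ind, span)
    delta <- sum(sqrt(apply((mu_new - params$mu)^2, c(1L, 2L), sum)))
    params$mu <- mu_new
    pr <- update_priors(post$z_tilde, post$y_tilde, E, Fw)
    params$pi <- pr$pi
    params$eta <- pr$eta
    params$cluster_means <- cluster_level_means(params$mu, params$eta)

    if (delta < tol) { converged <- TRUE; break }
  }

  # final E-step so labels reflect the last parameter update
  if (recompute_regions) {
    rough <- assign_rough_regions(image, params$cluster_means, thr)
  }
  for (k in seq_len(K)) for (l in seq_len(L)) {
    s <- draw_mc_samples(params$mu[k, l, ],
                         matrix(params$sigma[k, l, , ], pm$d, pm$d), M)
    hv <- point_indicator(s, params$cluster_means[k, ], thr, span)
    params$normalizer[k, l] <- max(sum(hv) / M, NORMALIZER_FLOOR)
  }
  est <- suppressWarnings(estep_core(pm$x, params, log(rough$indicator)))
  post <- suppressWarnings(
    apply_rough_overrides(list(z = est$z, y = est$y), rough))
  labels <- field(max.col(post$z_tilde, ties.method = "first"), pm$h, pm$w)

  structure(
    list(labels = labels, z_tilde = post$z_tilde, params = params,
         rough = rough, thresholds = thr, objective_trace = trace,
         n_iter = n_iter, converged = converged,
         config = list(K = K, L = L, mc_samples = M, max_iter = max_iter,
                       tol = tol, seed = seed,
                       recompute_regions = recompute_regions,
                       frozen_samples = frozen_samples),
         dim = c(pm$h, pm$w)),
    class = "rsbgmm")
}

#' @export
print.rsbgmm <- function(x, ...) {
  cat(sprintf(
    "rough-set bounded asymmetric GMM segmentation\n  %d x %d pixels, K = %d clusters, L = %d components\n  %d iteration(s), %s (final objective %.4f)\n",
    x$dim[1L], x$dim[2L], x$config$K, x$config$L, x$n_iter,
    if (x$converged) "converged" else "not converged",
    utils::tail(x$objective_trace, 1L)))
  invisible(x)
}

#' @export
plot.rsbgmm <- function(x, ...) {
  lab <- x$labels
  graphics::image(t(lab)[, nrow(lab):1], col = grDevices::gray.colors(
    x$config$K, start = 0, end = 1), axes = FALSE, asp = nrow(lab) / ncol(lab),
    main = "segmentation labels", ...)
  invisible(x)
}
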