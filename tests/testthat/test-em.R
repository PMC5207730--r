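test_that("k-means initialization recovers separated intensities", {
  ph <- make_phantom(size = 16, luminances = c(0, 1), layout = "stripes")
  # two-value noiseless image, K = 2: means are exactly the two values
  p <- init_kmeans(ph$image, K = 2, L = 1, seed = 1)
  expect_equal(sort(p$mu[, 1, 1]), c(0, 1))
  expect_equal(p$cluster_means[, 1], c(0, 1))
  # L = 1 component mean equals the k-means centroid
  expect_equal(p$mu[, 1, ], p$cluster_means[, 1])
  # uniform priors
  expect_true(all(p$pi == 0.5))
  expect_true(all(p$eta == 1))
  # noisy two-class sample: centroids within 0.05 of the true means
  set.seed(3)
  img <- matrix(c(stats::rnorm(128, 0.25, 0.05), stats::rnorm(128, 0.75, 0.05)),
                16, 16)
  p2 <- init_kmeans(img, K = 2, L = 1, seed = 7)
  expect_lt(max(abs(sort(p2$cluster_means[, 1]) - c(0.25, 0.75))), 0.05)
})

test_that("initialization handles fewer distinct values than components", {
  ph <- make_phantom(size = 16, luminances = c(0, 1), layout = "stripes")
  p <- init_kmeans(ph$image, K = 2, L = 3, seed = 1)  # constant sub-clusters
  expect_equal(dim(p$mu), c(2L, 3L, 1L))
  expect_true(all(is.finite(p$sigma)))
  expect_true(all(p$sigma > 0))
})

test_that("rough overrides implement the region case analysis", {
  N <- 6; K <- 3; L <- 2
  z <- matrix(stats::runif(N * K), N, K); z <- z / rowSums(z)
  y <- array(stats::runif(N * K * L), dim = c(N, K, L))
  y <- y / rep(apply(y, c(1, 2), sum), L)
  region <- matrix(2L, N, K)          # everything boundary by default
  region[1, ] <- c(2L, 1L, 3L)        # pixel 1: Po for cluster 2, Ne for 3
  region[2, ] <- c(3L, 3L, 3L)        # pixel 2: Ne everywhere
  rough <- structure(list(region = region), class = "rough_partition")
  expect_warning(
    post <- apply_rough_overrides(list(z = z, y = y), rough),
    "negative region")
  # pixel 1: kept soft in Bo, forced 1 in Po, 0 in Ne
  expect_equal(post$z_tilde[1, ], c(z[1, 1], 1, 0))
  expect_equal(post$y_tilde[1, 2, ], c(1, 1))
  expect_equal(post$y_tilde[1, 3, ], c(0, 0))
  expect_equal(post$y_tilde[1, 1, ], y[1, 1, ])
  # pixel 2 in Ne of every cluster keeps its soft posteriors
  expect_equal(post$z_tilde[2, ], z[2, ])
  expect_equal(post$y_tilde[2, , ], y[2, , ])
  # all-boundary pixels are unchanged
  expect_equal(post$z_tilde[3, ], z[3, ])
})

test_that("mean update recovers the weighted data mean when corrections vanish", {
  set.seed(71)
  N <- 20
  x <- matrix(stats::runif(N), ncol = 1)
  zt <- matrix(stats::runif(N), N, 1)
  yt <- array(1, dim = c(N, 1, 1))
  mu_old <- array(0.5, dim = c(1, 1, 1))
  M <- 5000
  s <- matrix(stats::rnorm(M, 0.5, 0.1), ncol = 1)
  # indicator identically one: correction = mu_old - sample mean ~ 0
  mu <- update_means(x, zt, yt, mu_old, list(list(s)), list(list(rep(1, M))))
  wmean <- sum(zt * x) / sum(zt)
  expect_equal(mu[1, 1, 1], wmean - (0.5 - mean(s)), tolerance = 1e-12)
  expect_lt(abs(mu[1, 1, 1] - wmean), 3 * 0.1 / sqrt(M))
  # all weight on one pixel, zero correction: mean lands on that pixel
  zt2 <- matrix(0, N, 1); zt2[4, 1] <- 1
  mu2 <- update_means(x, zt2, yt, mu_old, list(list(s)),
                      list(list(rep(0, M))))
  expect_equal(mu2[1, 1, 1], x[4, 1])
  # vanishing responsibility keeps the previous mean with a warning
  expect_warning(
    mu3 <- update_means(x, matrix(0, N, 1), yt, mu_old, list(list(s)),
                        list(list(rep(1, M)))),
    "vanishing")
  expect_equal(mu3[1, 1, 1], 0.5)
})

test_that("mean and covariance updates match a hand-evaluated instance", {
  x <- matrix(c(0.1, 0.2, 0.7, 0.9), ncol = 1)
  zt <- matrix(c(0.9, 0.8, 0.1, 0.05), ncol = 1)
  yt <- array(1, dim = c(4, 1, 1))
  mu_old <- array(0.3, dim = c(1, 1, 1))
  sg_old <- array(0.04, dim = c(1, 1, 1, 1))
  s <- matrix(c(0.25, 0.4, 0.1), ncol = 1)
  hv <- c(1, 0.5, 0.25)
  mu <- update_means(x, zt, yt, mu_old, list(list(s)), list(list(hv)))
  w <- zt[, 1]
  dmean <- sum(w * x) / sum(w)
  corr <- sum((0.3 - s) * hv) / sum(hv)
  expect_equal(mu[1, 1, 1], dmean - corr, tolerance = 1e-14)
  sg <- update_covariances(x, zt, yt, mu, sg_old, list(list(s)),
                           list(list(hv)), span = 1)
  scat <- sum(w * (x - mu[1, 1, 1])^2) / sum(w)
  mc <- sum(((s - mu[1, 1, 1])^2 - 0.04) * hv) / sum(hv)
  expect_equal(sg[1, 1, 1, 1], max(scat - mc, 1e-6), tolerance = 1e-12)
})

test_that("covariance update stays positive definite in degenerate cases", {
  x <- matrix(c(0.1, 0.5, 0.9, 0.3), ncol = 1)
  zt <- matrix(c(1, 0, 0, 0), ncol = 1)  # single-pixel weight: zero scatter
  yt <- array(1, dim = c(4, 1, 1))
  mu <- array(0.1, dim = c(1, 1, 1))
  sg_old <- array(0.01, dim = c(1, 1, 1, 1))
  s <- matrix(stats::rnorm(100, 0.1, 0.1), ncol = 1)
  sg <- update_covariances(x, zt, yt, mu, sg_old, list(list(s)),
                           list(list(rep(0, 100))), span = 1)
  expect_gte(sg[1, 1, 1, 1], 1e-6)
})

test_that("prior updates renormalize and follow the plug-in arithmetic", {
  N <- 5; K <- 4; L <- 2
  zt <- matrix(0, N, K)
  E <- matrix(1 / K, N, K)
  yt <- array(stats::runif(N * K * L), dim = c(N, K, L))
  Fw <- array(1 / L, dim = c(N, K, L))
  # all-zero z-tilde row: pi equals E exactly
  pr <- update_priors(zt, yt, E, Fw)
  expect_equal(pr$pi, E)
  # unit z-tilde for one cluster with uniform E: pi = (1 + 1/K) / 2
  zt2 <- matrix(0, N, K); zt2[, 2] <- 1
  pr2 <- update_priors(zt2, yt, E, Fw)
  expect_equal(pr2$pi[, 2], rep((1 + 1 / K) / 2, N))
  expect_equal(rowSums(pr2$pi), rep(1, N), tolerance = 1e-12)
  expect_equal(apply(pr2$eta, c(1, 2), sum), matrix(1, N, K),
               tolerance = 1e-12)
  # naive loop agreement
  set.seed(83)
  ztr <- matrix(stats::runif(N * K), N, K)
  Er <- matrix(stats::runif(N * K), N, K); Er <- Er / rowSums(Er)
  prr <- update_priors(ztr, yt, Er, Fw)
  for (i in 1:N) {
    expect_equal(prr$pi[i, ], (ztr[i, ] + Er[i, ]) / sum(ztr[i, ] + Er[i, ]))
    for (k in 1:K) {
      expect_equal(prr$eta[i, k, ],
                   (yt[i, k, ] + 0.5) / sum(yt[i, k, ] + 0.5))
    }
  }
})

test_that("noiseless two-label phantom is segmented perfectly", {
  ph <- make_phantom(size = 24, luminances = c(0, 1), layout = "stripes")
  fit <- fit_rsbgmm(ph$image, K = 2, L = 1, mc_samples = 500, max_iter = 10,
                    seed = 1)
  expect_equal(ccr(fit$labels, ph$labels), 1.0)
})

test_that("infinite tolerance exits after one iteration", {
  ph <- make_phantom(size = 16, luminances = c(0, 0.5, 1), layout = "stripes")
  img <- add_gaussian_noise(ph$image, 0, 0.01, seed = 5)
  fit <- fit_rsbgmm(img, K = 3, L = 1, mc_samples = 200, max_iter = 50,
                    tol = Inf, seed = 1)
  expect_equal(fit$n_iter, 1L)
  expect_true(fit$converged)
})

test_that("identical seeds give bit-identical label maps", {
  ph <- make_phantom(size = 16, luminances = c(0, 0.5, 1), layout = "stripes")
  img <- add_gaussian_noise(ph$image, 0, 0.02, seed = 9)
  f1 <- fit_rsbgmm(img, K = 3, L = 2, mc_samples = 300, max_iter = 5, seed = 4)
  f2 <- fit_rsbgmm(img, K = 3, L = 2, mc_samples = 300, max_iter = 5, seed = 4)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("EM iterations preserve the simplex and SPD invariants", {
  ph <- make_phantom(size = 16, luminances = c(0, 0.5, 1), layout = "stripes")
  img <- add_gaussian_noise(ph$image, 0, 0.02, seed = 15)
  fit <- fit_rsbgmm(img, K = 3, L = 2, mc_samples = 300, max_iter = 8, seed = 2)
  p <- fit$params
  expect_equal(rowSums(p$pi), rep(1, 256), tolerance = 1e-10)
  expect_equal(apply(p$eta, c(1, 2), sum), matrix(1, 256, 3),
               tolerance = 1e-10)
  expect_true(all(p$sigma[, , 1, 1] > 0))
  expect_true(all(p$normalizer > 0 & p$normalizer <= 1))
  # region consistency of the final overridden posteriors
  reg <- fit$rough$region
  expect_true(all(fit$z_tilde[reg == 1L] == 1))
})

test_that("tidy and glance summarize the fit", {
  ph <- make_phantom(size = 16, luminances = c(0, 1), layout = "stripes")
  fit <- fit_rsbgmm(ph$image, K = 2, L = 2, mc_samples = 200, max_iter = 3,
                    seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_named(td, c("cluster", "component", "mean", "var", "weight",
                     "normalizer"))
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_equal(gl$n_pixels, 256)
})
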