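# Naive double-loop reference implementations, kept deliberately independent
# of the vectorized package code paths.

clampi <- function(i, n) min(max(i, 1L), n)

# rough-set distance of pixel (r, c) to level g, explicit 3x3 loop
naive_distance <- function(img, r, c, g) {
  h <- nrow(img); w <- ncol(img)
  span <- max(img) - min(img)
  acc <- 0
  for (dr in -1:1) for (dc in -1:1) {
    acc <- acc + (img[clampi(r + dr, h), clampi(c + dc, w)] - g)^2
  }
  acc / (9 * span)
}

naive_distance_field <- function(img, g) {
  out <- img * 0
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    out[r, c] <- naive_distance(img, r, c, g)
  }
  out
}

naive_thresholds <- function(img, levels) {
  dmin <- NULL; dmean <- NULL
  for (g in levels) {
    d <- naive_distance_field(img, g)
    dmin <- if (is.null(dmin)) d else pmin(dmin, d)
    dmean <- if (is.null(dmean)) d else dmean + d
  }
  list(t1 = mean(dmin), t2 = mean(dmean / length(levels)))
}

naive_regions <- function(img, means, t1, t2) {
  N <- length(img); K <- length(means)
  d <- sapply(seq_len(K), function(k) as.numeric(naive_distance_field(img, means[k])))
  region <- matrix(3L, N, K)
  for (i in seq_len(N)) for (k in seq_len(K)) {
    if (d[i, k] <= t1) region[i, k] <- 1L
    else if (d[i, k] <= t2) region[i, k] <- 2L
  }
  for (i in seq_len(N)) {
    po <- which(region[i, ] == 1L)
    if (length(po) > 1L) {
      keep <- po[which.min(d[i, po])]
      region[i, setdiff(po, keep)] <- 2L
    }
  }
  list(region = region, distance = d)
}

# per-pixel posteriors by direct summation (1-D intensities)
naive_posteriors <- function(x, pi, eta, mu, sigma, H, normalizer) {
  N <- length(x); K <- ncol(pi); L <- dim(eta)[3]
  psi <- array(0, dim = c(N, K, L))
  for (k in 1:K) for (l in 1:L) {
    phi <- stats::dnorm(x, mu[k, l], sqrt(sigma[k, l]))
    psi[, k, l] <- phi * H[, k] / normalizer[k, l]
  }
  pk <- matrix(0, N, K)
  y <- array(0, dim = c(N, K, L))
  for (k in 1:K) {
    pk[, k] <- sapply(1:N, function(i) sum(eta[i, k, ] * psi[i, k, ]))
    for (l in 1:L) y[, k, l] <- eta[, k, l] * psi[, k, l] / pk[, k]
  }
  z <- pi * pk
  z <- z / rowSums(z)
  list(z = z, y = y)
}

# directional selection and prior factors, explicit loops (1-D intensities)
dir_members <- function(r, c, s, h, w) {
  off <- switch(s,
    list(c(0, -1), c(0, 0), c(0, 1)),
    list(c(-1, 0), c(0, 0), c(1, 0)),
    list(c(-1, -1), c(0, 0), c(1, 1)),
    list(c(-1, 1), c(0, 0), c(1, -1)))
  lapply(off, function(o) c(clampi(r + o[1], h), clampi(c + o[2], w)))
}

naive_select_direction <- function(img, mu) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0L, h, w)
  for (r in 1:h) for (c in 1:w) {
    best <- Inf; bs <- 1L
    for (s in 1:4) {
      tot <- sum(sapply(dir_members(r, c, s, h, w),
                        function(m) abs(img[m[1], m[2]] - mu)))
      if (tot < best - 1e-15) { best <- tot; bs <- s }
    }
    out[r, c] <- bs
  }
  out
}

naive_prior_between <- function(z, pi, img, means) {
  h <- nrow(img); w <- ncol(img); K <- length(means)
  arg <- matrix(0, h * w, K)
  for (k in 1:K) {
    dirs <- naive_select_direction(img, means[k])
    A <- matrix(z[, k] + pi[, k], h, w)
    for (r in 1:h) for (c in 1:w) {
      mem <- dir_members(r, c, dirs[r, c], h, w)
      arg[(c - 1) * h + r, k] <- mean(sapply(mem, function(m) A[m[1], m[2]]))
    }
  }
  e <- exp(arg)
  e / rowSums(e)
}

# quadratic-time PRI straight from the pairwise definition
naive_pri <- function(seg, gts) {
  if (!is.list(gts)) gts <- list(gts)
  s <- as.integer(seg); n <- length(s)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cij <- as.numeric(s[i] == s[j])
    pij <- mean(sapply(gts, function(g) as.numeric(g[i] == g[j])))
    tot <- tot + cij * pij + (1 - cij) * (1 - pij)
    np <- np + 1
  }
  tot / np
}

# one standard spatially-weighted GMM EM iteration (K clusters, L = 1,
# unbounded): reference for the reduction property
reference_gmm_iteration <- function(x, pi, mu, sigma, E) {
  K <- length(mu)
  dens <- sapply(1:K, function(k) stats::dnorm(x, mu[k], sqrt(sigma[k])))
  num <- pi * dens
  z <- num / rowSums(num)
  mu_new <- sapply(1:K, function(k) sum(z[, k] * x) / sum(z[, k]))
  sigma_new <- sapply(1:K, function(k)
    sum(z[, k] * (x - mu_new[k])^2) / sum(z[, k]))
  pi_new <- (z + E) / rowSums(z + E)
  list(z = z, mu = mu_new, sigma = sigma_new, pi = pi_new)
}

random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(stats::runif(h * w), h, w)
}
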