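#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted component parameters
#'
#' One row per (cluster, component): means, variances/covariance entries,
#' average component weight and the Monte-Carlo truncation constant.
#'
#' @param x an `rsbgmm` fit.
#' @param ... unused.
#' @return a data frame with columns `cluster`, `component`, `mean.*`,
#'   `var.*`, `weight`, `normalizer`.
#' @method tidy rsbgmm
#' @export
tidy.rsbgmm <- function(x, ...) {
  K <- x$config$K; L <- x$config$L; D <- x$params$D
  etabar <- apply(x$params$eta, c(2L, 3L), mean)
  rows <- expand.grid(component = seq_len(L), cluster = seq_len(K))
  out <- data.frame(cluster = rows$cluster, component = rows$component)
  for (d in seq_len(D)) {
    out[[if (D == 1L) "mean" else paste0("mean.", d)]] <-
      mapply(function(k, l) x$params$mu[k, l, d], rows$cluster, rows$component)
    out[[if (D == 1L) "var" else paste0("var.", d)]] <-
      mapply(function(k, l) x$params$sigma[k, l, d, d],
             rows$cluster, rows$component)
  }
  out$weight <- mapply(function(k, l) etabar[k, l],
                       rows$cluster, rows$component)
  out$normalizer <- mapply(function(k, l) x$params$normalizer[k, l],
                           rows$cluster, rows$component)
  out
}

#' One-line fit summary
#'
#' @param x an `rsbgmm` fit.
#' @param ... unused.
#' @return a one-row data frame: cluster/component counts, iterations,
#'   convergence flag, final objective.
#' @method glance rsbgmm
#' @export
glance.rsbgmm <- function(x, ...) {
  data.frame(K = x$config$K, L = x$config$L, n_pixels = prod(x$dim),
             n_iter = x$n_iter, converged = x$converged,
             objective = utils::tail(x$objective_trace, 1L))
}
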