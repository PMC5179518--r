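# log density of a 2-D Gaussian at rows of x (closed-form inverse/determinant)
ldmvnorm2 <- function(x, mu, sigma) {
  a <- sigma[1, 1]; b <- sigma[1, 2]; d <- sigma[2, 2]
  det <- a * d - b * b
  if (det <= 0) return(rep(-Inf, nrow(x)))
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (d * dx^2 - 2 * b * dx * dy + a * dy^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Gaussian mixture model by expectation-maximization
#'
#' Full-covariance Gaussian mixture on a 2-D point set (the Gaussian, i.e.
#' nu = infinity, limit of a t-mixture), fitted by EM to a relative
#' log-likelihood tolerance of 1e-15 with up to 10,000 iterations; the best
#' of several k-means-seeded restarts is kept. Per-point responsibilities are
#' normalized, BIC (`2*logLik - npar*log(N)`) is recorded, and points whose
#' squared Mahalanobis distance to their assigned component exceeds the 80%
#' quantile of the chi-squared(2) law are flagged as outliers (out of
#' cluster).
#'
#' @param points N x 2 matrix or tibble (e.g. a t-SNE embedding).
#' @param K Number of components (N > 5K required).
#' @param tol Relative log-likelihood convergence tolerance. Default 1e-15.
#' @param max_iter Maximum EM iterations. Default 10000.
#' @param n_restarts Random restarts. Default 3.
#' @param outlier_quantile Coverage of the per-component quantile region
#'   outside which points are flagged. Default 0.8.
#' @param seed Integer seed.
#' @return An object of class `cluster_model`: `K`, `weights`, `means`
#'   (K x 2), `covariances` (list of 2 x 2), `log_likelihood`, `BIC`,
#'   `assignments`, `outlier`, `ll_trace` (per-iteration log-likelihood of
#'   the winning restart), `n_iter`.
#' @export
fit_gmm_em <- function(points, K, tol = 1e-15, max_iter = 10000,
                       n_restarts = 3, outlier_quantile = 0.8, seed = 1) {
  x <- if (is.matrix(points)) points else
    as.matrix(dplyr::select_if(as_tibble(points), is.numeric))
  if (ncol(x) != 2) abort("`points` must be 2-D.")
  n <- nrow(x)
  if (n <= 5 * K) abort("Need N > 5*K points.")
  floor_var <- 1e-8 * mean(apply(x, 2, var))
  if (floor_var <= 0) floor_var <- 1e-12

  run_em <- function(restart) {
    set.seed(derive_seed(seed, 10 + restart))
    mu <- if (K == 1) matrix(colMeans(x), 1) else {
      km <- suppressWarnings(kmeans(x, K, nstart = 1, iter.max = 50))
      km$centers
    }
    sig <- replicate(K, cov(x) / K + diag(floor_var, 2), simplify = FALSE)
    w <- rep(1 / K, K)

    ll_old <- -Inf
    ll_trace <- numeric(0)
    logdens <- matrix(0, n, K)
    for (iter in seq_len(max_iter)) {
      for (k in seq_len(K)) {
        logdens[, k] <- log(w[k]) + ldmvnorm2(x, mu[k, ], sig[[k]])
      }
      m <- apply(logdens, 1, max)
      if (any(!is.finite(m))) return(NULL)  # collapsed component
      lse <- m + log(rowSums(exp(logdens - m)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      r <- exp(logdens - lse)

      nk <- colSums(r)
      if (any(nk < 1e-10)) return(NULL)
      w <- nk / n
      for (k in seq_len(K)) {
        mu[k, ] <- colSums(r[, k] * x) / nk[k]
        dx <- sweep(x, 2, mu[k, ])
        s <- crossprod(dx * r[, k], dx) / nk[k]
        s <- s + diag(floor_var, 2)
        if (s[1, 1] * s[2, 2] - s[1, 2]^2 <= 0) return(NULL)
        sig[[k]] <- s
      }
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-300)) break
      ll_old <- ll
    }
    list(w = w, mu = mu, sig = sig, ll = ll, ll_trace = ll_trace,
         n_iter = length(ll_trace))
  }

  fits <- purrr::compact(purrr::map(seq_len(n_restarts), run_em))
  if (length(fits) == 0) {
    abort("All EM restarts collapsed (singular component covariance).")
  }
  best <- fits[[which.max(vapply(fits, function(f) f$ll, 0))]]

  logdens <- vapply(seq_len(K), function(k) {
    log(best$w[k]) + ldmvnorm2(x, best$mu[k, ], best$sig[[k]])
  }, numeric(n))
  logdens <- matrix(logdens, n, K)
  assign <- max.col(logdens)

  npar <- (K - 1) + 2 * K + 3 * K
  model <- structure(
    list(K = K, weights = best$w, means = best$mu,
         covariances = best$sig,
         log_likelihood = best$ll,
         BIC = 2 * best$ll - npar * log(n),
         assignments = assign,
         ll_trace = best$ll_trace, n_iter = best$n_iter,
         outlier_quantile = outlier_quantile,
         points = x),
    class = "cluster_model")
  model$outlier <- flag_outliers(model, x, quantile = outlier_quantile)
  model
}

#' Flag out-of-cluster points by Mahalanobis quantile
#'
#' A point is an outlier of its assigned component when its squared
#' Mahalanobis distance exceeds the `quantile` quantile of the chi-squared
#' distribution with 2 degrees of freedom (~3.219 at the default 80%
#' coverage).
#'
#' @param model A `cluster_model`.
#' @param points N x 2 matrix (defaults to the fitted points).
#' @param quantile Coverage of the in-cluster region. Default 0.8.
#' @return Logical vector.
#' @export
flag_outliers <- function(model, points = model$points, quantile = 0.8) {
  x <- as.matrix(points)
  thr <- qchisq(quantile, df = 2)
  assign <- if (nrow(x) == length(model$assignments)) model$assignments else {
    ld <- vapply(seq_len(model$K), function(k) {
      log(model$weights[k]) + ldmvnorm2(x, model$means[k, ],
                                        model$covariances[[k]])
    }, numeric(nrow(x)))
    max.col(matrix(ld, nrow(x), model$K))
  }
  d2 <- numeric(nrow(x))
  for (k in seq_len(model$K)) {
    i <- assign == k
    if (!any(i)) next
    d2[i] <- stats::mahalanobis(x[i, , drop = FALSE], model$means[k, ],
                                model$covariances[[k]])
  }
  d2 > thr
}

#' Choose the number of mixture components
#'
#' Fits candidate component counts and returns the smallest K whose BIC is
#' within a tolerance of the best (maximum) BIC across candidates — the "BIC
#' close to the optimum, minimal number of clusters" rule. The tolerance is
#' `delta_frac` of the BIC range over candidates, so the rule is invariant to
#' the BIC's scale; with all candidates tied the minimal K wins.
#'
#' @param points N x 2 matrix or tibble.
#' @param k_range Candidate component counts. Default 1:12.
#' @param delta_frac Fraction of the candidate BIC range used as closeness
#'   tolerance. Default 0.01.
#' @param ... Passed to [fit_gmm_em()].
#' @return A list of class `k_selection`: `K` (chosen), `bic` (tibble of
#'   candidates), `models` (fitted `cluster_model`s).
#' @export
select_k <- function(points, k_range = 1:12, delta_frac = 0.01, ...) {
  if (length(k_range) == 0) abort("Empty candidate set.")
  models <- purrr::map(k_range, function(k) {
    tryCatch(fit_gmm_em(points, K = k, ...), error = function(e) NULL)
  })
  keep <- !vapply(models, is.null, TRUE)
  if (!any(keep)) abort("No candidate K could be fitted.")
  k_range <- k_range[keep]
  models <- models[keep]
  bic <- vapply(models, function(m) m$BIC, 0)
  delta <- delta_frac * diff(range(bic))
  ok <- bic >= max(bic) - delta
  chosen <- min(k_range[ok])
  structure(
    list(K = chosen,
         bic = tibble(K = k_range, BIC = bic, within_tolerance = ok),
         models = setNames(models, paste0("K", k_range))),
    class = "k_selection")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> K =", x$K, " BIC =", round(x$BIC, 1),
      " logLik =", round(x$log_likelihood, 1),
      " outliers =", sum(x$outlier), "/", length(x$outlier), "\n")
  invisible(x)
}

#' @export
tidy.cluster_model <- function(x, ...) {
  tibble(component = seq_len(x$K),
         weight = x$weights,
         mean_1 = x$means[, 1], mean_2 = x$means[, 2],
         var_1 = vapply(x$covariances, function(s) s[1, 1], 0),
         var_2 = vapply(x$covariances, function(s) s[2, 2], 0),
         cov_12 = vapply(x$covariances, function(s) s[1, 2], 0),
         n_points = as.integer(table(factor(x$assignments,
                                            levels = seq_len(x$K)))))
}

#' @export
glance.cluster_model <- function(x, ...) {
  tibble(K = x$K, log_likelihood = x$log_likelihood, BIC = x$BIC,
         n_iter = x$n_iter, outlier_fraction = mean(x$outlier),
         nobs = length(x$assignments))
}

#' @export
augment.cluster_model <- function(x, ...) {
  tibble(tsne_1 = x$points[, 1], tsne_2 = x$points[, 2],
         cluster = factor(x$assignments), outlier = x$outlier)
}

#' @importFrom generics augment
#' @export
generics::augment

#' @describeIn fit_gmm_em Embedding colored by cluster, outliers hollow.
#' @param object A `cluster_model`.
#' @param ... Unused.
#' @export
autoplot.cluster_model <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne_1, y = .data$tsne_2,
                                   colour = .data$cluster,
                                   shape = .data$outlier)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(shape = "outlier")
}
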