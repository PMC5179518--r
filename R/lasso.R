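as_xy <- function(x, y) {
  if (inherits(x, "cyto_design")) {
    list(x = x$x, y = x$y, columns = x$columns)
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    if (length(y) != nrow(x)) abort("rows(x) must equal length(y).")
    list(x = x, y = as.numeric(y), columns = NULL)
  }
}

default_lambda_grid <- function(x, y, nlambda = 50, min_ratio = 1e-3) {
  n <- nrow(x)
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  lam_max <- max(abs(crossprod(xc, yc))) / n
  if (lam_max <= 0) lam_max <- 1
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = nlambda))
}

#' Fit an L1-penalized (lasso) regression path
#'
#' Coordinate descent over a decreasing lambda grid for the objective
#' `(1/2n) * ||y - b0 - X b||^2 + lambda * ||b||_1` with an unpenalized
#' intercept, warm-started along the grid. Predictors enter the penalty on
#' the \[0,1\] scale produced by [build_design()]; no internal
#' re-standardization is applied (double-scaling would distort the
#' uniformized interaction predictors).
#'
#' @param x A `cyto_design` from [build_design()], or a numeric predictor
#'   matrix.
#' @param y Response vector (ignored when `x` is a `cyto_design`).
#' @param lambda Decreasing positive grid; computed from the data when `NULL`
#'   (`nlambda` log-spaced values from the smallest all-zero lambda down to
#'   `lambda_min_ratio` of it).
#' @param nlambda,lambda_min_ratio Grid shape when `lambda` is `NULL`.
#' @param tol Convergence tolerance on the largest coefficient change per
#'   sweep. Default 1e-7.
#' @param max_sweeps Maximum coordinate-descent sweeps per lambda.
#' @param trace Record the objective value after every sweep (for
#'   monotonicity diagnostics)?
#' @return An object of class `lasso_fit`: `lambda`, `beta`
#'   (predictors x lambda), `intercept`, `columns` metadata (when fitted from
#'   a `cyto_design`), and optionally `objective_trace`.
#' @export
fit_lasso_path <- function(x, y = NULL, lambda = NULL, nlambda = 50,
                           lambda_min_ratio = 1e-3, tol = 1e-7,
                           max_sweeps = 10000, trace = FALSE) {
  d <- as_xy(x, y)
  if (nrow(d$x) < 2) abort("Need at least two samples.")
  if (any(apply(d$x, 2, function(v) max(v) == min(v)))) {
    abort("Degenerate predictor: constant column.")
  }
  if (is.null(lambda)) {
    lambda <- default_lambda_grid(d$x, d$y, nlambda, lambda_min_ratio)
  }
  lambda <- as.numeric(lambda)
  if (any(lambda <= 0) || is.unsorted(rev(lambda), strictly = FALSE)) {
    abort("`lambda` must be positive and decreasing.")
  }
  fit <- lasso_path_cpp(d$x, d$y, lambda, tol, as.integer(max_sweeps), trace)
  rownames(fit$beta) <- colnames(d$x)
  structure(
    list(lambda = lambda, beta = fit$beta,
         intercept = as.numeric(fit$intercept),
         objective_trace = fit$objective_trace %||% NULL,
         columns = d$columns, n = nrow(d$x), tol = tol),
    class = "lasso_fit"
  )
}

make_folds <- function(n, n_folds, n_repeats, seed, donors = NULL) {
  set.seed(derive_seed(seed, 2))
  if (!is.null(donors)) {
    donors <- as.character(donors)
    ids <- unique(donors)
    k <- n_folds
    if (length(ids) < n_folds) {
      k <- length(ids)
      warn(sprintf(
        "Only %d donors for %d folds; using %d donor-grouped folds.",
        length(ids), n_folds, k))
    }
    t(vapply(seq_len(n_repeats), function(r) {
      df <- sample(rep(seq_len(k), length.out = length(ids)))
      names(df) <- ids
      unname(df[donors])
    }, integer(n)))
  } else {
    if (n_folds > n) abort("More folds than samples.")
    t(vapply(seq_len(n_repeats), function(r) {
      sample(rep(seq_len(n_folds), length.out = n))
    }, integer(n)))
  }
}

#' Repeated cross-validation for the shrinkage parameter
#'
#' Ten-fold cross-validation with squared-error loss determines the shrinkage
#' parameter; because different fold-split realizations give different CV
#' curves, the curve is averaged over `n_repeats` independent realizations
#' and the optimal lambda is the minimizer of the mean curve. Folds can be
#' grouped by donor so that all samples of a donor stay in one fold
#' (responses within a donor are dependent); when fewer donors than folds are
#' available the fold count drops to the donor count.
#'
#' @inheritParams fit_lasso_path
#' @param n_folds Folds per CV run. Default 10.
#' @param n_repeats Fold-split realizations averaged. Default 50; the full
#'   published profile uses 1000.
#' @param seed Integer seed; identical seeds give identical folds, curves and
#'   selected lambda.
#' @param donors Optional per-row donor ids for donor-grouped folds (used
#'   automatically when `x` is a `cyto_design`; pass `NULL` explicitly to
#'   disable).
#' @return A `lasso_cv` object (extends `lasso_fit`, fitted on the full
#'   data): adds `cv_mean_error`, `run_error` (repeats x lambda),
#'   `lambda_opt`, `n_folds`, `n_repeats`.
#' @export
cross_validate <- function(x, y = NULL, lambda = NULL, n_folds = 10,
                           n_repeats = 50, seed = 1,
                           donors = if (inherits(x, "cyto_design"))
                             x$samples$donor else NULL,
                           nlambda = 50, lambda_min_ratio = 1e-3,
                           tol = 1e-7, max_sweeps = 10000) {
  d <- as_xy(x, y)
  n <- nrow(d$x)
  if (n_folds > n) abort("More folds than samples.")
  fit <- fit_lasso_path(x, y, lambda = lambda, nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio, tol = tol,
                        max_sweeps = max_sweeps)
  folds <- make_folds(n, n_folds, n_repeats, seed, donors)
  cv <- lasso_cv_cpp(d$x, d$y, fit$lambda, folds, tol,
                     as.integer(max_sweeps))
  fit$cv_mean_error <- as.numeric(cv$cv_mean_error)
  fit$run_error <- cv$run_error
  fit$lambda_opt <- fit$lambda[which.min(fit$cv_mean_error)]
  fit$n_folds <- n_folds
  fit$n_repeats <- n_repeats
  fit$seed <- seed
  class(fit) <- c("lasso_cv", "lasso_fit")
  fit
}

coef_at_lambda <- function(fit, lambda) {
  i <- which.min(abs(fit$lambda - lambda))
  list(beta = fit$beta[, i], intercept = fit$intercept[i],
       lambda = fit$lambda[i])
}

#' Net effects of cytokines and cytokine pairs
#'
#' At the selected lambda, the net effect of a single cytokine is its
#' regression coefficient; the net effect of a cytokine pair is the sum of
#' the two single-cytokine coefficients and their interaction coefficient.
#'
#' @param fit A `lasso_cv` (uses `lambda_opt`) or `lasso_fit` with `lambda`
#'   supplied; must have been fitted from a `cyto_design` so that column
#'   roles are known.
#' @param lambda Lambda at which to read coefficients (default
#'   `fit$lambda_opt`).
#' @return A tibble of class `net_effects`: `term`, `type`
#'   (`"cytokine"`/`"pair"`), `net_effect`, and the contributing coefficients
#'   `coef_a`, `coef_b`, `coef_interaction`.
#' @export
net_effects <- function(fit, lambda = fit$lambda_opt) {
  if (is.null(fit$columns)) {
    abort("Fit carries no column roles; fit from a `cyto_design`.")
  }
  if (is.null(lambda)) abort("No lambda selected; run cross_validate().")
  cf <- coef_at_lambda(fit, lambda)$beta
  cols <- fit$columns
  singles <- cols |>
    filter(.data$role == "cytokine") |>
    mutate(term = .data$column, type = "cytokine",
           coef_a = unname(cf[.data$column]), coef_b = NA_real_,
           coef_interaction = NA_real_,
           net_effect = unname(cf[.data$column]))
  prs <- cols |> filter(.data$role == "pair")
  if (nrow(prs)) {
    missing <- setdiff(prs$column, names(cf))
    if (length(missing)) {
      abort(paste0("Missing interaction column(s): ",
                   paste(missing, collapse = ", ")))
    }
    prs <- prs |>
      mutate(term = .data$column, type = "pair",
             coef_a = unname(cf[.data$cytokine_a]),
             coef_b = unname(cf[.data$cytokine_b]),
             coef_interaction = unname(cf[.data$column]),
             net_effect = .data$coef_a + .data$coef_b +
               .data$coef_interaction)
  }
  out <- bind_rows(singles, prs) |>
    select("term", "type", "net_effect", "coef_a", "coef_b",
           "coef_interaction")
  class(out) <- c("net_effects", class(out))
  attr(out, "lambda") <- coef_at_lambda(fit, lambda)$lambda
  out
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> ", nrow(x$beta), " predictors, ", length(x$lambda),
      " lambda values\n", sep = "")
  if (!is.null(x$lambda_opt)) {
    cat("  lambda_opt = ", signif(x$lambda_opt, 4), " (", x$n_repeats,
        " x ", x$n_folds, "-fold CV)\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.lasso_fit <- function(x, lambda = x$lambda_opt, ...) {
  if (is.null(lambda)) {
    # full path in long form
    as_tibble(as.data.frame(x$beta)) |>
      mutate(term = rownames(x$beta)) |>
      tidyr::pivot_longer(-"term", names_to = "step",
                          values_to = "estimate") |>
      mutate(lambda = rep(x$lambda, times = nrow(x$beta))) |>
      select("term", "lambda", "estimate")
  } else {
    cf <- coef_at_lambda(x, lambda)
    tibble(term = rownames(x$beta), estimate = unname(cf$beta),
           lambda = cf$lambda)
  }
}

#' @export
glance.lasso_cv <- function(x, ...) {
  tibble(lambda_opt = x$lambda_opt,
         cv_error_min = min(x$cv_mean_error),
         n_folds = x$n_folds, n_repeats = x$n_repeats,
         n_active = sum(coef_at_lambda(x, x$lambda_opt)$beta != 0),
         nobs = x$n)
}

#' @describeIn cross_validate Mean CV error curve over the lambda grid, with
#'   the selected lambda marked.
#' @param object A `lasso_cv` object.
#' @param ... Unused.
#' @export
autoplot.lasso_cv <- function(object, ...) {
  df <- tibble(lambda = object$lambda, cv = object$cv_mean_error)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda_opt, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda),
                  y = "mean CV squared error",
                  title = sprintf("Repeated %d-fold CV (%d repeats)",
                                  object$n_folds, object$n_repeats))
}

#' @describeIn net_effects Diverging bar chart of net effects.
#' @param object A `net_effects` tibble.
#' @param ... Unused.
#' @export
autoplot.net_effects <- function(object, ...) {
  df <- object |> filter(.data$net_effect != 0)
  ggplot2::ggplot(df,
                  ggplot2::aes(x = stats::reorder(.data$term,
                                                  .data$net_effect),
                               y = .data$net_effect, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "net effect on Δ % positive cells")
}
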