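#' Uniformization transform for products of unit uniforms
#'
#' The product of n independent Uniform(0,1) variables has density
#' `(-ln x)^(n-1) / (n-1)!` on (0,1\]; its CDF,
#' `F(p) = p * sum_{k=0}^{n-1} (-ln p)^k / k!`, maps the product back onto a
#' uniform scale. Interaction predictors pass through this transform so that
#' they share the \[0,1\] uniform range of the main-effect predictors. For
#' n = 2 the CDF reduces to the closed form `p - p*ln(p)`.
#'
#' @param p Numeric vector of product values in (0, 1\].
#' @param n Number of uniform factors in the product (integer >= 2).
#' @return Transformed values in (0, 1\]; strictly increasing in `p`.
#' @examples
#' uniformize_product(exp(-1))        # 2/e
#' uniformize_product(c(0.1, 0.5, 1))
#' @export
uniformize_product <- function(p, n = 2) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (length(n) != 1 || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.")
  }
  if (any(p <= 0 | p > 1)) {
    abort("`p` must lie in (0, 1]; zero products are handled upstream by continuity.")
  }
  .uniformize0(p, n)
}

# lim_{p->0} F(p) = 0 by continuity; used internally where exact-zero products
# (absent cytokines) are legitimate.
.uniformize0 <- function(p, n = 2) {
  out <- numeric(length(p))
  pos <- p > 0
  pp <- p[pos]
  lg <- -log(pp)
  acc <- rep(1, length(pp))   # k = 0 term
  term <- rep(1, length(pp))
  for (k in seq_len(n - 1)) {
    term <- term * lg / k
    acc <- acc + term
  }
  out[pos] <- pp * acc
  out
}

#' Build the net-effect regression design from a screen
#'
#' Assembles the predictor matrix and response vector of the cytokine
#' net-effect regression: one column per cytokine (concentration min-max
#' normalized across all conditions), one per unordered cytokine pair (the
#' product of the two normalized concentrations passed through
#' [uniformize_product()]), and one for time (min-max normalized). The
#' response is the within-donor change in %positive versus the donor-,
#' time- and experiment-matched control; control rows are excluded, and
#' replicate rows of the same (donor, condition, time, experiment) are
#' averaged first.
#'
#' @param design Design tibble from [generate_design()].
#' @param fractions Tibble with columns `donor`, `condition_id`, `time_days`,
#'   `fraction` (measured %positive per sample) and optionally `experiment`
#'   (controls are matched within experiment; a single implicit experiment is
#'   assumed when absent).
#' @return An object of class `cyto_design`: a list with
#'   \describe{
#'   \item{x}{numeric predictor matrix, all entries in \[0,1\]}
#'   \item{y}{numeric response vector (percentage points)}
#'   \item{columns}{tibble of column metadata: `column`, `role`
#'     (cytokine/pair/time), `cytokine_a`, `cytokine_b`}
#'   \item{samples}{tibble of row metadata incl. the matched control id}
#'   }
#' @export
build_design <- function(design, fractions) {
  validate_design(design)
  fractions <- as_tibble(fractions)
  need <- c("donor", "condition_id", "time_days", "fraction")
  if (!all(need %in% names(fractions))) {
    abort(paste0("`fractions` needs columns: ", paste(need, collapse = ", ")))
  }
  if (!"experiment" %in% names(fractions)) fractions$experiment <- "E1"

  # replicate wells averaged before differencing
  fractions <- fractions |>
    group_by(.data$donor, .data$condition_id, .data$time_days,
             .data$experiment) |>
    summarise(fraction = mean(.data$fraction), .groups = "drop")

  xnorm <- normalized_concentrations(design)
  cyt <- colnames(xnorm)
  key <- paste(design$condition_id, design$time_days)
  rownames(xnorm) <- key

  if (length(unique(design$time_days)) < 2) {
    abort("Time normalization needs more than one activation duration.")
  }
  time_norm <- minmax_normalize(design$time_days)
  names(time_norm) <- key

  ctrl <- fractions |>
    dplyr::semi_join(design |> filter(.data$is_control), by = "condition_id") |>
    select("donor", "time_days", "experiment", control_fraction = "fraction",
           control_id = "condition_id")
  treated <- fractions |>
    dplyr::anti_join(design |> filter(.data$is_control), by = "condition_id") |>
    left_join(ctrl, by = c("donor", "time_days", "experiment"))
  if (anyNA(treated$control_fraction)) {
    bad <- treated |> filter(is.na(.data$control_fraction))
    abort(paste0("No matched control for sample(s): ",
                 paste(utils::head(paste(bad$donor, bad$condition_id,
                                         bad$time_days, sep = "/"), 5),
                       collapse = ", ")))
  }

  rkey <- paste(treated$condition_id, treated$time_days)
  missing_rows <- setdiff(rkey, key)
  if (length(missing_rows)) {
    abort(paste0("Samples not present in the design: ",
                 paste(head(missing_rows, 5), collapse = ", ")))
  }
  xr <- xnorm[rkey, , drop = FALSE]

  k <- length(cyt)
  cols <- list()
  xlist <- list()
  for (j in seq_len(k)) {
    cols[[length(cols) + 1]] <- tibble(column = cyt[j], role = "cytokine",
                                       cytokine_a = cyt[j],
                                       cytokine_b = NA_character_)
    xlist[[length(xlist) + 1]] <- xr[, j]
  }
  if (k >= 2) {
    cmb <- utils::combn(cyt, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      cols[[length(cols) + 1]] <- tibble(column = pair_key(a, b),
                                         role = "pair",
                                         cytokine_a = a, cytokine_b = b)
      xlist[[length(xlist) + 1]] <- .uniformize0(xr[, a] * xr[, b])
    }
  }
  cols[[length(cols) + 1]] <- tibble(column = "time", role = "time",
                                     cytokine_a = NA_character_,
                                     cytokine_b = NA_character_)
  xlist[[length(xlist) + 1]] <- unname(time_norm[rkey])

  x <- do.call(cbind, xlist)
  columns <- bind_rows(cols)
  colnames(x) <- columns$column
  rownames(x) <- NULL

  structure(
    list(
      x = x,
      y = treated$fraction - treated$control_fraction,
      columns = columns,
      samples = treated |>
        select("donor", "condition_id", "time_days", "experiment",
               "fraction", "control_fraction", "control_id")
    ),
    class = "cyto_design"
  )
}

#' @export
print.cyto_design <- function(x, ...) {
  cat("<cyto_design> ", nrow(x$x), " samples x ", ncol(x$x), " predictors (",
      sum(x$columns$role == "cytokine"), " cytokines, ",
      sum(x$columns$role == "pair"), " pairs, time)\n", sep = "")
  invisible(x)
}

#' @export
tidy.cyto_design <- function(x, ...) {
  bind_cols(x$samples, as_tibble(x$x), tibble(delta = x$y))
}
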