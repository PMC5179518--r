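as_gated_events <- function(sample) {
  ev <- if (inherits(sample, "gated_sample")) sample$events else
    as_tibble(sample)
  if (nrow(ev) == 0) abort("No gated cells.")
  ev
}

require_positivity <- function(ev, markers) {
  need <- paste0("pos_", markers)
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    abort(paste0("Positivity not computed for: ",
                 paste(sub("^pos_", "", missing), collapse = ", ")))
  }
  if (!"generation" %in% names(ev)) abort("Generations not assigned.")
  invisible(ev)
}

#' Marker-positive fraction within each proliferation cycle
#'
#' Computes %positive independently within every generation, conditioning on
#' proliferation and thereby eliminating its confounding effect on marker
#' fractions. Generations with fewer than `min_cells` cells are reported as
#' missing (not zero) to control binomial noise.
#'
#' @param sample A `gated_sample` (or its event tibble) with `generation` and
#'   `pos_<marker>` columns.
#' @param marker Marker name.
#' @param min_cells Minimum cells per generation for reporting. Default 20.
#' @return Tibble: `generation`, `n_cells`, `pct_positive`.
#' @export
fraction_by_cycle <- function(sample, marker, min_cells = 20) {
  ev <- require_positivity(as_gated_events(sample), marker)
  ev |>
    group_by(generation = .data$generation) |>
    summarise(n_cells = n(),
              pct_positive = 100 * mean(.data[[paste0("pos_", marker)]]),
              .groups = "drop") |>
    mutate(pct_positive = ifelse(.data$n_cells < min_cells, NA_real_,
                                 .data$pct_positive)) |>
    arrange(.data$generation)
}

#' Quadrant composition per proliferation cycle
#'
#' For a marker pair, the four joint-positivity quadrants (++, +-, -+, --)
#' are quantified within each generation; the four fractions sum to 100 per
#' generation. With a third marker the triple-positive fraction is reported
#' as well.
#'
#' @inheritParams fraction_by_cycle
#' @param marker_a,marker_b Quadrant marker pair.
#' @param marker_c Optional third marker for the triple-positive fraction.
#' @return Tibble: `generation`, `n_cells`, `pct_pos_pos`, `pct_pos_neg`,
#'   `pct_neg_pos`, `pct_neg_neg` (A then B), and `pct_triple` when
#'   `marker_c` is given. Rows with fewer than `min_cells` cells carry `NA`
#'   fractions.
#' @export
quadrant_by_cycle <- function(sample, marker_a, marker_b, marker_c = NULL,
                              min_cells = 20) {
  ev <- require_positivity(as_gated_events(sample),
                           c(marker_a, marker_b, marker_c))
  pa <- ev[[paste0("pos_", marker_a)]]
  pb <- ev[[paste0("pos_", marker_b)]]
  out <- tibble(generation = ev$generation,
                pp = pa & pb, pn = pa & !pb, np = !pa & pb, nn = !pa & !pb)
  if (!is.null(marker_c)) {
    out$triple <- pa & pb & ev[[paste0("pos_", marker_c)]]
  }
  res <- out |>
    group_by(.data$generation) |>
    summarise(n_cells = n(),
              pct_pos_pos = 100 * mean(.data$pp),
              pct_pos_neg = 100 * mean(.data$pn),
              pct_neg_pos = 100 * mean(.data$np),
              pct_neg_neg = 100 * mean(.data$nn),
              pct_triple = if ("triple" %in% names(out))
                100 * mean(.data$triple) else NA_real_,
              .groups = "drop") |>
    arrange(.data$generation)
  if (is.null(marker_c)) res$pct_triple <- NULL
  mask <- res$n_cells < min_cells
  res[mask, setdiff(names(res), c("generation", "n_cells"))] <- NA_real_
  res
}

#' Distribution of cells across proliferation cycles
#'
#' @inheritParams fraction_by_cycle
#' @return Tibble: `generation`, `n_cells`, `pct_of_cells` (sums to 100).
#' @export
cycle_distribution <- function(sample) {
  ev <- as_gated_events(sample)
  if (!"generation" %in% names(ev)) abort("Generations not assigned.")
  ev |>
    group_by(generation = .data$generation) |>
    summarise(n_cells = n(), .groups = "drop") |>
    mutate(pct_of_cells = 100 * .data$n_cells / sum(.data$n_cells)) |>
    arrange(.data$generation)
}

#' @describeIn fraction_by_cycle Line plot of per-cycle positive fractions.
#' @param object Result tibble of `fraction_by_cycle()`.
#' @param ... Unused.
#' @export
plot_fraction_by_cycle <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation,
                                       y = .data$pct_positive)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "proliferation cycle", y = "% positive within cycle")
}
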