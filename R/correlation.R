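#' Population-level marker co-expression across stimulation conditions
#'
#' Spearman correlation of %positive-cell fractions between marker pairs
#' across samples (each sample = stimulation condition x donor x experiment).
#' The p-value treats the per-donor Spearman coefficient as the random
#' variable: rho is computed within each donor across that donor's samples
#' and a one-sample two-sided t-test of the per-donor rho values against zero
#' is reported. This operationalizes a paired test on rho; it is one
#' defensible reading of testing H0: rho = 0 with donor pairing and is
#' flagged as such in the output.
#'
#' @param fraction_table Tibble with one row per sample: a `donor` column and
#'   one numeric %positive column per marker.
#' @param markers Marker columns to correlate (default: all numeric columns
#'   except metadata).
#' @return Tibble of class `correlation_result`: `marker_a`, `marker_b`,
#'   `rho` (pooled across all samples), `p_value` (t-test on per-donor rho;
#'   `NA` when fewer than 2 donors contribute), `n_samples`, `n_donors`,
#'   `level = "population"`, `flag` (degenerate/constant cases).
#' @export
population_correlation <- function(fraction_table, markers = NULL) {
  ft <- as_tibble(fraction_table)
  if (!"donor" %in% names(ft)) abort("`fraction_table` needs a `donor` column.")
  meta <- c("donor", "condition_id", "time_days", "experiment", "group")
  if (is.null(markers)) {
    markers <- setdiff(names(ft)[vapply(ft, is.numeric, TRUE)],
                       meta)
  }
  if (length(markers) < 2) abort("Need at least two marker columns.")
  if (nrow(ft) < 3) abort("Need at least 3 samples.")

  cmb <- utils::combn(markers, 2)
  out <- purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    xa <- ft[[a]]; xb <- ft[[b]]
    flag <- NA_character_
    if (sd(xa) == 0 || sd(xb) == 0) {
      return(tibble(marker_a = a, marker_b = b, rho = NA_real_,
                    p_value = NA_real_, n_samples = nrow(ft),
                    n_donors = dplyr::n_distinct(ft$donor),
                    level = "population", flag = "constant marker"))
    }
    rho <- cor(xa, xb, method = "spearman")
    per_donor <- ft |>
      group_by(.data$donor) |>
      summarise(rho_d = if (n() >= 3 && sd(.data[[a]]) > 0 &&
                            sd(.data[[b]]) > 0)
        cor(.data[[a]], .data[[b]], method = "spearman")
        else NA_real_, .groups = "drop") |>
      filter(!is.na(.data$rho_d))
    p <- if (nrow(per_donor) >= 2 && sd(per_donor$rho_d) > 0) {
      # degenerate spread (all donors at the same rho) leaves p undefined
      tryCatch(t.test(per_donor$rho_d, mu = 0)$p.value,
               error = function(e) NA_real_)
    } else NA_real_
    tibble(marker_a = a, marker_b = b, rho = rho, p_value = p,
           n_samples = nrow(ft), n_donors = dplyr::n_distinct(ft$donor),
           level = "population", flag = flag)
  })
  class(out) <- c("correlation_result", class(out))
  out
}

#' Single-cell marker co-expression per sample
#'
#' Spearman correlation between marker pairs over the single cells of each
#' sample, computed on (min-max normalized) fluorescence intensities — a rank
#' statistic, so any strictly monotone per-channel transform leaves it
#' unchanged. Results are grouped by stimulation-condition class for
#' box-summary export. Samples with fewer than `min_cells` cells are skipped
#' with a warning.
#'
#' @param cell_table Tibble of single cells with a `sample_id` column (or
#'   `donor` + `condition_id`), an optional `group` column (condition class),
#'   and one intensity column per marker.
#' @param pairs Two-column matrix or list of character pairs; default all
#'   pairs of `markers`.
#' @param markers Marker columns (default: numeric non-metadata columns).
#' @param min_cells Minimum cells per sample. Default 10.
#' @return Tibble of class `correlation_result`: one row per
#'   (sample, pair) with `rho`, `n_cells`, `group`, `level = "single_cell"`.
#' @export
single_cell_correlation <- function(cell_table, pairs = NULL, markers = NULL,
                                    min_cells = 10) {
  ct <- as_tibble(cell_table)
  if (!"sample_id" %in% names(ct)) {
    if (all(c("donor", "condition_id") %in% names(ct))) {
      ct$sample_id <- paste(ct$donor, ct$condition_id, sep = "/")
    } else {
      abort("`cell_table` needs `sample_id` (or donor + condition_id).")
    }
  }
  if (!"group" %in% names(ct)) ct$group <- "all"
  meta <- c("sample_id", "group", "donor", "condition_id", "time_days",
            "experiment")
  if (is.null(markers)) {
    markers <- setdiff(names(ct)[vapply(ct, is.numeric, TRUE)], meta)
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(markers, 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }

  out <- ct |>
    group_by(.data$sample_id, .data$group) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(res = purrr::map(.data$data, function(d) {
      if (nrow(d) < min_cells) return(NULL)
      purrr::map_dfr(seq_len(nrow(pairs)), function(j) {
        a <- pairs[j, 1]; b <- pairs[j, 2]
        tibble(marker_a = a, marker_b = b,
               rho = suppressWarnings(
                 cor(d[[a]], d[[b]], method = "spearman")),
               n_cells = nrow(d))
      })
    }))
  skipped <- sum(vapply(out$res, is.null, TRUE))
  if (skipped > 0) {
    warn(sprintf("%d sample(s) skipped (< %d cells).", skipped, min_cells))
  }
  res <- out |>
    filter(!vapply(.data$res, is.null, TRUE)) |>
    select("sample_id", "group", "res") |>
    tidyr::unnest("res") |>
    mutate(level = "single_cell")
  class(res) <- c("correlation_result", class(res))
  res
}

#' Paired group comparison with normality pre-test
#'
#' Shapiro-Wilk is applied to the paired differences first; when normality is
#' rejected at the 5% level (or n is too small for the test), the
#' non-parametric Wilcoxon signed-rank test paired within each donor is used,
#' otherwise a paired t-test. The test actually applied is reported. With all
#' differences zero the comparison is degenerate and reported as p = 1 with a
#' flag.
#'
#' @param x,y Equal-length paired measurement vectors (one entry per donor).
#' @param method `"auto"` (normality pre-test decides), or force
#'   `"wilcoxon"` / `"t"`.
#' @param exact Exact Wilcoxon p (enumeration) where available; default uses
#'   the exact distribution for n <= 50 without ties, as in
#'   [stats::wilcox.test()].
#' @return One-row tibble: `method`, `p_value`, `statistic`, `n_pairs`,
#'   `normality_p`, `flag`.
#' @examples
#' compare_paired(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
#' @export
compare_paired <- function(x, y, method = c("auto", "wilcoxon", "t"),
                           exact = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("Need at least 2 pairs.")
  d <- x - y
  if (all(d == 0)) {
    return(tibble(method = "degenerate (all differences zero)",
                  p_value = 1, statistic = NA_real_, n_pairs = length(d),
                  normality_p = NA_real_, flag = "degenerate"))
  }
  sw_p <- if (length(unique(d)) >= 3 && length(d) >= 3 && length(d) <= 5000) {
    tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  } else NA_real_
  use_wilcox <- switch(method,
                       auto = is.na(sw_p) || sw_p < 0.05,
                       wilcoxon = TRUE,
                       t = FALSE)
  if (use_wilcox) {
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
    tibble(method = "Wilcoxon signed-rank (paired)", p_value = wt$p.value,
           statistic = unname(wt$statistic), n_pairs = length(d),
           normality_p = sw_p, flag = NA_character_)
  } else {
    tt <- t.test(x, y, paired = TRUE)
    tibble(method = "paired t-test", p_value = tt$p.value,
           statistic = unname(tt$statistic), n_pairs = length(d),
           normality_p = sw_p, flag = NA_character_)
  }
}

#' @describeIn single_cell_correlation Boxplot of per-sample single-cell rho
#'   by marker pair and condition group.
#' @param object A `correlation_result` from [single_cell_correlation()].
#' @param ... Unused.
#' @export
autoplot.correlation_result <- function(object, ...) {
  if (!"level" %in% names(object) || !any(object$level == "single_cell")) {
    df <- object |> mutate(pair = paste(.data$marker_a, .data$marker_b,
                                        sep = " ~ "))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pair,
                                                          .data$rho),
                                       y = .data$rho)) +
        ggplot2::geom_col() + ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = expression(rho))
    )
  }
  df <- object |>
    filter(.data$level == "single_cell") |>
    mutate(pair = paste(.data$marker_a, .data$marker_b, sep = " ~ "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$rho)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = expression(rho ~ "(per sample)")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
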