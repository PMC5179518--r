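#' Perplexity from the 10%-of-N rule
#'
#' The embedding perplexity is one tenth of the number of pooled data points,
#' rounded half-up to the nearest integer (e.g. 2,580 pooled cells give
#' perplexity 258).
#'
#' @param n_points Number of data points (>= 30; below that the effective
#'   neighborhood is ill-posed).
#' @return Integer perplexity.
#' @examples
#' compute_perplexity(2580)
#' @export
compute_perplexity <- function(n_points) {
  if (length(n_points) != 1 || n_points < 30) {
    abort("Perplexity rule needs at least 30 points.")
  }
  as.integer(round_half_up(0.10 * n_points))
}

#' Pool equal numbers of marker-positive cells per donor and condition
#'
#' Selects cells positive for the gating marker (default GM-CSF), samples an
#' equal count from every (donor, condition) group, drops the selection
#' marker's own channel, and min-max normalizes the remaining feature
#' channels across the pooled cells.
#'
#' @param cells Tibble of gated cells with `donor`, `condition_id`, a
#'   `pos_<marker>` positivity column, and intensity channels.
#' @param marker Selection marker. Default `"GM-CSF"`.
#' @param per_group_count Cells sampled per (donor, condition).
#' @param features Feature channels kept; default the five non-selection
#'   markers of the panel (`FOXP3`, `CD25`, `IFN-g`, `ProlifDye`, `IL-2`)
#'   intersected with available channels.
#' @param seed Integer seed for the subsampling.
#' @return Tibble: `donor`, `condition_id`, and the normalized feature
#'   columns (all values in \[0,1\]).
#' @export
select_positive_subset <- function(cells, marker = "GM-CSF",
                                   per_group_count,
                                   features = NULL, seed = 1) {
  cells <- as_tibble(cells)
  pcol <- paste0("pos_", marker)
  need <- c("donor", "condition_id", pcol)
  if (!all(need %in% names(cells))) {
    abort(paste0("`cells` needs columns: ", paste(need, collapse = ", ")))
  }
  if (is.null(features)) {
    features <- intersect(c("FOXP3", "CD25", "IFN-g", "ProlifDye", "IL-2"),
                          names(cells))
  }
  features <- setdiff(features, marker)
  if (length(features) == 0) abort("No feature channels left.")

  pos <- cells |> filter(.data[[pcol]])
  counts <- pos |> dplyr::count(.data$donor, .data$condition_id)
  short <- counts |> filter(.data$n < per_group_count)
  groups_all <- cells |> distinct(.data$donor, .data$condition_id)
  missing <- dplyr::anti_join(groups_all, counts,
                              by = c("donor", "condition_id"))
  if (nrow(short) || nrow(missing)) {
    bad <- c(paste(short$donor, short$condition_id, sep = "/"),
             paste(missing$donor, missing$condition_id, sep = "/"))
    abort(paste0("Insufficient ", marker, "+ cells (need ",
                 per_group_count, ") for: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  set.seed(derive_seed(seed, 3))
  pooled <- pos |>
    group_by(.data$donor, .data$condition_id) |>
    dplyr::slice_sample(n = per_group_count) |>
    ungroup() |>
    select("donor", "condition_id", dplyr::all_of(features))
  pooled |>
    mutate(across(dplyr::all_of(features), minmax_normalize))
}

#' Exact t-SNE embedding
#'
#' Exact-gradient (theta = 0, no tree approximation) t-SNE of a feature
#' matrix into two dimensions, with the standard momentum schedule and early
#' exaggeration. Initialization is the first two principal components scaled
#' to SD 1e-4 plus a seeded jitter, so identical seeds give identical
#' embeddings. The default iteration budget matches the published profile
#' (10,000); the perplexity defaults to the 10%-of-N rule of
#' [compute_perplexity()].
#'
#' @param features Numeric matrix or tibble of features (rows = cells),
#'   typically in \[0,1\]; no missing values.
#' @param perplexity Perplexity; default `compute_perplexity(nrow(features))`.
#' @param max_iter Gradient iterations. Default 10000.
#' @param eta Learning rate. Default 200.
#' @param seed Integer seed.
#' @return A tibble of class `tsne_embedding` with columns `tsne_1`,
#'   `tsne_2`; attributes `kl_trace` (KL divergence every 50 iterations) and
#'   `kl_final`.
#' @export
run_tsne <- function(features, perplexity = NULL, max_iter = 10000,
                     eta = 200, seed = 1) {
  x <- if (is.matrix(features)) features else
    as.matrix(dplyr::select_if(as_tibble(features), is.numeric))
  if (!is.numeric(x)) abort("`features` must be numeric.")
  if (nrow(x) < 30) abort("Need at least 30 points.")
  if (anyNA(x) || any(!is.finite(x))) abort("Features contain NaN/NA.")
  if (is.null(perplexity)) perplexity <- compute_perplexity(nrow(x))
  if (perplexity >= nrow(x) / 3) {
    abort("Perplexity must be below N/3.")
  }
  set.seed(derive_seed(seed, 4))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  y0 <- matrix(0, nrow(x), 2)
  y0[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
  y0 <- scale(y0, center = TRUE, scale = FALSE)
  sds <- apply(y0, 2, sd)
  sds[sds == 0] <- 1
  y0 <- sweep(y0, 2, sds, "/") * 1e-4
  y0 <- y0 + matrix(rnorm(length(y0), 0, 1e-6), nrow(y0))

  res <- tsne_exact_cpp(x, y0, perplexity, as.integer(max_iter), eta,
                        12, min(250L, as.integer(max_iter %/% 3)),
                        250L, 50L)
  out <- tibble(tsne_1 = res$Y[, 1], tsne_2 = res$Y[, 2])
  attr(out, "kl_trace") <- res$kl_trace
  attr(out, "kl_final") <- utils::tail(res$kl_trace, 1)
  attr(out, "perplexity") <- perplexity
  class(out) <- c("tsne_embedding", class(out))
  out
}

#' @describeIn run_tsne Scatter plot of the embedding, optionally colored.
#' @param object A `tsne_embedding`.
#' @param colour Optional vector to color points by.
#' @param ... Unused.
#' @export
autoplot.tsne_embedding <- function(object, colour = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne_1, y = .data$tsne_2))
  if (is.null(colour)) {
    p + ggplot2::geom_point(size = 0.5, alpha = 0.6)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour),
                            size = 0.5, alpha = 0.8) +
      ggplot2::labs(colour = NULL)
  }
}
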