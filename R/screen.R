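#' Simulate a full multi-marker cytokine screen
#'
#' Generates, for every (donor, condition) of a design at one time point, a
#' single-cell event table whose per-marker positive fractions follow
#' marker-specific additive effect models, with a shared per-cell copula for
#' marker co-expression, and returns the true fractions alongside. This is
#' the fixture generator for the population-vs-single-cell dissociation: the
#' population-level co-regulation of two markers is planted through similar
#' effect specs, while single-cell co-expression is planted through the
#' copula — the two are independent dials, as they are in the biology.
#'
#' @param design Design tibble from [generate_design()].
#' @param n_donors Donors per condition.
#' @param marker_effects Named list marker -> [effect_spec()].
#' @param copula Marker correlation matrix (latent scale) passed to
#'   [simulate_events()]; identity when `NULL`.
#' @param n_cells Events per sample.
#' @param time_days Which design time point to simulate. Default: smallest.
#' @param contamination,generations Passed to [simulate_events()].
#' @param seed Integer root seed; per-sample seeds are derived by a counter.
#' @return List with `samples` (one event tibble per donor x condition, with
#'   `donor`/`condition_id` columns) and `fractions` (tibble: `donor`,
#'   `condition_id`, `marker`, true `fraction`).
#' @export
simulate_screen <- function(design, n_donors, marker_effects,
                            copula = NULL, n_cells = 2000,
                            time_days = NULL,
                            contamination = c(debris = 0.05, doublet = 0.03,
                                              dead = 0.05),
                            generations = c(1, 2, 4, 6, 4, 2),
                            seed = 1) {
  stopifnot(length(marker_effects) >= 1, !is.null(names(marker_effects)))
  time_days <- time_days %||% min(design$time_days)
  dsub <- design |> filter(.data$time_days == !!time_days)

  fr <- purrr::imap_dfr(marker_effects, function(eff, mk) {
    simulate_fractions(dsub, eff, n_donors,
                       seed = derive_seed(seed, match(mk, names(marker_effects)))) |>
      mutate(marker = mk)
  })

  keys <- fr |> distinct(.data$donor, .data$condition_id)
  counter <- 100
  samples <- purrr::pmap(keys, function(donor, condition_id) {
    spec <- fr |>
      filter(.data$donor == !!donor, .data$condition_id == !!condition_id)
    fspec <- setNames(spec$fraction, spec$marker)
    counter <<- counter + 1
    simulate_events(fspec, n_cells = n_cells, copula = copula,
                    contamination = contamination,
                    generations = generations,
                    meta = list(donor = donor, condition_id = condition_id,
                                time_days = time_days),
                    seed = derive_seed(seed, counter))
  })
  names(samples) <- paste(keys$donor, keys$condition_id, sep = "/")
  list(samples = samples,
       fractions = fr |>
         select("donor", "condition_id", "time_days", "is_control",
                "marker", "fraction"))
}

#' Simulate a sample with generation-dependent marker positivity
#'
#' Builds an event table in which each marker's %positive is an explicit
#' function of the proliferation generation, by stacking per-generation
#' batches. The companion fixture for confounder-removal checks: a
#' "treatment" that only shifts the generation distribution leaves the
#' per-cycle fractions untouched.
#'
#' @param pos_by_gen Matrix or data frame: rows = generations (0-based),
#'   columns = markers, entries = %positive within that generation.
#' @param gen_weights Generation weights (same number of rows).
#' @param n_cells Total events.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_events()] (optics, copula, meta, ...).
#' @return Event tibble as from [simulate_events()].
#' @export
simulate_cycle_sample <- function(pos_by_gen, gen_weights, n_cells,
                                  seed = 1, ...) {
  pos_by_gen <- as.matrix(pos_by_gen)
  g_n <- nrow(pos_by_gen)
  if (length(gen_weights) != g_n) {
    abort("`gen_weights` must match rows of `pos_by_gen`.")
  }
  gw <- gen_weights / sum(gen_weights)
  set.seed(derive_seed(seed, 5))
  counts <- as.vector(stats::rmultinom(1, n_cells, gw))
  batches <- purrr::map(seq_len(g_n), function(g) {
    if (counts[g] == 0) return(NULL)
    w <- rep(0, g_n); w[g] <- 1
    simulate_events(setNames(pos_by_gen[g, ], colnames(pos_by_gen)),
                    n_cells = counts[g], generations = w,
                    seed = derive_seed(seed, 20 + g), ...)
  })
  bind_rows(purrr::compact(batches))
}
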