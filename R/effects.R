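#' Ground-truth effect specification for the synthetic screen
#'
#' Encodes the generative counterpart of the net-effect regression: each
#' cytokine has a main effect on the change in %GM-CSF+ cells at normalized
#' concentration 1, each unordered pair may have an interaction effect applied
#' to the uniformized product predictor, donors carry an additive random
#' offset (which cancels in within-donor differences), and residual noise is
#' Gaussian.
#'
#' @param main_effects Named numeric vector, cytokine -> effect in percentage
#'   points at normalized concentration 1.
#' @param interaction_effects Named numeric vector, `"A:B"` -> effect in
#'   percentage points applied to the uniformized product of the pair's
#'   normalized concentrations. Pair order is irrelevant.
#' @param donor_sd Donor random-effect SD in percentage points (>= 0).
#' @param noise_sd Residual noise SD in percentage points (>= 0).
#' @param baseline_fraction %GM-CSF+ under activation alone (0-100).
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(main_effects = c("TGF-b1" = 10, "IL-6" = -10))
#' @export
effect_spec <- function(main_effects = numeric(),
                        interaction_effects = numeric(),
                        donor_sd = 3,
                        noise_sd = 2,
                        baseline_fraction = 10) {
  stopifnot(donor_sd >= 0, noise_sd >= 0,
            baseline_fraction >= 0, baseline_fraction <= 100)
  if (length(main_effects) && is.null(names(main_effects))) {
    abort("`main_effects` must be named by cytokine.")
  }
  if (length(interaction_effects) && is.null(names(interaction_effects))) {
    abort("`interaction_effects` must be named \"A:B\".")
  }
  structure(
    list(main_effects = main_effects,
         interaction_effects = interaction_effects,
         donor_sd = donor_sd, noise_sd = noise_sd,
         baseline_fraction = baseline_fraction),
    class = "effect_spec"
  )
}

#' Default planted effects of the synthetic screen
#'
#' TGF-b induces GM-CSF while IL-6 and IL-23 repress it; the remaining
#' cytokines are null. Effect magnitudes are 10 percentage points against a
#' residual noise SD of 2, i.e. a signal-to-noise ratio of 5.
#'
#' @param noise_sd Residual noise SD (default 2 percentage points).
#' @param donor_sd Donor random-effect SD (default 3 percentage points).
#' @return An `effect_spec`.
#' @export
default_effects <- function(noise_sd = 2, donor_sd = 3) {
  effect_spec(
    main_effects = c("TGF-b1" = 10, "IL-6" = -10, "IL-23" = -10),
    interaction_effects = c("IL-6:IL-23" = -4),
    donor_sd = donor_sd, noise_sd = noise_sd,
    baseline_fraction = 10
  )
}

# Normalized concentration matrix (per-cytokine min-max over the design) and
# uniformized pair products; shared by the generator and the design-matrix
# builder so the generative model and the regression see the same predictors.
normalized_concentrations <- function(design) {
  conc_cols <- grep("^conc_", names(design), value = TRUE)
  concs <- as.matrix(design[conc_cols])
  colnames(concs) <- sub("^conc_", "", conc_cols)
  apply(concs, 2, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) abort("Constant cytokine concentration column.")
    (x - rng[1]) / (rng[2] - rng[1])
  })
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

#' Simulate true per-sample GM-CSF+ fractions for a design
#'
#' Draws, for each (donor, condition, time) sample, the true %positive under
#' the additive generative model: baseline + donor offset + sum of main
#' effects on normalized concentrations + sum of interaction effects on
#' uniformized pair products + Gaussian noise. The within-donor difference
#' versus the matched control (same donor, same time) is returned alongside;
#' the donor offset shifts treated and control samples identically and
#' cancels in the difference.
#'
#' @param design Design tibble from [generate_design()].
#' @param effects An [effect_spec()].
#' @param n_donors Number of donors (>= 1).
#' @param seed Integer seed.
#' @return Tibble with columns `donor`, `condition_id`, `time_days`,
#'   `is_control`, `fraction` (true %positive, clipped to \[0, 100\]) and
#'   `delta` (% points vs the donor- and time-matched control; `NA` for the
#'   control rows themselves).
#' @export
simulate_fractions <- function(design, effects, n_donors, seed = 1) {
  stopifnot(n_donors >= 1)
  validate_design(design)
  set.seed(derive_seed(seed, 0))

  xnorm <- normalized_concentrations(design)
  cyt <- colnames(xnorm)

  main <- rep(0, length(cyt)); names(main) <- cyt
  known <- intersect(names(effects$main_effects), cyt)
  main[known] <- effects$main_effects[known]

  signal <- as.numeric(xnorm %*% main)
  if (length(effects$interaction_effects)) {
    for (k in names(effects$interaction_effects)) {
      ab <- strsplit(k, ":", fixed = TRUE)[[1]]
      if (!all(ab %in% cyt)) next
      prod_u <- .uniformize0(xnorm[, ab[1]] * xnorm[, ab[2]])
      signal <- signal + effects$interaction_effects[[k]] * prod_u
    }
  }

  out <- tidyr::crossing(donor = paste0("D", seq_len(n_donors)),
                         design["condition_id"]) |>
    left_join(design, by = "condition_id", relationship = "many-to-many") |>
    select("donor", "condition_id", "time_days", "is_control")
  # one signal per design row, replicated over donors in design-row order
  sig_tbl <- design |>
    select("condition_id", "time_days") |>
    mutate(signal = signal)
  out <- left_join(out, sig_tbl, by = c("condition_id", "time_days"))

  donor_off <- rnorm(n_donors, 0, effects$donor_sd)
  names(donor_off) <- paste0("D", seq_len(n_donors))

  out <- out |>
    mutate(
      fraction = effects$baseline_fraction + unname(donor_off[.data$donor]) +
        .data$signal + rnorm(n(), 0, effects$noise_sd),
      fraction = pmin(pmax(.data$fraction, 0), 100)
    )

  ctrl <- out |>
    filter(.data$is_control) |>
    select("donor", "time_days", control_fraction = "fraction")
  out |>
    left_join(ctrl, by = c("donor", "time_days")) |>
    mutate(delta = ifelse(.data$is_control, NA_real_,
                          .data$fraction - .data$control_fraction)) |>
    select("donor", "condition_id", "time_days", "is_control",
           "fraction", "delta")
}
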