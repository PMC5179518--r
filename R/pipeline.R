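pipeline_schema <- function() {
  list(
    seed = "integer",
    output_dir = "character",
    design = c("n_donors", "times", "levels"),
    effects = c("marker", "main_effects", "interaction_effects", "donor_sd",
                "noise_sd", "baseline_fraction"),
    events = c("n_cells", "copula", "contamination", "generations",
               "markers"),
    gating = c("lymphocyte_rule", "doublet_rule", "viability_rule",
               "positivity_quantile", "max_generation"),
    lasso = c("n_folds", "n_repeats", "nlambda", "lambda_min_ratio"),
    cluster = c("per_group_count", "max_iter", "k_range", "delta_frac",
                "n_restarts"),
    cycles = c("min_cells", "marker", "quadrant")
  )
}

#' Validate a pipeline configuration
#'
#' Configurations are nested lists (typically read from YAML); unknown keys
#' at the top level or within a stage are rejected before any computation
#' runs.
#'
#' @param config Nested list, or path to a YAML file.
#' @return The validated config (invisibly a list), with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (stage in intersect(names(config), names(schema))) {
    allowed <- schema[[stage]]
    if (length(allowed) > 1 && is.list(config[[stage]])) {
      bad <- setdiff(names(config[[stage]]), allowed)
      if (length(bad)) {
        abort(paste0("Unknown key(s) in `", stage, "`: ",
                     paste(bad, collapse = ", ")))
      }
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% tempfile("cytoscreen_run_")
  invisible(config)
}

write_stage <- function(obj, dir, name) {
  path <- file.path(dir, name)
  if (grepl("\\.csv$", name)) {
    write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  path
}

#' Run the full screen analysis pipeline on synthetic data
#'
#' Orchestrates every stage end to end — design generation, fraction and
#' event simulation, sequential gating, net-effect regression with repeated
#' CV, population- and single-cell correlation, embedding + mixture
#' clustering of the GM-CSF+ subset, and per-cycle quantification — writing
#' one output file per stage plus a machine-readable manifest (parameters,
#' seeds, file MD5 hashes). Deterministic: the same config and seed give
#' byte-identical manifests and numeric outputs.
#'
#' @param config Nested list or YAML path, see [validate_config()].
#' @return Invisibly, a list with the per-stage results and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  files <- character()
  log_stage <- function(msg) message("[cytoscreen] ", msg)

  # -- design ----------------------------------------------------------------
  log_stage("stage 1/7: design")
  times <- cfg$design$times %||% c(3, 5, 7)
  n_donors <- cfg$design$n_donors %||% 6
  design <- generate_design(times = times)
  files["design"] <- write_stage(design, cfg$output_dir, "design.csv")

  # -- fractions (generative truth for the regression) -----------------------
  log_stage("stage 2/7: simulate fractions")
  eff <- effect_spec(
    main_effects = unlist(cfg$effects$main_effects %||%
                            c("TGF-b1" = 10, "IL-6" = -10, "IL-23" = -10)),
    interaction_effects = unlist(cfg$effects$interaction_effects %||%
                                   c("IL-6:IL-23" = -4)),
    donor_sd = cfg$effects$donor_sd %||% 3,
    noise_sd = cfg$effects$noise_sd %||% 2,
    baseline_fraction = cfg$effects$baseline_fraction %||% 10)
  fractions <- simulate_fractions(design, eff, n_donors, seed = seed)
  files["fractions"] <- write_stage(fractions, cfg$output_dir,
                                    "fractions.csv")

  # -- net-effect regression -------------------------------------------------
  log_stage("stage 3/7: lasso net effects")
  dm <- build_design(design, fractions |> filter(!.data$is_control) |>
                       bind_rows(fractions |> filter(.data$is_control)))
  cv <- cross_validate(dm,
                       n_folds = cfg$lasso$n_folds %||% 10,
                       n_repeats = cfg$lasso$n_repeats %||% 50,
                       nlambda = cfg$lasso$nlambda %||% 50,
                       seed = seed)
  ne <- net_effects(cv)
  files["lasso"] <- write_stage(
    list(lambda = cv$lambda, cv_mean_error = cv$cv_mean_error,
         lambda_opt = cv$lambda_opt, n_folds = cv$n_folds,
         n_repeats = cv$n_repeats,
         coefficients = as.list(coef_at_lambda(cv, cv$lambda_opt)$beta)),
    cfg$output_dir, "lasso.json")
  files["net_effects"] <- write_stage(ne, cfg$output_dir, "net_effects.csv")

  # -- events + gating -------------------------------------------------------
  log_stage("stage 4/7: simulate events and gate")
  markers <- cfg$events$markers %||%
    c("GM-CSF", "IFN-g", "IL-17A", "FOXP3", "CD25", "IL-2")
  m <- length(markers)
  cop <- diag(m); dimnames(cop) <- list(markers, markers)
  cop["GM-CSF", "IFN-g"] <- cop["IFN-g", "GM-CSF"] <- 0.6
  mk_eff <- list(
    "GM-CSF" = eff,
    "FOXP3" = effect_spec(main_effects = unlist(
      cfg$effects$main_effects %||%
        c("TGF-b1" = 10, "IL-6" = -10, "IL-23" = -10)) * 0.8,
      donor_sd = eff$donor_sd, noise_sd = eff$noise_sd,
      baseline_fraction = 8))
  for (mk in setdiff(markers, names(mk_eff))) {
    mk_eff[[mk]] <- effect_spec(donor_sd = eff$donor_sd,
                                noise_sd = eff$noise_sd,
                                baseline_fraction = 15)
  }
  sub_design <- design |>
    filter(.data$time_days == min(.data$time_days),
           .data$is_control | .data$condition_id %in%
             sub("^conc_", "", grep("^conc_", names(design), value = TRUE)))
  screen <- simulate_screen(sub_design, n_donors = 3,
                            marker_effects = mk_eff, copula = cop,
                            n_cells = cfg$events$n_cells %||% 2000,
                            seed = seed)
  cfg_gate <- do.call(gating_config, cfg$gating %||% list())
  neg_ctrl <- simulate_events(setNames(rep(0, m), markers), n_cells = 3000,
                              seed = derive_seed(seed, 99))
  gated <- purrr::imap(screen$samples, function(ev, nm) {
    gate_sample(ev, cfg_gate, controls = list(markers = neg_ctrl),
                markers = markers)
  })
  files["gate_counts"] <- write_stage(
    purrr::map(gated, function(g) as.list(g$gate_counts)),
    cfg$output_dir, "gate_counts.json")

  # -- correlations ----------------------------------------------------------
  log_stage("stage 5/7: correlations")
  pop_tbl <- purrr::imap_dfr(gated, function(g, nm) {
    ev <- g$events
    out <- tibble(donor = ev$donor[1], condition_id = ev$condition_id[1])
    for (mk in markers) out[[mk]] <- 100 * mean(ev[[paste0("pos_", mk)]])
    out
  })
  pop_cor <- population_correlation(pop_tbl, markers = markers)
  files["population_correlation"] <- write_stage(
    pop_cor, cfg$output_dir, "population_correlation.csv")
  cell_tbl <- purrr::imap_dfr(gated, function(g, nm) {
    g$events |>
      mutate(sample_id = nm,
             group = ifelse(.data$condition_id == "control",
                            "no cytokine", "cytokine")) |>
      select("sample_id", "group", dplyr::all_of(markers)) |>
      mutate(across(dplyr::all_of(markers), minmax_normalize))
  })
  sc_cor <- single_cell_correlation(
    cell_tbl, pairs = t(vapply(setdiff(markers, "GM-CSF"),
                               function(mk) c("GM-CSF", mk), character(2))))
  files["single_cell_correlation"] <- write_stage(
    sc_cor, cfg$output_dir, "single_cell_correlation.csv")

  # -- embedding + clustering ------------------------------------------------
  log_stage("stage 6/7: embedding and clustering")
  cells <- purrr::map_dfr(gated, function(g) g$events)
  per_group <- cfg$cluster$per_group_count %||% 60
  pooled <- select_positive_subset(
    cells |> filter(.data$condition_id %in% c("control", "TGF-b1")),
    per_group_count = per_group, seed = seed)
  feats <- pooled |> select(-"donor", -"condition_id")
  emb <- run_tsne(feats, max_iter = cfg$cluster$max_iter %||% 1000,
                  seed = seed)
  ks <- select_k(emb, k_range = cfg$cluster$k_range %||% 1:6,
                 delta_frac = cfg$cluster$delta_frac %||% 0.01,
                 n_restarts = cfg$cluster$n_restarts %||% 2, seed = seed)
  model <- ks$models[[paste0("K", ks$K)]]
  files["clusters"] <- write_stage(
    bind_cols(pooled |> select("donor", "condition_id"), augment(model)),
    cfg$output_dir, "clusters.csv")
  files["cluster_model"] <- write_stage(
    list(K = model$K, BIC = ks$bic, weights = model$weights,
         means = model$means, kl_final = attr(emb, "kl_final"),
         perplexity = attr(emb, "perplexity")),
    cfg$output_dir, "cluster_model.json")

  # -- cycle analysis --------------------------------------------------------
  log_stage("stage 7/7: cycle analysis")
  cyc_marker <- cfg$cycles$marker %||% "GM-CSF"
  cyc <- purrr::imap_dfr(gated, function(g, nm) {
    fraction_by_cycle(g, cyc_marker,
                      min_cells = cfg$cycles$min_cells %||% 20) |>
      mutate(sample_id = nm, metric = paste0("pct_", cyc_marker)) |>
      rename(value = "pct_positive")
  })
  dist <- purrr::imap_dfr(gated, function(g, nm) {
    cycle_distribution(g) |>
      mutate(sample_id = nm, metric = "pct_of_cells") |>
      rename(value = "pct_of_cells")
  })
  files["cycles"] <- write_stage(
    bind_rows(cyc, dist) |>
      select("sample_id", "generation", "metric", "value"),
    cfg$output_dir, "cycles.csv")

  manifest <- list(
    seed = seed,
    parameters = cfg[setdiff(names(cfg), c("seed", "output_dir"))],
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  files["manifest"] <- write_stage(manifest, cfg$output_dir, "manifest.json")
  log_stage(paste0("done; outputs in ", cfg$output_dir))

  invisible(list(design = design, fractions = fractions, cv = cv,
                 net_effects = ne, gated = gated,
                 population_correlation = pop_cor,
                 single_cell_correlation = sc_cor,
                 embedding = emb, k_selection = ks, cycles = cyc,
                 manifest = manifest, files = files))
}
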