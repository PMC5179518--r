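test_that("lymphocyte gate recovers the dominant scatter mode", {
  # 70% lymphocytes vs debris separated by ~5 component SDs of scatter
  ev <- simulate_events(c("GM-CSF" = 20), n_cells = 6000,
                        contamination = c(debris = 0.3), seed = 11)
  g <- gate_lymphocytes(ev)
  truth_lymph <- ev$truth_class == "lymphocyte"
  recall <- sum(g$truth_class == "lymphocyte") / sum(truth_lymph)
  precision <- mean(g$truth_class == "lymphocyte")
  expect_gte(recall, 0.90)
  expect_gte(precision, 0.90)
})

test_that("lymphocyte gate on a pure sample retains at least the rule fraction", {
  ev <- make_clean_sample(n_cells = 4000, seed = 12)
  g <- gate_lymphocytes(ev, gating_config(lymphocyte_rule = 0.9))
  expect_gte(nrow(g) / nrow(ev), 0.9)
})

test_that("gating rejects missing channels and empty tables", {
  ev <- make_clean_sample(n_cells = 100, seed = 13)
  expect_error(gate_lymphocytes(ev[0, ]), "Empty")
  expect_error(gate_lymphocytes(dplyr::select(ev, -`SSC-A`)), "SSC-A")
  expect_error(exclude_doublets(dplyr::select(ev, -`FSC-W`)), "FSC-W")
  expect_error(gate_live(dplyr::select(ev, -Viability)), "Viability")
})

test_that("doublet exclusion keeps singlets and removes planted doublets", {
  singlets <- make_clean_sample(n_cells = 5000, seed = 14)
  kept <- exclude_doublets(singlets)
  expect_gte(nrow(kept) / nrow(singlets), 0.99)
  expect_identical(names(kept), names(singlets))

  mixed <- simulate_events(c("GM-CSF" = 20), n_cells = 6000,
                           contamination = c(doublet = 0.1), seed = 15)
  kept2 <- exclude_doublets(mixed)
  n_doub <- sum(mixed$truth_class == "doublet")
  removed <- n_doub - sum(kept2$truth_class == "doublet")
  expect_gte(removed / n_doub, 0.95)
})

test_that("viability gate keeps live cells and drops dead cells", {
  clean <- make_clean_sample(n_cells = 3000, seed = 16)
  expect_gte(nrow(gate_live(clean)) / nrow(clean), 0.99)

  mixed <- simulate_events(c("GM-CSF" = 20), n_cells = 6000,
                           contamination = c(dead = 0.2), seed = 17)
  g <- gate_live(mixed)
  live_recall <- sum(g$truth_class != "dead") /
    sum(mixed$truth_class != "dead")
  expect_gte(live_recall, 0.98)
  expect_lt(mean(g$truth_class == "dead"), 0.01)

  # an all-dead sample needs the stained control, as at the bench
  dead_opts <- list(viability_live_meanlog = default_optics()$viability_dead_meanlog)
  all_dead <- simulate_events(c("GM-CSF" = 20), n_cells = 2000,
                              optics = dead_opts, seed = 18)
  stained_control <- all_dead
  g2 <- gate_live(all_dead, control = stained_control)
  expect_lte(nrow(g2) / nrow(all_dead), 0.02)
})

test_that("positivity threshold is the control quantile and behaves at the edges", {
  ctrl <- make_negative_control(n_cells = 20000, markers = "GM-CSF")
  self <- threshold_positive(ctrl, ctrl, "GM-CSF",
                             gating_config(positivity_quantile = 0.999))
  expect_lt(abs(mean(self$positive) - 0.001), 5e-4)

  sample <- make_clean_sample(c("GM-CSF" = 25), n_cells = 20000, seed = 19)
  tp <- threshold_positive(sample, ctrl, "GM-CSF")
  expect_lt(abs(100 * mean(tp$positive) - 25), 1)

  low <- sample
  low[["GM-CSF"]] <- low[["GM-CSF"]] / 1e6
  expect_equal(sum(threshold_positive(low, ctrl, "GM-CSF")$positive), 0)

  expect_error(threshold_positive(sample, ctrl[0, ], "GM-CSF"), "empty")
})

test_that("positivity threshold is monotone in the control quantile", {
  ctrl <- make_negative_control(n_cells = 5000, markers = "GM-CSF")
  sample <- make_clean_sample(c("GM-CSF" = 25), n_cells = 2000, seed = 20)
  qs <- c(0.9, 0.95, 0.99, 0.999)
  thr <- vapply(qs, function(q) {
    threshold_positive(sample, ctrl, "GM-CSF",
                       gating_config(positivity_quantile = q))$threshold
  }, 0)
  expect_false(is.unsorted(thr))
})

test_that("generation assignment is exact without noise and accurate at 10% CV", {
  ref <- 1000
  ev <- tibble::tibble(ProlifDye = c(1000, 250, 125, 1000 / 2^5))
  expect_equal(assign_generation(ev, ref), c(0L, 2L, 3L, 5L))

  noisy <- simulate_events(c("GM-CSF" = 10), n_cells = 20000,
                           generations = c(2, 3, 3, 2),
                           optics = list(dye_cv = 0.10), seed = 21)
  gen <- assign_generation(noisy, default_optics()$dye_undivided_mean)
  expect_gte(mean(gen == noisy$truth_generation), 0.99)

  bad <- tibble::tibble(ProlifDye = c(10, -1))
  expect_error(assign_generation(bad, ref), "positive")
  expect_error(assign_generation(ev, 0), "undivided_reference")
})

test_that("sequential gate counts never increase and end-to-end F1 is high", {
  ev <- simulate_events(
    setNames(c(25, 15, 5, 10, 40, 20), panel6), n_cells = 8000,
    contamination = c(debris = 0.12, doublet = 0.05, dead = 0.08),
    generations = c(1, 2, 3, 2), seed = 22)
  ctrl <- make_negative_control()
  gs <- gate_sample(ev, controls = list(markers = ctrl),
                    markers = c("GM-CSF", "FOXP3"))
  expect_true(all(diff(gs$gate_counts) <= 0))
  expect_true(all(c("pos_GM-CSF", "pos_FOXP3", "generation") %in%
                    names(gs$events)))

  # live-lymphocyte-singlet retrieval quality
  tp <- sum(gs$events$truth_class == "lymphocyte")
  precision <- tp / nrow(gs$events)
  recall <- tp / sum(ev$truth_class == "lymphocyte")
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.9)
})
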