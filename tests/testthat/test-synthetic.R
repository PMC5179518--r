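test_that("null effect model gives exactly zero deltas", {
  d <- generate_design(times = c(3, 5))
  eff <- effect_spec(donor_sd = 0, noise_sd = 0, baseline_fraction = 10)
  fr <- simulate_fractions(d, eff, n_donors = 3, seed = 1)
  expect_true(all(fr$delta[!fr$is_control] == 0))
})

test_that("a planted main effect is recovered in expectation", {
  d <- generate_design(times = c(3, 5))
  eff <- effect_spec(main_effects = c("TGF-b1" = 10), donor_sd = 3,
                     noise_sd = 1, baseline_fraction = 20)
  deltas <- vapply(1:10, function(s) {
    fr <- simulate_fractions(d, eff, n_donors = 50, seed = s)
    mean(fr$delta[fr$condition_id == "TGF-b1"])
  }, 0)
  # 1000 replicate (donor x time) samples in total; SE ~ sqrt(2)/sqrt(1000)
  expect_lt(abs(mean(deltas) - 10), 0.1)
})

test_that("donor random effects cancel exactly in within-donor deltas", {
  d <- generate_design(times = c(3, 5))
  eff_hi <- effect_spec(main_effects = c("IL-6" = -8), donor_sd = 50,
                        noise_sd = 0, baseline_fraction = 50)
  eff_lo <- effect_spec(main_effects = c("IL-6" = -8), donor_sd = 0,
                        noise_sd = 0, baseline_fraction = 50)
  fr_hi <- simulate_fractions(d, eff_hi, n_donors = 4, seed = 2)
  fr_lo <- simulate_fractions(d, eff_lo, n_donors = 4, seed = 2)
  # same signal, wildly different donor offsets: identical deltas wherever
  # no clipping occurred
  keep <- !fr_hi$is_control & fr_hi$fraction > 0 & fr_hi$fraction < 100
  expect_equal(fr_hi$delta[keep], fr_lo$delta[keep], tolerance = 1e-12)

  eff0 <- effect_spec(donor_sd = 50, noise_sd = 0, baseline_fraction = 50)
  fr0 <- simulate_fractions(d, eff0, n_donors = 6, seed = 3)
  expect_true(all(fr0$delta[!fr0$is_control] == 0))
})

test_that("marker positivity counts follow the binomial law", {
  ev <- simulate_events(c("GM-CSF" = 30), n_cells = 10000, seed = 4)
  n_pos <- sum(ev[["truth_pos_GM-CSF"]])
  expect_lt(abs(n_pos - 3000), 3 * sqrt(10000 * 0.3 * 0.7))

  ev0 <- simulate_events(c("GM-CSF" = 0), n_cells = 2000, seed = 5)
  expect_equal(sum(ev0[["truth_pos_GM-CSF"]]), 0)
})

test_that("undivided cells sit at the dye reference; generations make unit-spaced log2 peaks", {
  ev <- simulate_events(c("GM-CSF" = 10), n_cells = 4000,
                        generations = 1, seed = 6)
  ref <- default_optics()$dye_undivided_mean
  expect_lt(abs(median(log2(ev$ProlifDye)) - log2(ref)), 0.05)

  ev2 <- simulate_events(c("GM-CSF" = 10), n_cells = 30000,
                         generations = c(1, 1, 1, 1), seed = 7)
  peaks <- tapply(log2(ev2$ProlifDye), ev2$truth_generation, mean)
  spacing <- -diff(peaks)
  expect_true(all(abs(spacing - 1) < 0.02))
})

test_that("per-cell copula plants the requested rank correlation", {
  cop <- diag(2); dimnames(cop) <- list(c("A", "B"), c("A", "B"))
  cop["A", "B"] <- cop["B", "A"] <- 0.6
  ev <- simulate_events(c(A = 50, B = 50), n_cells = 20000, copula = cop,
                        seed = 8)
  rho <- cor(ev$A, ev$B, method = "spearman")
  # Gaussian copula rank correlation: (6/pi) * asin(rho/2)
  expect_lt(abs(rho - 6 / pi * asin(0.3)), 0.03)
})

test_that("event generator rejects invalid inputs", {
  expect_error(simulate_events(c(A = 30), n_cells = 0), "positive")
  expect_error(simulate_events(c(A = 130), n_cells = 10), "0, 100")
  expect_error(simulate_events(c(A = 30), n_cells = 10,
                               contamination = c(debris = 0.6, dead = 0.5)),
               "sum to < 1")
})

test_that("CSV event round trip preserves channels, truth and metadata", {
  ev <- make_clean_sample(c("GM-CSF" = 25, "IFN-g" = 10), n_cells = 300,
                          seed = 9,
                          meta = list(donor = "D1", condition_id = "TGF-b1",
                                      time_days = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_identical(channel_names(back), channel_names(ev))
  expect_equal(back[["GM-CSF"]], ev[["GM-CSF"]], tolerance = 1e-9)
  expect_equal(back$truth_class, ev$truth_class)
  expect_equal(back$donor[1], "D1")
})

test_that("FCS round trip preserves event count, names and stored precision", {
  ev <- make_clean_sample(c("GM-CSF" = 25), n_cells = 500, seed = 10)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_events(ev, path, format = "fcs")
  back <- read_events(path, format = "fcs")
  expect_equal(nrow(back), nrow(ev))
  expect_identical(names(back), channel_names(ev))
  # float32 storage: relative error bounded by 2^-23
  rel <- abs(back[["GM-CSF"]] - ev[["GM-CSF"]]) / ev[["GM-CSF"]]
  expect_lt(max(rel), 1e-6)
})

test_that("writing degenerate event tables errors", {
  empty <- tibble::tibble(truth_class = character(0))
  expect_error(write_events(empty, tempfile()), "no channel")
  expect_error(write_events(make_clean_sample(), tempfile(),
                            format = "xlsx"))
})
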