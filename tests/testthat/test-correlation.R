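test_that("population correlation is a rank statistic with exact extremes", {
  ft <- tibble::tibble(donor = rep(c("D1", "D2"), each = 4),
                       A = 1:8,
                       B = c(10, 20, 40, 80, 95, 120, 260, 300),
                       C = c(80, 41, 33, 25, 17, 12, 8, 3))
  res <- population_correlation(ft, markers = c("A", "B", "C"))
  expect_equal(res$rho[res$marker_a == "A" & res$marker_b == "B"], 1)
  expect_equal(res$rho[res$marker_a == "A" & res$marker_b == "C"], -1)
})

test_that("constant markers are flagged, tiny tables rejected", {
  ft <- tibble::tibble(donor = c("D1", "D1", "D2", "D2"),
                       A = c(1, 2, 3, 4), B = rep(5, 4))
  res <- population_correlation(ft, markers = c("A", "B"))
  expect_true(is.na(res$rho))
  expect_equal(res$flag, "constant marker")
  expect_error(population_correlation(ft[1:2, ], markers = c("A", "B")),
               "3 samples")
})

test_that("planted co-regulation orders population-level correlations", {
  d <- small_screen_design()
  eff <- coregulated_effects(noise_sd = 3)
  frs <- lapply(c("GM-CSF", "FOXP3", "IL-17A"), function(mk) {
    simulate_fractions(d, eff[[mk]], n_donors = 6, seed = 61) |>
      dplyr::mutate(marker = mk)
  })
  ft <- dplyr::bind_rows(frs) |>
    tidyr::pivot_wider(id_cols = c("donor", "condition_id", "time_days"),
                       names_from = "marker", values_from = "fraction")
  res <- population_correlation(ft, markers = c("GM-CSF", "FOXP3", "IL-17A"))
  rho_foxp3 <- res$rho[res$marker_a == "GM-CSF" & res$marker_b == "FOXP3"]
  rho_il17 <- res$rho[res$marker_a == "GM-CSF" & res$marker_b == "IL-17A"]
  expect_gt(rho_foxp3, rho_il17)
  p_foxp3 <- res$p_value[res$marker_a == "GM-CSF" & res$marker_b == "FOXP3"]
  expect_lt(p_foxp3, 0.05)
})

test_that("independent markers give near-zero single-cell correlation", {
  samples <- lapply(1:6, function(i) {
    make_clean_sample(c(A = 40, B = 40), n_cells = 500, seed = 70 + i) |>
      dplyr::mutate(sample_id = paste0("S", i))
  })
  ct <- dplyr::bind_rows(samples)
  res <- single_cell_correlation(ct, markers = c("A", "B"))
  se <- sd(res$rho) / sqrt(nrow(res))
  expect_lt(abs(mean(res$rho)), 3 * se + 0.02)
})

test_that("single-cell rho is invariant under monotone channel transforms", {
  ev <- make_clean_sample(c(A = 40, B = 40), n_cells = 400, seed = 77,
                          copula = {
                            m <- diag(2)
                            dimnames(m) <- list(c("A", "B"), c("A", "B"))
                            m[1, 2] <- m[2, 1] <- 0.5
                            m
                          }) |>
    dplyr::mutate(sample_id = "S1")
  r1 <- single_cell_correlation(ev, markers = c("A", "B"))$rho
  ev2 <- ev |> dplyr::mutate(A = log(A + 1)^3)
  r2 <- single_cell_correlation(ev2, markers = c("A", "B"))$rho
  expect_equal(r1, r2)
})

test_that("under-sized samples are skipped with a warning", {
  ct <- dplyr::bind_rows(
    make_clean_sample(c(A = 30, B = 30), n_cells = 5, seed = 78) |>
      dplyr::mutate(sample_id = "tiny"),
    make_clean_sample(c(A = 30, B = 30), n_cells = 100, seed = 79) |>
      dplyr::mutate(sample_id = "ok"))
  expect_warning(res <- single_cell_correlation(ct, markers = c("A", "B")),
                 "skipped")
  expect_identical(unique(res$sample_id), "ok")
})

test_that("planted copula makes IFN-g the top single-cell partner in every group", {
  cop <- copula_ifng()
  groups <- c("no cytokine", "TGF-b", "Th17")
  ct <- dplyr::bind_rows(lapply(seq_along(groups), function(gi) {
    dplyr::bind_rows(lapply(1:4, function(si) {
      make_clean_sample(setNames(c(30, 25, 8, 15, 40, 20), panel6),
                        n_cells = 600, copula = cop,
                        seed = 100 + 10 * gi + si) |>
        dplyr::mutate(sample_id = paste0("g", gi, "s", si),
                      group = groups[gi])
    }))
  }))
  pairs <- t(vapply(setdiff(panel6, "GM-CSF"),
                    function(mk) c("GM-CSF", mk), character(2)))
  res <- single_cell_correlation(ct, pairs = pairs, markers = panel6)
  med <- res |>
    dplyr::group_by(group, marker_b) |>
    dplyr::summarise(m = median(rho), .groups = "drop")
  for (g in groups) {
    top <- med |> dplyr::filter(group == g) |>
      dplyr::slice_max(m, n = 1)
    expect_equal(as.character(top$marker_b), "IFN-g", ignore_attr = TRUE)
  }
})

test_that("degenerate paired comparisons report p = 1 with a flag", {
  x <- c(3, 4, 5)
  res <- compare_paired(x, x)
  expect_equal(res$p_value, 1)
  expect_equal(res$flag, "degenerate")
  expect_error(compare_paired(1:3, 1:4), "equal length")
  expect_error(compare_paired(1, 2), "2 pairs")
})

test_that("exact Wilcoxon matches full sign enumeration up to n = 12", {
  set.seed(80)
  for (n in c(6, 9, 12)) {
    d <- round(rnorm(n, 0.4, 1), 3)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n, 0.4, 1), 3)
    ours <- compare_paired(d, rep(0, n), method = "wilcoxon",
                           exact = TRUE)$p_value
    expect_equal(ours, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
  # normal approximation stays close to enumeration at n = 12
  d <- round(rnorm(12, 0.6, 1), 3)
  while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(12, 0.6, 1), 3)
  approx_p <- suppressWarnings(
    stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(approx_p - enumerate_signed_rank_p(d)), 0.02)
})

test_that("normality pre-test routes to the right test and is reported", {
  set.seed(81)
  x <- rnorm(20, 1); y <- rnorm(20)
  res <- compare_paired(x, y)
  expect_true(res$method %in% c("paired t-test",
                                "Wilcoxon signed-rank (paired)"))
  expect_false(is.na(res$normality_p))
  skewed <- rexp(20)^3 + y
  res2 <- compare_paired(skewed, y)
  expect_equal(res2$method, "Wilcoxon signed-rank (paired)")
})
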