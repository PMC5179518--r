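make_gated_fixture <- function(pos_by_gen, gen_weights, n_cells = 8000,
                               seed = 1) {
  ev <- simulate_cycle_sample(pos_by_gen, gen_weights, n_cells, seed = seed)
  ev$generation <- ev$truth_generation
  for (mk in colnames(pos_by_gen)) {
    ev[[paste0("pos_", mk)]] <- ev[[paste0("truth_pos_", mk)]]
  }
  ev
}

test_that("per-cycle fractions handle degenerate compositions exactly", {
  pos <- matrix(c(100, 0), 2, 1, dimnames = list(NULL, "GM-CSF"))
  ev <- make_gated_fixture(pos, c(1, 1), n_cells = 2000, seed = 120)
  fb <- fraction_by_cycle(ev, "GM-CSF")
  expect_equal(fb$pct_positive[fb$generation == 0], 100)
  expect_equal(fb$pct_positive[fb$generation == 1], 0)
  expect_error(fraction_by_cycle(ev[0, ], "GM-CSF"), "No gated cells")
})

test_that("cycle-independent positivity is flat across generations", {
  pos <- matrix(30, 5, 1, dimnames = list(NULL, "GM-CSF"))
  ev <- make_gated_fixture(pos, rep(1, 5), n_cells = 10000, seed = 121)
  fb <- fraction_by_cycle(ev, "GM-CSF")
  for (i in seq_len(nrow(fb))) {
    tol <- 3 * 100 * sqrt(0.3 * 0.7 / fb$n_cells[i])
    expect_lt(abs(fb$pct_positive[i] - 30), tol)
  }
})

test_that("planted increasing positivity is recovered monotonically", {
  pos <- matrix(c(5, 15, 25, 35, 45), 5, 1,
                dimnames = list(NULL, "GM-CSF"))
  ev <- make_gated_fixture(pos, rep(1, 5), n_cells = 15000, seed = 122)
  fb <- fraction_by_cycle(ev, "GM-CSF")
  expect_false(is.unsorted(fb$pct_positive))
})

test_that("sparse generations are reported missing, not zero", {
  pos <- matrix(20, 3, 1, dimnames = list(NULL, "GM-CSF"))
  ev <- make_gated_fixture(pos, c(500, 500, 1), n_cells = 3000, seed = 123)
  fb <- fraction_by_cycle(ev, "GM-CSF", min_cells = 20)
  sparse <- fb |> dplyr::filter(n_cells < 20)
  if (nrow(sparse)) expect_true(all(is.na(sparse$pct_positive)))
})

test_that("quadrants partition every generation and bound the triple positives", {
  pos <- matrix(c(30, 40, 25, 35, 20, 30), 2, 3,
                dimnames = list(NULL, c("GM-CSF", "IFN-g", "FOXP3")))
  ev <- make_gated_fixture(pos, c(1, 1), n_cells = 6000, seed = 124)
  q <- quadrant_by_cycle(ev, "GM-CSF", "IFN-g", "FOXP3", min_cells = 5)
  sums <- q$pct_pos_pos + q$pct_pos_neg + q$pct_neg_pos + q$pct_neg_neg
  expect_equal(sums, rep(100, nrow(q)), tolerance = 1e-6)
  pair_ab <- q$pct_pos_pos
  expect_true(all(q$pct_triple <= pair_ab + 1e-9))

  neg <- make_gated_fixture(
    matrix(0, 1, 2, dimnames = list(NULL, c("GM-CSF", "IFN-g"))), 1,
    n_cells = 500, seed = 125)
  q0 <- quadrant_by_cycle(neg, "GM-CSF", "IFN-g", min_cells = 5)
  expect_equal(q0$pct_neg_neg, 100)
  expect_error(quadrant_by_cycle(ev, "GM-CSF", "CD25"), "CD25")
})

test_that("cycle distribution sums to 100 and recovers planted weights", {
  pos <- matrix(10, 4, 1, dimnames = list(NULL, "GM-CSF"))
  w <- c(8, 4, 2, 1)
  ev <- make_gated_fixture(pos, w, n_cells = 12000, seed = 126)
  cd <- cycle_distribution(ev)
  expect_equal(sum(cd$pct_of_cells), 100, tolerance = 1e-9)
  p <- w / sum(w)
  for (i in seq_along(p)) {
    tol <- 3 * 100 * sqrt(p[i] * (1 - p[i]) / 12000)
    expect_lt(abs(cd$pct_of_cells[i] - 100 * p[i]), tol)
  }

  undiv <- make_gated_fixture(pos[1, , drop = FALSE], 1, n_cells = 800,
                              seed = 127)
  cd0 <- cycle_distribution(undiv)
  expect_equal(cd0$pct_of_cells, 100)
})

test_that("conditioning on cycles removes a proliferation-only treatment effect", {
  # positivity depends only on generation; 'treatment' only shifts the
  # generation distribution
  pos <- matrix(c(5, 12, 20, 30, 40), 5, 1,
                dimnames = list(NULL, "GM-CSF"))
  ctrl <- make_gated_fixture(pos, c(10, 6, 3, 1.5, 0.8), n_cells = 20000,
                             seed = 128)
  trt <- make_gated_fixture(pos, c(0.8, 1.5, 3, 6, 10), n_cells = 20000,
                            seed = 129)

  # marginal fractions differ strongly ...
  overall_ctrl <- 100 * mean(ctrl[["pos_GM-CSF"]])
  overall_trt <- 100 * mean(trt[["pos_GM-CSF"]])
  expect_gt(abs(overall_trt - overall_ctrl), 10)

  # ... but per-cycle fractions are treatment-invariant within binomial noise
  fb_c <- fraction_by_cycle(ctrl, "GM-CSF")
  fb_t <- fraction_by_cycle(trt, "GM-CSF")
  joined <- dplyr::inner_join(fb_c, fb_t, by = "generation",
                              suffix = c("_c", "_t"))
  for (i in seq_len(nrow(joined))) {
    p <- pos[joined$generation[i] + 1, 1] / 100
    se <- 100 * sqrt(p * (1 - p)) *
      sqrt(1 / joined$n_cells_c[i] + 1 / joined$n_cells_t[i])
    expect_lt(abs(joined$pct_positive_c[i] - joined$pct_positive_t[i]),
              3 * se + 1e-9)
  }
})
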