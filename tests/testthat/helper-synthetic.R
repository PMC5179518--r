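# Shared fixtures, built in code at test time.

panel6 <- c("GM-CSF", "IFN-g", "IL-17A", "FOXP3", "CD25", "IL-2")

# negative control sample (all markers at 0% positive)
make_negative_control <- function(n_cells = 3000, markers = panel6,
                                  seed = 99) {
  simulate_events(setNames(rep(0, length(markers)), markers),
                  n_cells = n_cells, seed = seed)
}

# clean lymphocyte-only sample with configurable marker fractions
make_clean_sample <- function(fractions = c("GM-CSF" = 30), n_cells = 5000,
                              seed = 1, ...) {
  simulate_events(fractions, n_cells = n_cells, seed = seed, ...)
}

# exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (assumes untied nonzero differences)
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  stopifnot(n <= 16, all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  v_obs <- sum(r[d > 0])
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# small screen design restricted to a handful of conditions, for fast
# correlation fixtures
small_screen_design <- function() {
  d <- generate_design(times = c(3, 5)) |>
    dplyr::filter(condition_id %in% c("control", "TGF-b1", "IL-6", "IL-23",
                                      "IL-2", "IL-1b", "IL-6+TGF-b1",
                                      "IL-23+TGF-b1"))
  # keep only cytokines that still vary over the retained conditions
  conc <- grep("^conc_", names(d), value = TRUE)
  dead <- conc[colSums(d[conc]) == 0]
  d[setdiff(names(d), dead)]
}

# copula with planted GM-CSF/IFN-g single-cell co-expression
copula_ifng <- function(markers = panel6, rho_ifng = 0.6, rho_foxp3 = 0.2) {
  m <- length(markers)
  cop <- diag(m)
  dimnames(cop) <- list(markers, markers)
  cop["GM-CSF", "IFN-g"] <- cop["IFN-g", "GM-CSF"] <- rho_ifng
  cop["GM-CSF", "FOXP3"] <- cop["FOXP3", "GM-CSF"] <- rho_foxp3
  cop
}

# marker effect specs planting population-level GM-CSF/FOXP3 co-regulation:
# FOXP3 shares GM-CSF's inducers/repressors, the other markers do not
coregulated_effects <- function(noise_sd = 1.5) {
  gm <- c("TGF-b1" = 10, "IL-6" = -10, "IL-23" = -10)
  list(
    "GM-CSF" = effect_spec(main_effects = gm, donor_sd = 2,
                           noise_sd = noise_sd, baseline_fraction = 12),
    "FOXP3" = effect_spec(main_effects = gm * 0.8, donor_sd = 2,
                          noise_sd = noise_sd, baseline_fraction = 10),
    "IFN-g" = effect_spec(main_effects = c("IL-2" = 3), donor_sd = 2,
                          noise_sd = noise_sd, baseline_fraction = 25),
    "IL-17A" = effect_spec(main_effects = c("IL-1b" = 4), donor_sd = 2,
                           noise_sd = noise_sd, baseline_fraction = 6),
    "CD25" = effect_spec(main_effects = c("IL-2" = 4), donor_sd = 2,
                         noise_sd = noise_sd, baseline_fraction = 40),
    "IL-2" = effect_spec(donor_sd = 2, noise_sd = noise_sd,
                         baseline_fraction = 20)
  )
}

# design with columns orthogonal to the intercept and to each other,
# scaled so that x_j'x_j / n = 1 (soft-thresholding oracle regime)
make_orthonormal_design <- function(n = 40, p = 5, seed = 41) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n))))[, 2:(p + 1)]
  q <- q * sqrt(n)
  colnames(q) <- paste0("x", 1:p)
  q
}

# two well-separated planted 2-D Gaussians (separation in component SDs)
make_two_gaussians <- function(n_per = 1000, sep_sd = 6, seed = 1) {
  set.seed(seed)
  s <- 1
  x <- rbind(
    MASS::mvrnorm(n_per, c(0, 0), diag(s^2, 2)),
    MASS::mvrnorm(n_per, c(sep_sd * s, 0), diag(s^2, 2))
  )
  list(points = x, labels = rep(1:2, each = n_per),
       means = rbind(c(0, 0), c(sep_sd * s, 0)))
}
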