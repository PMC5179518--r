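#' Gating configuration
#'
#' Parameters of the sequential gate: lymphocyte scatter gate, doublet
#' exclusion on pulse width vs forward-scatter area, viability gate, marker
#' positivity thresholding against a negative control, and proliferation
#' generation assignment.
#'
#' @param lymphocyte_rule Coverage of the dominant scatter mode retained by
#'   the lymphocyte gate, in (0,1). Default 0.95.
#' @param doublet_rule Upper bound, in robust residual SDs, on the pulse-width
#'   excess over the robust linear trend vs FSC-A. Default 4.
#' @param viability_rule Quantile of the dead-cell (stained control)
#'   distribution placing the live/dead threshold. Default 0.01.
#' @param positivity_quantile Quantile of the negative-control distribution
#'   used as a marker's positivity threshold; 0.999 mirrors isotype/FMO
#'   practice (about 0.1% of the control calls positive). Default 0.999.
#' @param max_generation Proliferation generations beyond this are pooled
#'   into the last bin (dye resolution limit). Default 7.
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(lymphocyte_rule = 0.95,
                          doublet_rule = 4,
                          viability_rule = 0.01,
                          positivity_quantile = 0.999,
                          max_generation = 7) {
  stopifnot(lymphocyte_rule > 0, lymphocyte_rule < 1,
            doublet_rule > 0,
            viability_rule > 0, viability_rule < 1,
            positivity_quantile > 0, positivity_quantile < 1,
            max_generation >= 1)
  structure(list(lymphocyte_rule = lymphocyte_rule,
                 doublet_rule = doublet_rule,
                 viability_rule = viability_rule,
                 positivity_quantile = positivity_quantile,
                 max_generation = max_generation),
            class = "gating_config")
}

require_channels <- function(events, chans) {
  missing <- setdiff(chans, names(events))
  if (length(missing)) {
    abort(paste0("Missing channel(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(events) == 0) abort("Empty event table.")
  invisible(events)
}

#' Lymphocyte scatter gate
#'
#' Retains the dominant FSC-A/SSC-A density mode: a Gaussian mixture (1-3
#' components, BIC-selected) is fitted to the scatter plane, events are
#' assigned to the heaviest component, and within that component events up to
#' the empirical `lymphocyte_rule` quantile of Mahalanobis distance are kept.
#' Deterministic; no hand-drawn polygon.
#'
#' @param events Event tibble with `FSC-A` and `SSC-A` channels.
#' @param cfg A [gating_config()].
#' @return The retained subset of `events` (schema unchanged).
#' @export
gate_lymphocytes <- function(events, cfg = gating_config()) {
  require_channels(events, c("FSC-A", "SSC-A"))
  xy <- cbind(events[["FSC-A"]], events[["SSC-A"]])
  n <- nrow(xy)
  # fit on a deterministic subsample for large tables, classify everything
  idx <- if (n > 4000) round(seq(1, n, length.out = 4000)) else seq_len(n)
  fit <- suppressWarnings(
    mclust::Mclust(xy[idx, , drop = FALSE], G = 1:3,
                   modelNames = c("VVV", "VII"), verbose = FALSE)
  )
  if (is.null(fit)) abort("Scatter mixture fit failed.")
  cl <- if (fit$G == 1) rep(1L, n) else {
    predict(fit, newdata = xy)$classification
  }
  dom <- as.integer(names(which.max(table(cl))))
  in_dom <- cl == dom
  mu <- colMeans(xy[in_dom, , drop = FALSE])
  sig <- cov(xy[in_dom, , drop = FALSE])
  d2 <- stats::mahalanobis(xy, mu, sig)
  thr <- quantile(d2[in_dom], cfg$lymphocyte_rule, names = FALSE)
  events[in_dom & d2 <= thr, ]
}

#' Doublet exclusion on pulse width vs forward-scatter area
#'
#' Fits a robust (M-estimator) linear trend of `FSC-W` on `FSC-A` and removes
#' events whose positive residual exceeds `doublet_rule` robust SDs: doublets
#' carry roughly doubled pulse width at a given area.
#'
#' @inheritParams gate_lymphocytes
#' @return The singlet subset of `events`.
#' @export
exclude_doublets <- function(events, cfg = gating_config()) {
  require_channels(events, c("FSC-A", "FSC-W"))
  a <- events[["FSC-A"]]
  w <- events[["FSC-W"]]
  # doublets double both area and width, making them high-leverage points
  # that drag an M-estimated line; anchor the trend on the FSC-A bulk first
  qa <- quantile(a, c(0.25, 0.75), names = FALSE)
  fence <- c(qa[1] - 3 * diff(qa), qa[2] + 3 * diff(qa))
  bulk <- a >= fence[1] & a <= fence[2]
  if (sum(bulk) < 10) bulk <- rep(TRUE, length(a))
  fit <- MASS::rlm(w[bulk] ~ a[bulk], maxit = 50)
  co <- coef(fit)
  r <- w - (co[1] + co[2] * a)
  s <- mad(r[bulk])
  if (s == 0) s <- sd(r[bulk])
  if (!is.finite(s) || s == 0) return(events)
  events[r <= cfg$doublet_rule * s, ]
}

#' Viability gate
#'
#' Retains events negative for the fixable viability dye. When a stained
#' (dead-cell) control is given, the threshold is its `viability_rule`
#' quantile. Without a control a two-component mixture is fitted to the log
#' dye intensity (BIC against one component); the threshold is then placed at
#' the lower `viability_rule` quantile of the fitted dead component. A
#' unimodal sample without control is treated as all live.
#'
#' @inheritParams gate_lymphocytes
#' @param control Optional event tibble of dead/stained control events.
#' @param channel Viability channel name. Default `"Viability"`.
#' @return The live subset of `events`.
#' @export
gate_live <- function(events, cfg = gating_config(), control = NULL,
                      channel = "Viability") {
  require_channels(events, channel)
  v <- events[[channel]]
  if (any(v <= 0)) abort("Viability intensities must be positive.")
  if (!is.null(control)) {
    require_channels(control, channel)
    thr <- quantile(control[[channel]], cfg$viability_rule, names = FALSE)
  } else {
    lx <- log(v)
    fit <- suppressWarnings(
      mclust::Mclust(lx, G = 1:2, modelNames = c("E", "V"), verbose = FALSE)
    )
    if (is.null(fit) || fit$G == 1) return(events)
    mus <- fit$parameters$mean
    sds <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sds) == 1) sds <- rep(sds, 2)
    dead <- which.max(mus)
    # require genuine separation before trusting the second component
    if (abs(diff(mus)) < 2 * max(sds)) return(events)
    thr <- exp(qnorm(cfg$viability_rule, mus[dead], sds[dead]))
  }
  events[v < thr, ]
}

#' Marker positivity threshold from a negative control
#'
#' The threshold is the `positivity_quantile` quantile of the control
#' (isotype or FMO) distribution for the marker; sample events strictly above
#' it are positive.
#'
#' @param sample_events Event tibble to classify.
#' @param control_events Negative-control event tibble (isotype or FMO).
#' @param marker Channel name present in both tables.
#' @inheritParams gate_lymphocytes
#' @return A list with `positive` (logical vector over `sample_events`) and
#'   `threshold` (numeric).
#' @export
threshold_positive <- function(sample_events, control_events, marker,
                               cfg = gating_config()) {
  require_channels(sample_events, marker)
  if (is.null(control_events) || nrow(control_events) == 0) {
    abort("Control event table is empty.")
  }
  require_channels(control_events, marker)
  thr <- quantile(control_events[[marker]], cfg$positivity_quantile,
                  names = FALSE)
  list(positive = sample_events[[marker]] > thr, threshold = thr)
}

#' Proliferation generation from dye dilution
#'
#' The covalent proliferation dye halves per division, so
#' `log2(reference / intensity)` counts divisions. Generation g is assigned
#' on \[g - 0.5, g + 0.5) (boundaries at half-integer log2 dilutions), capped
#' at `max_generation`.
#'
#' @param events Event tibble with the dye channel.
#' @param undivided_reference Mean dye intensity of undivided (generation 0)
#'   cells; must be positive.
#' @inheritParams gate_lymphocytes
#' @param channel Dye channel name. Default `"ProlifDye"`.
#' @return Integer vector of generation indices.
#' @export
assign_generation <- function(events, undivided_reference,
                              cfg = gating_config(), channel = "ProlifDye") {
  require_channels(events, channel)
  if (undivided_reference <= 0) abort("`undivided_reference` must be > 0.")
  x <- events[[channel]]
  if (any(x <= 0)) abort("Dye intensities must be positive.")
  g <- round_half_up(log2(undivided_reference / x))
  as.integer(pmin(pmax(g, 0L), cfg$max_generation))
}

#' Sequential gating of one sample
#'
#' Applies the full gate sequence — lymphocyte scatter gate, doublet
#' exclusion, viability gate, optional CD4 positivity gate (applied only when
#' a CD4 channel exists) — then annotates marker positivity against the
#' supplied controls and the proliferation generation.
#'
#' @param events Raw event tibble.
#' @param cfg A [gating_config()].
#' @param controls Named list: `viability` (optional dead/stained control) and
#'   one negative-control event table per marker to threshold (named by
#'   marker), or a single `markers` entry used for all.
#' @param markers Character vector of marker channels to call positivity on.
#' @param undivided_reference Generation-0 dye reference; when `NULL` the
#'   brightest dye peak (mode of log2 intensity) of the gated events is used.
#' @return A list of class `gated_sample`: `events` (gated tibble with
#'   `generation` and `pos_<marker>` columns), `gate_counts` (named,
#'   monotonically non-increasing), `thresholds` (per marker).
#' @export
gate_sample <- function(events, cfg = gating_config(), controls = list(),
                        markers = character(), undivided_reference = NULL) {
  counts <- c(total = nrow(events))
  g1 <- gate_lymphocytes(events, cfg)
  counts["lymphocytes"] <- nrow(g1)
  g2 <- exclude_doublets(g1, cfg)
  counts["singlets"] <- nrow(g2)
  g3 <- if ("Viability" %in% names(g2)) {
    gate_live(g2, cfg, control = controls$viability)
  } else g2
  counts["live"] <- nrow(g3)
  if ("CD4" %in% names(g3) && !is.null(controls[["CD4"]])) {
    cd4 <- threshold_positive(g3, controls[["CD4"]], "CD4", cfg)
    g3 <- g3[cd4$positive, ]
    counts["cd4"] <- nrow(g3)
  }
  if (nrow(g3) == 0) abort("No events survive the gate sequence.")

  thresholds <- list()
  for (mk in markers) {
    ctrl <- controls[[mk]] %||% controls$markers
    if (is.null(ctrl)) abort(paste0("No control events for marker ", mk))
    tp <- threshold_positive(g3, ctrl, mk, cfg)
    g3[[paste0("pos_", mk)]] <- tp$positive
    thresholds[[mk]] <- tp$threshold
  }
  if ("ProlifDye" %in% names(g3)) {
    if (is.null(undivided_reference)) {
      # generation 0 is the brightest dye peak, not necessarily the most
      # populated one: take the right-most local density maximum carrying at
      # least 5% of the peak height
      l2 <- log2(g3[["ProlifDye"]])
      d <- stats::density(l2, n = 512)
      y <- d$y
      is_peak <- c(FALSE, y[2:511] > y[1:510] & y[2:511] > y[3:512], FALSE)
      is_peak <- is_peak & y >= 0.05 * max(y)
      ref_x <- if (any(is_peak)) max(d$x[is_peak]) else d$x[which.max(y)]
      undivided_reference <- 2^ref_x
    }
    g3$generation <- assign_generation(g3, undivided_reference, cfg)
  }
  structure(list(events = g3, gate_counts = counts, thresholds = thresholds,
                 config = cfg),
            class = "gated_sample")
}

#' @export
print.gated_sample <- function(x, ...) {
  cat("<gated_sample> gate survivors:",
      paste(names(x$gate_counts), x$gate_counts, sep = "=", collapse = " > "),
      "\n")
  invisible(x)
}

#' @export
tidy.gated_sample <- function(x, ...) x$events

#' @export
glance.gated_sample <- function(x, ...) {
  as_tibble(as.list(x$gate_counts))
}
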