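#' Default cytokine panel of the screen
#'
#' The eight recombinant cytokines of the differentiation screen with their
#' working concentrations (RnD Systems panel): IL-1beta 12.5 ng/ml, IL-6
#' 25 ng/ml, IL-21 25 ng/ml, IL-23 25 ng/ml, IL-2 100 IU/ml, IL-10 25 ng/ml,
#' TGF-b1 5 ng/ml, TGF-b3 5 ng/ml.
#'
#' @return A tibble with columns `cytokine`, `concentration`, `unit`.
#' @export
default_cytokines <- function() {
  tibble(
    cytokine = c("IL-1b", "IL-6", "IL-21", "IL-23", "IL-2", "IL-10",
                 "TGF-b1", "TGF-b3"),
    concentration = c(12.5, 25, 25, 25, 100, 25, 5, 5),
    unit = c("ng/ml", "ng/ml", "ng/ml", "ng/ml", "IU/ml", "ng/ml",
             "ng/ml", "ng/ml")
  )
}

#' Generate a cytokine condition design
#'
#' Builds the condition table of a combinatorial cytokine screen: for every
#' time point a no-cytokine control, every single cytokine at each of its
#' concentration levels, and every unordered pair of cytokines at their
#' (highest) working concentrations. One row per (condition, time); cytokine
#' concentrations are wide columns.
#'
#' @param cytokines Tibble with columns `cytokine`, `concentration`
#'   (working/highest level) and optionally `unit`; or a character vector of
#'   names (then all concentrations default to 1).
#' @param levels Optional named list mapping cytokine name to a numeric vector
#'   of nonzero concentration levels for the single-cytokine conditions;
#'   defaults to the single working concentration.
#' @param times Numeric vector of activation durations in days (default 3, 5,
#'   7, inside the screen's 3-7 day window).
#' @param pairs Include all pairwise combinations? (default TRUE)
#' @return A tibble with columns `condition_id`, `time_days`, `is_control`,
#'   and one numeric concentration column per cytokine (prefix `conc_`).
#'   Units are kept in the `units` attribute.
#' @examples
#' d <- generate_design()
#' sum(d$is_control)
#' @export
generate_design <- function(cytokines = default_cytokines(),
                            levels = NULL,
                            times = c(3, 5, 7),
                            pairs = TRUE) {
  if (is.character(cytokines)) {
    cytokines <- tibble(cytokine = cytokines, concentration = 1, unit = "ng/ml")
  }
  cytokines <- as_tibble(cytokines)
  if (nrow(cytokines) < 1) abort("At least one cytokine is required.")
  if (anyDuplicated(cytokines$cytokine)) abort("Duplicated cytokine names.")
  if (any(cytokines$concentration <= 0)) {
    abort("Working concentrations must be positive.")
  }
  if (length(times) < 1 || any(times <= 0)) abort("`times` must be positive days.")

  nm <- cytokines$cytokine
  conc_cols <- paste0("conc_", nm)
  top <- setNames(cytokines$concentration, nm)

  zero_row <- function() setNames(as.list(rep(0, length(nm))), conc_cols)

  rows <- list()
  rows[["control"]] <- tibble(condition_id = "control", !!!zero_row())

  for (cy in nm) {
    lv <- levels[[cy]] %||% top[[cy]]
    lv <- lv[lv > 0]
    if (length(lv) == 0) abort(paste0("No nonzero level for cytokine ", cy))
    for (l in lv) {
      id <- if (length(lv) > 1) paste0(cy, "_", format(l)) else cy
      r <- zero_row()
      r[[paste0("conc_", cy)]] <- l
      rows[[id]] <- tibble(condition_id = id, !!!r)
    }
  }

  if (pairs && length(nm) >= 2) {
    cmb <- utils::combn(nm, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      r <- zero_row()
      r[[paste0("conc_", a)]] <- top[[a]]
      r[[paste0("conc_", b)]] <- top[[b]]
      id <- paste0(a, "+", b)
      rows[[id]] <- tibble(condition_id = id, !!!r)
    }
  }

  base <- bind_rows(rows)
  design <- tidyr::crossing(base, time_days = as.numeric(times)) |>
    mutate(is_control = rowSums(across(dplyr::all_of(conc_cols))) == 0) |>
    select("condition_id", "time_days", "is_control",
           dplyr::all_of(conc_cols)) |>
    arrange(.data$time_days, .data$condition_id != "control",
            .data$condition_id)
  attr(design, "units") <- setNames(
    cytokines$unit %||% rep("ng/ml", length(nm)), nm)
  validate_design(design)
  design
}

#' @rdname generate_design
#' @param design A design tibble to validate.
#' @export
validate_design <- function(design) {
  conc_cols <- grep("^conc_", names(design), value = TRUE)
  if (length(conc_cols) == 0) abort("Design has no `conc_*` columns.")
  concs <- as.matrix(design[conc_cols])
  if (any(concs < 0)) abort("Concentrations must be nonnegative.")
  allzero <- rowSums(concs) == 0
  if (!identical(unname(allzero), unname(design$is_control))) {
    abort("`is_control` must flag exactly the all-zero rows.")
  }
  if (any(colSums(concs) == 0)) {
    abort(paste0("Cytokine column(s) with no nonzero entry: ",
                 paste(conc_cols[colSums(concs) == 0], collapse = ", ")))
  }
  invisible(design)
}

#' Read / write a condition design as CSV
#'
#' @param path File path.
#' @return `read_design()` returns a validated design tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(paste0("Design file not found: ", path))
  design <- as_tibble(read.csv(path, check.names = FALSE))
  if (!all(c("condition_id", "time_days") %in% names(design))) {
    abort("Design CSV must have `condition_id` and `time_days` columns.")
  }
  conc_cols <- grep("^conc_", names(design), value = TRUE)
  if (!"is_control" %in% names(design)) {
    design$is_control <- rowSums(as.matrix(design[conc_cols])) == 0
  }
  design$is_control <- as.logical(design$is_control)
  validate_design(design)
  design
}

#' @rdname read_design
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  write.csv(design, path, row.names = FALSE)
  invisible(path)
}
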