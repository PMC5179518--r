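#' Min-max normalization to the unit interval
#'
#' Linear scaling of a numeric vector onto \[0, 1\]:
#' `f(x) = (x - min(x)) / (max(x) - min(x))`. This is the only scaling applied
#' to predictors anywhere in the package; it keeps cytokine concentrations,
#' time, and fluorescence intensities on a common range without reshaping
#' their distributions.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector of the same length with minimum 0 and maximum 1.
#' @examples
#' minmax_normalize(c(0, 5, 10))
#' @export
minmax_normalize <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  if (anyNA(x)) abort("`x` must not contain missing values.")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    abort("Normalization undefined for a constant vector (max == min).")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Final sodium concentration of a supplemented culture medium
#'
#' Serum-free X-VIVO 15 medium contains 115.8 mM sodium; supplementing with
#' 30 mM NaCl brings it to the 145.8 mM "physiologic" level used for the
#' screen (blood plasma is 135-145 mM Na+). The low-sodium condition is the
#' unsupplemented base medium.
#'
#' @param base_mM Sodium concentration of the base medium in mM
#'   (default 115.8, X-VIVO 15).
#' @param added_nacl_mM NaCl added in mM (default 30; each mole of NaCl
#'   contributes one mole of Na+).
#' @return Final sodium concentration in mM.
#' @examples
#' medium_sodium()          # physiologic condition, 145.8
#' medium_sodium(added_nacl_mM = 0)  # low-sodium condition, 115.8
#' @export
medium_sodium <- function(base_mM = 115.8, added_nacl_mM = 30) {
  stopifnot(is.numeric(base_mM), is.numeric(added_nacl_mM),
            base_mM >= 0, added_nacl_mM >= 0)
  base_mM + added_nacl_mM
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Derive a child seed from a root seed and a counter; kept below 2^31 so the
# result is always a valid R integer seed.
derive_seed <- function(root, counter) {
  as.integer((as.double(root) * 48271 + as.double(counter) * 9973) %% 2147483647)
}

`%||%` <- rlang::`%||%`
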