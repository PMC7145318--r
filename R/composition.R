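#' Mixture composition arithmetic
#'
#' The simulated mixtures hold a fixed number of water molecules and a
#' variable number of disaccharide (THAL) molecules; composition is reported
#' as the THAL mass fraction
#' \deqn{\omega = n_T M_T / (n_T M_T + n_W M_W)}
#' with molar masses M_T = 342.296 and M_W = 18.0153 g/mol.
#'
#' `composition()` builds the record from integer counts;
#' `composition_builder()` finds the integer THAL count whose recomputed mass
#' fraction is closest to a target \eqn{\omega}.
#'
#' @param n_water,n_thal molecule counts (non-negative integers).
#' @return list of class `Composition` with `n_water`, `n_thal`, `omega`.
#' @export
composition <- function(n_water, n_thal) {
  if (n_water < 0 || n_thal < 0) stop("counts must be non-negative", call. = FALSE)
  mt <- n_thal * M_THAL; mw <- n_water * M_WATER
  if (mt + mw <= 0) stop("empty system has no composition", call. = FALSE)
  structure(list(n_water = as.integer(n_water), n_thal = as.integer(n_thal),
                 omega = mt / (mt + mw)),
            class = "Composition")
}

#' @param omega_target target THAL mass fraction in [0, 1).
#' @rdname composition
#' @return `composition_builder`: a `Composition` with an extra
#'   `omega_error` field, the absolute deviation of the realized mass
#'   fraction from the target.
#' @examples
#' composition_builder(1500, 0.760)  # 250 THAL per 1500 waters
#' @export
composition_builder <- function(n_water, omega_target) {
  if (n_water <= 0) stop("n_water must be positive", call. = FALSE)
  if (omega_target < 0 || omega_target >= 1) {
    stop("omega_target must lie in [0, 1): a finite THAL count cannot reach ",
         "omega = 1 with a fixed number of waters", call. = FALSE)
  }
  n_thal <- round(n_water * M_WATER * omega_target / (M_THAL * (1 - omega_target)))
  out <- composition(n_water, n_thal)
  out$omega_error <- abs(out$omega - omega_target)
  out
}

#' @export
print.Composition <- function(x, ...) {
  cat(sprintf("Composition: %d water + %d THAL, omega = %.4f", x$n_water,
              x$n_thal, x$omega))
  if (!is.null(x$omega_error)) cat(sprintf(" (|error| = %.2e)", x$omega_error))
  cat("\n")
  invisible(x)
}
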