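#' Glass-transition temperature from a density-temperature curve
#'
#' The simulations locate Tg at the maximum of the density-vs-temperature
#' curve of each mixture (an NPT signature of the glass transition in these
#' systems). `quadratic_window` fits a least-squares parabola to the five
#' tabulated points bracketing the grid maximum and reports the vertex;
#' `spline` takes the argmax of a cubic smoothing spline. Both enforce
#' negative curvature at the optimum.
#'
#' @param curve data.frame with columns `T` (K, strictly increasing, >= 4
#'   points) and `rho` (g/cm^3), for a single composition.
#' @param fit "quadratic_window" or "spline".
#' @return list of class `TgEstimate`: `tg` (K), `method`, `curvature`,
#'   `residual`.
#' @export
estimate_tg_from_density <- function(curve, fit = c("quadratic_window", "spline")) {
  fit <- match.arg(fit)
  t_ <- curve$T; rho <- curve$rho
  if (length(t_) < 4) stop("need >= 4 points", call. = FALSE)
  if (any(diff(t_) <= 0)) stop("temperatures must be strictly increasing",
                               call. = FALSE)
  pk <- which.max(rho)
  if (pk == 1 || pk == length(t_)) {
    stop("no density maximum in span: the curve is monotone at the boundary",
         call. = FALSE)
  }
  if (fit == "quadratic_window") {
    lo <- max(1L, pk - 2L); hi <- min(length(t_), pk + 2L)
    lo <- max(1L, min(lo, hi - 4L)); hi <- min(length(t_), lo + 4L)
    w <- lo:hi
    qf <- stats::lm(rho[w] ~ t_[w] + I(t_[w]^2))
    co <- stats::coef(qf)
    if (!is.finite(co[[3]]) || co[[3]] >= 0) {
      stop("window fit has non-negative curvature; no interior maximum",
           call. = FALSE)
    }
    tg <- -co[[2]] / (2 * co[[3]])
    if (tg < t_[lo] || tg > t_[hi]) {
      warning("parabola vertex outside the bracketing window; ",
              "falling back to the grid argmax")
      tg <- t_[pk]
    }
    structure(list(tg = tg, method = "density_maximum",
                   curvature = co[[3]],
                   residual = sqrt(mean(stats::resid(qf)^2))),
              class = "TgEstimate")
  } else {
    sp <- stats::smooth.spline(t_, rho)
    grid <- seq(t_[2], t_[length(t_) - 1], length.out = 2000)
    pred <- stats::predict(sp, grid)$y
    i <- which.max(pred)
    # negative-curvature check via second differences at the optimum
    d2 <- diff(pred, differences = 2)
    j <- min(max(i - 1, 1), length(d2))
    if (d2[j] >= 0) {
      stop("spline argmax is not a local maximum", call. = FALSE)
    }
    structure(list(tg = grid[i], method = "density_maximum",
                   curvature = d2[j] / diff(grid)[1]^2,
                   residual = sqrt(mean((stats::predict(sp, t_)$y - rho)^2))),
              class = "TgEstimate")
  }
}

#' @export
print.TgEstimate <- function(x, ...) {
  cat(sprintf("Tg = %.2f K (%s; curvature %.3g, RMS residual %.3g)\n",
              x$tg, x$method, x$curvature, x$residual))
  invisible(x)
}

#' Couchman-Karasz mixture glass-transition temperature
#'
#' Standard heat-capacity-increment mixing rule for the Tg of a binary
#' mixture:
#' \deqn{T_g(\omega) = \frac{\omega \Delta C_{p,T} T_{g,T} +
#'   (1-\omega) \Delta C_{p,W} T_{g,W}}{\omega \Delta C_{p,T} +
#'   (1-\omega) \Delta C_{p,W}}}
#' Default component parameters are literature-typical placeholders for
#' water and trehalose and are fully configurable; they are inputs, not
#' fitted values.
#'
#' @param omega THAL mass fraction in `[0, 1]` (vectorized).
#' @param tg_water,tg_thal component glass-transition temperatures (K).
#' @param dcp_water,dcp_thal heat-capacity increments at Tg (J/(g K)).
#' @return Tg of the mixture (K).
#' @export
couchman_karasz_tg <- function(omega, tg_water = 136, dcp_water = 1.94,
                               tg_thal = 388, dcp_thal = 0.55) {
  if (any(omega < 0 | omega > 1)) stop("omega must lie in [0, 1]", call. = FALSE)
  if (any(c(tg_water, tg_thal) <= 0) || any(c(dcp_water, dcp_thal) <= 0)) {
    stop("component Tg and delta-Cp must be positive", call. = FALSE)
  }
  (omega * dcp_thal * tg_thal + (1 - omega) * dcp_water * tg_water) /
    (omega * dcp_thal + (1 - omega) * dcp_water)
}

#' Compare Tg estimates against a model curve
#'
#' @param md data.frame with columns `omega`, `tg` (simulation estimates).
#' @param ck data.frame with columns `omega`, `tg` (model values) on the
#'   same omega grid.
#' @return list with the per-omega `table` (`omega`, `tg_md`, `tg_ck`,
#'   `diff`), `mad` (mean absolute difference, K) and `max_diff` (K).
#' @export
compare_tg <- function(md, ck) {
  if (nrow(md) != nrow(ck) ||
      max(abs(sort(md$omega) - sort(ck$omega))) > 1e-9) {
    stop("omega grids do not match", call. = FALSE)
  }
  md <- md[order(md$omega), ]; ck <- ck[order(ck$omega), ]
  tab <- data.frame(omega = md$omega, tg_md = md$tg, tg_ck = ck$tg,
                    diff = md$tg - ck$tg)
  list(table = tab, mad = mean(abs(tab$diff)), max_diff = max(abs(tab$diff)))
}
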