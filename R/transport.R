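#' Mean-square displacement of molecular centres of mass
#'
#' MSD(tau) averaged over molecules and time origins, computed from the
#' trajectory's unwrapped coordinates. Computing MSD on wrapped coordinates
#' is meaningless under periodic boundaries, so a trajectory without an
#' unwrapped channel is rejected.
#'
#' Lags are log-spaced (up to `n_lags` distinct integer lags) and, when the
#' full origin average would be too expensive, origins are strided; both the
#' lag set and the per-lag sample counts are reported.
#'
#' @param traj a [trajectory()] with `unwrapped` coordinates.
#' @param species molecule type to analyse.
#' @param max_lag maximum lag time (ps); default half the span.
#' @param n_lags maximum number of distinct lags.
#' @param origin_stride origin subsampling stride; `NULL` picks one that
#'   caps the work at roughly 3e8 operations.
#' @return data.frame of class `MSDSeries` with columns `tau` (ps), `msd`
#'   (Angstrom^2), `n_samples`.
#' @export
compute_msd <- function(traj, species, max_lag = NULL, n_lags = 120,
                        origin_stride = NULL) {
  if (is.null(traj$unwrapped)) {
    stop("trajectory has no unwrapped coordinates; MSD must not be computed ",
         "from wrapped positions -- regenerate with an unwrapped channel",
         call. = FALSE)
  }
  nf <- n_frames(traj)
  if (nf < 3) stop("need >= 3 frames", call. = FALSE)
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) {
    stop("non-uniform frame times", call. = FALSE)
  }
  dt <- dts[1]
  top <- traj$topology
  sel <- which(top$molecule_type == species)
  if (!length(sel)) stop("no molecules of type ", species, call. = FALSE)
  mol <- top$molecule_id[sel]
  mol_f <- factor(mol)
  n_mol <- nlevels(mol_f)
  mass <- top$mass[sel]
  mtot <- as.numeric(tapply(mass, mol_f, sum))
  single_site <- length(sel) == n_mol
  # centre-of-mass array: n_mol x 3 x nf
  com <- array(0, c(n_mol, 3, nf))
  if (single_site) {
    com <- traj$unwrapped[sel, , , drop = FALSE]
  } else {
    for (f in seq_len(nf)) {
      xyz <- traj$unwrapped[sel, , f, drop = TRUE]
      com[, , f] <- rowsum(xyz * mass, mol_f) / mtot
    }
  }
  if (is.null(max_lag)) max_lag <- (traj$times[nf] - traj$times[1]) / 2
  max_lag_f <- max(1L, min(nf - 1L, floor(max_lag / dt)))
  lags <- sort(unique(round(exp(seq(0, log(max_lag_f), length.out = n_lags)))))
  if (is.null(origin_stride)) {
    work <- sum(nf - lags) * n_mol * 3
    origin_stride <- max(1L, ceiling(work / 3e8))
  }
  msd <- numeric(length(lags)); nsamp <- integer(length(lags))
  for (li in seq_along(lags)) {
    lag <- lags[li]
    orig <- seq(1L, nf - lag, by = origin_stride)
    d2 <- (com[, , orig + lag, drop = FALSE] - com[, , orig, drop = FALSE])^2
    msd[li] <- sum(d2) / (length(orig) * n_mol)
    nsamp[li] <- length(orig) * n_mol
  }
  out <- data.frame(tau = c(0, lags * dt), msd = c(0, msd),
                    n_samples = c(n_mol * nf, nsamp))
  class(out) <- c("MSDSeries", "data.frame")
  out
}

#' Einstein-relation diffusion coefficient with diffusive-window detection
#'
#' Finds the longest contiguous lag range where the local log-log slope
#' beta of MSD vs tau satisfies `|beta - 1| <= beta_tol` (fully diffusive
#' regime), then fits MSD = 6 D tau there by least squares.
#'
#' @param msd an `MSDSeries` from [compute_msd()].
#' @param beta_tol tolerance on the log-log slope (default 0.1).
#' @param min_points minimum number of lags in the window.
#' @return list of class `DiffusionEstimate`: `D` (Angstrom^2/ps), `window`
#'   (ps), `beta` (mean slope in window), `se` (standard error of D).
#' @export
fit_diffusion <- function(msd, beta_tol = 0.1, min_points = 5) {
  pos <- msd$tau > 0
  tau <- msd$tau[pos]; m <- msd$msd[pos]
  if (length(tau) < 10) stop("need >= 10 lag points", call. = FALSE)
  if (max(m) < 1e-10) {
    return(structure(list(D = 0, window = range(tau), beta = NA_real_,
                          se = 0), class = "DiffusionEstimate"))
  }
  lt <- log(tau); lm_ <- log(pmax(m, 1e-300))
  n <- length(lt)
  beta <- rep(NA_real_, n)
  beta[2:(n - 1)] <- (lm_[3:n] - lm_[1:(n - 2)]) / (lt[3:n] - lt[1:(n - 2)])
  beta <- stats::filter(beta, rep(1 / 5, 5), sides = 2)
  good <- !is.na(beta) & abs(beta - 1) <= beta_tol
  # longest contiguous run of good points
  r <- rle(as.vector(good))
  if (!any(r$values)) {
    stop("no diffusive regime found (|beta - 1| <= ", beta_tol,
         " nowhere); run a longer trajectory", call. = FALSE)
  }
  best <- which(r$values & r$lengths == max(r$lengths[r$values]))[1]
  i1 <- sum(r$lengths[seq_len(best - 1)]) + 1L
  i2 <- i1 + r$lengths[best] - 1L
  if (i2 - i1 + 1L < min_points) {
    stop("no diffusive regime found (longest window has ", i2 - i1 + 1L,
         " points); run a longer trajectory", call. = FALSE)
  }
  win <- i1:i2
  fit <- stats::lm(m[win] ~ tau[win])
  slope <- stats::coef(fit)[[2]]
  se <- summary(fit)$coefficients[2, 2] / 6
  structure(list(D = slope / 6, window = range(tau[win]),
                 beta = mean(beta[win]), se = se),
            class = "DiffusionEstimate")
}

#' @export
print.DiffusionEstimate <- function(x, ...) {
  cat(sprintf("D = %.4g Angstrom^2/ps (window %.3g-%.3g ps, beta = %.3f)\n",
              x$D, x$window[1], x$window[2], x$beta))
  invisible(x)
}

#' Arrhenius diagnostics for diffusion coefficients
#'
#' Linear fit of ln D against 1/T. Strong structured residuals and a low
#' R-squared flag super-Arrhenius (glassy, Vogel-Fulcher-like) behaviour.
#'
#' @param D_by_T data.frame with columns `T` (K) and `D` (Angstrom^2/ps),
#'   or a named numeric vector (names = temperatures).
#' @return list of class `ArrheniusFit`: `Ea` activation energy (kJ/mol),
#'   `A` pre-exponential factor (Angstrom^2/ps), `r_squared`, `residuals`
#'   data.frame, `excluded` temperatures with non-positive D.
#' @export
arrhenius_analysis <- function(D_by_T) {
  if (!is.data.frame(D_by_T)) {
    D_by_T <- data.frame(T = as.numeric(names(D_by_T)), D = as.numeric(D_by_T))
  }
  bad <- D_by_T$D <= 0 | !is.finite(D_by_T$D)
  if (any(bad)) {
    warning("excluding ", sum(bad), " point(s) with non-positive D")
  }
  df <- D_by_T[!bad, , drop = FALSE]
  if (nrow(df) < 2) stop("need >= 2 temperatures with D > 0", call. = FALSE)
  if (nrow(df) == 2) warning("only 2 points: fit is exact, no degrees of freedom")
  x <- 1 / df$T; y <- log(df$D)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (nrow(df) > 2) summary(fit)$r.squared else 1
  structure(list(Ea = -co[[2]] * GAS_R, A = exp(co[[1]]), r_squared = r2,
                 residuals = data.frame(T = df$T, residual = stats::resid(fit)),
                 excluded = D_by_T$T[bad]),
            class = "ArrheniusFit")
}

#' @export
print.ArrheniusFit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.4g kJ/mol, A = %.4g A^2/ps, R^2 = %.4f\n",
              x$Ea, x$A, x$r_squared))
  invisible(x)
}
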