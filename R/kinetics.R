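#' Bond population series
#'
#' Container for intermittent hydrogen-bond populations: a 0/1 matrix `h`
#' (frames x tracked pairs) on a uniform time grid, plus an optional
#' `present` indicator of the pair being within the reformation cutoff.
#'
#' @param h integer/logical matrix, frames x pairs, 1 = bonded.
#' @param dt frame spacing (ps).
#' @param present optional matrix like `h`; `NULL` means always present.
#' @param class pair-class token (WW/WT/TW/TT or ALL).
#' @param pairs optional data.frame identifying the tracked pairs.
#' @return list of class `BondPopulationSeries`.
#' @export
bond_population_series <- function(h, dt, present = NULL, class = "ALL",
                                   pairs = NULL) {
  h <- as.matrix(h)
  if (!all(h %in% c(0, 1))) stop("h must be 0/1", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.null(present) && !identical(dim(present), dim(h))) {
    stop("present must match h in shape", call. = FALSE)
  }
  structure(list(h = h, present = present, dt = dt, class = class,
                 pairs = pairs),
            class = "BondPopulationSeries")
}

#' Build bond population series from a trajectory
#'
#' Tracks every donor-acceptor oxygen pair bonded in at least one frame and
#' records its bonded indicator h(t) per frame, plus an auxiliary
#' present(t) indicator of the pair separation being within `pair_cutoff`
#' (needed for the broken-but-adjacent correlation n(t)).
#'
#' @param traj a [trajectory()] with uniform frame spacing.
#' @param criteria an [hbond_criteria()].
#' @param class_filter optional class token (WW/WT/TW/TT) to restrict pairs.
#' @param pair_cutoff separation cutoff for `present` (Angstrom); defaults
#'   to the bonding distance cutoff.
#' @param ... passed to [detect_hbonds()].
#' @return a [bond_population_series()].
#' @export
build_population_series <- function(traj, criteria = hbond_criteria(),
                                    class_filter = NULL,
                                    pair_cutoff = criteria$d_max, ...) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need >= 2 frames", call. = FALSE)
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) {
    stop("non-uniform frame times; kinetics needs a uniform grid", call. = FALSE)
  }
  recs <- vector("list", nf)
  for (f in seq_len(nf)) {
    hb <- detect_hbonds(get_frame(traj, f), traj$topology, criteria, ...)
    if (!is.null(class_filter)) hb <- hb[hb$class %in% class_filter, , drop = FALSE]
    hb$frame <- f
    recs[[f]] <- hb
  }
  all_rec <- do.call(rbind, recs)
  if (!nrow(all_rec)) stop("no hydrogen bonds found in any frame", call. = FALSE)
  key <- paste(all_rec$donor_o, all_rec$acceptor_o)
  pairs <- unique(all_rec[, c("donor_o", "acceptor_o")])
  pair_key <- paste(pairs$donor_o, pairs$acceptor_o)
  np <- nrow(pairs)
  h <- matrix(0L, nf, np)
  h[cbind(all_rec$frame, match(key, pair_key))] <- 1L
  present <- matrix(0L, nf, np)
  ia <- pairs$donor_o + 1L; ib <- pairs$acceptor_o + 1L
  for (f in seq_len(nf)) {
    L <- traj$boxes[f, ]
    xyz <- traj$coords[, , f, drop = TRUE]
    d <- sqrt(rowSums(minimum_image_displacement(xyz[ia, , drop = FALSE],
                                                 xyz[ib, , drop = FALSE], L)^2))
    present[f, ] <- as.integer(d <= pair_cutoff)
  }
  bond_population_series(h, dt = dts[1], present = present,
                         class = if (is.null(class_filter)) "ALL" else class_filter,
                         pairs = pairs)
}

# column-blocked FFT correlation sums:
# auto[tau+1]  = sum_p sum_t0 h[t0] h[t0+tau]
# cross[tau+1] = sum_p sum_t0 h[t0] g[t0+tau]
fft_correlation_sums <- function(h, g, n_lags, block = 1000L) {
  n <- nrow(h); np <- ncol(h)
  m <- 2^ceiling(log2(2L * n))
  auto <- numeric(n_lags); cross <- numeric(n_lags)
  for (start in seq(1L, np, by = block)) {
    idx <- start:min(np, start + block - 1L)
    hp <- rbind(h[, idx, drop = FALSE],
                matrix(0, m - n, length(idx)))
    fh <- stats::mvfft(hp)
    sa <- Re(stats::mvfft(fh * Conj(fh), inverse = TRUE)) / m
    auto <- auto + rowSums(sa[seq_len(n_lags), , drop = FALSE])
    if (!is.null(g)) {
      gp <- rbind(g[, idx, drop = FALSE], matrix(0, m - n, length(idx)))
      fg <- stats::mvfft(gp)
      sc <- Re(stats::mvfft(Conj(fh) * fg, inverse = TRUE)) / m
      cross <- cross + rowSums(sc[seq_len(n_lags), , drop = FALSE])
    }
  }
  list(auto = auto, cross = cross)
}

#' Intermittent bond correlation functions c(t) and n(t)
#'
#' Reactive-flux inputs with the intermittent population operator:
#' \deqn{c(t) = \sum_p \langle h(0) h(t)\rangle / \sum_p \langle h(0)\rangle}
#' \deqn{n(t) = \sum_p \langle h(0)(1 - h(t))\,present(t)\rangle /
#'   \sum_p \langle h(0)\rangle}
#' averaged over all time origins, so c(0) = 1 and n(0) = 0. n(t) measures
#' pairs that are broken but still within the reformation cutoff.
#'
#' @param series a [bond_population_series()].
#' @param t_max maximum lag (ps); must be below the series span.
#' @return data.frame with columns `t`, `c`, `n`, of class `BondCorrelations`.
#' @export
compute_correlations <- function(series, t_max) {
  h <- series$h
  n <- nrow(h)
  n_lags <- floor(t_max / series$dt) + 1L
  if (n_lags >= n) stop("t_max must be below the trajectory span", call. = FALSE)
  if (sum(h) == 0) stop("no bonded origin events", call. = FALSE)
  g <- (1L - h) * (if (is.null(series$present)) 1L else series$present)
  sums <- fft_correlation_sums(h, g, n_lags)
  # the sums are counts of 0/1 products: integers, so strip FFT round-off
  sums$auto <- round(sums$auto)
  sums$cross <- round(sums$cross)
  s_t <- rowSums(h)
  denom <- cumsum(s_t)[n - (seq_len(n_lags) - 1L)]  # sum over origins 1..n-tau
  out <- data.frame(t = (seq_len(n_lags) - 1L) * series$dt,
                    c = sums$auto / denom, n = sums$cross / denom)
  class(out) <- c("BondCorrelations", "data.frame")
  out
}

#' Reactive-flux rate fit: forward and backward lifetimes
#'
#' Fits the two-rate reactive-flux relation
#' \deqn{k(t) = -dc/dt = k_f c(t) - k_b n(t)}
#' by least squares over a time window, with non-negativity of both rates
#' enforced. Lifetimes are the reciprocal rates: tau_forward = 1/k_f (bond
#' persistence) and tau_backward = 1/k_b (difficulty of reforming a broken
#' bond).
#'
#' @param corr a `BondCorrelations` data.frame from [compute_correlations()]
#'   (columns `t`, `c`, `n`).
#' @param window length-2 numeric (ps). Default `c(0.1, 0.5) * max(t)`,
#'   skipping the short-time transient and the noisy tail.
#' @param smooth integer; odd running-mean half-window applied to the
#'   numerical derivative (0 = off, the default).
#' @return list of class `KineticsResult`: `k_forward`, `k_backward`,
#'   `tau_forward`, `tau_backward` (ps), `window`, `residual` (RMS of the
#'   fit), and the `k_t` curve used.
#' @export
fit_reactive_flux <- function(corr, window = NULL, smooth = 0) {
  t_ <- corr$t; cc <- corr$c; nn <- corr$n
  if (length(t_) < 5) stop("correlation curves too short to fit", call. = FALSE)
  dt <- t_[2] - t_[1]
  if (is.null(window)) window <- c(0.1, 0.5) * max(t_)
  k_t <- rep(NA_real_, length(t_))
  k_t[2:(length(t_) - 1)] <- -(cc[3:length(t_)] - cc[1:(length(t_) - 2)]) / (2 * dt)
  if (smooth > 0) {
    w <- 2 * smooth + 1
    k_t <- stats::filter(k_t, rep(1 / w, w), sides = 2)
  }
  sel <- which(t_ >= window[1] & t_ <= window[2] & !is.na(k_t))
  if (length(sel) < 3) stop("fit window contains too few points", call. = FALSE)
  x1 <- cc[sel]; x2 <- -nn[sel]; y <- k_t[sel]
  if (stats::sd(x1) < 1e-12 && all(abs(x2) < 1e-12)) {
    stop("singular design: c(t) constant and n(t) = 0 in the window",
         call. = FALSE)
  }
  xm <- cbind(kf = x1, kb = x2)
  fit <- tryCatch(stats::lm.fit(xm, y)$coefficients,
                  error = function(e) c(kf = NA_real_, kb = NA_real_))
  if (any(is.na(fit))) fit <- c(kf = 0, kb = 0)
  if (fit[["kb"]] < 0) {
    fit[["kb"]] <- 0
    fit[["kf"]] <- sum(x1 * y) / sum(x1^2)
  }
  if (fit[["kf"]] < 0) fit[["kf"]] <- 0
  resid <- sqrt(mean((y - (fit[["kf"]] * x1 + fit[["kb"]] * x2))^2))
  if (fit[["kf"]] == 0) {
    warning("k_forward = 0; tau_forward reported as infinite")
  }
  structure(list(k_forward = fit[["kf"]], k_backward = fit[["kb"]],
                 tau_forward = 1 / fit[["kf"]], tau_backward = 1 / fit[["kb"]],
                 window = window, residual = resid,
                 k_t = data.frame(t = t_, k = k_t)),
            class = "KineticsResult")
}

#' @export
print.KineticsResult <- function(x, ...) {
  cat(sprintf(paste0("Reactive-flux fit: k_f = %.4g /ps (tau_f = %.4g ps), ",
                     "k_b = %.4g /ps (tau_b = %.4g ps)\n"),
              x$k_forward, x$tau_forward, x$k_backward, x$tau_backward))
  cat(sprintf("  window %.3g-%.3g ps, RMS residual %.3g\n",
              x$window[1], x$window[2], x$residual))
  invisible(x)
}
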