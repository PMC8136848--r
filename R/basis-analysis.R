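## Characterization of learned basis vectors: windowed linear-FM template
## fits (ILD, ITD, center frequency, sweep rate), pure-tone probing of
## binaural units, and tuning-curve classification.

chirp_phase <- function(t, fc, m, t0) 2 * pi * (fc * (t - t0) + m / 2 * (t - t0)^2)

#' Synthesize a binaural Gaussian-windowed chirp pair
#'
#' Utility for constructing test pairs with known interaural parameters:
#' both components share the envelope and instantaneous-frequency track;
#' positive `ild_db` makes the right component louder and positive
#' `itd_s` advances the right component's phase (right ear leading), the
#' same conventions used throughout the package.
#'
#' @param n Samples per component.
#' @param fs Sampling rate, Hz.
#' @param fc Center frequency at the envelope center, Hz.
#' @param sweep Sweep rate, Hz per second (negative = downward).
#' @param ild_db Interaural level difference, dB.
#' @param itd_s Interaural time difference, seconds.
#' @param t0 Envelope center, s (default mid-window).
#' @param width Envelope standard deviation, s.
#' @param phase0 Common phase offset, radians.
#' @return List with `left` and `right` numeric vectors.
#' @export
make_chirp_pair <- function(n = 50, fs = 5e5, fc = 40e3, sweep = -23e6,
                            ild_db = 0, itd_s = 0, t0 = (n - 1) / fs / 2,
                            width = (n / fs) / 4, phase0 = 0) {
  t <- (seq_len(n) - 1) / fs
  env <- exp(-(t - t0)^2 / (2 * width^2))
  psi <- chirp_phase(t, fc, sweep, t0)
  al <- 10^(-ild_db / 40); ar <- 10^(ild_db / 40)
  list(left = al * env * cos(psi + phase0),
       right = ar * env * cos(psi + phase0 + 2 * pi * fc * itd_s))
}

## Analytic-signal initial estimates of (fc, sweep, t0, width) for one
## component.
chirp_init <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 } else h[2:((n + 1) / 2)] <- 2
  z <- stats::fft(X * h, inverse = TRUE) / n
  env <- Mod(z)
  t <- (seq_len(n) - 1) / fs
  w2 <- env^2 / sum(env^2)
  t0 <- sum(w2 * t)
  width <- sqrt(max(sum(w2 * (t - t0)^2), (1 / fs)^2))
  ph <- Arg(z)
  ph <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi)) - 2 * pi * cumsum(c(0, diff(ph) > pi))
  ## weighted linear fit of instantaneous frequency against time
  finst <- c(diff(ph), 0) * fs / (2 * pi)
  wts <- w2[-n]
  tt <- t[-n]; ff <- finst[-n]
  wm <- function(v) sum(wts * v) / sum(wts)
  beta <- sum(wts * (tt - wm(tt)) * (ff - wm(ff))) / max(sum(wts * (tt - wm(tt))^2), 1e-30)
  fc <- wm(ff) + beta * (t0 - wm(tt))
  list(fc = fc, sweep = beta, t0 = t0, width = width)
}

## Linear amplitude/phase solve for one component given the nonlinear
## template parameters; returns c1, c2 and the residual sum of squares.
chirp_linfit <- function(x, t, fc, m, t0, width) {
  env <- exp(-(t - t0)^2 / (2 * width^2))
  psi <- chirp_phase(t, fc, m, t0)
  X <- cbind(env * cos(psi), env * sin(psi))
  fit <- stats::lm.fit(X, x)
  list(c1 = unname(fit$coefficients[1]), c2 = unname(fit$coefficients[2]),
       rss = sum(fit$residuals^2))
}

#' Characterize a binaural basis vector by a windowed linear-FM fit
#'
#' Fits a Gaussian-windowed linear chirp `g(t)` to the left and right
#' components jointly (shared center frequency, sweep rate, envelope
#' center and width; per-component amplitude and phase).  The interaural
#' level difference is the amplitude ratio in dB (positive: right
#' louder); the interaural time difference is the phase difference
#' divided by `2 pi fc`, wrapped to one period (positive: right leads).
#'
#' @param left,right Component vectors (same length).
#' @param fs Sampling rate of the components, Hz (fine-scale windows are
#'   at the raw 500 kHz; coarse windows at 250 kHz after decimation).
#' @return A `basis_fit` list with `ild_db`, `itd_s`, `fc`, `sweep`
#'   (Hz/s), `amp_left`, `amp_right`, `residual` (relative RSS), an
#'   `fc_in_band` flag (plausible center frequency) and `converged`
#'   (small residual with in-band fc).
#' @export
characterize_basis <- function(left, right, fs = 5e5) {
  if (length(left) != length(right)) stop_invalid("components differ in length")
  n <- length(left)
  t <- (seq_len(n) - 1) / fs
  dom <- if (sum(left^2) >= sum(right^2)) left else right
  init <- chirp_init(dom, fs)
  obj <- function(par) {
    fc <- par[1] * 1e3; m <- par[2] * 1e6; t0 <- par[3] / fs; w <- exp(par[4]) / fs
    if (fc <= 0 || w <= 0) return(1e6)
    chirp_linfit(left, t, fc, m, t0, w)$rss +
      chirp_linfit(right, t, fc, m, t0, w)$rss
  }
  p0 <- c(init$fc / 1e3, init$sweep / 1e6, init$t0 * fs, log(init$width * fs))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-11))
  par <- opt$par
  fc <- par[1] * 1e3; m <- par[2] * 1e6; t0 <- par[3] / fs; w <- exp(par[4]) / fs
  fl <- chirp_linfit(left, t, fc, m, t0, w)
  fr <- chirp_linfit(right, t, fc, m, t0, w)
  amp <- function(f) sqrt(f$c1^2 + f$c2^2)
  ph <- function(f) atan2(f$c2, f$c1)
  dphi <- ph(fl) - ph(fr)   # right phase advanced => positive ITD
  dphi <- atan2(sin(dphi), cos(dphi))
  tot <- sum(left^2) + sum(right^2)
  rel <- (fl$rss + fr$rss) / max(tot, 1e-30)
  fc_in_band <- fc >= 5e3 && fc <= 1.2e5
  structure(list(ild_db = 20 * log10(amp(fr) / amp(fl)),
                 itd_s = dphi / (2 * pi * fc),
                 fc = fc, sweep = m, fc_in_band = fc_in_band,
                 amp_left = amp(fl), amp_right = amp(fr),
                 residual = rel, converged = rel < 0.5 && fc_in_band),
            class = "basis_fit")
}

#' @export
print.basis_fit <- function(x, ...) {
  cat(sprintf("basis fit: ILD %.2f dB, ITD %.2f us, fc %.1f kHz, sweep %.1f kHz/ms (rel. RSS %.3f)\n",
              x$ild_db, x$itd_s * 1e6, x$fc / 1e3, x$sweep / 1e6, x$residual))
  invisible(x)
}

#' Interaural cue table for all basis vectors of a binaural GASSOM
#'
#' Runs [characterize_basis()] on every basis vector (two per unit,
#' split into the left and right halves of the binaural window).
#'
#' @param g A binaural `gassom` (even input dimension).
#' @param fs Sampling rate of the windows, Hz.
#' @return Data frame with columns `unit`, `vector`, `ild_db`, `itd_us`,
#'   `fc_khz`, `sweep_khz_ms`, `residual`, `converged`.
#' @export
basis_cue_table <- function(g, fs = 5e5) {
  stopifnot(inherits(g, "gassom"))
  if (g$d %% 2L != 0L) stop_invalid("not a binaural dictionary")
  half <- g$d %/% 2L
  rows <- vector("list", 2L * g$J)
  for (j in seq_len(g$J)) {
    for (v in 1:2) {
      b <- g$Phi[, 2L * (j - 1L) + v]
      ft <- characterize_basis(b[seq_len(half)], b[half + seq_len(half)], fs)
      rows[[2L * (j - 1L) + v]] <- data.frame(
        unit = j, vector = v, ild_db = ft$ild_db, itd_us = ft$itd_s * 1e6,
        fc_khz = ft$fc / 1e3, sweep_khz_ms = ft$sweep / 1e6,
        residual = ft$residual, converged = ft$converged)
    }
  }
  do.call(rbind, rows)
}

#' Histogram of interaural cues over a dictionary
#'
#' @param values Cue values (ILD in dB or ITD in us).
#' @param breaks Bin edges; values outside are clamped into the end bins
#'   (2 dB bins over +/-21 dB, or 5 us bins over +/-52.5 us, by default
#'   choose via `cue`).
#' @param cue `"ild"` or `"itd"` (sets default breaks).
#' @return List with `breaks`, `counts` and normalized `p`.
#' @export
cue_histogram <- function(values, cue = c("ild", "itd"), breaks = NULL) {
  cue <- match.arg(cue)
  if (is.null(breaks)) {
    breaks <- if (cue == "ild") seq(-21, 21, by = 2) else seq(-52.5, 52.5, by = 5)
  }
  v <- pmin(pmax(values, min(breaks) + 1e-9), max(breaks) - 1e-9)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(breaks = breaks, counts = h$counts, p = h$counts / sum(h$counts))
}

## ---- pure-tone probing --------------------------------------------------

tone_pair_matrix <- function(freq, ild_db, itd_s, n, fs, phases) {
  t <- (seq_len(n) - 1) / fs
  al <- 10^(-ild_db / 40); ar <- 10^(ild_db / 40)
  S <- vapply(phases, function(p0) {
    l <- al * cos(2 * pi * freq * t + p0)
    r <- ar * cos(2 * pi * freq * t + p0 + 2 * pi * freq * itd_s)
    x <- c(l, r)
    x / sqrt(sum(x^2))
  }, numeric(2L * n))
  t(S)
}

unit_response <- function(g, j, S) {
  Phi_j <- g$Phi[, (2L * j - 1L):(2L * j), drop = FALSE]
  P <- S %*% Phi_j
  rowSums(P^2)
}

#' Pure-tone probing of binaural GASSOM units
#'
#' The protocol mirrors standard binaural physiology: first the best
#' frequency (BF) of every unit is found with equal-amplitude, in-phase
#' sinusoids stepped from 10 to 70 kHz in 1 kHz steps; then the ILD is
#' swept from -40 to 40 dB in 1 dB steps at BF (zero ITD); then the ITD
#' (as a phase delay) is swept from -80 to 80 us in 1 us steps at BF
#' (zero ILD).  Responses are averaged over stimulus onset phases and
#' normalized to a maximum of 1.
#'
#' @param g A binaural `gassom`.
#' @param fs Sampling rate of the windows, Hz.
#' @param freqs_hz,ilds_db,itds_s Probe grids.
#' @param n_phase Number of onset phases averaged per stimulus.
#' @return List of per-unit records: `bf_hz`, `freq_curve`, `ild_curve`,
#'   `itd_curve` (each a list with `x` and max-normalized `y`).
#' @export
probe_pure_tones <- function(g, fs = 5e5,
                             freqs_hz = seq(10e3, 70e3, by = 1e3),
                             ilds_db = seq(-40, 40, by = 1),
                             itds_s = seq(-80e-6, 80e-6, by = 1e-6),
                             n_phase = 8L) {
  stopifnot(inherits(g, "gassom"))
  if (g$d %% 2L != 0L) stop_invalid("not a binaural dictionary")
  half <- g$d %/% 2L
  phases <- seq(0, 2 * pi, length.out = n_phase + 1L)[-(n_phase + 1L)]
  ## stage 1: BF, all units at once
  Sf <- do.call(rbind, lapply(freqs_hz, function(f) {
    tone_pair_matrix(f, 0, 0, half, fs, phases)
  }))
  P <- Sf %*% g$Phi
  odd <- seq.int(1L, 2L * g$J, by = 2L)
  resp <- P[, odd, drop = FALSE]^2 + P[, odd + 1L, drop = FALSE]^2
  grpf <- rep(seq_along(freqs_hz), each = n_phase)
  freq_resp <- rowsum(resp, grpf) / n_phase   # n_freq x J
  norm_curve <- function(x, y) {
    m <- max(y)
    list(x = x, y = if (m > 0) y / m else y)
  }
  out <- vector("list", g$J)
  for (j in seq_len(g$J)) {
    fy <- freq_resp[, j]
    bf <- freqs_hz[which.max(fy)]
    Si <- do.call(rbind, lapply(ilds_db, function(ild) {
      tone_pair_matrix(bf, ild, 0, half, fs, phases)
    }))
    ily <- rowsum(unit_response(g, j, Si), rep(seq_along(ilds_db), each = n_phase)) / n_phase
    St <- do.call(rbind, lapply(itds_s, function(itd) {
      tone_pair_matrix(bf, 0, itd, half, fs, phases)
    }))
    ity <- rowsum(unit_response(g, j, St), rep(seq_along(itds_s), each = n_phase)) / n_phase
    out[[j]] <- list(bf_hz = bf,
                     freq_curve = norm_curve(freqs_hz, fy),
                     ild_curve = norm_curve(ilds_db, drop(ily)),
                     itd_curve = norm_curve(itds_s, drop(ity)))
  }
  out
}

#' Classify a tuning curve
#'
#' Labels a max-normalized response curve as `"monotonic"` (Spearman
#' |rho| at least `rho_min`), `"peaked"` (a single interior local
#' maximum with prominence at least `prominence_min`), `"cyclic"` (the
#' dominant nonzero Fourier component explains at least `cyclic_var` of
#' the variance, with at least one full period in range) or `"flat"`.
#' Monotonicity is tested first, then peakedness, then cyclicity, so a
#' single bump is peaked rather than cyclic.
#'
#' @param x Stimulus axis (strictly increasing).
#' @param y Responses.
#' @param rho_min,prominence_min,cyclic_var Classification thresholds.
#' @return One of `"monotonic"`, `"peaked"`, `"cyclic"`, `"flat"`.
#' @export
classify_tuning_curve <- function(x, y, rho_min = 0.9,
                                  prominence_min = 0.3, cyclic_var = 0.5) {
  if (length(x) < 10L || length(x) != length(y)) {
    stop_invalid("need at least 10 (x, y) points")
  }
  if (any(diff(x) <= 0)) stop_invalid("stimulus axis must be strictly increasing")
  m <- max(y)
  if (m <= 0 || stats::sd(y) < 1e-9 * max(abs(y), 1)) return("flat")
  y <- y / m
  if (diff(range(y)) < 0.05) return("flat")
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (!is.na(rho) && abs(rho) >= rho_min) return("monotonic")
  n <- length(y)
  interior <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(interior) == 1L) {
    ipk <- interior
    prom <- y[ipk] - max(min(y[1:ipk]), min(y[ipk:n]))
    if (prom >= prominence_min) return("peaked")
  }
  z <- y - mean(y)
  sp <- Mod(stats::fft(z))^2
  half_idx <- 2:(floor(n / 2) + 1L)
  k <- which.max(sp[half_idx])            # k full periods in range
  ## variance explained by component k (and its conjugate):
  ## 2|c_k|^2 / n^2 out of var(z) = sum(z^2) / n
  frac <- 2 * sp[half_idx][k] / (n * sum(z^2))
  if (frac >= cyclic_var && k >= 1L) return("cyclic")
  "flat"
}
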