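## Sonar call synthesis, synthetic head-related transfer functions,
## binaural echo rendering with joint normalization, and the cochlear
## front-end variant.

#' Synthesize a sonar call
#'
#' A linear downward frequency-modulated sweep (70 to 15 kHz by default)
#' sampled at 500 kHz.  When `duration_ms` is not given it is drawn from a
#' gamma distribution with shape 8.0 and scale 0.3 ms (mean 2.4 ms, sd
#' 0.85 ms), matching big brown bat calls during target approach.
#'
#' @param duration_ms Call duration in ms, or `NULL` to sample one.
#' @param fs Sampling rate in Hz.
#' @param f_start,f_end Sweep start and end frequencies in Hz.
#' @param seed Optional seed for the sampled duration.
#' @return A `call_signal` list with `waveform`, `fs`, `duration_ms`,
#'   `f_start`, `f_end`.
#' @examples
#' length(synthesize_call(2)$waveform)  # 1000 samples at 500 kHz
#' @export
synthesize_call <- function(duration_ms = NULL, fs = 5e5,
                            f_start = 70e3, f_end = 15e3, seed = NULL) {
  if (is.null(duration_ms)) {
    duration_ms <- with_seed_if(seed, stats::rgamma(1, shape = 8.0, scale = 0.3))
  }
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    stop_invalid("call duration must be positive")
  }
  n <- round(duration_ms * 1e-3 * fs)
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  ## linear chirp: instantaneous frequency f_start + (f_end - f_start) t / T
  phase <- 2 * pi * (f_start * t + (f_end - f_start) / (2 * dur) * t^2)
  structure(list(waveform = sin(phase), fs = fs, duration_ms = duration_ms,
                 f_start = f_start, f_end = f_end),
            class = "call_signal")
}

#' Sample call durations
#'
#' @param n Number of durations.
#' @param seed Optional seed.
#' @return Durations in ms from the gamma(8.0, scale 0.3) call-duration
#'   distribution.
#' @export
sample_call_durations <- function(n, seed = NULL) {
  with_seed_if(seed, stats::rgamma(n, shape = 8.0, scale = 0.3))
}

## ---- synthetic HRTF -----------------------------------------------------

#' Synthetic head-related transfer function set
#'
#' A spherical-head stand-in for measured bat HRTFs, sampled on a
#' (horizontal angle, elevation) grid of the frontal hemisphere:
#' \itemize{
#'   \item ITD from the Woodworth formula `a (alpha + sin alpha) / c`
#'     (the horizontal angle is exactly the cone-of-confusion coordinate),
#'     applied as opposite-signed fractional delays at the two ears;
#'   \item ILD from a first-order head-shadow shelf whose high-frequency
#'     gain rises on the ipsilateral and falls on the contralateral side,
#'     applied as a zero-phase magnitude response so the interaural delay
#'     is exactly the Woodworth value;
#'   \item an optional elevation-dependent spectral notch (on by default)
#'     whose center sweeps 35 to 65 kHz as elevation goes from -40 to 40
#'     deg, giving a monaural elevation cue as in measured HRTFs.
#' }
#' The set is symmetric about the median plane: at horizontal angle zero
#' both ears receive identical impulse responses.
#'
#' @param alpha_grid,phi_grid Horizontal-angle and elevation grids, deg.
#' @param fs Sampling rate, Hz.
#' @param n_taps Impulse-response length, samples.
#' @param head_radius Effective head radius, m (bat scale; the default
#'   7 mm spans ITDs of about +/-52 us).
#' @param c_sound Speed of sound, m/s.
#' @param shadow_strength High-frequency shadow asymmetry in (0, 1).
#' @param notch Logical; include the elevation notch.
#' @param notch_depth_db,notch_width_hz Notch depth (dB) and Gaussian
#'   width (Hz).
#' @return An `hrtf_set` object.
#' @export
synthetic_hrtf <- function(alpha_grid = seq(-80, 80, by = 10),
                           phi_grid = seq(-80, 80, by = 10),
                           fs = 5e5, n_taps = 128L,
                           head_radius = 0.007, c_sound = 343,
                           shadow_strength = 0.8,
                           notch = TRUE, notch_depth_db = 15,
                           notch_width_hz = 5e3) {
  if (head_radius <= 0) stop_invalid("invalid config: head radius must be positive")
  if (shadow_strength <= 0 || shadow_strength >= 1) {
    stop_invalid("invalid config: shadow_strength must be in (0, 1)")
  }
  nf <- n_taps %/% 2L + 1L
  freq <- (seq_len(nf) - 1) * fs / n_taps
  na <- length(alpha_grid); np <- length(phi_grid)
  base_delay <- (n_taps / 4) / fs

  mag <- array(0, c(na, np, nf, 2L))
  phase <- array(0, c(na, np, nf, 2L))
  f_corner <- c_sound / (2 * pi * head_radius)
  for (ia in seq_len(na)) {
    al <- deg2rad(alpha_grid[ia])
    itd <- head_radius * (al + sin(al)) / c_sound  # >0: source right, right ear leads
    delay <- c(left = base_delay + itd / 2, right = base_delay - itd / 2)
    x <- sin(al)  # lateral displacement, +1 = far right
    for (ear in 1:2) {
      xe <- if (ear == 1L) -x else x  # + towards this ear
      ac <- 1 + shadow_strength * xe
      gain <- sqrt((1 + (ac * freq / f_corner)^2) / (1 + (freq / f_corner)^2))
      for (ip in seq_len(np)) {
        g <- gain
        if (notch) {
          ph <- phi_grid[ip]
          fc_n <- 50e3 + 15e3 * pmax(-1, pmin(1, ph / 40))
          dip <- notch_depth_db * exp(-(freq - fc_n)^2 / (2 * notch_width_hz^2))
          g <- g * 10^(-dip / 20)
        }
        mag[ia, ip, , ear] <- g
        phase[ia, ip, , ear] <- -2 * pi * freq * delay[ear]
      }
    }
  }
  structure(list(alpha = alpha_grid, phi = phi_grid, fs = fs,
                 n_taps = as.integer(n_taps), freq = freq,
                 mag = mag, phase = phase,
                 head_radius = head_radius, c_sound = c_sound,
                 provenance = "synthetic"),
            class = "hrtf_set")
}

#' @export
print.hrtf_set <- function(x, ...) {
  cat(sprintf("HRTF set (%s): %d x %d directions, %d taps at %g kHz\n",
              x$provenance, length(x$alpha), length(x$phi), x$n_taps,
              x$fs / 1e3))
  invisible(x)
}

#' Woodworth interaural time difference of an HRTF set
#'
#' @param hrtf An `hrtf_set`.
#' @param alpha Horizontal angle, deg.
#' @return ITD in seconds (positive: right ear leads).
#' @export
hrtf_itd <- function(hrtf, alpha) {
  al <- deg2rad(alpha)
  hrtf$head_radius * (al + sin(al)) / hrtf$c_sound
}

## Real inverse FFT of a half-spectrum (length n/2+1) to n real samples.
irfft <- function(half, n) {
  full <- c(half, Conj(half[(n %/% 2L):2L]))
  Re(stats::fft(full, inverse = TRUE)) / n
}

bilinear_weights <- function(grid, v) {
  if (v < min(grid) - 1e-9 || v > max(grid) + 1e-9) {
    stop_invalid("out of range: direction outside the HRTF grid hull")
  }
  v <- min(max(v, min(grid)), max(grid))
  i <- findInterval(v, grid, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(grid) - 1L)
  w <- (v - grid[i]) / (grid[i + 1L] - grid[i])
  list(i = i, w = w)
}

#' Interpolate an HRTF at an arbitrary direction
#'
#' Bilinear interpolation on the (horizontal angle, elevation) grid of the
#' per-ear magnitude and (unwrapped) phase responses; exact at grid nodes.
#'
#' @param hrtf An `hrtf_set`.
#' @param alpha,phi Direction, deg.
#' @return List with `left` and `right` impulse responses (`n_taps`
#'   samples) and the interpolated `mag`/`phase` half-spectra.
#' @export
interpolate_hrtf <- function(hrtf, alpha, phi) {
  wa <- bilinear_weights(hrtf$alpha, alpha)
  wp <- bilinear_weights(hrtf$phi, phi)
  ia <- wa$i; ip <- wp$i
  w <- c((1 - wa$w) * (1 - wp$w), wa$w * (1 - wp$w),
         (1 - wa$w) * wp$w, wa$w * wp$w)
  idx <- cbind(c(ia, ia + 1L, ia, ia + 1L), c(ip, ip, ip + 1L, ip + 1L))
  nf <- length(hrtf$freq)
  mag <- matrix(0, nf, 2); phase <- matrix(0, nf, 2)
  for (k in 1:4) {
    if (w[k] == 0) next
    mag <- mag + w[k] * hrtf$mag[idx[k, 1], idx[k, 2], , ]
    phase <- phase + w[k] * hrtf$phase[idx[k, 1], idx[k, 2], , ]
  }
  spec <- mag * exp(1i * phase)
  list(left = irfft(spec[, 1], hrtf$n_taps),
       right = irfft(spec[, 2], hrtf$n_taps),
       mag = mag, phase = phase, freq = hrtf$freq)
}

## FFT convolution of a call with one impulse response.
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                     stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Render a binaural echo
#'
#' Filters the call through the left and right interpolated HRTFs for the
#' target direction, then normalizes the two channels jointly so the RMS
#' of the concatenated stereo signal is 1.  Joint normalization discards
#' overall magnitude (the target sits at a fixed nominal distance and no
#' propagation delay or attenuation is modelled) but preserves the
#' left/right level ratio exactly.
#'
#' @param call A `call_signal`.
#' @param hrtf An `hrtf_set`.
#' @param alpha,phi Target direction in head coordinates, deg.
#' @return A `binaural_echo` list with `left`, `right`, `fs`,
#'   `norm_const` and the rendering direction.
#' @export
render_echo <- function(call, hrtf, alpha, phi) {
  stopifnot(inherits(call, "call_signal"), inherits(hrtf, "hrtf_set"))
  ir <- interpolate_hrtf(hrtf, alpha, phi)
  l <- fft_convolve(call$waveform, ir$left)
  r <- fft_convolve(call$waveform, ir$right)
  g <- sqrt(mean(c(l, r)^2))
  if (g < 1e-30) stop_invalid("degenerate echo: zero energy")
  structure(list(left = l / g, right = r / g, fs = call$fs,
                 norm_const = g, alpha = alpha, phi = phi),
            class = "binaural_echo")
}

#' Measure ITD and ILD from a rendered echo
#'
#' ITD by cross-correlation with parabolic sub-sample interpolation of the
#' peak (positive: right ear leads); ILD as the RMS level difference in dB
#' (positive: right ear louder).
#'
#' @param echo A `binaural_echo`.
#' @param max_lag_s Largest |ITD| searched, seconds.
#' @return List with `itd` (s) and `ild` (dB).
#' @export
measure_echo_cues <- function(echo, max_lag_s = 100e-6) {
  stopifnot(inherits(echo, "binaural_echo"))
  ml <- round(max_lag_s * echo$fs)
  cc <- stats::ccf(echo$left, echo$right, lag.max = ml, plot = FALSE,
                   type = "covariance")
  v <- as.numeric(cc$acf); lag <- as.numeric(cc$lag)
  i <- which.max(v)
  d <- lag[i]
  if (i > 1 && i < length(v)) {
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (denom < 0) d <- d + 0.5 * (v[i - 1] - v[i + 1]) / denom
  }
  ## left lags right by d samples when the peak sits at positive lag of
  ## ccf(left, right); that means the right ear led.
  list(itd = d / echo$fs,
       ild = 20 * log10(sqrt(mean(echo$right^2)) / sqrt(mean(echo$left^2))))
}

## ---- cochlear front end -------------------------------------------------

#' Cochlear front-end transform
#'
#' Per ear: an 81-channel bandpass filterbank spanning 20-100 kHz
#' (Gaussian bands of the call spectrum, one per 1-kHz-spaced center
#' frequency), half-wave rectification and a 1-kHz low-pass (a cascade of
#' two first-order smoothers, which cannot overshoot, so features stay
#' non-negative).  Envelopes are cut into 100-us windows with a 10-us
#' stride and downsampled by 10, and the two ears are concatenated,
#' giving 2 ears x 81 channels x 5 samples = 810 dimensions per window.
#'
#' @param echo A `binaural_echo` at 500 kHz.
#' @param n_channels Number of bandpass channels.
#' @param f_lo,f_hi Filterbank range, Hz.
#' @param band_sd Gaussian band standard deviation, Hz.
#' @param lp_cutoff Envelope low-pass cutoff, Hz.
#' @param window_s,stride_s Window length and stride, seconds.
#' @param downsample Temporal downsampling factor within a window.
#' @return Matrix of per-window features (rows: windows; 810 columns,
#'   ordered left ear then right, channel-major).  Zero rows arise from
#'   silent input; an echo shorter than one window yields a zero-row
#'   matrix with a warning.
#' @export
cochlear_features <- function(echo, n_channels = 81L, f_lo = 20e3,
                              f_hi = 100e3, band_sd = 1.5e3,
                              lp_cutoff = 1e3, window_s = 100e-6,
                              stride_s = 10e-6, downsample = 10L) {
  stopifnot(inherits(echo, "binaural_echo"))
  fs <- echo$fs
  centers <- seq(f_lo, f_hi, length.out = n_channels)
  n <- length(echo$left)
  win <- round(window_s * fs); stride <- round(stride_s * fs)
  keep <- seq(1L, win, by = downsample)
  dim_out <- 2L * n_channels * length(keep)
  if (n < win) {
    warning("echo shorter than one cochlear window; returning empty features")
    return(matrix(numeric(0), 0L, dim_out))
  }
  nfft <- stats::nextn(n, 2)
  fax <- (0:(nfft - 1)) * fs / nfft
  fax <- pmin(fax, fs - fax)  # two-sided frequency axis
  ## one-pole coefficient of the envelope smoother
  a_lp <- exp(-2 * pi * lp_cutoff / fs)
  env_one <- function(x) {
    X <- stats::fft(c(x, numeric(nfft - n)))
    sapply(seq_len(n_channels), function(ch) {
      band <- exp(-(fax - centers[ch])^2 / (2 * band_sd^2))
      y <- Re(stats::fft(X * band, inverse = TRUE))[seq_len(n)] / nfft
      y <- pmax(y, 0)
      y <- as.numeric(stats::filter(y * (1 - a_lp), a_lp, method = "recursive"))
      as.numeric(stats::filter(y * (1 - a_lp), a_lp, method = "recursive"))
    })
  }
  env <- list(env_one(echo$left), env_one(echo$right))  # n x n_channels each
  starts <- seq(1L, n - win + 1L, by = stride)
  feats <- vapply(starts, function(s0) {
    idx <- s0 + keep - 1L
    c(env[[1]][idx, ], env[[2]][idx, ])
  }, numeric(dim_out))
  t(feats)
}
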