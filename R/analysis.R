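## Post-hoc analysis battery: step-response fitting, steady-state error,
## distribution comparison and group statistics.

#' Fit an exponential step response to a trajectory
#'
#' Fits `s(t) = A * exp(-t / tau) + B` by least squares.  For a fixed
#' `tau` the problem is linear in `(A, B)`, so the fit profiles the
#' residual over `tau` (log-spaced multi-start grid plus golden-section
#' refinement); the time constant `tau` measures the number of iterations
#' needed to cut the initial error by 63%.
#'
#' @param s Angle sequence over iterations, degrees.
#' @param t Time axis (defaults to `1..length(s)`), iterations.
#' @param tau_range Search range for `tau`, iterations.
#' @return A `step_fit` list with `A`, `B`, `tau`, `residual` (RSS) and
#'   `at_bound` (`TRUE` when `tau` hit the search bound).
#' @export
fit_step_response <- function(s, t = seq_along(s),
                              tau_range = c(0.05, 200)) {
  s <- as.numeric(s); t <- as.numeric(t)
  if (length(s) < 5L) stop_invalid("need at least 5 trajectory points")
  if (stats::sd(s) == 0) stop_invalid("ill-posed: constant trajectory")
  rss_tau <- function(tau) {
    X <- cbind(exp(-t / tau), 1)
    fit <- stats::lm.fit(X, s)
    sum(fit$residuals^2)
  }
  grid <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = 80))
  rss <- vapply(grid, rss_tau, 0)
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(lt) rss_tau(exp(lt)), c(log(lo), log(hi)),
                         tol = 1e-12)
  tau <- exp(opt$minimum)
  X <- cbind(exp(-t / tau), 1)
  cf <- stats::lm.fit(X, s)$coefficients
  structure(list(A = unname(cf[1]), B = unname(cf[2]), tau = tau,
                 residual = rss_tau(tau),
                 at_bound = tau <= tau_range[1] * 1.01 ||
                   tau >= tau_range[2] * 0.99),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("step fit: A = %.4f deg, B = %.4f deg, tau = %.4f iterations (RSS %.3g)%s\n",
              x$A, x$B, x$tau, x$residual,
              if (x$at_bound) " [tau at search bound]" else ""))
  invisible(x)
}

#' Steady-state mean squared localization error
#'
#' The mean over trials of `theta^2 + phi^2` at the final iteration of
#' each trace, optionally normalized by a reference value (the
#' zero-roll condition in the reference analysis).
#'
#' @param traces A data frame from [evaluate_grid()] (columns `trial`,
#'   `iter`, `alpha`, `elevation`), or a matrix/data frame with one row
#'   per trial holding final `alpha` and `elevation`.
#' @param final_iter Final iteration `T` (default: the maximum present;
#'   trials not reaching it are an error).
#' @param reference Optional reference MSE for normalization.
#' @return List with `mse`, `n` and (when `reference` is given)
#'   `normalized`.
#' @export
steady_state_mse <- function(traces, final_iter = NULL, reference = NULL) {
  if (is.data.frame(traces) && !is.null(traces$iter)) {
    if (is.null(final_iter)) final_iter <- max(traces$iter)
    fin <- traces[traces$iter == final_iter, , drop = FALSE]
    trials <- unique(traces$trial %||% 1L)
    if (nrow(fin) != length(trials)) {
      stop_invalid("traces of mixed length: not every trial reaches iteration ",
                   final_iter)
    }
    e2 <- fin$alpha^2 + fin$elevation^2
  } else {
    m <- as.matrix(traces)
    e2 <- m[, 1]^2 + m[, 2]^2
  }
  out <- list(mse = mean(e2), n = length(e2))
  if (!is.null(reference)) out$normalized <- out$mse / reference
  out
}

#' Kullback-Leibler divergence and Bhattacharyya coefficient
#'
#' For two histograms over identical bins: `KL = sum(p * log(p / q))`
#' (with additive smoothing of `q` where needed) and
#' `BC = sum(sqrt(p * q))`.
#'
#' @param p,q Nonnegative histogram weights over identical bins
#'   (normalized internally).
#' @param smooth Additive smoothing applied to `q` in bins where `p > 0`
#'   but `q = 0`.
#' @return List with `kl` and `bc`.
#' @export
compare_distributions <- function(p, q, smooth = 1e-6) {
  if (length(p) != length(q)) stop_invalid("mismatched histogram binning")
  if (any(p < 0) || any(q < 0)) stop_invalid("negative histogram weights")
  p <- p / sum(p)
  if (any(q[p > 0] == 0)) q <- q + smooth
  q <- q / sum(q)
  pos <- p > 0
  list(kl = sum(p[pos] * log(p[pos] / q[pos])),
       bc = sum(sqrt(p * q)))
}

#' One-way ANOVA and pairwise Cohen's d across groups
#'
#' Standard between/within sums of squares; Cohen's d uses the pooled
#' standard deviation of each pair.
#'
#' @param groups Named list of numeric vectors.
#' @return List with `F`, `df` (between, within), `p` and a data frame
#'   `cohens_d` of pairwise effect sizes.
#' @export
effect_stats <- function(groups) {
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L)) {
    stop_invalid("need at least two groups with at least two values each")
  }
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssw == 0) stop_invalid("undefined F: zero within-group variance")
  df1 <- k - 1L; df2 <- N - k
  Fv <- (ssb / df1) / (ssw / df2)
  nm <- names(groups) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  d <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    sp <- sqrt(((n[i] - 1) * stats::var(groups[[i]]) +
                (n[j] - 1) * stats::var(groups[[j]])) / (n[i] + n[j] - 2))
    (means[i] - means[j]) / sp
  })
  list(F = Fv, df = c(df1, df2), p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       cohens_d = data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                             d = d))
}
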