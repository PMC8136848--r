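## Windowing of binaural echoes and the GASSOM subspace coder.
##
## Each GASSOM unit is a two-dimensional subspace spanned by two
## orthonormal basis vectors; the unit response to a window x is the
## squared projection length ||Phi' x||^2 and the reconstruction error is
## ||x||^2 minus the response.  Units sit on a square grid and learn with
## SOM-style neighborhood cooperation; window-to-unit assignment is soft,
## with a sticky first-order Markov prior across consecutive windows
## implementing the temporal-smoothness constraint of the generative
## model.

#' Extract acoustic windows from a binaural echo
#'
#' The left and right waveforms are cut into fine (50-sample) and coarse
#' (100-sample) windows with a 5-sample stride; coarse windows are
#' downsampled by 2 before encoding.  Six streams result: for each scale,
#' a binaural stream (concatenation of the left and right windows, 100
#' dimensions) and two monaural streams (50 dimensions).  Windows are
#' normalized to unit norm (scale-free encoding); zero-norm windows are
#' dropped.
#'
#' @param echo A `binaural_echo`.
#' @param fine,coarse Window lengths in samples.
#' @param stride Stride in samples.
#' @return Named list of six matrices (rows = windows):
#'   `fine_binaural`, `fine_left`, `fine_right`, `coarse_binaural`,
#'   `coarse_left`, `coarse_right`.  Empty (0-row) matrices with a warning
#'   if the echo is shorter than the coarse window.
#' @export
extract_windows <- function(echo, fine = 50L, coarse = 100L, stride = 5L) {
  stopifnot(inherits(echo, "binaural_echo"))
  l <- echo$left; r <- echo$right
  n <- length(l)
  slide <- function(x, width) {
    starts <- seq.int(1L, n - width + 1L, by = stride)
    matrix(x[outer(starts, 0:(width - 1L), `+`)], length(starts), width)
  }
  out <- list()
  if (n < coarse) {
    warning("echo shorter than one coarse window; returning empty window streams")
    for (nm in c("fine_binaural", "fine_left", "fine_right",
                 "coarse_binaural", "coarse_left", "coarse_right")) {
      out[[nm]] <- matrix(numeric(0), 0L, if (grepl("binaural", nm)) 2L * fine else fine)
    }
    return(out)
  }
  lf <- slide(l, fine); rf <- slide(r, fine)
  keep <- seq.int(1L, coarse, by = 2L)
  lc <- slide(l, coarse)[, keep, drop = FALSE]
  rc <- slide(r, coarse)[, keep, drop = FALSE]
  unitize <- function(X) {
    nr <- sqrt(rowSums(X^2))
    ok <- nr > 1e-12
    X[ok, , drop = FALSE] / nr[ok]
  }
  list(fine_binaural = unitize(cbind(lf, rf)),
       fine_left = unitize(lf),
       fine_right = unitize(rf),
       coarse_binaural = unitize(cbind(lc, rc)),
       coarse_left = unitize(lc),
       coarse_right = unitize(rc))
}

#' Create a GASSOM dictionary
#'
#' @param input_dim Window dimension (100 binaural, 50 monaural).
#' @param n_units Number of subspace units (a full model uses 400 on a
#'   20x20 grid; the reduced profile uses 64 on 8x8).
#' @param grid Grid rows/columns; must multiply to `n_units`.
#' @param seed Optional seed for the random orthonormal initialization.
#' @param anneal_T Number of window presentations over which the learning
#'   rate, neighborhood radius and assignment temperature anneal.
#' @param eta,radius,sigma_n Two-element vectors (start, end) of the
#'   annealed learning rate, Gaussian neighborhood radius (grid units) and
#'   assignment noise scale.
#' @param stay Markov stay probability of the sticky assignment prior.
#' @return A `gassom` object.
#' @export
gassom_new <- function(input_dim, n_units = 400L,
                       grid = c(floor(sqrt(n_units)), floor(sqrt(n_units))),
                       seed = NULL, anneal_T = 5e5,
                       eta = c(5e-2, 2e-3), radius = c(3, 0.5),
                       sigma_n = c(0.5, 0.15), stay = 0.9) {
  if (prod(grid) != n_units) stop_invalid("grid dims must multiply to n_units")
  Phi <- with_seed_if(seed, {
    m <- matrix(stats::rnorm(input_dim * 2L * n_units), input_dim)
    m
  })
  g <- structure(
    list(d = as.integer(input_dim), J = as.integer(n_units),
         grid = as.integer(grid),
         coords = cbind(rep(seq_len(grid[1]), grid[2]),
                        rep(seq_len(grid[2]), each = grid[1])),
         Phi = Phi, t = 0,
         pars = list(eta = eta, radius = radius, sigma_n = sigma_n,
                     stay = stay, anneal_T = anneal_T)),
    class = "gassom")
  g$Phi <- orthonormalize_bases(g$Phi)
  ## squared grid distances for the neighborhood kernel
  g$dist2 <- as.matrix(stats::dist(g$coords))^2
  g
}

#' @export
print.gassom <- function(x, ...) {
  cat(sprintf("GASSOM: %d units (%dx%d grid), input dim %d, %g windows seen\n",
              x$J, x$grid[1], x$grid[2], x$d, x$t))
  invisible(x)
}

## Gram-Schmidt on every unit's two columns (odd = first basis vector).
orthonormalize_bases <- function(Phi) {
  J2 <- ncol(Phi)
  odd <- seq.int(1L, J2, by = 2L); even <- odd + 1L
  u <- Phi[, odd, drop = FALSE]; v <- Phi[, even, drop = FALSE]
  nu <- sqrt(colSums(u^2))
  nu[nu < 1e-12] <- 1
  u <- sweep(u, 2, nu, `/`)
  v <- v - sweep(u, 2, colSums(u * v), `*`)
  nv <- sqrt(colSums(v^2))
  bad <- nv < 1e-9
  if (any(bad)) {
    ## degenerate second direction: re-draw orthogonal completion
    v[, bad] <- stats::rnorm(nrow(Phi) * sum(bad))
    v[, bad] <- v[, bad, drop = FALSE] -
      sweep(u[, bad, drop = FALSE], 2,
            colSums(u[, bad, drop = FALSE] * v[, bad, drop = FALSE]), `*`)
    nv <- sqrt(colSums(v^2))
  }
  v <- sweep(v, 2, nv, `/`)
  Phi[, odd] <- u; Phi[, even] <- v
  Phi
}

gassom_anneal <- function(g) {
  f <- min(1, g$t / g$pars$anneal_T)
  geom <- function(p) p[1] * (p[2] / p[1])^f
  list(eta = geom(g$pars$eta), radius = geom(g$pars$radius),
       sigma_n = geom(g$pars$sigma_n))
}

#' Encode windows with a GASSOM
#'
#' Responses are squared projection lengths onto each unit's subspace;
#' reconstruction errors are the squared residuals (response + error =
#' `||x||^2` for every unit).  The soft assignment is the filtering
#' posterior of a hidden Markov chain over units with sticky transitions
#' (stay probability `stay`, otherwise uniform) and Gaussian emission
#' `exp(-E / (2 sigma_n^2))`.
#'
#' @param g A `gassom`.
#' @param X Window matrix (rows = consecutive windows) or a single window.
#' @param smooth Use the sticky Markov prior (otherwise independent
#'   softmax assignment).
#' @return List with `responses`, `errors` (n x J), `posterior` (n x J),
#'   `winners` (max-posterior unit per window) and `expected_error`
#'   (posterior-weighted reconstruction error per window).
#' @export
gassom_encode <- function(g, X, smooth = TRUE) {
  stopifnot(inherits(g, "gassom"))
  if (is.null(dim(X))) X <- matrix(X, 1L)
  if (ncol(X) != g$d) stop_invalid("window dimension ", ncol(X),
                                   " does not match dictionary dim ", g$d)
  n <- nrow(X)
  if (n == 0L) stop_invalid("no windows to encode")
  sn <- gassom_anneal(g)$sigma_n
  out <- .gassom_encode_core(X, g$Phi, sn, g$pars$stay, isTRUE(smooth))
  out$expected_error <- drop(out$expected_error)
  out$winners <- max.col(out$posterior, ties.method = "first")
  out
}

#' One learning step of a GASSOM on a batch of windows
#'
#' Each unit's basis moves towards the windows assigned to it (soft
#' assignment spread over the grid by a Gaussian neighborhood), then is
#' re-orthonormalized.  The step per unit is the neighborhood-weighted
#' mean of the response gradient `x (x' Phi)`, scaled by the annealed
#' learning rate.
#'
#' @param g A `gassom`.
#' @param X Window matrix (consecutive windows of one echo).
#' @param enc Optional precomputed [gassom_encode()] result for `X`.
#' @param eta Optional learning-rate override (0 leaves `g` unchanged).
#' @return The updated `gassom`.
#' @export
gassom_update <- function(g, X, enc = NULL, eta = NULL) {
  stopifnot(inherits(g, "gassom"))
  if (is.null(dim(X))) X <- matrix(X, 1L)
  if (nrow(X) == 0L) return(g)
  if (is.null(enc)) enc <- gassom_encode(g, X)
  ann <- gassom_anneal(g)
  if (is.null(eta)) eta <- ann$eta
  if (eta < 0) stop_invalid("learning rate must be >= 0")
  if (eta > 0) {
    H <- exp(-g$dist2 / (2 * ann$radius^2))
    Phi <- .gassom_update_core(X, enc$proj, enc$posterior, H, g$Phi, eta)
    if (!all(is.finite(Phi))) {
      stop("training failure: non-finite GASSOM update (t=", g$t, ")")
    }
    g$Phi <- Phi
  }
  g$t <- g$t + nrow(X)
  g
}

#' Pool GASSOM responses over time into the state feature vector
#'
#' Average pooling of the per-window response vectors of each GASSOM,
#' concatenated across the six (scale, channel) streams.
#'
#' @param encodings List of [gassom_encode()] results, one per stream.
#' @return Numeric feature vector of length `6 * n_units` (2400 for the
#'   full 400-unit model); entries lie in \code{[0, 1]} for unit-norm
#'   windows.
#' @export
pool_features <- function(encodings) {
  if (length(encodings) == 0L) stop_invalid("no encodings to pool")
  parts <- lapply(encodings, function(e) {
    if (is.null(e$responses) || nrow(e$responses) == 0L) {
      stop_invalid("empty stream: cannot pool features")
    }
    colMeans(e$responses)
  })
  unlist(parts, use.names = FALSE)
}

#' Encode one echo with a bank of six GASSOMs
#'
#' @param gassoms Named list of six `gassom` objects (names as in
#'   [extract_windows()]).
#' @param echo A `binaural_echo`.
#' @param smooth Passed to [gassom_encode()].
#' @return List with per-stream `encodings`, the pooled `features` and
#'   the window streams.
#' @export
encode_echo <- function(gassoms, echo, smooth = TRUE) {
  win <- extract_windows(echo)
  enc <- lapply(names(gassoms), function(nm) {
    gassom_encode(gassoms[[nm]], win[[nm]], smooth = smooth)
  })
  names(enc) <- names(gassoms)
  list(encodings = enc, features = pool_features(enc), windows = win)
}
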