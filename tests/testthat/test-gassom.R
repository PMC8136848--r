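make_echo <- function(n = 1000, seed = 1) {
  set.seed(seed)
  structure(list(left = rnorm(n), right = rnorm(n), fs = 5e5),
            class = "binaural_echo")
}

test_that("window extraction yields the six unit-norm streams", {
  w <- extract_windows(make_echo(1000))
  expect_equal(nrow(w$fine_binaural), 191L)  # (1000 - 50) / 5 + 1
  expect_equal(ncol(w$fine_binaural), 100L)
  expect_equal(ncol(w$coarse_binaural), 100L)
  expect_equal(ncol(w$fine_left), 50L)
  expect_equal(ncol(w$coarse_right), 50L)
  for (s in w) expect_equal(sqrt(rowSums(s^2)), rep(1, nrow(s)), tolerance = 1e-12)
  ## binaural windows are [left; right] concatenations
  e <- make_echo(300)
  w <- extract_windows(e)
  raw <- c(e$left[1:50], e$right[1:50])
  expect_equal(w$fine_binaural[1, ], raw / sqrt(sum(raw^2)), tolerance = 1e-12)
  ## coarse windows are decimated by 2
  raw_c <- c(e$left[seq(1, 100, 2)], e$right[seq(1, 100, 2)])
  expect_equal(w$coarse_binaural[1, ], raw_c / sqrt(sum(raw_c^2)), tolerance = 1e-12)
  ## zero echo: all windows dropped
  silent <- structure(list(left = numeric(500), right = numeric(500), fs = 5e5),
                      class = "binaural_echo")
  expect_equal(nrow(extract_windows(silent)$fine_binaural), 0L)
  short <- structure(list(left = numeric(60), right = numeric(60), fs = 5e5),
                     class = "binaural_echo")
  expect_warning(w <- extract_windows(short), "short")
  expect_equal(nrow(w$coarse_binaural), 0L)
})

test_that("encoding satisfies the projection identities", {
  w <- extract_windows(make_echo(1000, 2))$fine_binaural
  g <- gassom_new(100, 64, seed = 3)
  en <- gassom_encode(g, w)
  ## Pythagoras: response + error = ||x||^2 = 1 for every unit and window
  expect_lt(max(abs(en$responses + en$errors - 1)), 1e-9)
  expect_true(all(en$responses >= 0 & en$responses <= 1 + 1e-12))
  ## responses equal brute-force projection-matrix evaluation
  set.seed(4)
  for (k in 1:100) {
    i <- sample(nrow(w), 1); j <- sample(g$J, 1)
    Phi_j <- g$Phi[, (2 * j - 1):(2 * j)]
    brute <- sum(((Phi_j %*% t(Phi_j)) %*% w[i, ])^2)
    expect_lt(abs(brute - en$responses[i, j]), 1e-10)
  }
  ## a window inside a unit's subspace: zero error, unit response
  x <- g$Phi[, 11] * 0.6 + g$Phi[, 12] * 0.8
  en1 <- gassom_encode(g, x)
  expect_lt(en1$errors[1, 6], 1e-9)
  expect_equal(en1$responses[1, 6], 1, tolerance = 1e-9)
  ## an orthogonal window: zero response
  x2 <- rnorm(100)
  B <- g$Phi[, 11:12]
  x2 <- x2 - B %*% crossprod(B, x2)
  x2 <- x2 / sqrt(sum(x2^2))
  en2 <- gassom_encode(g, drop(x2))
  ## only orthogonal to unit 6 by construction
  expect_lt(en2$responses[1, 6], 1e-9)
  expect_error(gassom_encode(g, rnorm(50)), "dimension")
})

test_that("posterior is a sticky-Markov filtering distribution", {
  w <- extract_windows(make_echo(600, 5))$fine_binaural
  g <- gassom_new(100, 16, grid = c(4, 4), seed = 6)
  en <- gassom_encode(g, w)
  expect_equal(rowSums(en$posterior), rep(1, nrow(w)), tolerance = 1e-9)
  ## sticky smoothing increases temporal agreement of winners
  en_iid <- gassom_encode(g, w, smooth = FALSE)
  stickiness <- function(z) mean(diff(z) == 0)
  expect_gte(stickiness(en$winners), stickiness(en_iid$winners))
})

test_that("learning converges onto a planted subspace and stays orthonormal", {
  set.seed(7)
  B <- qr.Q(qr(matrix(rnorm(200), 100, 2)))
  X <- t(B %*% matrix(rnorm(2 * 6000), 2))
  X <- X / sqrt(rowSums(X^2))
  g <- gassom_new(100, 16, grid = c(4, 4), seed = 8)
  g0 <- g
  ## zero learning rate leaves the dictionary unchanged
  expect_equal(gassom_update(g, X[1:50, ], eta = 0)$Phi, g0$Phi)
  for (i in seq(1, 6000, by = 20)) g <- gassom_update(g, X[i:(i + 19), ], eta = 0.05)
  en <- gassom_encode(g, X[1:500, ])
  expect_lt(min(colMeans(en$errors)), 1e-3)
  ## all bases remain orthonormal after the 300 batch updates
  odd <- seq(1, 2 * g$J, 2)
  u <- g$Phi[, odd]; v <- g$Phi[, odd + 1]
  expect_lt(max(abs(colSums(u * v))), 1e-6)
  expect_lt(max(abs(colSums(u^2) - 1)), 1e-6)
  expect_lt(max(abs(colSums(v^2) - 1)), 1e-6)
})

test_that("held-out reconstruction error decreases over training on echoes", {
  h <- synthetic_hrtf()
  cl <- synthesize_call(1.5)
  set.seed(9)
  dirs <- cbind(runif(40, -40, 40), runif(40, -40, 40))
  echoes <- lapply(1:40, function(i) render_echo(cl, h, dirs[i, 1], dirs[i, 2]))
  heldout <- lapply(echoes[31:40], function(e) extract_windows(e)$fine_binaural)
  g <- gassom_new(100, 64, seed = 10, anneal_T = 30 * 220)
  err_at <- function(g) {
    mean(vapply(heldout, function(X) mean(gassom_encode(g, X)$expected_error), 0))
  }
  e0 <- err_at(g)
  for (rep in 1:3) {
    for (i in 1:30) g <- gassom_update(g, extract_windows(echoes[[i]])$fine_binaural)
  }
  expect_lt(err_at(g), e0)
})

test_that("pooling averages responses and concatenates the streams", {
  w <- extract_windows(make_echo(800, 11))
  gs <- list(a = gassom_new(100, 16, grid = c(4, 4), seed = 1),
             b = gassom_new(50, 16, grid = c(4, 4), seed = 2))
  enc <- list(gassom_encode(gs$a, w$fine_binaural),
              gassom_encode(gs$b, w$fine_left))
  f <- pool_features(enc)
  expect_length(f, 32L)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(f[1:16], colMeans(enc[[1]]$responses))
  ## identical responses pool to the per-window vector
  one <- list(list(responses = rbind(c(1, 2), c(1, 2)),
                   expected_error = c(0, 0)))
  expect_equal(pool_features(one), c(1, 2))
  ## linearity
  half <- list(list(responses = rbind(c(1, 2), c(1, 2)) / 2,
                    expected_error = c(0, 0)))
  expect_equal(pool_features(half), c(0.5, 1))
  expect_error(pool_features(list()), "pool")
})
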