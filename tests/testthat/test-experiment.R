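ci_agent <- function(sigma = 10, seed = 1, ...) {
  agent_new(batroll_config("ci", sigma_roll = sigma, ...), seed = seed)
}

test_that("an oracle controller centers the target from iteration 2 onward", {
  ag <- ci_agent(10)
  res <- run_episode(ag, c(30, -20), mode = "oracle", duration_ms = 2, seed = 5)
  tr <- res$trace
  expect_false(res$truncated)
  expect_equal(nrow(tr), 20L)
  expect_lt(max(abs(tr$alpha[-1])), 1e-9)
  expect_lt(max(abs(tr$elevation[-1])), 1e-9)
  ## rolls keep arriving but cannot move a centered target
  expect_gt(stats::sd(tr$roll), 0)
})

test_that("episodes are bit-reproducible under a fixed seed", {
  ag <- ci_agent(20)
  r1 <- run_episode(ag, c(25, 15), mode = "train", seed = 7)
  r2 <- run_episode(ag, c(25, 15), mode = "train", seed = 7)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$agent$gassoms$fine_binaural$Phi,
                   r2$agent$gassoms$fine_binaural$Phi)
  ev1 <- evaluate_grid(r1$agent, alphas = c(-20, 20), phis = c(0), seed = 3)
  ev2 <- evaluate_grid(r1$agent, alphas = c(-20, 20), phis = c(0), seed = 3)
  expect_identical(ev1, ev2)
})

test_that("the zero-roll condition keeps torsion at the Listing value", {
  ag <- ci_agent(0)
  res <- run_episode(ag, c(20, 20), mode = "train", duration_ms = 2, seed = 9)
  tr <- res$trace
  expect_equal(tr$roll, rep(0, nrow(tr)))
  expect_equal(tr$torsion, listing_torsion(tr$head_yaw, tr$head_pitch),
               tolerance = 1e-12)
})

test_that("training improves the reward within a short budget", {
  ag <- ci_agent(10, seed = 3, n_targets = 40L)
  res <- train_agent(ag, seed = 11)
  cur <- res$curve
  expect_equal(nrow(cur), 40L)
  first <- mean(cur$reward[1:8])
  last <- mean(cur$reward[33:40])
  expect_gt(last, first)
  expect_gt(res$agent$train_step, 0L)
})

test_that("checkpoints reload and evaluate identically", {
  ag <- ci_agent(10, seed = 4, n_targets = 10L)
  ag <- train_agent(ag, seed = 12)$agent
  path <- withr::local_tempfile(fileext = ".rds")
  save_agent(ag, path)
  ag2 <- load_agent(path)
  ev1 <- evaluate_grid(ag, alphas = c(-20, 0), phis = c(10), seed = 6)
  ev2 <- evaluate_grid(ag2, alphas = c(-20, 0), phis = c(10), seed = 6)
  expect_identical(ev1, ev2)
})

test_that("untrained agents evaluate with a warning", {
  ag <- ci_agent(0)
  expect_warning(ev <- evaluate_grid(ag, alphas = c(0), phis = c(0),
                                     seed = 2), "untrained")
  expect_true(nrow(ev) >= 1)
})

test_that("the error surface has the right geometry and rotates with roll", {
  ag <- ci_agent(10, seed = 5)
  ## default reference grid is 81 x 81
  cfg_grid <- seq(-80, 80, by = 2)
  expect_length(cfg_grid, 81L)
  alphas <- seq(-40, 40, by = 10)
  es <- error_surface(ag, alphas = alphas, phis = alphas, n_calls = 2,
                      rolls = 0, seed = 3)
  expect_equal(dim(es$surface), c(9L, 9L))
  expect_true(all(is.finite(es$surface)))
  expect_length(es$argmin, 2L)
  ## fixed +/-20 deg rolls probe the same dictionary on rotated directions:
  ## the +20 surface matches the -20 surface rotated by 40 degrees
  ep <- error_surface(ag, alphas = alphas, phis = alphas, n_calls = 2,
                      rolls = 20, seed = 3)
  em <- error_surface(ag, alphas = alphas, phis = alphas, n_calls = 2,
                      rolls = -20, seed = 3)
  rot <- rotate_surface(em, -40)
  keep <- !is.na(rot)
  expect_gt(stats::cor(ep$surface[keep], rot[keep], method = "spearman"), 0.9)
})

test_that("a GASSOM-frozen ablation still improves the reward", {
  ag <- ci_agent(10, seed = 6, n_targets = 40L)
  res <- train_agent(ag, seed = 13, learn_gassom = FALSE)
  expect_identical(res$agent$gassoms$fine_binaural$Phi,
                   ag$gassoms$fine_binaural$Phi)
  expect_gte(mean(tail(res$curve$reward, 10)),
             mean(head(res$curve$reward, 10)) - 0.02)
})

test_that("trained policies place targets nearer the center than untrained", {
  trained <- vapply(1:3, function(s) {
    eval_summary(cached_trained_agent(0, s), seed = s + 900)$mse
  }, 0)
  untrained <- vapply(1:3, function(s) {
    ag <- agent_new(batroll_config("ci", sigma_roll = 0), seed = s)
    suppressWarnings(eval_summary(ag, seed = s + 900)$mse)
  }, 0)
  expect_lt(stats::median(trained), stats::median(untrained))
})
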