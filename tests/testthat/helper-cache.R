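## Trained scaled-down agents are expensive; the closed-loop acceptance
## checks share them through this per-session cache.
.batroll_test_cache <- new.env(parent = emptyenv())

cached_trained_agent <- function(sigma, seed,
                                 n_targets = 150L) {
  key <- sprintf("agent_s%g_seed%d_n%d", sigma, seed, n_targets)
  if (is.null(.batroll_test_cache[[key]])) {
    cfg <- batroll_config("ci", sigma_roll = sigma, n_targets = n_targets)
    agent <- agent_new(cfg, seed = seed)
    .batroll_test_cache[[key]] <- train_agent(agent, seed = seed + 1000)$agent
  }
  .batroll_test_cache[[key]]
}

## Greedy evaluation summarized for the behavioral contrasts.
eval_summary <- function(agent, seed) {
  ev <- suppressWarnings(evaluate_grid(
    agent, alphas = seq(-40, 40, 20), phis = seq(-40, 40, 20),
    durations_ms = 2, seed = seed))
  fin <- ev[ev$iter == max(agent$config$iterations), , drop = FALSE]
  list(traces = ev, final = fin,
       mse = if (nrow(fin)) mean(fin$alpha^2 + fin$elevation^2) else NA_real_)
}

## Median elevation time constant over top/bottom starting directions.
elevation_tau <- function(traces) {
  taus <- c()
  trials <- unique(traces$trial[traces$alpha0 == 0 & abs(traces$phi0) == 40])
  for (tr in trials) {
    y <- traces$elevation[traces$trial == tr]
    if (length(y) < 8L) next
    ft <- tryCatch(fit_step_response(y), error = function(e) NULL)
    if (!is.null(ft) && !ft$at_bound) taus <- c(taus, ft$tau)
  }
  if (length(taus)) stats::median(taus) else NA_real_
}
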