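## The closed-loop simulation: agent state, 20-iteration episodes,
## training schedule, greedy evaluation trajectories and
## reconstruction-error-surface probing.

#' Simulation configuration
#'
#' The `"full"` profile matches the reference conditions (400-unit
#' GASSOMs on 20x20 grids, 500 hidden policy units); the `"ci"` profile
#' is a scaled-down model (64-unit GASSOMs on 8x8 grids, 128 hidden
#' units, a coarser HRTF grid) whose training runs in minutes on one CPU
#' while preserving the qualitative behavior.
#'
#' @param profile `"ci"` or `"full"`.
#' @param sigma_roll Head-roll marginal standard deviation, degrees
#'   (the study conditions use 0, 10, 20, 30).
#' @param ... Named overrides of any config field.
#' @return A `bat_config` list.
#' @export
batroll_config <- function(profile = c("ci", "full"), sigma_roll = 10, ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    sigma_roll = sigma_roll,
    iterations = 20L,            # echoes per target
    target_distance = 1,         # m (nominal; no distance cues are rendered)
    target_region = c(40, 40),   # half-width in horizontal angle, elevation (deg)
    hull = 80,                   # HRTF coverage, deg
    n_units = if (profile == "ci") 64L else 400L,
    som_grid = if (profile == "ci") c(8L, 8L) else c(20L, 20L),
    hidden = if (profile == "ci") 64L else 500L,
    sigma_e = 10, clip = 30, discount = 0.3,
    lr_critic = 0.05, lr_w = 0.2, lr_actor = 0.01,
    lr_decay = 1,                # optional multiplicative decay over training
    n_targets = if (profile == "ci") 250L else 5000L,
    hrtf_step = if (profile == "ci") 20 else 10,
    anneal_T = NULL              # windows; default set from the budget
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (is.null(cfg$anneal_T)) {
    ## the representation anneals over the first third of the planned
    ## window budget, then stays quasi-static while the policy learns
    ## (timescale separation of the two learners)
    cfg$anneal_T <- round(cfg$n_targets * cfg$iterations * 220 / 3)
  }
  class(cfg) <- "bat_config"
  cfg
}

#' Create an untrained echolocating agent
#'
#' Builds the synthetic HRTF set, the six GASSOMs (binaural and monaural,
#' fine and coarse), the policy and critic networks and the calibrated
#' AR(5) roll model.
#'
#' @param config A [batroll_config()].
#' @param seed Seed for all initializations.
#' @return A `bat_agent` object.
#' @export
agent_new <- function(config = batroll_config(), seed = 1) {
  hrtf <- synthetic_hrtf(alpha_grid = seq(-config$hull, config$hull, by = config$hrtf_step),
                         phi_grid = seq(-config$hull, config$hull, by = config$hrtf_step))
  streams <- c("fine_binaural", "fine_left", "fine_right",
               "coarse_binaural", "coarse_left", "coarse_right")
  dims <- c(100L, 50L, 50L, 100L, 50L, 50L)
  gassoms <- Map(function(d, k) {
    gassom_new(d, n_units = config$n_units, grid = config$som_grid,
               seed = seed + k, anneal_T = config$anneal_T)
  }, dims, seq_along(dims))
  names(gassoms) <- streams
  roll_model <- default_roll_model(config$sigma_roll)
  roll_state <- if (config$sigma_roll > 0) {
    sample_roll_sequence(roll_model, roll_model$order, seed = seed + 99)
  } else {
    numeric(roll_model$order)
  }
  structure(list(
    config = config, hrtf = hrtf, gassoms = gassoms,
    policy = policy_new(6L * config$n_units, hidden = config$hidden,
                        sigma_e = config$sigma_e, clip = config$clip,
                        seed = seed + 7),
    critic = critic_new(6L * config$n_units),
    roll_model = roll_model, roll_state = roll_state,
    train_step = 0L, seed = seed
  ), class = "bat_agent")
}

#' @export
print.bat_agent <- function(x, ...) {
  cat(sprintf("bat_agent (%s profile): %d-unit GASSOMs, sigma_roll %g deg, %d training steps\n",
              x$config$profile, x$config$n_units, x$config$sigma_roll,
              x$train_step))
  invisible(x)
}

## Current annealed policy learning rates.
agent_lrs <- function(agent) {
  cfg <- agent$config
  total <- max(1L, cfg$n_targets * cfg$iterations)
  frac <- min(1, agent$train_step / total)
  decay <- cfg$lr_decay^frac
  list(critic = cfg$lr_critic * decay, w = cfg$lr_w * decay,
       actor = cfg$lr_actor * decay)
}

#' Run one 20-iteration localization episode
#'
#' Per iteration: advance the head-roll stream by one echo, compose the
#' head pose (Listing torsion plus the roll sample), transform the target
#' into head coordinates, synthesize a call and render the binaural echo,
#' window and encode it with the six GASSOMs, pool the responses into the
#' feature vector, compute the reward, choose a yaw/pitch command and
#' update the accumulated head rotation.  In `"train"` mode the GASSOMs
#' learn from every echo and the natural actor-critic learns from every
#' transition (no bootstrapping across targets).
#'
#' @param agent A `bat_agent`.
#' @param target Target direction `c(alpha, phi)` in horizontal-angle /
#'   elevation coordinates, degrees (body frame).
#' @param mode `"train"` (stochastic policy, learning on), `"greedy"`
#'   (deterministic policy, learning off) or `"oracle"` (a kinematic
#'   cheat controller that turns exactly towards the target; used for
#'   sanity checks).
#' @param duration_ms Fixed call duration, or `NULL` to sample each call
#'   from the gamma duration distribution.
#' @param n_iter Iterations (echoes) in the episode.
#' @param seed Optional seed; fixing agent and seed makes the episode
#'   bit-reproducible.
#' @return List with the updated `agent`, the per-iteration `trace`
#'   data frame and a `truncated` flag (target left the HRTF hull; the
#'   trace stops there, and in training the escaping transition earns
#'   the worst-case reconstruction reward).
#' @export
run_episode <- function(agent, target, mode = c("train", "greedy", "oracle"),
                        duration_ms = NULL, n_iter = agent$config$iterations,
                        seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(agent, "bat_agent"), length(target) == 2L)
  with_seed_if(seed, {
    cfg <- agent$config
    s_B <- direction_vector(azimuth_from_horizontal(target[1], target[2]),
                            target[2])
    Rbar <- diag(3)
    rows <- vector("list", n_iter)
    truncated <- FALSE
    f_prev <- NULL; act_prev <- NULL
    learn <- mode == "train"
    for (t_i in seq_len(n_iter)) {
      ## one roll sample per received echo
      if (cfg$sigma_roll > 0) {
        roll <- ar_advance(agent$roll_model, agent$roll_state, 1L)
        agent$roll_state <- c(agent$roll_state[-1L], roll)
      } else {
        roll <- 0
      }
      h <- drop(t(Rbar) %*% c(1, 0, 0))
      yaw_n <- rad2deg(atan2(h[2], h[1]))
      pitch_n <- rad2deg(-asin(pmin(1, pmax(-1, h[3]))))
      torsion <- listing_torsion(yaw_n, pitch_n) + roll
      R_HB <- fick_rotation(yaw_n, pitch_n, torsion)
      tic <- target_in_head_coords(t(R_HB), s_B)
      ang <- tic$angles
      if (abs(ang$alpha) > cfg$hull || abs(ang$elevation) > cfg$hull ||
          tic$s_H[1] < 0) {
        truncated <- TRUE
        ## an echo from outside the measured HRTF region is
        ## unrepresentable: the window error bound (1 for unit-norm
        ## windows) applies, so in training the escaping action earns the
        ## worst-case reward before the trace is truncated
        if (learn && !is.null(f_prev)) {
          lrs <- agent_lrs(agent)
          up <- nac_update(agent$policy, agent$critic, f_prev, act_prev,
                           reward = -1, terminal = TRUE,
                           discount = cfg$discount, lr_critic = lrs$critic,
                           lr_w = lrs$w, lr_actor = lrs$actor)
          agent$policy <- up$policy
          agent$critic <- up$critic
        }
        break
      }
      call <- synthesize_call(duration_ms)
      echo <- render_echo(call, agent$hrtf, ang$alpha, ang$elevation)
      enc <- encode_echo(agent$gassoms, echo)
      r <- compute_reward(enc$encodings)
      f <- enc$features
      if (learn) {
        agent$gassoms <- Map(function(g, nm) {
          gassom_update(g, enc$windows[[nm]], enc = enc$encodings[[nm]])
        }, agent$gassoms, names(agent$gassoms))
        if (!is.null(f_prev)) {
          lrs <- agent_lrs(agent)
          up <- nac_update(agent$policy, agent$critic, f_prev, act_prev, r,
                           f_next = f, terminal = FALSE,
                           discount = cfg$discount, lr_critic = lrs$critic,
                           lr_w = lrs$w, lr_actor = lrs$actor)
          agent$policy <- up$policy
          agent$critic <- up$critic
        }
        agent$train_step <- agent$train_step + 1L
      }
      act <- if (mode == "oracle") {
        ## exact aligning command in the torsion-free accumulated frame
        pre <- direction_angles(drop(Rbar %*% s_B))
        list(action = c(pre$azimuth, pre$elevation),
             raw = c(pre$azimuth, pre$elevation))
      } else {
        policy_act(agent$policy, f, if (mode == "train") "train" else "greedy")
      }
      rows[[t_i]] <- c(
        iter = t_i, roll = roll, head_yaw = yaw_n, head_pitch = pitch_n,
        torsion = torsion, alpha = ang$alpha, azimuth = ang$azimuth,
        elevation = ang$elevation, dtheta = act$action[1],
        dphi = act$action[2], reward = r,
        duration_ms = call$duration_ms)
      f_prev <- f; act_prev <- act
      Rbar <- update_head_rotation(Rbar, act$action[1], act$action[2])$R
    }
    keep <- !vapply(rows, is.null, TRUE)
    trace <- if (any(keep)) {
      as.data.frame(do.call(rbind, rows[keep]))
    } else {
      NULL
    }
    list(agent = agent, trace = trace, truncated = truncated)
  })
}

#' Train an agent over a sequence of random targets
#'
#' Repeated 20-iteration episodes with target directions drawn uniformly
#' from the configured horizontal x elevation rectangle; GASSOM and
#' actor-critic updates are interleaved within every episode.
#'
#' @param agent A `bat_agent`.
#' @param n_targets Number of training targets (episodes).
#' @param seed Seed controlling targets, calls, rolls and exploration.
#' @param learn_policy Set `FALSE` to freeze the policy (GASSOM-only
#'   ablation) -- the complementary GASSOM freeze is available through
#'   `learn_gassom`.
#' @param learn_gassom Set `FALSE` to freeze the perceptual
#'   representation.
#' @return List with the trained `agent` and a `curve` data frame
#'   (episode, mean reward, mean final error).
#' @export
train_agent <- function(agent, n_targets = agent$config$n_targets, seed = 1,
                        learn_policy = TRUE, learn_gassom = TRUE) {
  stopifnot(inherits(agent, "bat_agent"))
  with_seed_if(seed, {
    cfg <- agent$config
    if (!learn_policy) {
      cfg0 <- agent$config
      agent$config$lr_actor <- 0; agent$config$lr_w <- 0
      agent$config$lr_critic <- 0
    }
    curve <- data.frame(episode = integer(), reward = numeric(),
                        final_error = numeric())
    for (ep in seq_len(n_targets)) {
      target <- c(stats::runif(1, -cfg$target_region[1], cfg$target_region[1]),
                  stats::runif(1, -cfg$target_region[2], cfg$target_region[2]))
      if (!learn_gassom) {
        keep <- agent$gassoms
        res <- run_episode(agent, target, mode = "train")
        res$agent$gassoms <- keep
      } else {
        res <- run_episode(agent, target, mode = "train")
      }
      agent <- res$agent
      tr <- res$trace
      curve <- rbind(curve, data.frame(
        episode = ep, reward = mean(tr$reward),
        final_error = sqrt(tr$alpha[nrow(tr)]^2 + tr$elevation[nrow(tr)]^2)))
    }
    if (!learn_policy) agent$config <- cfg0
    list(agent = agent, curve = curve)
  })
}

#' Evaluate greedy localization episodes from a grid of initial targets
#'
#' @param agent A trained `bat_agent` (an untrained agent triggers a
#'   warning but still runs).
#' @param alphas,phis Initial target directions, degrees (defaults: the
#'   target region at 20-degree spacing).
#' @param durations_ms Call durations to test, ms.
#' @param seed Seed (rolls are still stochastic under nonzero
#'   `sigma_roll`).
#' @return A long data frame of traces with identifiers `trial`,
#'   `alpha0`, `phi0`, `duration_ms`.
#' @export
evaluate_grid <- function(agent, alphas = NULL, phis = NULL,
                          durations_ms = 2, seed = 1) {
  stopifnot(inherits(agent, "bat_agent"))
  if (agent$train_step == 0L) {
    warning("evaluating an untrained agent")
  }
  cfg <- agent$config
  if (is.null(alphas)) alphas <- seq(-cfg$target_region[1], cfg$target_region[1], by = 20)
  if (is.null(phis)) phis <- seq(-cfg$target_region[2], cfg$target_region[2], by = 20)
  grid <- expand.grid(alpha0 = alphas, phi0 = phis, duration_ms = durations_ms)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- run_episode(agent, c(grid$alpha0[i], grid$phi0[i]), mode = "greedy",
                       duration_ms = grid$duration_ms[i], seed = seed + i)
    agent$roll_state <- res$agent$roll_state
    tr <- res$trace
    if (is.null(tr) || nrow(tr) == 0L) next
    tr$trial <- i; tr$alpha0 <- grid$alpha0[i]; tr$phi0 <- grid$phi0[i]
    tr$truncated <- res$truncated
    out[[i]] <- tr
  }
  do.call(rbind, out)
}

#' Reconstruction-error surface over target directions
#'
#' Mean reconstruction error of the agent's GASSOM bank for echoes
#' arriving from a grid of directions, averaged over call durations and
#' head-roll angles.  With the head in the reference pose and torsion
#' `gamma`, a target at direction d is heard from `R_X(-gamma) d`.
#'
#' @param agent A `bat_agent` with trained GASSOMs.
#' @param alphas,phis Direction grids, degrees (the reference analysis
#'   uses -80 to 80 in steps of 2).
#' @param n_calls Number of call durations averaged per direction.
#' @param n_rolls Number of roll angles drawn from the agent's AR roll
#'   stream (all zero under `sigma_roll = 0`).
#' @param rolls Optional numeric vector of fixed roll angles (deg)
#'   overriding `n_rolls`.
#' @param seed Seed for call durations and sampled rolls.
#' @return List with `alpha`, `phi`, the error `surface`
#'   (length(alphas) x length(phis)), the `argmin` direction and the
#'   fraction of (direction, roll) pairs `clipped` outside the HRTF hull
#'   (excluded from the average).
#' @export
error_surface <- function(agent, alphas = seq(-80, 80, by = 2),
                          phis = seq(-80, 80, by = 2), n_calls = 30,
                          n_rolls = 100, rolls = NULL, seed = 1) {
  stopifnot(inherits(agent, "bat_agent"))
  with_seed_if(seed, {
    cfg <- agent$config
    durations <- sample_call_durations(n_calls)
    gammas <- if (!is.null(rolls)) {
      as.numeric(rolls)
    } else if (cfg$sigma_roll > 0) {
      sample_roll_sequence(agent$roll_model, as.integer(n_rolls))
    } else {
      numeric(as.integer(n_rolls))
    }
    calls <- lapply(durations, synthesize_call)
    surface <- matrix(0, length(alphas), length(phis),
                      dimnames = list(alphas, phis))
    nclip <- 0L; ntot <- 0L
    for (ia in seq_along(alphas)) {
      for (ip in seq_along(phis)) {
        ## a (horizontal, elevation) pair is a direction only where
        ## |sin(alpha)| <= cos(phi) (cone-of-confusion geometry)
        if (abs(sin(deg2rad(alphas[ia]))) > cos(deg2rad(phis[ip]))) {
          surface[ia, ip] <- NA_real_
          next
        }
        d <- direction_vector(azimuth_from_horizontal(alphas[ia], phis[ip]),
                              phis[ip])
        errs <- numeric(0)
        for (g in gammas) {
          dh <- drop(rotation_matrix("X", -g) %*% d)
          ah <- direction_angles(dh)
          ntot <- ntot + 1L
          if (abs(ah$alpha) > cfg$hull || abs(ah$elevation) > cfg$hull ||
              dh[1] < 0) {
            nclip <- nclip + 1L
            next
          }
          for (cl in calls) {
            echo <- render_echo(cl, agent$hrtf, ah$alpha, ah$elevation)
            enc <- encode_echo(agent$gassoms, echo)
            errs <- c(errs, -compute_reward(enc$encodings))
          }
        }
        surface[ia, ip] <- if (length(errs)) mean(errs) else NA_real_
      }
    }
    amin <- arrayInd(which.min(surface), dim(surface))
    list(alpha = alphas, phi = phis, surface = surface,
         argmin = c(alpha = alphas[amin[1]], phi = phis[amin[2]]),
         clipped = nclip / max(1L, ntot))
  })
}

#' Rotate an error surface about the origin
#'
#' Resamples a surface at directions rotated about the forward axis,
#' bilinearly interpolating on the (horizontal, elevation) grid; used to
#' compare error surfaces probed under different fixed head rolls.
#'
#' @param surf An [error_surface()] result.
#' @param angle Rotation angle about +X, degrees.
#' @return Matrix of the rotated surface (NA outside the grid).
#' @export
rotate_surface <- function(surf, angle) {
  R <- rotation_matrix("X", angle)
  out <- matrix(NA_real_, length(surf$alpha), length(surf$phi))
  interp <- function(a, p) {
    if (a < min(surf$alpha) || a > max(surf$alpha) ||
        p < min(surf$phi) || p > max(surf$phi)) return(NA_real_)
    wa <- bilinear_weights(surf$alpha, a); wp <- bilinear_weights(surf$phi, p)
    z <- surf$surface[wa$i + 0:1, wp$i + 0:1]
    if (anyNA(z)) return(NA_real_)
    (1 - wa$w) * ((1 - wp$w) * z[1, 1] + wp$w * z[1, 2]) +
      wa$w * ((1 - wp$w) * z[2, 1] + wp$w * z[2, 2])
  }
  for (ia in seq_along(surf$alpha)) {
    for (ip in seq_along(surf$phi)) {
      if (abs(sin(deg2rad(surf$alpha[ia]))) > cos(deg2rad(surf$phi[ip]))) next
      d <- direction_vector(azimuth_from_horizontal(surf$alpha[ia], surf$phi[ip]),
                            surf$phi[ip])
      dr <- drop(R %*% d)
      if (dr[1] < 0) next
      ar <- direction_angles(dr)
      out[ia, ip] <- interp(ar$alpha, ar$elevation)
    }
  }
  out
}

#' Save and restore an agent checkpoint
#'
#' @param agent A `bat_agent`.
#' @param path File path for the checkpoint.
#' @return `save_agent()` returns `path` invisibly; `load_agent()` the
#'   restored agent.
#' @export
save_agent <- function(agent, path) {
  stopifnot(inherits(agent, "bat_agent"))
  saveRDS(agent, path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  agent <- readRDS(path)
  stopifnot(inherits(agent, "bat_agent"))
  agent
}
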