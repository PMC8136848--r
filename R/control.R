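## Reward computation, Gaussian head-control policy and the incremental
## natural actor-critic.
##
## The actor is a one-hidden-layer tanh network mapping the pooled GASSOM
## feature vector to mean yaw/pitch commands; during training actions are
## drawn from an isotropic Gaussian around that mean (exploration sd
## sigma_e) and clipped.  The critic is linear in the features.  Both
## networks see online-standardized features (running mean/variance),
## which keeps the learning rates meaningful across representations.
## Learning follows the compatible-feature natural actor-critic: the TD
## error drives the critic and a normalized-LMS estimate w of the
## advantage in the compatible basis psi = grad log pi; the actor steps
## along w, the natural gradient of the discounted return.

#' Reward from reconstruction errors
#'
#' The negative reconstruction error averaged over scales, channels and
#' window indices: per stream the mean posterior-weighted window error,
#' then the mean across the six streams (identical to the flat
#' `-1/(6N) * sum` when all streams hold N windows).
#'
#' @param encodings List of per-stream [gassom_encode()] results (or any
#'   list of objects with an `expected_error` vector).
#' @return Scalar reward (non-positive for unit-norm windows).
#' @export
compute_reward <- function(encodings) {
  if (length(encodings) == 0L) stop_invalid("no encodings given")
  means <- vapply(encodings, function(e) {
    ee <- e$expected_error
    if (is.null(ee) || length(ee) == 0L) stop_invalid("stream without windows")
    mean(ee)
  }, 0)
  -mean(means)
}

#' Create a head-control policy network
#'
#' @param input_dim Feature dimension (2400 for the full model).
#' @param hidden Hidden tanh units (500 for the full model).
#' @param sigma_e Exploration standard deviation, degrees.
#' @param clip Symmetric per-iteration command bound, degrees.
#' @param seed Optional seed for the initialization.
#' @return A `policy_net` object.
#' @export
policy_new <- function(input_dim, hidden = 500L, sigma_e = 10, clip = 30,
                       seed = NULL) {
  with_seed_if(seed, {
    structure(list(
      W1 = matrix(stats::rnorm(input_dim * hidden, 0, 1 / sqrt(input_dim)),
                  hidden, input_dim),
      b1 = numeric(hidden),
      W2 = matrix(stats::rnorm(2L * hidden, 0, 0.1 / sqrt(hidden)), 2L, hidden),
      b2 = numeric(2L),
      sigma_e = sigma_e, clip = clip,
      norm = list(mean = numeric(input_dim), var = rep(1, input_dim), n = 0),
      w_adv = NULL  # natural-gradient estimate, allocated lazily
    ), class = "policy_net")
  })
}

#' Create a linear critic network
#'
#' @param input_dim Feature dimension.
#' @return A `critic_net` (single linear layer to one value output).
#' @export
critic_new <- function(input_dim) {
  structure(list(w = numeric(input_dim), b = 0), class = "critic_net")
}

standardize <- function(policy, f) {
  (f - policy$norm$mean) / sqrt(policy$norm$var + 1e-8)
}

## Exponential running update of the feature statistics.
norm_update <- function(policy, f, rate = 0.01) {
  nrm <- policy$norm
  r <- max(1 / (nrm$n + 1), rate)
  nrm$mean <- (1 - r) * nrm$mean + r * f
  nrm$var <- (1 - r) * nrm$var + r * (f - nrm$mean)^2
  nrm$n <- nrm$n + 1
  policy$norm <- nrm
  policy
}

policy_forward <- function(policy, f) {
  fz <- standardize(policy, f)
  h <- tanh(drop(policy$W1 %*% fz) + policy$b1)
  list(mu = drop(policy$W2 %*% h) + policy$b2, h = h, fz = fz)
}

critic_value <- function(critic, fz) sum(critic$w * fz) + critic$b

#' Choose a head-movement action
#'
#' In `"train"` mode the yaw/pitch command is sampled from a Gaussian
#' centered on the network output with sd `sigma_e`; in `"greedy"` mode
#' the mean itself is used (`sigma_e = 0`).  Commands are clipped to
#' `+/- clip` degrees after sampling.
#'
#' @param policy A `policy_net`.
#' @param f Feature vector.
#' @param mode `"train"` or `"greedy"`.
#' @param seed Optional seed for the exploration noise.
#' @return List with `action` (clipped `c(dtheta, dphi)`, deg), the
#'   pre-clip `raw` action, the policy `mu` and the hidden activations.
#' @export
policy_act <- function(policy, f, mode = c("train", "greedy"), seed = NULL) {
  mode <- match.arg(mode)
  if (!all(is.finite(f))) stop_invalid("non-finite feature vector")
  fwd <- policy_forward(policy, f)
  raw <- if (mode == "train") {
    with_seed_if(seed, fwd$mu + stats::rnorm(2L, 0, policy$sigma_e))
  } else {
    fwd$mu
  }
  list(action = pmin(policy$clip, pmax(-policy$clip, raw)),
       raw = raw, mu = fwd$mu, h = fwd$h, fz = fwd$fz)
}

## Gradient of log pi(a | f) with respect to the policy parameters,
## returned in the same (W1, b1, W2, b2) layout.  `act` must come from
## policy_act() on the same features.
policy_logp_grad <- function(policy, act) {
  gmu <- (act$raw - act$mu) / policy$sigma_e^2      # 2-vector
  dW2 <- outer(gmu, act$h)
  db2 <- gmu
  dh <- drop(crossprod(policy$W2, gmu)) * (1 - act$h^2)
  dW1 <- outer(dh, act$fz)
  db1 <- dh
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Natural actor-critic update
#'
#' One transition `(f, a, r, f_next)` updates (i) the running feature
#' statistics, (ii) the linear critic by a normalized TD step, (iii) the
#' compatible-feature advantage weights `w` by a normalized-LMS step
#' `w <- w + lr_w (delta - psi' w) psi / ||psi||^2` with
#' `psi = grad log pi(a | f)`, and (iv) the actor parameters along `w`
#' (the natural gradient).  Episode boundaries pass `terminal = TRUE`, in
#' which case no bootstrap value is used.
#'
#' @param policy A `policy_net`.
#' @param critic A `critic_net`.
#' @param f,f_next Feature vectors (state and successor state).
#' @param act The [policy_act()] result that produced the action.
#' @param reward Scalar reward.
#' @param terminal No bootstrapping past this transition.
#' @param discount Discount factor.
#' @param lr_critic,lr_w,lr_actor Learning rates (normalized steps; order
#'   one is meaningful).
#' @param w_forget Per-step forgetting factor of the advantage estimate
#'   (stale advantage directions decay once absorbed by the actor).
#' @param max_norm Divergence guard on the parameter norms.
#' @return List with updated `policy`, `critic` and `diagnostics`
#'   (TD error, gradient and natural-gradient norms).
#' @export
nac_update <- function(policy, critic, f, act, reward, f_next = NULL,
                       terminal = is.null(f_next), discount = 0.3,
                       lr_critic = 0.05, lr_w = 0.2, lr_actor = 0.01,
                       w_forget = 0.99, max_norm = 1e6) {
  if (!all(is.finite(c(f, reward)))) stop_invalid("non-finite transition")
  policy <- norm_update(policy, f)
  fz <- standardize(policy, f)
  v <- critic_value(critic, fz)
  v_next <- if (terminal) 0 else critic_value(critic, standardize(policy, f_next))
  delta <- reward + discount * v_next - v
  if (lr_critic > 0) {
    step <- lr_critic * delta / (sum(fz^2) + 1)
    critic$w <- critic$w + step * fz
    critic$b <- critic$b + lr_critic * delta
  }
  act$fz <- fz  # gradients taken at the current standardization
  psi <- policy_logp_grad(policy, act)
  if (is.null(policy$w_adv)) {
    policy$w_adv <- lapply(psi, function(p) p * 0)
  }
  adv_hat <- sum(mapply(function(w, p) sum(w * p), policy$w_adv, psi))
  gnorm2 <- sum(vapply(psi, function(p) sum(p^2), 0))
  resid <- delta - adv_hat
  wnorm2 <- 0
  for (nm in names(psi)) {
    if (lr_w > 0) {
      policy$w_adv[[nm]] <- w_forget * policy$w_adv[[nm]] +
        lr_w * resid * psi[[nm]] / (gnorm2 + 1e-8)
    }
    if (lr_actor > 0) {
      policy[[nm]] <- policy[[nm]] + lr_actor * policy$w_adv[[nm]]
    }
    wnorm2 <- wnorm2 + sum(policy$w_adv[[nm]]^2)
  }
  if (max(abs(policy$W1), abs(policy$W2), abs(critic$w)) > max_norm) {
    stop("training failure: diverging network weights")
  }
  list(policy = policy, critic = critic,
       diagnostics = list(td_error = delta, grad_norm = sqrt(gnorm2),
                          natgrad_norm = sqrt(wnorm2)))
}
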