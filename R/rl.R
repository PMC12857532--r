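#' Planning environment binding a phantom, arc, machine and dose model
#'
#' Precomputes everything the episode loops need: the beamlet bank, mask
#' vectors, beam's-eye-view rotation index maps per control-point angle, and
#' the objective specification. All doses inside the environment are handled
#' as flat voxel vectors for speed.
#'
#' @param phantom A `vmat_phantom`.
#' @param arc A `vmat_arc`.
#' @param machine A `vmat_machine`.
#' @param spec A `vmat_objective_spec`.
#' @param kernel A `vmat_kernel`.
#' @param bank Optional precomputed `vmat_beamlet_bank` (else computed here).
#' @return A `vmat_env`.
#' @export
plan_env <- function(phantom, arc, machine = machine_model(),
                     spec = objective_spec(), kernel = beam_kernel(),
                     bank = NULL) {
  if (is.null(bank)) bank <- precompute_beamlets(phantom, arc, machine, kernel)
  ptv <- as.vector(phantom$masks$PTV)
  oar <- as.vector(oar_union_mask(phantom))
  bev <- lapply(arc$cp_angles, function(a) {
    rotation_index(phantom$grid_shape, phantom$spacing, a,
                   center_mm = phantom$isocenter)
  })
  env <- list(phantom = phantom, arc = arc, machine = machine, spec = spec,
              bank = bank, ptv = ptv, oar = oar, bev = bev,
              n_vox = prod(phantom$grid_shape),
              hw = machine$field_half_width, mu_max = max_cp_mu(machine))
  class(env) <- "vmat_env"
  env
}

# anchored dose vector + objective for a raw cumulative dose vector;
# errors if the PTV D95 cannot be anchored
env_objective <- function(env, cum_raw) {
  d <- as_dose(cum_raw, env$bank, "raw")
  d <- normalize_d95(d, env$phantom$masks$PTV)
  list(dose = d, obj = objective_value(d, env$phantom, env$spec))
}

# per-CP dose vectors per MU for the current apertures
plan_unit_doses <- function(env, plan) {
  lapply(seq_len(plan$arc$n_cp), function(t) {
    cp_dose_vector(plan$arc$cp_angles[t], plan$leaves[t, ], 1, env$bank)
  })
}

# rotate a voxel vector into the beam frame of CP t (nearest neighbour)
bev_rotate <- function(env, vec, t) {
  c(vec, 0)[env$bev[[t]]]
}

# MLC state: BEV-aligned anchored dose + masks, one token per leaf pair + MU
mlc_state <- function(env, anch_vec, leaves_t, mu_t, t) {
  vol <- cbind(bev_rotate(env, anch_vec, t),
               bev_rotate(env, as.numeric(env$ptv), t),
               bev_rotate(env, as.numeric(env$oar), t))
  np <- env$machine$leaf_pairs
  vec <- rbind(cbind(leaves_t[seq_len(np)], leaves_t[np + seq_len(np)]) / env$hw,
               c(mu_t / env$mu_max, 0))
  list(vol = vol, vec = vec)
}

# MU state: cumulative anchored dose + full anatomy, one token per CP
mu_state <- function(env, anch_vec, leaves, mu) {
  vol <- cbind(anch_vec, as.numeric(env$ptv), as.numeric(env$oar))
  vec <- cbind(leaves / env$hw, mu / env$mu_max)
  list(vol = vol, vec = vec)
}

# reward assigned to a degenerate (non-normalizable) proposal: the worst
# reward seen so far in the episode (or a unit penalty when none yet)
degenerate_reward <- function(rewards) {
  if (length(rewards)) min(c(rewards, 0)) else -1
}

#' Run one MLC episode over the arc
#'
#' The MLC policy acts sequentially per control point: at step t it observes
#' the BEV-aligned cumulative dose and anatomy plus the current CP machine
#' parameters, proposes 52 leaf positions, the environment projects them onto
#' the statically valid set, replaces CP t, recomputes the cumulative dose
#' incrementally, re-anchors D95, and rewards the objective decrease.
#' Degenerate proposals that defeat D95 anchoring are discarded and earn the
#' episode's worst reward so far. The final step carries the done flag.
#'
#' @param env A `vmat_env`.
#' @param plan Baseline `vmat_plan`.
#' @param net The MLC `vmat_network`.
#' @param mode `"train"` (sampled actions) or `"infer"` (mean actions).
#' @return List: `traj` (states, actions, log_probs, values, rewards, dones),
#'   updated `plan`, `v_start`, `v_end`.
#' @export
run_mlc_episode <- function(env, plan, net, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  n <- plan$arc$n_cp
  units <- plan_unit_doses(env, plan)
  cum <- Reduce(`+`, Map(`*`, units, as.list(plan$mu)))
  st <- env_objective(env, cum)
  v_cur <- st$obj$total
  v_start <- v_cur
  anch <- as.vector(st$dose$values)
  states <- vector("list", n)
  actions <- matrix(NA_real_, n, net$cfg$out_dim)
  log_probs <- values <- rewards <- numeric(n)
  for (t in seq_len(n)) {
    s <- mlc_state(env, anch, plan$leaves[t, ], plan$mu[t], t)
    out <- net_forward(net, s)
    sa <- sample_action(out, mode)
    states[[t]] <- s
    actions[t, ] <- sa$action
    log_probs[t] <- sa$log_prob
    values[t] <- out$value
    proj <- project_action_to_bounds(sa$action, env$machine)
    new_unit <- cp_dose_vector(plan$arc$cp_angles[t], proj, 1, env$bank)
    cum_new <- cum - units[[t]] * plan$mu[t] + new_unit * plan$mu[t]
    res <- tryCatch(env_objective(env, cum_new), error = function(e) NULL)
    if (is.null(res)) {
      rewards[t] <- degenerate_reward(rewards[seq_len(t - 1)])
    } else {
      plan$leaves[t, ] <- proj
      units[[t]] <- new_unit
      cum <- cum_new
      anch <- as.vector(res$dose$values)
      rewards[t] <- v_cur - res$obj$total
      v_cur <- res$obj$total
    }
  }
  traj <- list(states = states, actions = actions, log_probs = log_probs,
               values = values, rewards = rewards,
               dones = c(rep(0, n - 1), 1))
  list(traj = traj, plan = plan, v_start = v_start, v_end = v_cur)
}

#' Run one MU refinement episode
#'
#' The MU policy acts globally, like a segment weight optimizer: each of the
#' `steps` inference steps observes the cumulative dose, anatomy and the full
#' machine-parameter vector, proposes MU values for all control points at
#' once (clamped to the deliverable range), recomputes the dose, re-anchors
#' D95 and rewards the objective decrease. A proposal making the PTV dose
#' non-anchorable is discarded with the episode's worst reward.
#'
#' @param env A `vmat_env`.
#' @param plan `vmat_plan` with the apertures fixed.
#' @param net The MU `vmat_network`.
#' @param steps Global refinement steps per episode (default 8).
#' @param mode `"train"` or `"infer"`.
#' @return Same structure as [run_mlc_episode()].
#' @export
run_mu_episode <- function(env, plan, net, steps = 8, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  units <- plan_unit_doses(env, plan)
  U <- do.call(cbind, units)
  mu <- plan$mu
  st <- env_objective(env, as.vector(U %*% mu))
  v_cur <- st$obj$total
  v_start <- v_cur
  anch <- as.vector(st$dose$values)
  states <- vector("list", steps)
  actions <- matrix(NA_real_, steps, net$cfg$out_dim)
  log_probs <- values <- rewards <- numeric(steps)
  for (s_i in seq_len(steps)) {
    s <- mu_state(env, anch, plan$leaves, mu)
    out <- net_forward(net, s)
    sa <- sample_action(out, mode)
    states[[s_i]] <- s
    actions[s_i, ] <- sa$action
    log_probs[s_i] <- sa$log_prob
    values[s_i] <- out$value
    mu_new <- pmin(pmax(sa$action, 0), env$mu_max)
    res <- tryCatch(env_objective(env, as.vector(U %*% mu_new)),
                    error = function(e) NULL)
    if (is.null(res)) {
      rewards[s_i] <- degenerate_reward(rewards[seq_len(s_i - 1)])
    } else {
      mu <- mu_new
      anch <- as.vector(res$dose$values)
      rewards[s_i] <- v_cur - res$obj$total
      v_cur <- res$obj$total
    }
  }
  plan$mu <- mu
  traj <- list(states = states, actions = actions, log_probs = log_probs,
               values = values, rewards = rewards,
               dones = c(rep(0, steps - 1), 1))
  list(traj = traj, plan = plan, v_start = v_start, v_end = v_cur)
}

#' Generalized advantage estimation by backward recursion
#'
#' Temporal-difference residuals `delta_t = r_t + gamma (1 - d_t) V_{t+1}
#' - V_t` (with `V_{T+1} = 0` past the terminal step) are combined by the
#' backward recursion `A_t = delta_t + gamma lambda (1 - d_t) A_{t+1}`,
#' equivalent to the exponentially weighted forward sum of residuals.
#' Returns `G_t = A_t + V_t` and batch-normalized advantages (mean 0, sd 1)
#' alongside the raw values.
#'
#' @param traj Trajectory list with `rewards`, `values`, `dones`.
#' @param gamma Discount factor (default 0.99).
#' @param lambda GAE decay (default 0.95).
#' @return A `vmat_advantages`: `advantage`, `ret`, `adv_norm`, `mean`, `sd`.
#' @export
compute_gae <- function(traj, gamma = 0.99, lambda = 0.95) {
  r <- traj$rewards
  v <- traj$values
  d <- traj$dones
  n <- length(r)
  if (n == 0) stop("empty trajectory")
  stopifnot(length(v) == n, length(d) == n)
  v_next <- c(v[-1], 0)
  delta <- r + gamma * (1 - d) * v_next - v
  adv <- numeric(n)
  run <- 0
  for (t in rev(seq_len(n))) {
    run <- delta[t] + gamma * lambda * (1 - d[t]) * run
    adv[t] <- run
  }
  m <- mean(adv)
  s <- if (n >= 2) stats::sd(adv) else 0
  adv_norm <- if (s > 0) (adv - m) / (s + 1e-8) else adv * 0
  out <- list(advantage = adv, ret = adv + v, adv_norm = adv_norm,
              mean = m, sd = s)
  class(out) <- "vmat_advantages"
  out
}

#' Clipped-surrogate PPO objective with value and entropy terms
#'
#' For each step the importance ratio `R_t = exp(logpi_new - logpi_old)` is
#' combined with the advantage in the clipped surrogate
#' `min(R A, clip(R, 1 - eps, 1 + eps) A)`; the critic term is the mean
#' squared error between the new value and the return `G`; the entropy bonus
#' is the mean diagonal-Gaussian entropy. The objective
#' `L_clip - c1 L_VF + c2 S` is maximized; `loss` is its negative, which
#' training minimizes. With `grad = TRUE`, per-step gradients of the loss
#' with respect to each step's mean, log-std and value are returned for
#' backpropagation.
#'
#' @param batch List with `actions` (matrix, one row per step),
#'   `log_prob_old`, `adv` (normalized advantages), `ret` (returns `G`), and
#'   `outs` (list of per-step [net_forward()] outputs under the current
#'   parameters).
#' @param clip_eps Clipping parameter (default 0.15).
#' @param c1,c2 Value and entropy coefficients (defaults 0.45, 0.005).
#' @param grad Also return per-step gradients.
#' @return List: `objective`, `loss`, `clip_term`, `vf_term`, `entropy_term`,
#'   `ratios` (and `d_mean`, `d_log_std`, `d_value` when `grad = TRUE`).
#' @export
ppo_loss <- function(batch, clip_eps = 0.15, c1 = 0.45, c2 = 0.005,
                     grad = FALSE) {
  n <- length(batch$outs)
  stopifnot(n >= 1)
  clip_t <- vf_t <- ent_t <- ratio <- numeric(n)
  d_mean <- d_log_std <- vector("list", n)
  d_value <- numeric(n)
  for (t in seq_len(n)) {
    o <- batch$outs[[t]]
    a <- batch$actions[t, ]
    A <- batch$adv[t]
    sig <- exp(o$log_std)
    z <- (a - o$mean) / sig
    logp <- sum(-0.5 * log(2 * pi) - o$log_std - 0.5 * z^2)
    r <- exp(logp - batch$log_prob_old[t])
    ratio[t] <- r
    unclipped <- r * A
    clipped <- min(max(r, 1 - clip_eps), 1 + clip_eps) * A
    clip_t[t] <- min(unclipped, clipped)
    vf_t[t] <- (o$value - batch$ret[t])^2
    ent_t[t] <- sum(0.5 * log(2 * pi * exp(1)) + o$log_std)
    if (grad) {
      active <- (A >= 0 && r < 1 + clip_eps) || (A < 0 && r > 1 - clip_eps)
      g <- if (active) r * A / n else 0
      # gradients of the *loss* (negative objective)
      d_mean[[t]] <- -(g * z / sig)
      d_log_std[[t]] <- -(g * (z^2 - 1) + c2 / n)
      d_value[t] <- c1 * 2 * (o$value - batch$ret[t]) / n
    }
  }
  objective <- mean(clip_t) - c1 * mean(vf_t) + c2 * mean(ent_t)
  if (!is.finite(objective)) {
    stop(sprintf("non-finite PPO loss (clip %g, vf %g, entropy %g)",
                 mean(clip_t), mean(vf_t), mean(ent_t)))
  }
  out <- list(objective = objective, loss = -objective,
              clip_term = mean(clip_t), vf_term = mean(vf_t),
              entropy_term = mean(ent_t), ratios = ratio)
  if (grad) {
    out$d_mean <- d_mean
    out$d_log_std <- d_log_std
    out$d_value <- d_value
  }
  out
}

# one PPO update pass over an episode trajectory
ppo_update <- function(net, opt, traj, cfg) {
  adv <- compute_gae(traj, cfg$gamma, cfg$lambda)
  n <- length(traj$rewards)
  idx_all <- seq_len(n)
  last <- NULL
  for (ep in seq_len(cfg$ppo_epochs)) {
    perm <- sample(idx_all)
    chunks <- split(perm, ceiling(seq_along(perm) / cfg$minibatch))
    for (mb in chunks) {
      caches <- outs <- vector("list", length(mb))
      for (k in seq_along(mb)) {
        fw <- net_forward(net, traj$states[[mb[k]]], cache = TRUE)
        caches[[k]] <- fw$cache
        outs[[k]] <- fw[c("mean", "log_std", "value")]
      }
      batch <- list(actions = traj$actions[mb, , drop = FALSE],
                    log_prob_old = traj$log_probs[mb],
                    adv = adv$adv_norm[mb], ret = adv$ret[mb], outs = outs)
      pl <- ppo_loss(batch, cfg$clip_eps, cfg$c1, cfg$c2, grad = TRUE)
      grads <- zero_grads(net$params)
      for (k in seq_along(mb)) {
        gk <- net_backward(net, caches[[k]], pl$d_mean[[k]],
                           pl$d_log_std[[k]], pl$d_value[k])
        grads <- add_grads(grads, gk)
      }
      stp <- adam_step(net$params, grads, opt, lr = cfg$lr, clip = cfg$grad_clip)
      net$params <- stp$params
      opt <- stp$state
      last <- pl
    }
  }
  list(net = net, opt = opt, loss = last)
}

#' Training configuration
#'
#' Bundles the RL and imitation-learning hyperparameters. Reward/advantage
#' constants follow the published configuration (`gamma` 0.99, `lambda` 0.95,
#' `clip_eps` 0.15, `c1` 0.45, `c2` 0.005, 8 MU refinement steps per
#' episode); the full-scale schedule is 2000 RL iterations after 500
#' imitation epochs, while the desk-scale default is 50/50. The PPO update
#' regimen (4 epochs, minibatch 64, Adam step 1e-4, gradient-norm clip 1.0)
#' is a package default, as is the behavioral-cloning step size.
#'
#' @param iterations RL iterations (toy default 50; full scale 2000).
#' @param il_epochs Behavioral-cloning epochs (toy default 50; full 500).
#' @param gamma,lambda GAE constants.
#' @param clip_eps,c1,c2 PPO constants.
#' @param mu_steps MU refinement steps per episode.
#' @param ppo_epochs,minibatch,lr,grad_clip PPO update regimen.
#' @param bc_lr Behavioral-cloning Adam step size.
#' @param infer_cap Maximum outer MLC+MU passes at inference.
#' @param seed Root seed for all randomness in a training run.
#' @return A `vmat_train_config` list.
#' @export
train_config <- function(iterations = 50, il_epochs = 50, gamma = 0.99,
                         lambda = 0.95, clip_eps = 0.15, c1 = 0.45,
                         c2 = 0.005, mu_steps = 8, ppo_epochs = 4,
                         minibatch = 64, lr = 1e-4, grad_clip = 1.0,
                         bc_lr = 1e-3, infer_cap = 8, seed = 0) {
  stopifnot(gamma > 0, gamma <= 1, lambda > 0, lambda <= 1, clip_eps > 0,
            iterations >= 1, il_epochs >= 1, mu_steps >= 1)
  cfg <- list(iterations = iterations, il_epochs = il_epochs, gamma = gamma,
              lambda = lambda, clip_eps = clip_eps, c1 = c1, c2 = c2,
              mu_steps = mu_steps, ppo_epochs = ppo_epochs,
              minibatch = minibatch, lr = lr, grad_clip = grad_clip,
              bc_lr = bc_lr, infer_cap = infer_cap, seed = seed)
  class(cfg) <- "vmat_train_config"
  cfg
}

#' Behavioral-cloning initialization of the MLC network
#'
#' Supervised pretraining: for every control point of every expert
#' demonstration, the per-CP MLC state is built from the expert plan and the
#' mean head is regressed onto the expert leaf positions with a
#' mean-squared-error loss minimized by Adam. Returns the initialized network
#' and the per-epoch loss curve; the plans predicted by the initialized
#' network become the initial states of RL training.
#'
#' @param net The MLC `vmat_network`.
#' @param demos List of `vmat_expert_demo`, aligned with `envs`.
#' @param envs List of `vmat_env`.
#' @param epochs Training epochs (toy default 50).
#' @param lr Adam step size.
#' @param minibatch Pairs per update.
#' @return List `net`, `loss_curve` (length `epochs`).
#' @export
behavioral_cloning <- function(net, demos, envs, epochs = 50, lr = 1e-3,
                               minibatch = 16) {
  if (!length(demos)) stop("no expert demonstrations supplied")
  pairs <- list()
  for (i in seq_along(demos)) {
    env <- envs[[i]]
    plan <- expert_plan(demos[[i]], env$arc, env$machine)
    units <- plan_unit_doses(env, plan)
    cum <- Reduce(`+`, Map(`*`, units, as.list(plan$mu)))
    anch <- as.vector(env_objective(env, cum)$dose$values)
    for (t in seq_len(env$arc$n_cp)) {
      pairs[[length(pairs) + 1L]] <- list(
        state = mlc_state(env, anch, plan$leaves[t, ], plan$mu[t], t),
        target = demos[[i]]$apertures[t, ])
    }
  }
  opt <- adam_init(net$params)
  loss_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample(seq_along(pairs))
    chunks <- split(perm, ceiling(seq_along(perm) / minibatch))
    ep_loss <- 0
    for (mb in chunks) {
      grads <- zero_grads(net$params)
      mb_loss <- 0
      for (k in mb) {
        fw <- net_forward(net, pairs[[k]]$state, cache = TRUE)
        err <- fw$mean - pairs[[k]]$target
        mb_loss <- mb_loss + mean(err^2)
        d_mean <- 2 * err / length(err) / length(mb)
        gk <- net_backward(net, fw$cache, d_mean,
                           numeric(length(err)), 0)
        grads <- add_grads(grads, gk)
      }
      stp <- adam_step(net$params, grads, opt, lr = lr, clip = 1.0)
      net$params <- stp$params
      opt <- stp$state
      ep_loss <- ep_loss + mb_loss
    }
    loss_curve[ep] <- ep_loss / length(pairs)
  }
  list(net = net, loss_curve = loss_curve)
}

#' Train the tandem MLC/MU policies
#'
#' Nested loop: behavioral cloning initializes the MLC network and the
#' IL-predicted plans become each patient's initial state; then every RL
#' iteration processes every patient — one sequential MLC episode, one global
#' MU refinement episode, and a PPO update of each network from its own
#' trajectory (trajectories are never shared across the tandem). A patient's
#' baseline plan is replaced only when the episode's final plan strictly
#' improves the total reward (equivalently, strictly lowers the dose
#' objective), giving a progressively improving baseline. The iteration with
#' the best mean total plan reward (on the validation set when given) is
#' checkpointed.
#'
#' @param envs List of training `vmat_env`s (one per patient).
#' @param demos Matching list of `vmat_expert_demo`s.
#' @param cfg A `vmat_train_config`.
#' @param val_envs,val_demos Optional validation split used for checkpoint
#'   selection (defaults to the training set).
#' @param verbose Print per-iteration progress.
#' @return A `vmat_training`: final and best-checkpoint networks, per-iteration
#'   log (`data.frame`: iteration, mean_reward, mean_objective,
#'   constraints_met), final baselines, BC loss curve, the config.
#' @export
train <- function(envs, demos, cfg = train_config(), val_envs = NULL,
                  val_demos = NULL, verbose = FALSE) {
  stopifnot(length(envs) >= 1, length(envs) == length(demos))
  set.seed(cfg$seed)
  env1 <- envs[[1]]
  n_cp <- env1$arc$n_cp
  mlc_net <- build_network("mlc", "toy", vol_shape = env1$phantom$grid_shape,
                           n_cp = n_cp, machine = env1$machine, seed = cfg$seed)
  mu_net <- build_network("mu", "toy", vol_shape = env1$phantom$grid_shape,
                          n_cp = n_cp, machine = env1$machine,
                          seed = cfg$seed + 1)
  bc <- behavioral_cloning(mlc_net, demos, envs, epochs = cfg$il_epochs,
                           lr = cfg$bc_lr)
  mlc_net <- bc$net
  # IL-predicted plans are the RL initial states
  baselines <- vector("list", length(envs))
  base_obj <- numeric(length(envs))
  for (i in seq_along(envs)) {
    p0 <- expert_plan(demos[[i]], envs[[i]]$arc, envs[[i]]$machine)
    ep <- run_mlc_episode(envs[[i]], p0, mlc_net, mode = "infer")
    baselines[[i]] <- ep$plan
    base_obj[i] <- ep$v_end
  }
  opt_mlc <- adam_init(mlc_net$params)
  opt_mu <- adam_init(mu_net$params)
  log <- data.frame(iteration = integer(), mean_reward = numeric(),
                    mean_objective = numeric(), constraints_met = numeric())
  init_obj <- mean(base_obj)
  best_reward <- -Inf
  best <- list(mlc = mlc_net$params, mu = mu_net$params, iteration = 0L)
  diverged_run <- 0L
  for (it in seq_len(cfg$iterations)) {
    total_rewards <- numeric(length(envs))
    ncons <- numeric(length(envs))
    for (i in seq_along(envs)) {
      ep1 <- run_mlc_episode(envs[[i]], baselines[[i]], mlc_net, "train")
      ep2 <- run_mu_episode(envs[[i]], ep1$plan, mu_net, cfg$mu_steps, "train")
      total_rewards[i] <- ep1$v_start - ep2$v_end
      if (ep2$v_end < base_obj[i]) {
        baselines[[i]] <- ep2$plan
        base_obj[i] <- ep2$v_end
      }
      up1 <- ppo_update(mlc_net, opt_mlc, ep1$traj, cfg)
      mlc_net <- up1$net; opt_mlc <- up1$opt
      up2 <- ppo_update(mu_net, opt_mu, ep2$traj, cfg)
      mu_net <- up2$net; opt_mu <- up2$opt
      ncons[i] <- sum(env_objective(envs[[i]],
        Reduce(`+`, Map(`*`, plan_unit_doses(envs[[i]], baselines[[i]]),
                        as.list(baselines[[i]]$mu))))$obj$n_sat)
    }
    mean_reward <- mean(total_rewards)
    log <- rbind(log, data.frame(iteration = it, mean_reward = mean_reward,
                                 mean_objective = mean(base_obj),
                                 constraints_met = mean(ncons)))
    if (verbose) {
      message(sprintf("iter %3d  mean reward %.5f  mean objective %.5f",
                      it, mean_reward, mean(base_obj)))
    }
    if (mean_reward > best_reward) {
      best_reward <- mean_reward
      best <- list(mlc = mlc_net$params, mu = mu_net$params, iteration = it)
    }
    diverged_run <- if (mean(base_obj) > 10 * init_obj) diverged_run + 1L else 0L
    if (diverged_run >= 5L) {
      warning(sprintf("training diverged (objective > 10x initial for 5 iterations), halting at iteration %d", it))
      break
    }
  }
  # checkpoint networks: the iteration with the best mean total plan reward
  # supplies the weights used at inference
  best_mlc <- mlc_net
  best_mlc$params <- best$mlc
  best_mu <- mu_net
  best_mu$params <- best$mu
  out <- list(mlc_net = mlc_net, mu_net = mu_net, best = best,
              best_mlc_net = best_mlc, best_mu_net = best_mu, log = log,
              baselines = baselines, baseline_objectives = base_obj,
              bc_loss = bc$loss_curve, cfg = cfg,
              initial_objective = init_obj)
  class(out) <- "vmat_training"
  out
}

#' @export
print.vmat_training <- function(x, ...) {
  cat(sprintf("Tandem RL training: %d iterations on %d patient(s)\n",
              nrow(x$log), length(x$baselines)))
  cat(sprintf("  mean objective %.5f -> %.5f (best reward at iteration %d)\n",
              x$initial_objective, utils::tail(x$log$mean_objective, 1),
              x$best$iteration))
  invisible(x)
}

#' Generate a plan for a phantom with trained policies
#'
#' Deterministic inference: starting from the conformal expert plan, the MLC
#' pass and the MU refinement are alternated with mean actions; each outer
#' pass is finalized with [enforce_deliverability()] and accepted only if it
#' strictly lowers the dose objective, stopping otherwise (hard cap
#' `infer_cap` outer iterations). The returned plan always passes
#' [check_deliverability()].
#'
#' @param env A `vmat_env` for the target phantom.
#' @param mlc_net,mu_net Trained networks (or checkpoint parameter sets
#'   applied to them).
#' @param cfg A `vmat_train_config` (uses `mu_steps`, `infer_cap`).
#' @param init_plan Optional starting plan (default: conformal expert plan).
#' @return List: deliverable `plan`, `objective` (`vmat_objective`),
#'   `passes` (outer iterations executed).
#' @export
infer <- function(env, mlc_net, mu_net, cfg = train_config(),
                  init_plan = NULL) {
  if (is.null(init_plan)) {
    demo <- generate_expert_demos(env$phantom, env$arc, env$machine)
    init_plan <- expert_plan(demo, env$arc, env$machine)
  }
  plan <- enforce_deliverability(init_plan, env$machine)
  v_cur <- env_objective(env, Reduce(`+`, Map(`*`, plan_unit_doses(env, plan),
                                              as.list(plan$mu))))$obj$total
  passes <- 0L
  for (k in seq_len(cfg$infer_cap)) {
    p1 <- run_mlc_episode(env, plan, mlc_net, "infer")$plan
    p2 <- run_mu_episode(env, p1, mu_net, cfg$mu_steps, "infer")$plan
    p3 <- enforce_deliverability(p2, env$machine)
    v3 <- env_objective(env, Reduce(`+`, Map(`*`, plan_unit_doses(env, p3),
                                             as.list(p3$mu))))$obj$total
    passes <- k
    if (v3 < v_cur) {
      plan <- p3
      v_cur <- v3
    } else {
      break
    }
  }
  obj <- env_objective(env, Reduce(`+`, Map(`*`, plan_unit_doses(env, plan),
                                            as.list(plan$mu))))$obj
  list(plan = plan, objective = obj, passes = passes)
}
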