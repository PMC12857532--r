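# independent oracle: GAE as the explicit forward double sum over residuals
gae_oracle <- function(r, v, d, gamma, lambda) {
  n <- length(r)
  v_next <- c(v[-1], 0)
  delta <- r + gamma * (1 - d) * v_next - v
  vapply(seq_len(n), function(t) {
    acc <- 0
    w <- 1
    for (l in 0:(n - t)) {
      acc <- acc + w * delta[t + l]
      if (d[t + l] == 1) break
      w <- w * gamma * lambda
    }
    acc
  }, numeric(1))
}

test_that("GAE backward recursion matches hand and brute-force oracles", {
  # single-step episode with zero value: advantage is the reward
  tr <- list(rewards = 0.7, values = 0, dones = 1)
  g <- compute_gae(tr)
  expect_equal(g$advantage, 0.7)
  expect_equal(g$ret, 0.7)
  # two steps, zero values, rewards (0, 1): A_0 = gamma * lambda * 1
  tr2 <- list(rewards = c(0, 1), values = c(0, 0), dones = c(0, 1))
  g2 <- compute_gae(tr2, gamma = 0.99, lambda = 0.95)
  expect_equal(g2$advantage[1], 0.99 * 0.95)
  expect_equal(g2$advantage[2], 1)
  # random length-30 trajectory against the double-sum oracle
  set.seed(12)
  r <- rnorm(30); v <- rnorm(30); d <- c(rep(0, 29), 1)
  tr3 <- list(rewards = r, values = v, dones = d)
  g3 <- compute_gae(tr3, 0.99, 0.95)
  expect_lt(max(abs(g3$advantage - gae_oracle(r, v, d, 0.99, 0.95))), 1e-10)
  expect_equal(g3$ret, g3$advantage + v)
  expect_error(compute_gae(list(rewards = numeric(0), values = numeric(0),
                                dones = numeric(0))), "empty")
})

test_that("advantage normalization has batch mean 0 and sd 1", {
  set.seed(13)
  for (n in c(2, 5, 40)) {
    tr <- list(rewards = rnorm(n), values = rnorm(n), dones = c(rep(0, n - 1), 1))
    g <- compute_gae(tr)
    expect_lt(abs(mean(g$adv_norm)), 1e-8)
    expect_lt(abs(sd(g$adv_norm) - 1), 1e-6)
  }
})

# assemble a synthetic PPO batch with prescribed ratios
ppo_batch <- function(n, dim = 3, seed = 1) {
  set.seed(seed)
  outs <- lapply(seq_len(n), function(t) {
    list(mean = rnorm(dim), log_std = rnorm(dim, 0, 0.3), value = rnorm(1))
  })
  actions <- t(vapply(outs, function(o) o$mean + exp(o$log_std) * rnorm(dim),
                      numeric(dim)))
  list(actions = actions,
       log_prob_old = vapply(seq_len(n), function(t) {
         gaussian_log_prob(actions[t, ], outs[[t]]$mean, outs[[t]]$log_std) +
           rnorm(1, 0, 0.1)
       }, numeric(1)),
       adv = rnorm(n), ret = rnorm(n), outs = outs)
}

test_that("PPO loss matches the clipped-surrogate definition case by case", {
  # new policy = old policy and V = G: ratio 1, zero critic term
  out <- list(mean = c(0.2, -0.1), log_std = c(0, -0.5), value = 1.7)
  a <- c(0.3, 0.1)
  batch <- list(actions = matrix(a, 1), adv = 2.0, ret = 1.7,
                log_prob_old = gaussian_log_prob(a, out$mean, out$log_std),
                outs = list(out))
  pl <- ppo_loss(batch, clip_eps = 0.15, c1 = 0.45, c2 = 0.005)
  expect_equal(pl$ratios, 1)
  expect_equal(pl$vf_term, 0)
  expect_equal(pl$objective, 2.0 + 0.005 * policy_entropy(out))
  # A = 1, R = 1.3, eps = 0.15: the clipped branch caps the term at 1.15
  batch$adv <- 1
  batch$log_prob_old <- batch$log_prob_old - log(1.3)
  pl2 <- ppo_loss(batch, clip_eps = 0.15, c1 = 0.45, c2 = 0.005)
  expect_equal(pl2$ratios, 1.3, tolerance = 1e-12)
  expect_equal(pl2$clip_term, 1.15, tolerance = 1e-12)
  # and the policy gradient vanishes where the clip is active
  pl2g <- ppo_loss(batch, clip_eps = 0.15, grad = TRUE)
  expect_equal(pl2g$d_mean[[1]], numeric(2))
  # with A > 0 and R < 1 + eps the clip is inactive and the gradient is live
  batch$log_prob_old <- gaussian_log_prob(a, out$mean, out$log_std)
  pl3 <- ppo_loss(batch, clip_eps = 0.15, grad = TRUE)
  expect_false(all(pl3$d_mean[[1]] == 0))
  # NaN inputs abort with a diagnostic
  bad <- batch
  bad$outs[[1]]$value <- NaN
  expect_error(ppo_loss(bad), "non-finite")
})

test_that("PPO loss equals an elementwise scalar oracle on random batches", {
  eps <- 0.15; c1 <- 0.45; c2 <- 0.005
  for (s in 1:20) {
    b <- ppo_batch(n = 8, dim = 4, seed = s)
    got <- ppo_loss(b, eps, c1, c2)
    # independent scalar evaluation
    cl <- vf <- en <- numeric(8)
    for (t in 1:8) {
      o <- b$outs[[t]]
      lp <- sum(-0.5 * log(2 * pi) - o$log_std -
                  0.5 * ((b$actions[t, ] - o$mean) / exp(o$log_std))^2)
      r <- exp(lp - b$log_prob_old[t])
      cl[t] <- min(r * b$adv[t], min(max(r, 1 - eps), 1 + eps) * b$adv[t])
      vf[t] <- (o$value - b$ret[t])^2
      en[t] <- sum(0.5 * log(2 * pi * exp(1)) + o$log_std)
    }
    oracle <- mean(cl) - c1 * mean(vf) + c2 * mean(en)
    expect_lt(abs(got$objective - oracle), 1e-10)
    expect_equal(got$loss, -got$objective)
  }
})

test_that("PPO per-step gradients match finite differences", {
  b <- ppo_batch(n = 5, dim = 3, seed = 99)
  pl <- ppo_loss(b, grad = TRUE)
  eps <- 1e-6
  for (t in c(1, 3, 5)) {
    for (field in c("mean", "log_std", "value")) {
      o <- b$outs[[t]]
      for (i in seq_along(o[[field]])) {
        b2 <- b
        b2$outs[[t]][[field]][i] <- o[[field]][i] + eps
        f1 <- ppo_loss(b2)$loss
        b2$outs[[t]][[field]][i] <- o[[field]][i] - eps
        f0 <- ppo_loss(b2)$loss
        num <- (f1 - f0) / (2 * eps)
        ana <- switch(field, mean = pl$d_mean[[t]][i],
                      log_std = pl$d_log_std[[t]][i], value = pl$d_value[t])
        expect_equal(ana, num, tolerance = 1e-5,
                     label = sprintf("d%s[%d] step %d", field, i, t))
      }
    }
  }
})

test_that("episode rewards telescope and trajectories are well-formed", {
  env <- toy_env(1)
  demo <- generate_expert_demos(env$phantom, env$arc, env$machine)
  plan <- expert_plan(demo, env$arc, env$machine)
  mach <- env$machine
  mlc_net <- build_network("mlc", "toy", vol_shape = env$phantom$grid_shape,
                           n_cp = env$arc$n_cp, machine = mach, seed = 1)
  mu_net <- build_network("mu", "toy", vol_shape = env$phantom$grid_shape,
                          n_cp = env$arc$n_cp, machine = mach, seed = 2)
  set.seed(31)
  ep <- run_mlc_episode(env, plan, mlc_net, "train")
  expect_length(ep$traj$rewards, env$arc$n_cp)  # one step per CP
  expect_equal(ep$traj$dones, c(rep(0, env$arc$n_cp - 1), 1))
  expect_equal(sum(ep$traj$rewards), ep$v_start - ep$v_end, tolerance = 1e-10)
  ep2 <- run_mu_episode(env, ep$plan, mu_net, 8, "train")
  expect_length(ep2$traj$rewards, 8)
  expect_equal(sum(ep2$traj$rewards), ep2$v_start - ep2$v_end, tolerance = 1e-10)
  expect_equal(formals(run_mu_episode)$steps, 8)  # default refinement depth
})

test_that("a policy replaying the baseline apertures is a no-op episode", {
  env <- toy_env(1)
  demo <- generate_expert_demos(env$phantom, env$arc, env$machine)
  plan <- expert_plan(demo, env$arc, env$machine)
  # constant policy emitting CP 1's own apertures on a one-CP arc
  arc1 <- list(cp_angles = env$arc$cp_angles[1], spacing_deg = 360, gap = NULL,
               gap_mode = "open", n_cp = 1L)
  class(arc1) <- "vmat_arc"
  plan1 <- new_plan(arc1, plan$leaves[1, , drop = FALSE], plan$mu[1],
                    env$machine)
  env1 <- plan_env(env$phantom, arc1, env$machine, bank = local({
    b <- env$bank; b$angles <- b$angles[1]; b$tensors <- b$tensors[1]; b
  }))
  pol <- const_policy(plan$leaves[1, ])
  ep <- run_mlc_episode(env1, plan1, pol, "infer")
  expect_equal(ep$traj$rewards, 0)
  expect_identical(ep$plan$leaves, plan1$leaves)
})

test_that("behavioral cloning reduces the imitation loss on a fixed seed", {
  env <- toy_env(1)
  demo <- generate_expert_demos(env$phantom, env$arc, env$machine)
  net <- build_network("mlc", "toy", vol_shape = env$phantom$grid_shape,
                       n_cp = env$arc$n_cp, machine = env$machine, seed = 5)
  set.seed(41)
  bc <- behavioral_cloning(net, list(demo), list(env), epochs = 12, lr = 1e-3)
  expect_length(bc$loss_curve, 12)
  expect_lt(bc$loss_curve[12], bc$loss_curve[1])
})

test_that("baseline plans are replaced only on strict improvement", {
  env <- toy_env(1)
  demo <- generate_expert_demos(env$phantom, env$arc, env$machine)
  cfg <- train_config(iterations = 2, il_epochs = 2, seed = 3)
  tr <- train(list(env), list(demo), cfg)
  expect_equal(nrow(tr$log), 2)           # one log entry per iteration
  # the tracked baseline objective never increases across iterations
  expect_true(all(diff(c(tr$initial_objective, tr$log$mean_objective)) <= 1e-12))
  expect_s3_class(tr, "vmat_training")
})

test_that("inference respects the outer-pass cap and monotone acceptance", {
  env <- toy_env(1)
  demo <- generate_expert_demos(env$phantom, env$arc, env$machine)
  cfg <- train_config(iterations = 1, il_epochs = 2, seed = 7)
  tr <- train(list(env), list(demo), cfg)
  expect_equal(formals(train_config)$infer_cap, 8)
  res <- infer(env, tr$mlc_net, tr$mu_net, cfg)
  expect_lte(res$passes, cfg$infer_cap)
  # returned plan is deliverable and no worse than the first accepted pass
  expect_equal(nrow(check_deliverability(res$plan, env$machine)), 0)
  expect_s3_class(res$objective, "vmat_objective")
})
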