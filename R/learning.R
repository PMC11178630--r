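# Policy learning: supervised behavioural cloning of expert
# demonstrations, and proximal policy optimisation with a clipped
# surrogate, a value-function loss and an entropy bonus,
#   L = E[ L_clip(theta) - c1 L_vf(w) + c2 H(pi_theta) ],
# maximised with Adam. Gradients are exact and hand-derived; the networks
# are small enough that no autodiff framework is needed. Advantages use
# generalized advantage estimation.

#' Imitation-learning configuration
#'
#' @param epochs training epochs (1000 default).
#' @param learning_rate Adam learning rate (5e-4 default).
#' @param batch_size minibatch size; `NULL` = full batch.
#' @param seed integer seed for shuffling.
#' @return a list of class `il_config`.
#' @export
il_config <- function(epochs = 1000L, learning_rate = 5e-4,
                      batch_size = NULL, seed = 1L) {
  stopifnot(epochs >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "il_config")
}

#' PPO configuration
#'
#' @param discount discount factor gamma in (0, 1].
#' @param gae_lambda generalized-advantage-estimation lambda.
#' @param clip clip range epsilon (> 0).
#' @param c1 value-loss weight; `c2` entropy-bonus weight (>= 0).
#' @param c2 entropy-bonus weight.
#' @param learning_rate Adam learning rate (5e-5 default; a low rate gives
#'   the most stable training-reward convergence).
#' @param episodes total training episodes; the desk-scale default is
#'   2000, a full training run uses many more.
#' @param rollout_episodes episodes collected per policy update.
#' @param n_epochs optimisation epochs per collected rollout.
#' @param minibatch_size minibatch size within each epoch.
#' @param validation_interval evaluate on validation cases every this many
#'   episodes and checkpoint when the mean episode reward improves.
#' @param max_steps episode cap passed to the environment.
#' @param seed root seed for initialisation, action sampling and episode
#'   streams.
#' @return a list of class `ppo_config`.
#' @export
ppo_config <- function(discount = 0.99, gae_lambda = 0.95, clip = 0.2,
                       c1 = 0.5, c2 = 0.01, learning_rate = 5e-5,
                       episodes = 2000L, rollout_episodes = 10L,
                       n_epochs = 10L, minibatch_size = 64L,
                       validation_interval = 100L, max_steps = 20L,
                       seed = 1L) {
  stopifnot(discount > 0, discount <= 1, clip > 0, c1 >= 0, c2 >= 0)
  structure(list(discount = discount, gae_lambda = gae_lambda, clip = clip,
                 c1 = c1, c2 = c2, learning_rate = learning_rate,
                 episodes = as.integer(episodes),
                 rollout_episodes = as.integer(rollout_episodes),
                 n_epochs = as.integer(n_epochs),
                 minibatch_size = as.integer(minibatch_size),
                 validation_interval = as.integer(validation_interval),
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed)),
            class = "ppo_config")
}

demo_features <- function(demos) {
  X <- t(vapply(demos$observations, encode_obs,
                numeric(length(encode_obs(demos$observations[[1]])))))
  A <- demos$actions
  storage.mode(A) <- "double"
  list(X = X, A = A)
}

#' Behavioural cloning of expert demonstrations
#'
#' Minimises the mean squared error `(1/n) sum (a_d - a_pred)^2` between
#' demonstrated actions and the actor's mean actions with Adam.
#'
#' @param demos a `demo_dataset` (see [plan_to_demos()], [merge_demos()]).
#' @param model a `policy_model`.
#' @param cfg an [il_config()].
#' @return the trained `policy_model`, with a `loss_history` attribute
#'   (numeric, one entry per epoch).
#' @export
behavioural_cloning <- function(demos, model, cfg = il_config()) {
  if (length(demos$observations) == 0L) stop("empty demonstration set")
  df <- demo_features(demos)
  X <- df$X; A <- df$A
  n <- nrow(X)
  params <- list(actor = model$actor)
  state <- adam_init(params)
  losses <- numeric(cfg$epochs)
  bs <- cfg$batch_size %||% n
  t <- 0L
  with_local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      ep_loss <- 0
      for (start in seq(1, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1, n)]
        Xb <- X[rows, , drop = FALSE]
        Ab <- A[rows, , drop = FALSE]
        am <- actor_mean(model, Xb)
        err <- am$mu - Ab
        loss <- sum(err^2) / nrow(Xb)
        if (!is.finite(loss)) stop("non-finite imitation loss; aborting")
        ep_loss <- ep_loss + loss * nrow(Xb) / n
        dMu <- 2 * err / nrow(Xb)
        dY <- sweep(dMu, 2, model$act_scale, `*`) * (1 - am$Tn^2)
        grads <- list(actor = mlp_backward(model$actor, Xb, am$fwd, dY))
        t <- t + 1L
        res <- adam_step(params, grads, state, t, cfg$learning_rate)
        params <- res$params
        state <- res$state
        model$actor <- params$actor
      }
      losses[ep] <- ep_loss
    }
  })
  attr(model, "loss_history") <- losses
  model
}

# Discounted GAE for one episode. v: values, r: rewards; terminal value 0
# (episodes end by hit-count success or the time cap, both treated as
# absorbing).
gae_advantages <- function(r, v, gamma, lambda) {
  T <- length(r)
  adv <- numeric(T)
  next_v <- 0
  next_adv <- 0
  for (t in T:1) {
    delta <- r[t] + gamma * next_v - v[t]
    adv[t] <- delta + gamma * lambda * next_adv
    next_v <- v[t]
    next_adv <- adv[t]
  }
  adv
}

collect_rollout <- function(envs, cases, model, cfg, episode_seeds) {
  X_all <- list(); A_all <- list(); logp_all <- list()
  adv_all <- list(); ret_all <- list()
  totals <- numeric(length(episode_seeds))
  sd_vec <- exp(model$log_std)
  for (k in seq_along(episode_seeds)) {
    ci <- sample.int(length(cases), 1L)
    e <- envs[[ci]]
    obs <- env_reset(e, episode_seeds[k])
    xs <- list(); as <- list(); lps <- c(); rs <- c(); vs <- c()
    repeat {
      x <- encode_obs(obs)
      xm <- matrix(x, nrow = 1)
      mu <- actor_mean(model, xm)$mu[1, ]
      a <- mu + stats::rnorm(3, 0, sd_vec)
      lp <- gaussian_logp(matrix(a, 1), matrix(mu, 1), model$log_std)
      v <- critic_value(model, xm)$v
      out <- env_step(e, a)
      xs[[length(xs) + 1L]] <- x
      as[[length(as) + 1L]] <- a
      lps <- c(lps, lp); rs <- c(rs, out$reward); vs <- c(vs, v)
      obs <- out$observation
      if (out$done) break
    }
    adv <- gae_advantages(rs, vs, cfg$discount, cfg$gae_lambda)
    X_all[[k]] <- do.call(rbind, xs)
    A_all[[k]] <- do.call(rbind, as)
    logp_all[[k]] <- lps
    adv_all[[k]] <- adv
    ret_all[[k]] <- adv + vs
    totals[k] <- sum(rs)
  }
  list(X = do.call(rbind, X_all), A = do.call(rbind, A_all),
       logp = unlist(logp_all), adv = unlist(adv_all),
       ret = unlist(ret_all), mean_reward = mean(totals))
}

#' Clipped PPO surrogate objective
#'
#' Per-sample contribution `min(ratio * adv, clip(ratio, 1-eps, 1+eps) * adv)`
#' and the mask of samples whose unclipped term is active (the only ones
#' through which the policy gradient flows).
#'
#' @param ratio importance ratios `pi_new / pi_old`.
#' @param adv advantages.
#' @param clip clip range epsilon.
#' @return list with `value` (per-sample surrogate) and `active` (logical).
#' @export
ppo_surrogate <- function(ratio, adv, clip) {
  clipped <- clamp(ratio, 1 - clip, 1 + clip)
  list(value = pmin(ratio * adv, clipped * adv),
       active = (adv >= 0 & ratio < 1 + clip) | (adv < 0 & ratio > 1 - clip))
}

ppo_update <- function(model, batch, cfg, params, state, t) {
  n <- nrow(batch$X)
  adv <- batch$adv
  if (stats::sd(adv) > 1e-8) adv <- (adv - mean(adv)) / stats::sd(adv)
  idx_all <- sample.int(n)
  bs <- min(cfg$minibatch_size, n)
  for (start in seq(1, n, by = bs)) {
    rows <- idx_all[start:min(start + bs - 1, n)]
    Xb <- batch$X[rows, , drop = FALSE]
    Ab <- batch$A[rows, , drop = FALSE]
    advb <- adv[rows]
    retb <- batch$ret[rows]
    lp_old <- batch$logp[rows]
    m <- length(rows)
    am <- actor_mean(model, Xb)
    sd_vec <- exp(model$log_std)
    lp_new <- gaussian_logp(Ab, am$mu, model$log_std)
    ratio <- exp(lp_new - lp_old)
    if (!all(is.finite(ratio))) return(NULL)
    # gradient flows only where the unclipped surrogate term is active
    surr <- ppo_surrogate(ratio, advb, cfg$clip)
    w <- ratio * advb * surr$active / m     # d(objective)/d(logp)
    Z <- sweep(Ab - am$mu, 2, sd_vec^2, `/`)
    dMu <- -Z * w                            # gradient of the LOSS (-J)
    dY_actor <- sweep(dMu, 2, model$act_scale, `*`) * (1 - am$Tn^2)
    g_actor <- mlp_backward(model$actor, Xb, am$fwd, dY_actor)
    # log-std gradient: surrogate term + entropy bonus c2 * H
    dlp_dls <- sweep((Ab - am$mu)^2, 2, sd_vec^2, `/`) - 1
    g_log_std <- -colSums(dlp_dls * w) - cfg$c2
    # value loss c1 * mean (v - ret)^2
    cv <- critic_value(model, Xb)
    verr <- cv$v - retb
    if (!all(is.finite(verr))) return(NULL)
    dV <- matrix(cfg$c1 * 2 * verr / m, ncol = 1)
    g_critic <- mlp_backward(model$critic, Xb, cv$fwd, dV)
    grads <- list(actor = g_actor, critic = g_critic, log_std = g_log_std)
    t <- t + 1L
    res <- adam_step(params, grads, state, t, cfg$learning_rate)
    params <- res$params
    state <- res$state
    model$actor <- params$actor
    model$critic <- params$critic
    model$log_std <- clamp(params$log_std, log(0.05), log(5))
    params$log_std <- model$log_std
  }
  list(model = model, params = params, state = state, t = t)
}

#' Train a policy with proximal policy optimisation
#'
#' Each episode interacts with a newly sampled training case. Every
#' `validation_interval` episodes the current policy is evaluated
#' (deterministically) on the validation cases and the model is
#' checkpointed when the mean validation episode reward strictly improves.
#' Supports warm-starting from a behavioural-cloning model (pass the
#' cloned model) or random initialisation.
#'
#' @param train_cases,val_cases lists of `patient_case`.
#' @param model a `policy_model` (optionally pre-trained by
#'   [behavioural_cloning()]).
#' @param cfg a [ppo_config()].
#' @param config an [env_config()] describing the training environment.
#' @return list of class `ppo_result`: `model` (best checkpoint), `log`
#'   (data.frame episode, mean_train_reward, val_reward), `checkpoints`
#'   (data.frame episode, val_reward), `final_model`.
#' @export
ppo_train <- function(train_cases, val_cases, model,
                      cfg = ppo_config(), config = env_config()) {
  if (length(train_cases) == 0L || length(val_cases) == 0L) {
    stop("need nonempty training and validation case lists")
  }
  config$max_steps <- cfg$max_steps
  envs <- lapply(train_cases, biopsy_env, config = config)
  params <- list(actor = model$actor, critic = model$critic,
                 log_std = model$log_std)
  state <- adam_init(params)
  t <- 0L
  ep_done <- 0L
  best_val <- -Inf
  best_model <- model
  log_rows <- list()
  ckpt_rows <- list()
  next_val_at <- cfg$validation_interval
  set.seed(cfg$seed)
  val0 <- validation_reward(model, val_cases, config, cfg$seed)
  while (ep_done < cfg$episodes) {
    n_ep <- min(cfg$rollout_episodes, cfg$episodes - ep_done)
    seeds <- vapply(seq_len(n_ep), function(k) derive_seed(cfg$seed, ep_done + k),
                    integer(1))
    batch <- collect_rollout(envs, train_cases, model, cfg, seeds)
    ep_done <- ep_done + n_ep
    if (cfg$learning_rate > 0) {
      for (epoch in seq_len(cfg$n_epochs)) {
        res <- ppo_update(model, batch, cfg, params, state, t)
        if (is.null(res)) {
          warning("non-finite PPO loss; returning last good checkpoint")
          return(finish_ppo(best_model, model, log_rows, ckpt_rows, val0))
        }
        model <- res$model; params <- res$params
        state <- res$state; t <- res$t
      }
    }
    val_r <- NA_real_
    if (ep_done >= next_val_at || ep_done >= cfg$episodes) {
      val_r <- validation_reward(model, val_cases, config, cfg$seed)
      while (next_val_at <= ep_done) next_val_at <- next_val_at + cfg$validation_interval
      if (is.finite(val_r) && val_r > best_val) {
        best_val <- val_r
        best_model <- model
        ckpt_rows[[length(ckpt_rows) + 1L]] <-
          data.frame(episode = ep_done, val_reward = val_r)
      }
    }
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(episode = ep_done, mean_train_reward = batch$mean_reward,
                 val_reward = val_r)
  }
  finish_ppo(best_model, model, log_rows, ckpt_rows, val0)
}

finish_ppo <- function(best_model, final_model, log_rows, ckpt_rows, val0) {
  structure(list(model = best_model, final_model = final_model,
                 log = do.call(rbind, log_rows),
                 checkpoints = if (length(ckpt_rows))
                   do.call(rbind, ckpt_rows) else
                     data.frame(episode = integer(), val_reward = numeric()),
                 initial_val_reward = val0),
            class = "ppo_result")
}

# Mean deterministic episode reward over validation cases.
validation_reward <- function(model, val_cases, config, seed) {
  pol <- model_policy(model, deterministic = TRUE)
  mean(vapply(seq_along(val_cases), function(i) {
    run_episode(pol, val_cases[[i]], config,
                seed = derive_seed(seed, 900000L + i))$total_reward
  }, numeric(1)))
}

#' @export
print.ppo_result <- function(x, ...) {
  cat(sprintf("ppo_result: %d episodes, %d checkpoints, best val reward %s\n",
              max(x$log$episode),
              nrow(x$checkpoints),
              if (nrow(x$checkpoints)) format(max(x$checkpoints$val_reward))
              else "none"))
  invisible(x)
}

#' Evaluate a policy on a set of cases
#'
#' Runs episodes for every case under one mismatch setting and aggregates
#' the clinical outcome metrics into a [metrics_report()].
#'
#' @param policy a policy object, bare function or `policy_model`.
#' @param cases list of `patient_case`.
#' @param config an [env_config()] (carries the mismatch setting).
#' @param episodes_per_case episodes per case; records are pooled within a
#'   case before computing its metrics.
#' @param seed root seed; episode seeds are derived per (case, episode).
#' @param label optional mismatch label stored on the report.
#' @return a `metrics_report`.
#' @export
evaluate_policy <- function(policy, cases, config = env_config(),
                            episodes_per_case = 1L, seed = 1L,
                            label = NA_character_) {
  if (length(cases) == 0L) stop("no cases to evaluate")
  if (inherits(policy, "policy_model")) policy <- model_policy(policy)
  episodes <- list()
  for (i in seq_along(cases)) {
    env <- biopsy_env(cases[[i]], config)
    for (k in seq_len(episodes_per_case)) {
      episodes[[length(episodes) + 1L]] <-
        run_episode(policy, cases[[i]], config,
                    seed = derive_seed(seed, i * 1000L + k), env = env)
    }
  }
  metrics_report(episodes, label = label)
}
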