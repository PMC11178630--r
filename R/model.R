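# Policy and value networks. Both are small one-hidden-layer perceptrons
# (tanh hidden units) of identical architecture, operating on a compact
# encoding of the five-channel observation: per-channel axis-marginal
# occupancy profiles at the configured observation shape, plus the current
# grid node, step fraction and hit fraction. Marginal profiles retain the
# in-plane localisation the sampling task needs (the lesion centroid is a
# linear functional of them) while keeping the parameter count small
# enough for exact, dependency-free gradients. The actor outputs a
# Gaussian action distribution: a bounded mean (scaled tanh, so dx and dy
# stay in (-10, 10) and dz in (-1, 1)) with a state-independent learnable
# log standard deviation per component.

# Map a native-resolution marginal onto `m` bins (nearest source index);
# normalised to an occupancy fraction so features are scale-free in [0, 1].
resample_marginal <- function(marg, m, n_plane) {
  n <- length(marg)
  if (n == m) return(marg / n_plane)
  idx <- clamp(round((seq_len(m) - 0.5) / m * n + 0.5), 1L, n)
  marg[idx] / n_plane
}

# Centroid (in grid-pitch units relative to the template centre) and
# occupancy of one channel, from its axis marginals. Empty channels
# contribute zeros.
channel_summary <- function(m, mask, grid) {
  tot <- sum(m$x)
  if (tot == 0) return(numeric(7))
  sp <- mask$spacing
  o <- mask$origin
  n <- c(length(m$x), length(m$y), length(m$z))
  cen <- c(sum(m$x * (o[1] + (seq_len(n[1]) - 1) * sp[1])),
           sum(m$y * (o[2] + (seq_len(n[2]) - 1) * sp[2])),
           sum(m$z * (o[3] + (seq_len(n[3]) - 1) * sp[3]))) / tot
  rel <- (cen[1:2] - grid$centre_mm) / grid$pitch_mm
  zmid <- o[3] + (n[3] - 1) * sp[3] / 2
  c(rel / 6,                      # in-plane centroid, grid units
    sin(pi * (rel - floor(rel))), # fractional offset within a grid cell
    (cen[3] - zmid) / (n[3] * sp[3] / 2),
    tot / prod(n)^(2 / 3),        # occupancy scale
    1)                            # channel nonempty flag
}

#' Encode an observation into the policy network's feature vector
#'
#' Per channel: axis-marginal occupancy profiles at the observation shape
#' plus summary features (centroid relative to the grid centre in pitch
#' units, its within-cell fractional offset, needle-axis centroid and
#' occupancy), followed by the current grid node, step fraction and hit
#' fraction.
#'
#' @param obs a `biopsy_observation`.
#' @return numeric feature vector; length depends only on the
#'   environment's `obs_shape`.
#' @export
encode_obs <- function(obs) {
  shp <- as.integer(obs$obs_shape)
  d <- dim(obs$channels$P$voxels)
  feats <- unlist(lapply(obs$marginals, function(m) {
    c(resample_marginal(m$x, shp[1], d[2] * d[3]),
      resample_marginal(m$y, shp[2], d[1] * d[3]),
      resample_marginal(m$z, shp[3], d[1] * d[2]))
  }), use.names = FALSE)
  sums <- unlist(lapply(obs$marginals, channel_summary,
                        mask = obs$channels$P, grid = obs$grid),
                 use.names = FALSE)
  c(feats, sums,
    (obs$node[1] - (obs$grid$n_rows + 1) / 2) / 6,
    (obs$node[2] - (obs$grid$n_cols + 1) / 2) / 6,
    obs$step / obs$max_steps,
    obs$hits / obs$target_hits)
}

#' Number of encoder features for an observation shape
#' @param obs_shape integer length-3.
#' @return integer feature count.
#' @export
n_features <- function(obs_shape = c(64L, 64L, 32L)) {
  5L * sum(as.integer(obs_shape)) + 5L * 7L + 4L
}

mlp_init <- function(n_in, n_hidden, n_out, gain = 1) {
  # scaled uniform (Glorot-style) initialisation
  lim1 <- sqrt(6 / (n_in + n_hidden))
  lim2 <- sqrt(6 / (n_hidden + n_out)) * gain
  list(W1 = matrix(stats::runif(n_in * n_hidden, -lim1, lim1), n_in, n_hidden),
       b1 = rep(0, n_hidden),
       W2 = matrix(stats::runif(n_hidden * n_out, -lim2, lim2), n_hidden, n_out),
       b2 = rep(0, n_out))
}

# X: n x n_in. Returns hidden activations and linear outputs.
mlp_forward <- function(net, X) {
  H <- tanh(sweep(X %*% net$W1, 2, net$b1, `+`))
  Y <- sweep(H %*% net$W2, 2, net$b2, `+`)
  list(H = H, Y = Y)
}

# Backprop given dL/dY; returns gradients and dL/dX is not needed.
mlp_backward <- function(net, X, fwd, dY) {
  gW2 <- crossprod(fwd$H, dY)
  gb2 <- colSums(dY)
  dH <- (dY %*% t(net$W2)) * (1 - fwd$H^2)
  gW1 <- crossprod(X, dH)
  gb1 <- colSums(dH)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Initialise a policy model
#'
#' @param n_feat encoder feature count, see [n_features()].
#' @param hidden hidden units per network (policy and value networks share
#'   the architecture).
#' @param init_log_std initial log standard deviations of the Gaussian
#'   action head `(dx, dy, dz)`; the defaults give wide in-plane
#'   exploration (about 3 grid steps) and a firing channel that crosses
#'   the decision thresholds often.
#' @param seed integer initialisation seed.
#' @return an object of class `policy_model`.
#' @export
policy_model <- function(n_feat = n_features(), hidden = 64L,
                         init_log_std = log(c(3, 3, 0.6)), seed = 1L) {
  with_local_seed(seed, {
    actor <- mlp_init(n_feat, hidden, 3L, gain = 0.1)
    critic <- mlp_init(n_feat, hidden, 1L)
  })
  structure(list(actor = actor, critic = critic,
                 log_std = as.numeric(init_log_std),
                 act_scale = c(10, 10, 1),
                 n_feat = n_feat, hidden = as.integer(hidden)),
            class = "policy_model")
}

#' @export
print.policy_model <- function(x, ...) {
  cat(sprintf("policy_model: %d features -> %d tanh units; sigma = (%.2f, %.2f, %.2f)\n",
              x$n_feat, x$hidden, exp(x$log_std[1]), exp(x$log_std[2]),
              exp(x$log_std[3])))
  invisible(x)
}

# Forward pass of the actor: bounded action means. X is n x n_feat.
actor_mean <- function(model, X) {
  fwd <- mlp_forward(model$actor, X)
  Tn <- tanh(fwd$Y)
  mu <- sweep(Tn, 2, model$act_scale, `*`)
  list(mu = mu, fwd = fwd, Tn = Tn)
}

critic_value <- function(model, X) {
  fwd <- mlp_forward(model$critic, X)
  list(v = fwd$Y[, 1], fwd = fwd)
}

# Log-density of actions under the diagonal Gaussian policy.
gaussian_logp <- function(a, mu, log_std) {
  sd <- exp(log_std)
  z <- sweep(a - mu, 2, sd, `/`)
  -0.5 * rowSums(z^2) - sum(log_std) - 1.5 * log(2 * pi)
}

#' Sample or take the mean action for one observation
#'
#' @param model a `policy_model`.
#' @param obs a `biopsy_observation` (or a precomputed feature vector).
#' @param deterministic take the mean action instead of sampling.
#' @return numeric `(dx, dy, dz)`.
#' @export
model_action <- function(model, obs, deterministic = TRUE) {
  x <- if (is.numeric(obs)) obs else encode_obs(obs)
  mu <- actor_mean(model, matrix(x, nrow = 1))$mu[1, ]
  if (deterministic) return(mu)
  mu + stats::rnorm(3, 0, exp(model$log_std))
}

#' Wrap a model as a policy object
#'
#' @param model a `policy_model`.
#' @param deterministic use mean actions (evaluation) or sample
#'   (exploration).
#' @return a policy object for [run_episode()].
#' @export
model_policy <- function(model, deterministic = TRUE) {
  list(reset = function() invisible(NULL),
       act = function(obs) model_action(model, obs, deterministic))
}

# ---- Adam optimiser over a nested list of parameter arrays ----

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

# params/grads: nested named lists of numeric arrays with identical
# structure. Returns list(params, state, t).
adam_step <- function(params, grads, state, t, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(names(p)) && !("m" %in% names(s))) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      upd(p, g, s)
    }
  }
  r <- walk(params, grads, state)
  list(params = r$p, state = r$s)
}
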