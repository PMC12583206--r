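# Generative / inference core. Every forward below is written against the
# autodiff ops, so the same code path serves numeric prediction (plain
# matrices in) and training (tape variables in).

LOG2PI <- log(2 * pi)

# ---- batching -------------------------------------------------------------

# Pack trajectories into padded per-timestep matrices. Padding rows are zero
# and carry valid = 0; treatment indices are padded with 1 (never used).
make_batch <- function(trajectories, params) {
  B <- length(trajectories)
  Tl <- vapply(trajectories, function(tr) nrow(tr$x), 1L)
  Tm <- max(Tl)
  onto <- params$ontology
  X <- Y <- M <- vector("list", Tm)
  Aidx <- matrix(1L, Tm, B)
  valid <- matrix(0, Tm, B)
  for (t in seq_len(Tm)) {
    X[[t]] <- matrix(0, B, params$d_x)
    Y[[t]] <- matrix(0, B, params$k)
    M[[t]] <- matrix(0, B, params$k)
  }
  for (i in seq_len(B)) {
    tr <- trajectories[[i]]
    ai <- treatment_index(tr$a, onto)
    for (t in seq_len(Tl[i])) {
      X[[t]][i, ] <- tr$x[t, ]
      Y[[t]][i, ] <- tr$y[t, ] * tr$m[t, ]  # zero-impute masked outcomes
      M[[t]][i, ] <- tr$m[t, ]
      Aidx[t, i] <- ai[t]
      valid[t, i] <- 1
    }
  }
  list(B = B, T_max = Tm, T_len = Tl, X = X, Y = Y, M = M,
       Aidx = Aidx, valid = valid,
       stages = vapply(trajectories, function(tr)
         if (is.null(tr$stage)) NA_character_ else tr$stage, ""))
}

# ---- embeddings and transition -------------------------------------------

# batched treatment embedding lookup; optionally gated by class attention
transition_inputs <- function(Z, aidx, gp, params, Evocab = NULL) {
  if (is.null(Evocab)) Evocab <- vocab_embeddings(gp, params$class_idx)
  Emb <- ad_rows(Evocab, aidx)
  if (isTRUE(params$gate_attention)) {
    alpha <- attention_rows(Z, gp, params)
    onehot <- matrix(0, length(aidx), nrow(vof(gp$E_sym)))
    onehot[cbind(seq_along(aidx), params$class_idx[aidx])] <- 1
    w <- ad_rowsums(ad_mul(alpha, onehot))
    Emb <- ad_mulcol(Emb, w)
  }
  Emb
}

# class attention distribution for a batch of latents (rows)
attention_rows <- function(Z, gp, params) {
  Zp <- if (params$d_z != params$m) ad_mm(Z, gp$P_attn) else Z
  ad_softmax_rows(ad_mm(Zp, ad_transpose(gp$E_sym)))
}

# f_theta(z, e(a)): identity + linear pathway + tanh-MLP residual
forward_transition <- function(Z, aidx, gp, params, Evocab = NULL) {
  Emb <- transition_inputs(Z, aidx, gp, params, Evocab)
  U <- ad_cbind(Z, Emb)
  lin <- ad_addrow(ad_mm(U, gp$W_lin), gp$b_lin)
  res <- ad_addrow(ad_mm(ad_tanh(ad_addrow(ad_mm(U, gp$W_h1), gp$b_h1)), gp$W_h2),
                   gp$b_h2)
  ad_add(Z, ad_add(lin, res))
}

# ---- decoders -------------------------------------------------------------

forward_decode <- function(Z, gp, params) {
  zy <- switch(params$y_act, relu = ad_relu(Z), identity = Z)
  zx <- switch(params$x_act, tanh = ad_tanh(Z), identity = Z)
  list(y_mean = ad_addrow(ad_mm(zy, gp$W_y), gp$b_y),
       y_var = ad_add(ad_softplus(ad_addrow(ad_mm(Z, gp$W_v), gp$b_v)),
                      params$var_floor_y),
       x_hat = ad_addrow(ad_mm(zx, gp$W_x), gp$b_x))
}

# ---- encoder --------------------------------------------------------------

# GRU over [x_t, y_t * m_t, m_t, e(a_t)], causal by construction; heads give
# a diagonal Gaussian posterior per timestep.
forward_encoder <- function(batch, gp, params, Evocab = NULL) {
  if (is.null(Evocab)) Evocab <- vocab_embeddings(gp, params$class_idx)
  B <- batch$B
  h <- matrix(0, B, params$d_h)
  mu <- var <- vector("list", batch$T_max)
  for (t in seq_len(batch$T_max)) {
    Emb <- ad_rows(Evocab, batch$Aidx[t, ])
    u <- ad_cbind(batch$X[[t]], batch$Y[[t]], batch$M[[t]], Emb)
    g <- ad_sigmoid(ad_addrow(ad_add(ad_mm(u, gp$W_g), ad_mm(h, gp$U_g)), gp$b_g))
    r <- ad_sigmoid(ad_addrow(ad_add(ad_mm(u, gp$W_r), ad_mm(h, gp$U_r)), gp$b_r))
    n <- ad_tanh(ad_addrow(ad_add(ad_mm(u, gp$W_n), ad_mm(ad_mul(r, h), gp$U_n)),
                           gp$b_n))
    h <- ad_add(ad_mul(g, h), ad_mul(ad_sub(1, g), n))
    mu[[t]] <- ad_addrow(ad_mm(h, gp$W_mu), gp$b_mu)
    var[[t]] <- ad_add(ad_softplus(ad_addrow(ad_mm(h, gp$W_lv), gp$b_lv)),
                       params$var_floor_q)
  }
  list(mu = mu, var = var)
}

# ---- Gaussian log-densities (row-wise) ------------------------------------

# sum_j log N(x_j; mean_j, var_j) per row; Var may be scalar or full shape
gauss_ll_rows <- function(X, Mean, Var) {
  q <- ad_div(ad_square(ad_sub(X, Mean)), Var)
  term <- ad_add(ad_add(LOG2PI, ad_log(Var)), q) # scalar Var broadcasts
  ad_mul(-0.5, ad_rowsums(term))
}

masked_gauss_ll_rows <- function(Y, M, Mean, Var) {
  term <- ad_add(ad_add(LOG2PI, ad_log(Var)), ad_div(ad_square(ad_sub(Y, Mean)), Var))
  ad_mul(-0.5, ad_rowsums(ad_mul(M, term)))
}

# expand a length-d (advar) vector to B x d
expand_rows <- function(v, B, d) ad_addrow(matrix(0, B, d), v)

# ---- batched ELBO ---------------------------------------------------------

# Single-sample reparameterised ELBO over a padded batch; returns a B x 1
# column of per-patient ELBO values. `eps` is a list over t of B x d_z
# standard-normal draws. transition_mode "first_order" uses the stochastic
# one-step mean f_theta; "second_order" uses the inertial mean
# z_{t-1} + gamma (f(z_{t-1}, a_{t-1}) - f(z_{t-2}, a_{t-2})) from t >= 3.
elbo_rows <- function(batch, gp, params, eps,
                      transition_mode = c("first_order", "second_order")) {
  transition_mode <- match.arg(transition_mode)
  B <- batch$B; d_z <- params$d_z
  Evocab <- vocab_embeddings(gp, params$class_idx)
  enc <- forward_encoder(batch, gp, params, Evocab)
  sig2 <- ad_square(sigma_of(gp))
  xvar <- xvar_of(gp)
  var0 <- ad_add(ad_softplus(gp$lv0), params$var_floor_q)

  Z <- f_prev <- vector("list", batch$T_max)
  total <- matrix(0, B, 1L)
  for (t in seq_len(batch$T_max)) {
    vcol <- matrix(batch$valid[t, ], ncol = 1L)
    Z[[t]] <- ad_add(enc$mu[[t]], ad_mul(ad_sqrt(enc$var[[t]]), eps[[t]]))
    dec <- forward_decode(Z[[t]], gp, params)
    ll_x <- gauss_ll_rows(batch$X[[t]], dec$x_hat, xvar)
    ll_y <- masked_gauss_ll_rows(batch$Y[[t]], batch$M[[t]], dec$y_mean, dec$y_var)
    ent <- ad_neg(gauss_ll_rows(Z[[t]], enc$mu[[t]], enc$var[[t]]))
    step <- ad_add(ad_add(ll_x, ll_y), ent)
    if (t == 1L) {
      prior <- gauss_ll_rows(Z[[1]], expand_rows(gp$mu0, B, d_z),
                             expand_rows(var0, B, d_z))
      step <- ad_add(step, prior)
    } else {
      f1 <- forward_transition(Z[[t - 1L]], batch$Aidx[t - 1L, ], gp, params, Evocab)
      mean_t <- if (transition_mode == "second_order" && t >= 3L) {
        ad_add(Z[[t - 1L]],
               ad_mul(gp$gamma, ad_sub(f1, f_prev[[t - 1L]])))
      } else f1
      f_prev[[t]] <- f1
      step <- ad_add(step, gauss_ll_rows(Z[[t]], mean_t, sig2))
    }
    total <- ad_add(total, ad_mul(step, vcol))
  }
  list(elbo = total, enc = enc, Z = Z, Evocab = Evocab)
}

# ---- public operations ----------------------------------------------------

#' Posterior over latent states for one trajectory
#'
#' Runs the gated-recurrent recognition network over the history
#' `H_t = {(x_s, a_s, y_s, m_s)}_{s<=t}` and returns the per-timestep
#' diagonal-Gaussian posterior. Masked outcome entries are zero-imputed and
#' the mask itself is part of the encoder input, so the posterior depends on
#' observed history only, and on nothing after `t` (causal).
#'
#' @param trajectory a trajectory list (`x`, `a`, `y`, `m`).
#' @param params a `td_params`.
#' @return `list(mean, var)`, both T x d_z; variances strictly positive.
#' @export
encode_posterior <- function(trajectory, params) {
  if (is.null(trajectory$x) || nrow(trajectory$x) == 0L)
    stop("empty trajectory (T = 0)")
  batch <- make_batch(list(trajectory), params)
  enc <- forward_encoder(batch, params$gen, params)
  list(mean = do.call(rbind, lapply(enc$mu, function(m) m[1, ])),
       var = do.call(rbind, lapply(enc$var, function(v) v[1, ])))
}

#' Latent transition mean
#'
#' `f_theta(z, e(a))`: the deterministic mean of the one-step latent update;
#' the stochastic step adds `N(0, sigma^2 I)` noise.
#'
#' @param z latent vector (length d_z) or matrix of row vectors.
#' @param a treatment id (single, or one per row of `z`).
#' @param params a `td_params`.
#' @export
transition_mean <- function(z, a, params) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  aidx <- treatment_index(rep_len(a, nrow(Z)), params$ontology)
  out <- forward_transition(Z, aidx, params$gen, params)
  if (is.matrix(z)) out else as.vector(out)
}

#' Second-order (inertial) latent transition
#'
#' `z_t + gamma * (f_theta(z_t, e(a_t)) - f_theta(z_{t-1}, e(a_{t-1})))`:
#' the change-of-change refinement of the one-step update, encoding
#' acceleration or deceleration of the response. Needs two lags; at the first
#' step the plain first-order update applies instead.
#'
#' @param z_t,z_tm1 current and previous latent vectors.
#' @param a_t,a_tm1 current and previous treatment ids.
#' @param params a `td_params`.
#' @export
transition_second_order <- function(z_t, z_tm1, a_t, a_tm1, params) {
  gamma <- params$gen$gamma
  as.vector(z_t) + gamma * (transition_mean(z_t, a_t, params) -
                              transition_mean(z_tm1, a_tm1, params))
}

#' Decode a latent state
#'
#' Outcome mean `W_y act_y(z) + b_y`, strictly positive heteroscedastic
#' outcome variances `softplus(W_v z + b_v) + floor`, and covariate
#' reconstruction `W_x act_x(z) + b_x`.
#'
#' @param z latent vector or matrix of row vectors.
#' @param params a `td_params`.
#' @return `list(y_mean, y_var, x_hat)`.
#' @export
decode <- function(z, params) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  dec <- forward_decode(Z, params$gen, params)
  if (is.matrix(z)) dec
  else list(y_mean = as.vector(dec$y_mean), y_var = as.vector(dec$y_var),
            x_hat = as.vector(dec$x_hat))
}

#' Masked Gaussian outcome log-likelihood
#'
#' `sum_j m_j log N(y_j; mu_j, var_j)`: masked-out dimensions contribute
#' nothing, so an all-zero mask gives exactly 0.
#'
#' @param y,m outcome and 0/1 mask vectors (length k).
#' @param y_mean,y_var predictive mean and strictly positive variance.
#' @export
masked_log_likelihood <- function(y, m, y_mean, y_var) {
  stopifnot(all(y_var > 0))
  sum(m * stats::dnorm(y, mean = y_mean, sd = sqrt(y_var), log = TRUE))
}

#' Monte-Carlo evidence lower bound for one trajectory
#'
#' Reparameterised estimate of the sequential ELBO: reconstruction terms for
#' covariates and masked outcomes, the initial-state prior, transition terms
#' under the Gaussian one-step model, and the posterior entropy terms.
#' Deterministic given `seed`.
#'
#' @param trajectory a trajectory list.
#' @param params a `td_params`.
#' @param n_samples number of Monte-Carlo samples (>= 1).
#' @param seed integer seed for the noise draws.
#' @param transition_mode `"first_order"` (stochastic one-step density) or
#'   `"second_order"` (inertial mean from the third step on).
#' @return the estimate, with attributes `se` (Monte-Carlo standard error)
#'   and `samples` (per-sample values).
#' @export
elbo <- function(trajectory, params, n_samples = 100L, seed = 1L,
                 transition_mode = "first_order") {
  stopifnot(n_samples >= 1L)
  # replicate the trajectory across the batch dimension: one row per sample
  batch1 <- make_batch(list(trajectory), params)
  B <- n_samples
  batch <- batch1
  batch$B <- B
  for (t in seq_len(batch1$T_max)) {
    batch$X[[t]] <- batch1$X[[t]][rep(1L, B), , drop = FALSE]
    batch$Y[[t]] <- batch1$Y[[t]][rep(1L, B), , drop = FALSE]
    batch$M[[t]] <- batch1$M[[t]][rep(1L, B), , drop = FALSE]
  }
  batch$Aidx <- batch1$Aidx[, rep(1L, B), drop = FALSE]
  batch$valid <- batch1$valid[, rep(1L, B), drop = FALSE]
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  eps <- lapply(seq_len(batch$T_max), function(t)
    matrix(stats::rnorm(B * params$d_z), B, params$d_z))
  vals <- elbo_rows(batch, params$gen, params, eps, transition_mode)$elbo[, 1]
  est <- mean(vals)
  attr(est, "se") <- stats::sd(vals) / sqrt(B)
  attr(est, "samples") <- vals
  est
}

#' Temporal latent-path regularizer
#'
#' `sum_{t>=2} ||z_t - z_{t-1}||^2`; zero for constant paths and for T = 1.
#' @param z_path T x d_z matrix (a vector is treated as d_z = 1).
#' @export
temporal_regularizer <- function(z_path) {
  Z <- if (is.matrix(z_path)) z_path else matrix(z_path, ncol = 1L)
  if (nrow(Z) < 2L) return(0)
  sum(diff(Z)^2)
}

#' Smoothness regularizer on decoded covariates
#'
#' Same squared-difference penalty as [temporal_regularizer()], applied to the
#' decoded covariate path.
#' @param x_hat_path T x d_x matrix.
#' @export
smoothness_regularizer <- function(x_hat_path) temporal_regularizer(x_hat_path)
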