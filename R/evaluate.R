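# Model scoring: rollout prediction accuracy and calibration, counterfactual
# error against simulated twins, and ground-truth effect recovery.

#' Constant-mean baseline "model"
#'
#' Predicts the training cohort's per-dimension masked-in outcome mean with
#' its empirical SD, at every horizon. Evaluated through the same code path
#' as a fitted model.
#'
#' @param train_cohort a `td_cohort`.
#' @export
baseline_mean_model <- function(train_cohort) {
  k <- attr(train_cohort, "k")
  Y <- as.matrix(train_cohort[, ycols(train_cohort), drop = FALSE])
  M <- as.matrix(train_cohort[, mcols(train_cohort), drop = FALSE])
  mu <- vapply(seq_len(k), function(j) mean(Y[M[, j] == 1, j]), 0)
  sd_ <- vapply(seq_len(k), function(j) stats::sd(Y[M[, j] == 1, j]), 0)
  structure(list(mean = mu, sd = sd_, k = k), class = "td_baseline_mean")
}

# Shared prediction engine: one row per (patient, prediction time, outcome
# dimension) with the predictive mean/sd, the true value and its mask.
predict_table <- function(model, cohort, horizon, n_samples = 100L, seed = 1L) {
  trs <- as_trajectories(cohort)
  Tl <- vapply(trs, function(tr) nrow(tr$x), 1L)
  if (all(Tl <= horizon)) stop("horizon exceeds every trajectory")
  out <- vector("list", length(trs))

  if (inherits(model, "td_baseline_mean")) {
    for (i in seq_along(trs)) {
      tr <- trs[[i]]
      times <- seq_len(Tl[i] - horizon)
      if (!length(times)) next
      grid <- expand.grid(t_pred = times + horizon, dim = seq_len(model$k))
      out[[i]] <- tibble::tibble(patient_id = tr$patient_id,
                                 t_from = grid$t_pred - horizon,
                                 t_pred = grid$t_pred, dim = grid$dim,
                                 mean = model$mean[grid$dim],
                                 sd = model$sd[grid$dim],
                                 y = tr$y[cbind(grid$t_pred, grid$dim)],
                                 m = tr$m[cbind(grid$t_pred, grid$dim)])
    }
    return(dplyr::bind_rows(out))
  }

  params <- as_params(model)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  sig <- softplus(params$gen$sigma_raw) + 1e-4
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    times <- seq_len(Tl[i] - horizon)
    if (!length(times)) next
    post <- encode_posterior(tr, params)
    aidx <- treatment_index(tr$a, params$ontology)
    rows <- vector("list", length(times))
    for (t in times) {
      Z <- matrix(post$mean[t, ], n_samples, params$d_z, byrow = TRUE) +
        matrix(stats::rnorm(n_samples * params$d_z), n_samples) %*%
        diag(sqrt(post$var[t, ]), params$d_z)
      for (u in t:(t + horizon - 1L)) {
        Z <- forward_transition(Z, rep(aidx[u], n_samples), params$gen, params) +
          sig * matrix(stats::rnorm(n_samples * params$d_z), n_samples)
      }
      dec <- forward_decode(Z, params$gen, params)
      pm <- colMeans(dec$y_mean)
      pv <- apply(dec$y_mean, 2L, stats::var) + colMeans(dec$y_var)
      rows[[t]] <- tibble::tibble(patient_id = tr$patient_id, t_from = t,
                                  t_pred = t + horizon,
                                  dim = seq_len(params$k),
                                  mean = pm, sd = sqrt(pv),
                                  y = tr$y[t + horizon, ],
                                  m = tr$m[t + horizon, ])
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Rollout prediction accuracy and interval calibration
#'
#' Rolls the model `horizon` steps forward from every prefix of every
#' trajectory (posterior at the prefix end, then stochastic transitions under
#' the administered treatments) and scores the masked-in outcomes at the
#' target time: RMSE, MAE, mean predictive log-likelihood, and empirical
#' coverage of central Gaussian 50% / 90% predictive intervals whose variance
#' combines the propagated latent spread with the decoded heteroscedastic
#' outcome variance.
#'
#' @param model a `td_fit` / `td_params`, or [baseline_mean_model()].
#' @param cohort held-out `td_cohort`.
#' @param horizon prediction horizon (>= 1).
#' @param n_samples Monte-Carlo rollout samples.
#' @param seed integer seed.
#' @return a `td_eval` list: `metrics` (one-row tibble) and `predictions`
#'   (the per-entry table).
#' @export
evaluate_prediction <- function(model, cohort, horizon = 1L,
                                n_samples = 100L, seed = 1L) {
  pt <- predict_table(model, cohort, horizon, n_samples, seed)
  obs <- pt[pt$m == 1, ]
  z90 <- stats::qnorm(0.95); z50 <- stats::qnorm(0.75)
  res <- obs$y - obs$mean
  metrics <- tibble::tibble(
    horizon = horizon,
    n_predictions = nrow(obs),
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    log_lik = mean(stats::dnorm(obs$y, obs$mean, obs$sd, log = TRUE)),
    coverage50 = mean(abs(res) <= z50 * obs$sd),
    coverage90 = mean(abs(res) <= z90 * obs$sd))
  structure(list(metrics = metrics, predictions = pt), class = "td_eval")
}

#' Sample counterfactual evaluation queries
#'
#' @param truth,config the simulator ground truth and configuration.
#' @param n_queries number of queries.
#' @param seed integer seed.
#' @return tibble with `patient`, `s`, `alt` (alternative treatment differs
#'   from the factual one at `s`).
#' @export
sample_cf_queries <- function(truth, config, n_queries = 200L, seed = 1L) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  sims <- simulate_cohort(truth, config)
  trs <- as_trajectories(sims$cohort)
  set.seed(seed + 7L)
  vocab <- truth$ontology$vocabulary
  patient <- sample.int(config$n_patients, n_queries, replace = TRUE)
  s <- sample.int(config$T_steps - 1L, n_queries, replace = TRUE)
  alt <- vapply(seq_len(n_queries), function(q) {
    fa <- trs[[patient[q]]]$a[s[q]]
    sample(setdiff(vocab, fa), 1L)
  }, "")
  tibble::tibble(patient = patient, s = s, alt = alt)
}

#' Counterfactual accuracy against simulated twins
#'
#' For each query the simulator generates a factual/counterfactual twin pair
#' under common random numbers; the model's mean-path counterfactual at
#' `s + 1` (posterior mean of the factual history at `s`, pushed through the
#' transition under the alternative treatment and decoded) is scored against
#' the twin's outcome. Two baselines share the code path: the model's own
#' factual prediction used as the counterfactual, and last-observation-
#' carried-forward.
#'
#' @param model a `td_fit` or `td_params`.
#' @param truth,config simulator ground truth and configuration.
#' @param queries tibble from [sample_cf_queries()]; sampled when `NULL`.
#' @param n_queries,seed used when sampling queries.
#' @return a `td_cf_eval` list: `metrics` (RMSEs), `queries` (per-query
#'   predictions and targets).
#' @export
evaluate_counterfactual <- function(model, truth, config, queries = NULL,
                                    n_queries = 200L, seed = 1L) {
  params <- as_params(model)
  if (is.null(queries)) queries <- sample_cf_queries(truth, config, n_queries, seed)
  rows <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    pat <- queries$patient[q]; s <- queries$s[q]; alt <- queries$alt[q]
    tw <- simulate_counterfactual_pair(truth, config, pat, s, alt)
    fa <- tw$factual; cf <- tw$counterfactual
    post <- encode_posterior(fa, params)
    z <- post$mean[s, ]
    y_model <- counterfactual_outcome(z, alt, params)
    y_factual_pred <- counterfactual_outcome(z, fa$a[s], params)
    seen <- which(rowSums(fa$m[seq_len(s), , drop = FALSE]) > 0)
    y_locf <- if (length(seen)) {
      t0 <- max(seen)
      ifelse(fa$m[t0, ] == 1, fa$y[t0, ], 0)
    } else rep(0, ncol(fa$y))
    y_true_cf <- as.numeric(cf$y[s + 1L, ])
    y_true_factual <- as.numeric(fa$y[s + 1L, ])
    rows[[q]] <- tibble::tibble(
      patient = pat, s = s, alt = alt, dim = seq_along(y_model),
      y_true_cf = y_true_cf, y_true_factual = y_true_factual,
      pred_model = as.numeric(y_model),
      pred_factual_baseline = as.numeric(y_factual_pred),
      pred_locf = y_locf)
  }
  tab <- dplyr::bind_rows(rows)
  rmse <- function(pred) sqrt(mean((tab$y_true_cf - pred)^2))
  metrics <- tibble::tibble(
    n_queries = nrow(queries),
    rmse_model = rmse(tab$pred_model),
    rmse_factual_baseline = rmse(tab$pred_factual_baseline),
    rmse_locf = rmse(tab$pred_locf))
  structure(list(metrics = metrics, queries = tab), class = "td_cf_eval")
}

#' Ground-truth treatment-effect recovery
#'
#' Compares learned class-level latent shifts with the simulator's true class
#' effects. Latent spaces are identified only up to an invertible linear
#' transform, so the true latents are first regressed onto the model's
#' posterior means (least squares); true effects are mapped through the
#' fitted linear part. Learned shifts `mean_z Delta(z, a)` are averaged over
#' reference posterior-mean latents and centred across the vocabulary (both
#' sides), removing the treatment-independent drift component. Classes are
#' matched by optimal one-to-one assignment on the cosine matrix.
#'
#' @param model a `td_fit`, `td_params`, or the `td_ground_truth` itself
#'   (oracle injection; yields cosine 1 for every class).
#' @param truth,config simulator ground truth and configuration.
#' @param max_ref maximum number of reference latents.
#' @return a `td_recovery` list: `table` (class, matched class, assignment
#'   cosine, and the identity-matched cosine), `mean_cosine` (assignment),
#'   `mean_cosine_identity` (no assignment — unbiased around 0 for a model
#'   that learned nothing, since the assignment's max-over-permutations is
#'   positively biased on small class counts), `within_dist`, `between_dist`.
#' @export
recovery_report <- function(model, truth, config, max_ref = 200L) {
  onto <- truth$ontology
  vocab <- onto$vocabulary
  sims <- simulate_cohort(truth, config)
  Ztrue <- do.call(rbind, sims$latents)

  if (inherits(model, "td_ground_truth")) {
    ref <- Ztrue[seq_len(min(max_ref, nrow(Ztrue))), , drop = FALSE]
    shift_of <- function(a) {
      colMeans(ref %*% t(model$A) - ref) + treatment_effect(model, a)
    }
    Mlin <- diag(length(truth$z1_mean))
  } else {
    params <- as_params(model)
    trs <- as_trajectories(sims$cohort)
    mus <- lapply(trs, function(tr) encode_posterior(tr, params)$mean)
    Zhat <- do.call(rbind, mus)
    fitlm <- stats::lm.fit(cbind(1, Ztrue), Zhat)
    Mlin <- fitlm$coefficients[-1, , drop = FALSE]  # true -> learned (row conv.)
    ref <- Zhat[round(seq(1L, nrow(Zhat), length.out = min(max_ref, nrow(Zhat)))), ,
                drop = FALSE]
    shift_of <- function(a) colMeans(latent_shift(ref, rep(a, nrow(ref)), params))
  }

  shifts <- t(vapply(vocab, shift_of, numeric(length(truth$z1_mean))))
  shifts_c <- sweep(shifts, 2L, colMeans(shifts))
  cls <- unname(onto$class_of[vocab])
  learned_class <- do.call(rbind, lapply(onto$classes, function(cl)
    colMeans(shifts_c[cls == cl, , drop = FALSE])))
  true_eff <- do.call(rbind, lapply(onto$classes, function(cl)
    truth$class_effects[[cl]]))
  true_mapped <- true_eff %*% Mlin
  true_mapped_c <- sweep(true_mapped, 2L, colMeans(true_mapped))

  cosmat <- cosine_matrix(learned_class, true_mapped_c)
  perm <- best_assignment(cosmat)
  tab <- tibble::tibble(class = onto$classes,
                        matched_class = onto$classes[perm],
                        cosine = cosmat[cbind(seq_along(perm), perm)],
                        cosine_identity = diag(cosmat))

  D <- as.matrix(stats::dist(shifts_c))
  same <- outer(cls, cls, "==") & upper.tri(D)
  diff_ <- (!outer(cls, cls, "==")) & upper.tri(D)
  structure(list(table = tab, mean_cosine = mean(tab$cosine),
                 mean_cosine_identity = mean(tab$cosine_identity),
                 within_dist = mean(D[same]), between_dist = mean(D[diff_])),
            class = "td_recovery")
}

cosine_matrix <- function(A, B) {
  An <- A / pmax(sqrt(rowSums(A^2)), 1e-300)
  Bn <- B / pmax(sqrt(rowSums(B^2)), 1e-300)
  An %*% t(Bn)
}

# exact optimal assignment by permutation enumeration (small class counts)
best_assignment <- function(S) {
  n <- nrow(S)
  perms <- all_perms(n)
  scores <- vapply(perms, function(p) sum(S[cbind(seq_len(n), p)]), 0)
  perms[[which.max(scores)]]
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (i in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}
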