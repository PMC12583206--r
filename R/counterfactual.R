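# Counterfactual decoding, the factual/counterfactual discriminator, and the
# shift-alignment penalty.

#' One-step counterfactual outcome
#'
#' `y_cf = D_y(f_theta(z, e(a_alt)))`: the latent is shifted by the
#' hypothetical treatment's embedding through the same transition network and
#' decoded by the same outcome decoder as factual predictions (mean-path
#' counterfactual). With `a_alt` equal to the factual treatment this is
#' exactly the factual one-step prediction.
#'
#' @param z latent vector.
#' @param a_alt hypothetical treatment id.
#' @param params a `td_params`.
#' @return a k-vector of predicted outcomes.
#' @export
counterfactual_outcome <- function(z, a_alt, params) {
  decode(transition_mean(z, a_alt, params), params)$y_mean
}

#' Monte-Carlo counterfactual expectation
#'
#' Estimates `E_{z_t ~ q} E_{z_{t+1} ~ T(z_t, a_alt)} [E_y(z_{t+1})]` by
#' sampling the posterior and the transition noise. Deterministic given
#' `seed`; as the posterior variance and transition noise vanish it collapses
#' to [counterfactual_outcome()] at the posterior mean.
#'
#' @param posterior_t `list(mean, var)` for the conditioning timestep
#'   (d_z vectors).
#' @param a_alt hypothetical treatment id.
#' @param params a `td_params`.
#' @param n_samples Monte-Carlo sample count (>= 1).
#' @param seed integer seed.
#' @return a k-vector with attribute `se` (per-dimension MC standard error).
#' @export
counterfactual_expectation <- function(posterior_t, a_alt, params,
                                       n_samples = 1000L, seed = 1L) {
  stopifnot(n_samples >= 1L)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  d_z <- params$d_z
  mu <- as.numeric(posterior_t$mean); v <- as.numeric(posterior_t$var)
  Zt <- matrix(mu, n_samples, d_z, byrow = TRUE) +
    matrix(stats::rnorm(n_samples * d_z), n_samples) %*% diag(sqrt(v), d_z)
  sig <- softplus(params$gen$sigma_raw) + 1e-4
  Znext <- transition_mean(Zt, rep(a_alt, n_samples), params) +
    sig * matrix(stats::rnorm(n_samples * d_z), n_samples)
  Y <- forward_decode(Znext, params$gen, params)$y_mean
  est <- colMeans(Y)
  attr(est, "se") <- apply(Y, 2L, stats::sd) / sqrt(n_samples)
  est
}

# discriminator forward: sigmoid MLP on [z, e(a)]; AD-capable
disc_forward <- function(Z, aidx, gp, dp, params, Evocab = NULL) {
  if (is.null(Evocab)) Evocab <- vocab_embeddings(gp, params$class_idx)
  Emb <- ad_rows(Evocab, aidx)
  U <- ad_cbind(Z, Emb)
  h <- ad_tanh(ad_addrow(ad_mm(U, dp$W_d1), dp$b_d1))
  ad_sigmoid(ad_addrow(ad_mm(h, dp$W_d2), dp$b_d2))
}

#' Discriminator score for a latent-treatment pair
#'
#' `D_psi(z, e(a))`: sigmoid-linked probability that the pair comes from the
#' factual distribution. A pure function of `(z, e(a))` — the score does not
#' depend on which arm the pair is labelled as.
#'
#' @param z latent vector.
#' @param a treatment id.
#' @param params a `td_params`.
#' @return scalar strictly inside (0, 1).
#' @export
discriminator_score <- function(z, a, params) {
  as.numeric(disc_forward(matrix(z, nrow = 1L),
                          treatment_index(a, params$ontology),
                          params$gen, params$disc, params))
}

# AD core over batches; clamped logs for stability
disc_loss_core <- function(Zr, ar_idx, Zc, ac_idx, gp, dp, params, eps = 1e-12) {
  sr <- disc_forward(Zr, ar_idx, gp, dp, params)
  sc <- disc_forward(Zc, ac_idx, gp, dp, params)
  ad_add(ad_mean(ad_log(ad_add(sr, eps))),
         ad_mean(ad_log(ad_add(ad_sub(1, sc), eps))))
}

#' Adversarial discriminator loss
#'
#' `L_disc = mean_real log D_psi(z, a) + mean_cf log(1 - D_psi(z, a_alt))`
#' (batch means estimating the two expectations). Always <= 0, approaching
#' its supremum 0 only under perfect separation. The discriminator ascends
#' this objective; the generator descends it (fooling the discriminator).
#'
#' @param real_pairs,cf_pairs `list(z = matrix of row vectors, a = ids)`.
#' @param params a `td_params`.
#' @export
discriminator_loss <- function(real_pairs, cf_pairs, params) {
  if (!length(real_pairs$a) || !length(cf_pairs$a)) stop("empty batch")
  disc_loss_core(real_pairs$z, treatment_index(real_pairs$a, params$ontology),
                 cf_pairs$z, treatment_index(cf_pairs$a, params$ontology),
                 params$gen, params$disc, params, eps = 0)
}

#' Shift-alignment penalty
#'
#' `||Delta(z, a) - Delta(z, a_alt)||^2` between the factual and
#' counterfactual latent shifts; zero when the treatments (or their
#' embeddings) coincide.
#'
#' @param z latent vector.
#' @param a factual treatment id.
#' @param a_alt hypothetical treatment id.
#' @param params a `td_params`.
#' @export
shift_alignment <- function(z, a, a_alt, params) {
  sum((latent_shift(z, a, params) - latent_shift(z, a_alt, params))^2)
}

#' Answer counterfactual queries against a cohort
#'
#' For each query `(patient_id, t, alt_treatment)` the factual history up to
#' `t` is encoded, and the posterior-mean latent is pushed through the
#' transition under the hypothetical treatment and decoded
#' (mean-path counterfactual at `t + 1`). The factual one-step prediction is
#' returned alongside as a baseline.
#'
#' @param params a `td_params` (or `td_fit`).
#' @param cohort a `td_cohort`.
#' @param queries tibble/data frame with columns `patient_id`, `t`,
#'   `alt_treatment`.
#' @return a tibble with one row per query and columns `yhat_cf_*`,
#'   `yhat_factual_*`.
#' @export
predict_counterfactual <- function(params, cohort, queries) {
  params <- as_params(params)
  trs <- as_trajectories(cohort)
  out <- lapply(seq_len(nrow(queries)), function(r) {
    q <- queries[r, ]
    tr <- trs[[as.character(q$patient_id)]]
    if (is.null(tr)) stop("unknown patient_id: ", q$patient_id)
    s <- as.integer(q$t)
    if (s < 1L || s > nrow(tr$x)) stop("query time outside the horizon")
    hist <- lapply(tr[c("x", "y", "m")], function(mm) mm[seq_len(s), , drop = FALSE])
    hist$a <- tr$a[seq_len(s)]
    post <- encode_posterior(hist, params)
    z <- post$mean[s, ]
    ycf <- counterfactual_outcome(z, as.character(q$alt_treatment), params)
    yf <- counterfactual_outcome(z, tr$a[s], params)
    tibble::tibble(patient_id = tr$patient_id, t = s,
                   alt_treatment = as.character(q$alt_treatment),
                   !!!stats::setNames(as.list(ycf), paste0("yhat_cf_", seq_along(ycf))),
                   !!!stats::setNames(as.list(yf), paste0("yhat_factual_", seq_along(yf))))
  })
  dplyr::bind_rows(out)
}

as_params <- function(x) {
  if (inherits(x, "td_fit")) x$params else x
}
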