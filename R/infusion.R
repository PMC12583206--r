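# Knowledge-infusion losses: ontology consistency, cumulative influence with
# safety corridor, drift, KL anchoring, stage-informed outcome penalty.

#' Treatment-induced latent shift
#'
#' `Delta(z, a) = f_theta(z, e(a)) - z`: the unit on which the consistency,
#' corridor, drift and shift-alignment losses operate.
#'
#' @param z latent vector or matrix of row vectors.
#' @param a treatment id(s).
#' @param params a `td_params`.
#' @export
latent_shift <- function(z, a, params) {
  transition_mean(z, a, params) - z
}

# AD core: shifts for a batch of latents under one treatment index
shift_rows <- function(Z, aidx1, gp, params, Evocab = NULL) {
  B <- nrow(vof(Z))
  ad_sub(forward_transition(Z, rep(aidx1, B), gp, params, Evocab), Z)
}

consistency_core <- function(Z, gp, params, Evocab = NULL) {
  edges <- params$ontology$similarity_edges
  if (!nrow(edges)) return(0)
  total <- 0
  for (r in seq_len(nrow(edges))) {
    i <- treatment_index(edges[r, 1], params$ontology)
    j <- treatment_index(edges[r, 2], params$ontology)
    di <- shift_rows(Z, i, gp, params, Evocab)
    dj <- shift_rows(Z, j, gp, params, Evocab)
    total <- ad_add(total, ad_mean(ad_rowsums(ad_square(ad_sub(di, dj)))))
  }
  total
}

#' Ontology consistency loss
#'
#' For every similarity edge `(a_i, a_j)`, penalises the expected squared
#' difference of the induced latent shifts,
#' `E_z ||Delta(z, a_i) - Delta(z, a_j)||^2`, estimated over the supplied
#' latent samples. Zero when the edge set is empty or the shifts coincide.
#'
#' @param z_samples matrix of latent row vectors (the `E_z` sample).
#' @param params a `td_params` (its ontology supplies the edges).
#' @export
consistency_loss <- function(z_samples, params) {
  Z <- if (is.matrix(z_samples)) z_samples else matrix(z_samples, nrow = 1L)
  consistency_core(Z, params$gen, params)
}

#' Cumulative therapeutic influence
#'
#' `Gamma_T = sum_t w_t Delta(z_{t-1}, a_t)` with geometric decay weights
#' `w_t = rho^(T-t)`: the net pharmacodynamic effect accumulated by time T,
#' recent treatments weighing most. `z_path` holds the state *before* each
#' administration (row t is the state treatment `treatments[t]` acts on).
#'
#' @param z_path T x d_z matrix of pre-treatment latent states.
#' @param treatments length-T treatment ids.
#' @param params a `td_params`.
#' @param rho decay in (0, 1]; 1 gives a plain sum.
#' @return a d_z vector.
#' @export
cumulative_influence <- function(z_path, treatments, params, rho = 1) {
  stopifnot(rho > 0, rho <= 1)
  Z <- if (is.matrix(z_path)) z_path else matrix(z_path, nrow = 1L)
  T_ <- nrow(Z)
  stopifnot(length(treatments) == T_)
  w <- rho^(T_ - seq_len(T_))
  shifts <- latent_shift(Z, treatments, params)
  as.vector(colSums(shifts * w))
}

#' Euclidean projection onto the safe region
#'
#' Box: per-coordinate clamp. Ball: radial scaling onto the sphere when
#' outside. Idempotent; projected points satisfy region membership exactly.
#'
#' @param gamma a d_z vector.
#' @param safe_region `list(type = "box", lower, upper)` or
#'   `list(type = "ball", center, radius)`.
#' @export
project_safe <- function(gamma, safe_region) {
  r <- check_safe_region(safe_region)
  if (r$type == "box") {
    pmin(pmax(gamma, r$lower), r$upper)
  } else {
    d <- gamma - r$center
    nrm <- sqrt(sum(d^2))
    if (nrm <= r$radius) gamma else r$center + d * (r$radius / nrm)
  }
}

#' Safety-corridor loss
#'
#' `0` inside `C_safe`, else the squared Euclidean distance to the region,
#' `||Gamma - Proj_{C_safe}(Gamma)||^2`.
#'
#' @inheritParams project_safe
#' @export
corridor_loss <- function(gamma, safe_region) {
  sum((gamma - project_safe(gamma, safe_region))^2)
}

# AD corridor loss for a batch of Gamma rows
corridor_rows <- function(G, safe_region) {
  if (safe_region$type == "box") {
    B <- nrow(vof(G))
    up <- matrix(safe_region$upper, B, length(safe_region$upper), byrow = TRUE)
    lo <- matrix(safe_region$lower, B, length(safe_region$lower), byrow = TRUE)
    ad_rowsums(ad_add(ad_square(ad_relu(ad_sub(G, up))),
                      ad_square(ad_relu(ad_sub(lo, G)))))
  } else {
    B <- nrow(vof(G))
    ctr <- matrix(safe_region$center, B, length(safe_region$center), byrow = TRUE)
    r <- ad_sqrt(ad_add(ad_rowsums(ad_square(ad_sub(G, ctr))), 1e-12))
    ad_square(ad_relu(ad_sub(r, safe_region$radius)))
  }
}

#' Drift (differential alignment) loss
#'
#' `sum_{t>=2} ||Delta(z_{t-1}, a_t) - Delta(z_{t-2}, a_{t-1})||^2`: abrupt
#' changes of latent influence direction across consecutive administrations
#' are penalised. Zero for T < 2.
#'
#' @inheritParams cumulative_influence
#' @export
drift_loss <- function(z_path, treatments, params) {
  Z <- if (is.matrix(z_path)) z_path else matrix(z_path, nrow = 1L)
  if (nrow(Z) < 2L) return(0)
  shifts <- latent_shift(Z, treatments, params)
  sum(diff(shifts)^2)
}

#' KL anchoring to a clinical prior
#'
#' `sum_t KL(q_t || pi_t)` for diagonal Gaussians, in closed form. The prior
#' is a single `(mean, var)` pair applied at every timestep or a per-timestep
#' matrix with at least T rows.
#'
#' @param posterior `list(mean, var)` as from [encode_posterior()].
#' @param anchor_mean,anchor_var prior parameters (vector or T x d_z matrix);
#'   variance strictly positive.
#' @export
anchor_kl <- function(posterior, anchor_mean, anchor_var) {
  qm <- as_matrix_rows(posterior$mean); qv <- as_matrix_rows(posterior$var)
  pm <- as_matrix_rows(anchor_mean); pv <- as_matrix_rows(anchor_var)
  if (any(pv <= 0)) stop("anchor prior variance must be strictly positive")
  T_ <- nrow(qm)
  if (nrow(pm) == 1L) { pm <- pm[rep(1L, T_), , drop = FALSE]; pv <- pv[rep(1L, T_), , drop = FALSE] }
  if (nrow(pm) < T_) stop("per-timestep anchor prior shorter than the trajectory")
  pm <- pm[seq_len(T_), , drop = FALSE]; pv <- pv[seq_len(T_), , drop = FALSE]
  sum(0.5 * (log(pv / qv) + (qv + (qm - pm)^2) / pv - 1))
}

# AD anchor KL for batched encoder outputs; returns B x 1 summed over t, d
anchor_kl_rows <- function(enc, valid, anchor_mean, anchor_var, params) {
  Tm <- length(enc$mu)
  B <- nrow(vof(enc$mu[[1]]))
  pm <- as_matrix_rows(anchor_mean); pv <- as_matrix_rows(anchor_var)
  per_t <- !(nrow(pm) == 1L)
  total <- matrix(0, B, 1L)
  for (t in seq_len(Tm)) {
    pmt <- matrix(if (per_t) pm[t, ] else pm[1, ], B, params$d_z, byrow = TRUE)
    pvt <- matrix(if (per_t) pv[t, ] else pv[1, ], B, params$d_z, byrow = TRUE)
    kl <- ad_mul(0.5, ad_sub(ad_add(ad_div(ad_add(enc$var[[t]],
                                                  ad_square(ad_sub(enc$mu[[t]], pmt))),
                                           pvt),
                                    ad_sub(log(pvt), ad_log(enc$var[[t]]))),
                             1))
    total <- ad_add(total, ad_mul(ad_rowsums(kl), matrix(valid[t, ], ncol = 1L)))
  }
  total
}

#' Stage-informed outcome penalty
#'
#' `sum_t ||y_hat_t - mu_stage(t)||^2` against the expected outcome curve of
#' the patient's disease stage.
#'
#' @param y_hat_path T x k matrix of predicted outcomes.
#' @param stage stage label (must have a curve in `priors`).
#' @param priors a [clinical_priors()] with `stage_curves`.
#' @export
stage_penalty <- function(y_hat_path, stage, priors) {
  Y <- if (is.matrix(y_hat_path)) y_hat_path else matrix(y_hat_path, ncol = 1L)
  curve <- priors$stage_curves[[stage]]
  if (is.null(curve)) stop("no stage curve for stage '", stage, "'")
  if (nrow(curve) < nrow(Y)) stop("stage curve shorter than trajectory")
  sum((Y - curve[seq_len(nrow(Y)), , drop = FALSE])^2)
}
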