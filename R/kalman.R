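#' Exact log-evidence of a trajectory under a linear-Gaussian ground truth
#'
#' Forward Kalman filter for the simulator's state-space model, conditioning
#' on the administered treatment sequence. At each timestep the observation
#' stacks the covariates (always observed) with the masked-in outcome
#' dimensions; masked-out outcomes contribute nothing, matching the masked
#' likelihood. Returns `log p(x_{1:T}, y_obs | a_{1:T})` exactly; used as an
#' independent upper bound when validating Monte-Carlo evidence lower bounds.
#'
#' @param trajectory a trajectory list with `x`, `y`, `m`, `a`
#'   (see [as_trajectories()]).
#' @param truth a `td_ground_truth`.
#' @return scalar log-evidence.
#' @export
kalman_loglik <- function(trajectory, truth) {
  x <- trajectory$x; y <- trajectory$y; m <- trajectory$m; a <- trajectory$a
  T_steps <- nrow(x)
  d_z <- length(truth$z1_mean); d_x <- nrow(truth$C); k <- nrow(truth$D)
  mu <- truth$z1_mean
  V <- diag(truth$z1_var, d_z)
  ll <- 0
  for (t in seq_len(T_steps)) {
    obs_y <- which(m[t, ] == 1)
    H <- rbind(truth$C, truth$D[obs_y, , drop = FALSE])
    o <- c(x[t, ], y[t, obs_y])
    Rdiag <- c(rep(truth$sigma_x^2, d_x), rep(truth$sigma_y^2, length(obs_y)))
    S <- H %*% V %*% t(H) + diag(Rdiag, length(o))
    S <- (S + t(S)) / 2
    innov <- o - as.vector(H %*% mu)
    ch <- chol(S)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, innov, transpose = TRUE)^2))
    K <- V %*% t(H) %*% chol2inv(ch)
    mu <- mu + as.vector(K %*% innov)
    V <- V - K %*% H %*% V
    V <- (V + t(V)) / 2
    if (t < T_steps) {
      mu <- as.vector(truth$A %*% mu) + treatment_effect(truth, a[t])
      V <- truth$A %*% V %*% t(truth$A) + diag(truth$sigma_z^2, d_z)
    }
  }
  ll
}
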