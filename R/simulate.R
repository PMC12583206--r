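#' Simulation configuration
#'
#' Study conditions for the linear-Gaussian ground-truth simulator. The
#' defaults describe the reference cohort used throughout the package's own
#' validation: 300 patients followed for 12 timesteps, a 4-dimensional latent
#' state, 6 covariates, 2 outcome dimensions, 3 therapeutic classes with 3
#' treatments each, small within-class effect spread, randomized treatment
#' assignment, and 20% outcome missingness.
#'
#' @param n_patients,T_steps,d_z,d_x,k cohort and dimension counts.
#' @param n_classes,treatments_per_class vocabulary structure; requires
#'   `n_classes <= d_z` so class effects can be mutually orthogonal.
#' @param within_class_spread norm of treatment-specific effect offsets
#'   relative to the mean class-effect norm.
#' @param confounding_strength scale of the latent-state logits in the
#'   treatment-assignment policy; 0 gives uniform randomized assignment.
#' @param effect_norm norm of each class effect vector.
#' @param spectral_radius spectral radius of the transition matrix `A` (< 1).
#' @param sigma_z,sigma_x,sigma_y transition / covariate / outcome noise SDs.
#' @param miss_rate i.i.d. probability that an outcome entry is masked out.
#' @param seed integer seed; every simulator operation is a pure function of
#'   (config, seed).
#' @return a `td_sim_config` list.
#' @export
sim_config <- function(n_patients = 300L, T_steps = 12L, d_z = 4L, d_x = 6L,
                       k = 2L, n_classes = 3L, treatments_per_class = 3L,
                       within_class_spread = 0.1, confounding_strength = 0,
                       effect_norm = 1, spectral_radius = 0.7,
                       sigma_z = 0.15, sigma_x = 0.3, sigma_y = 0.3,
                       miss_rate = 0.2, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_patients, T_steps, d_z, d_x, k, n_classes, treatments_per_class)
  if (any(counts < 1)) stop("config error: all counts must be >= 1")
  if (within_class_spread < 0) stop("config error: within_class_spread must be >= 0")
  if (n_classes > d_z)
    stop("config error: d_z inconsistent with requested structure (need n_classes <= d_z)")
  if (!(spectral_radius > 0 && spectral_radius < 1))
    stop("config error: spectral_radius must lie in (0, 1)")
  if (any(c(sigma_z, sigma_x, sigma_y) <= 0)) stop("config error: noise scales must be > 0")
  if (miss_rate < 0 || miss_rate >= 1) stop("config error: miss_rate must lie in [0, 1)")
  structure(cfg, class = "td_sim_config")
}

#' Draw a ground-truth model instance
#'
#' Instantiates the linear-Gaussian latent data-generating process:
#' `z_1 ~ N(mu0, diag(var0))`,
#' `z_{t+1} = A z_t + effect(a_t) + sigma_z * eps`,
#' `x_t = C z_t + sigma_x * eps`, `y_t = D z_t + sigma_y * eps`,
#' with `effect(a) = class_effect(alpha(a)) + specific_offset(a)`. Class
#' effects are mutually orthogonal unit-norm directions scaled to
#' `effect_norm`; specific offsets have norm
#' `within_class_spread * mean(class effect norm)`. The assignment policy is
#' multinomial-logit in the current latent state with scale
#' `confounding_strength` (0 = uniform). Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `td_ground_truth` list, including the generated [ontology()]
#'   (class map, intra-class similarity edges, default kernel).
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "td_sim_config"))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(config$seed)
  d_z <- config$d_z

  G <- matrix(stats::rnorm(d_z * d_z), d_z, d_z) + diag(d_z)
  A <- G * (config$spectral_radius / max(Mod(eigen(G, only.values = TRUE)$values)))

  # orthonormal class-effect directions (pairwise angles = 90 degrees)
  Q <- qr.Q(qr(matrix(stats::rnorm(d_z * config$n_classes), d_z)))
  classes <- paste0("class_", seq_len(config$n_classes))
  class_effects <- lapply(seq_len(config$n_classes),
                          function(c) Q[, c] * config$effect_norm)
  names(class_effects) <- classes

  vocab <- as.vector(vapply(seq_len(config$n_classes), function(c)
    paste0("drug_", c, "_", seq_len(config$treatments_per_class)),
    character(config$treatments_per_class)))
  class_of <- rep(classes, each = config$treatments_per_class)
  names(class_of) <- vocab
  onto <- ontology(class_of, similarity_edges = t(intra_pairs_ids(class_of)))

  off_norm <- config$within_class_spread * mean(vapply(class_effects, function(v)
    sqrt(sum(v^2)), 0))
  specific_offsets <- lapply(vocab, function(a) {
    v <- stats::rnorm(d_z)
    if (off_norm == 0) v * 0 else v / sqrt(sum(v^2)) * off_norm
  })
  names(specific_offsets) <- vocab

  C <- matrix(stats::rnorm(config$d_x * d_z), config$d_x, d_z) / sqrt(d_z)
  D <- matrix(stats::rnorm(config$k * d_z), config$k, d_z) / sqrt(d_z)
  W_pol <- matrix(stats::rnorm(length(vocab) * d_z), length(vocab), d_z)

  new_ground_truth(A = A, class_effects = class_effects,
                   specific_offsets = specific_offsets, C = C, D = D,
                   sigma_z = config$sigma_z, sigma_x = config$sigma_x,
                   sigma_y = config$sigma_y,
                   z1_mean = rep(0, d_z), z1_var = rep(1, d_z),
                   policy = list(type = "logit", W = W_pol,
                                 strength = config$confounding_strength),
                   miss_rate = config$miss_rate, ontology = onto)
}

intra_pairs_ids <- function(class_of) {
  v <- names(class_of)
  out <- matrix(character(0), nrow = 2L)
  for (cl in unique(class_of)) {
    members <- v[class_of == cl]
    if (length(members) >= 2L) out <- cbind(out, utils::combn(members, 2L))
  }
  out
}

#' Low-level ground-truth constructor
#'
#' @param A transition matrix; `validate = TRUE` enforces spectral radius < 1.
#' @param class_effects,specific_offsets named lists of d_z vectors.
#' @param C,D emission matrices (d_x x d_z, k x d_z).
#' @param sigma_z,sigma_x,sigma_y positive noise SDs.
#' @param z1_mean,z1_var initial-state prior (diagonal).
#' @param policy `list(type = "logit", W, strength)`.
#' @param miss_rate in [0, 1).
#' @param ontology a [ontology()] whose vocabulary names `specific_offsets`.
#' @param validate set `FALSE` to build deliberately degenerate fixtures.
#' @export
new_ground_truth <- function(A, class_effects, specific_offsets, C, D,
                             sigma_z, sigma_x, sigma_y, z1_mean, z1_var,
                             policy, miss_rate, ontology, validate = TRUE) {
  tr <- structure(list(A = A, class_effects = class_effects,
                       specific_offsets = specific_offsets, C = C, D = D,
                       sigma_z = sigma_z, sigma_x = sigma_x, sigma_y = sigma_y,
                       z1_mean = z1_mean, z1_var = z1_var, policy = policy,
                       miss_rate = miss_rate, ontology = ontology),
                  class = "td_ground_truth")
  if (validate) {
    rad <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rad >= 1) stop("unstable dynamics: spectral radius of A is ", signif(rad, 4))
    if (any(c(sigma_z, sigma_x, sigma_y) <= 0)) stop("noise scales must be > 0")
    if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must lie in [0, 1)")
  }
  tr
}

treatment_effect <- function(truth, a) {
  truth$class_effects[[truth$ontology$class_of[[a]]]] + truth$specific_offsets[[a]]
}

# deterministic per-patient seeds derived from the master seed
patient_seeds <- function(config) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_patients)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# Simulate one patient from its own seed. All noise is drawn up front so a
# counterfactual twin replays exactly the same randomness (common random
# numbers); `intervention = list(s, alt)` swaps the treatment at time s.
sim_patient <- function(truth, T_steps, seed, patient_id, intervention = NULL) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  d_z <- length(truth$z1_mean); d_x <- nrow(truth$C); k <- nrow(truth$D)
  vocab <- truth$ontology$vocabulary
  eps_z <- matrix(stats::rnorm(T_steps * d_z), T_steps, d_z)
  eps_x <- matrix(stats::rnorm(T_steps * d_x), T_steps, d_x)
  eps_y <- matrix(stats::rnorm(T_steps * k), T_steps, k)
  u_a <- stats::runif(T_steps)
  u_m <- matrix(stats::runif(T_steps * k), T_steps, k)

  z <- matrix(0, T_steps, d_z)
  x <- matrix(0, T_steps, d_x); y <- matrix(0, T_steps, k)
  a <- character(T_steps)
  z[1, ] <- truth$z1_mean + sqrt(truth$z1_var) * eps_z[1, ]
  for (t in seq_len(T_steps)) {
    x[t, ] <- as.vector(truth$C %*% z[t, ]) + truth$sigma_x * eps_x[t, ]
    y[t, ] <- as.vector(truth$D %*% z[t, ]) + truth$sigma_y * eps_y[t, ]
    logits <- truth$policy$strength * as.vector(truth$policy$W %*% z[t, ])
    p <- exp(logits - max(logits)); p <- p / sum(p)
    a[t] <- vocab[findInterval(u_a[t], cumsum(p), left.open = TRUE) + 1L]
    if (!is.null(intervention) && t == intervention$s) a[t] <- intervention$alt
    if (t < T_steps)
      z[t + 1, ] <- as.vector(truth$A %*% z[t, ]) + treatment_effect(truth, a[t]) +
        truth$sigma_z * eps_z[t + 1, ]
  }
  m <- (u_m < 1 - truth$miss_rate) * 1
  list(patient_id = patient_id, x = x, a = a, y = y, m = m,
       stage = NA_character_, z = z)
}

#' Simulate a cohort from a ground-truth instance
#'
#' @param truth a `td_ground_truth`.
#' @param config the [sim_config()] providing `n_patients`, `T_steps`, `seed`.
#' @return `list(cohort, latents)`: a `td_cohort` plus the list of true latent
#'   paths (T x d_z matrices, evaluation only).
#' @export
simulate_cohort <- function(truth, config) {
  seeds <- patient_seeds(config)
  sims <- lapply(seq_len(config$n_patients), function(i)
    sim_patient(truth, config$T_steps, seeds[i], sprintf("p%04d", i)))
  ch <- cohort_from_trajectories(sims)
  latents <- lapply(sims, `[[`, "z")
  names(latents) <- vapply(sims, `[[`, "", "patient_id")
  list(cohort = ch, latents = latents)
}

#' Simulate a factual / counterfactual twin pair
#'
#' Re-simulates one patient under identical noise draws (common random
#' numbers), once as in the factual cohort and once with the treatment at
#' time `s` replaced by `alt`. The twins agree exactly before `s` and differ
#' only through the intervention's downstream influence.
#'
#' @param truth,config as in [simulate_cohort()].
#' @param patient patient index (1-based, as generated by [simulate_cohort()]).
#' @param s intervention time, `1 <= s <= T_steps`.
#' @param alt alternative treatment id.
#' @return `list(factual, counterfactual)`, trajectories carrying `z` paths.
#' @export
simulate_counterfactual_pair <- function(truth, config, patient, s, alt) {
  if (!alt %in% truth$ontology$vocabulary)
    stop("unknown treatment id: ", alt)
  if (s < 1 || s > config$T_steps) stop("intervention time s outside the horizon")
  seeds <- patient_seeds(config)
  id <- sprintf("p%04d", patient)
  fact <- sim_patient(truth, config$T_steps, seeds[patient], id)
  cf <- sim_patient(truth, config$T_steps, seeds[patient], id,
                    intervention = list(s = s, alt = alt))
  list(factual = fact, counterfactual = cf)
}

#' Serialize / load ground truth as JSON
#' @param truth a `td_ground_truth`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$ontology <- list(class_of = as.list(truth$ontology$class_of),
                       similarity_edges = apply(truth$ontology$similarity_edges,
                                                1L, as.list, simplify = FALSE))
  writeLines(as.character(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  onto <- ontology(vapply(o$ontology$class_of, as.character, ""),
                   similarity_edges = edges_from_json(o$ontology$similarity_edges))
  new_ground_truth(A = o$A,
                   class_effects = lapply(o$class_effects, as.numeric),
                   specific_offsets = lapply(o$specific_offsets, as.numeric),
                   C = o$C, D = o$D, sigma_z = o$sigma_z, sigma_x = o$sigma_x,
                   sigma_y = o$sigma_y, z1_mean = o$z1_mean, z1_var = o$z1_var,
                   policy = list(type = o$policy$type, W = o$policy$W,
                                 strength = o$policy$strength),
                   miss_rate = o$miss_rate, ontology = onto)
}
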