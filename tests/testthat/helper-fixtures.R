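# Shared fixtures, all generated in code. Expensive objects are memoised per
# test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small simulated world: 2 classes x 2 treatments, d_z = 2
small_world <- function(seed = 5L, n_patients = 4L, T_steps = 3L) {
  key <- paste("world", seed, n_patients, T_steps)
  memo(key, {
    cfg <- sim_config(n_patients = n_patients, T_steps = T_steps, d_z = 2L,
                      d_x = 2L, k = 1L, n_classes = 2L,
                      treatments_per_class = 2L, seed = seed)
    truth <- make_ground_truth(cfg)
    sim <- simulate_cohort(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

# two-class ontology used for hand-built fixtures
toy_ontology <- function() {
  ontology(c(a1 = "cA", a2 = "cA", b1 = "cB", b2 = "cB"),
           similarity_edges = rbind(c("a1", "a2"), c("b1", "b2")))
}

toy_params <- function(seed = 2L, d_z = 2L, m = 2L, ...) {
  init_params(toy_ontology(), d_x = 2L, k = 1L, d_z = d_z, m = m,
              d_h = 3L, n_h = 3L, n_d = 3L, seed = seed, ...)
}

# zero out the transition so f_theta(z, e) = z exactly
identity_transition <- function(params) {
  g <- params$gen
  g$W_lin <- 0 * g$W_lin; g$b_lin <- 0 * g$b_lin
  g$W_h2 <- 0 * g$W_h2; g$b_h2 <- 0 * g$b_h2
  params$gen <- g
  params
}

# hand-built one-patient trajectory
toy_trajectory <- function(T_steps = 3L, d_x = 2L, k = 1L,
                           a = rep("a1", T_steps), m = NULL, seed = 1L) {
  set.seed(seed)
  list(patient_id = "pt1",
       x = matrix(rnorm(T_steps * d_x), T_steps, d_x),
       a = a,
       y = matrix(rnorm(T_steps * k), T_steps, k),
       m = if (is.null(m)) matrix(1, T_steps, k) else m,
       stage = NA_character_)
}

expect_near <- function(object, expected, tol = 1e-10) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|diff| = %g", max(abs(object - expected))))
}

train_world <- function() {
  memo("train_world", {
    cfg <- sim_config(n_patients = 24L, T_steps = 5L, d_z = 2L, d_x = 3L,
                      k = 1L, n_classes = 2L, treatments_per_class = 2L,
                      seed = 77L)
    truth <- make_ground_truth(cfg)
    sim <- simulate_cohort(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

small_fit_config <- function(...) {
  train_config(epochs = 3L, batch_size = 24L, lr_gen = 0.01, lr_disc = 0.02, ...)
}

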