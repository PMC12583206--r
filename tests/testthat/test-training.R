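# Composite objective bookkeeping, gradient checking, the dual-loop
# optimiser: determinism, decoupling, descent, checkpoint resume.

test_that("breakdown reconstructs the total and responds linearly to weights", {
  w <- train_world()
  p <- init_params(w$truth$ontology, d_x = 3L, k = 1L, d_z = 2L, m = 2L,
                   d_h = 3L, n_h = 3L, n_d = 3L, seed = 2L)
  pri <- clinical_priors(anchor_mean = c(0, 0), anchor_var = c(1, 1),
                         safe_region = list(type = "box", lower = c(-1, -1),
                                            upper = c(1, 1)),
                         decay_rho = 0.9,
                         loss_weights = default_loss_weights(
                           lambda_drift = 0.03, lambda_shift = 0.03,
                           lambda_ent = 0.01))
  gl <- total_generator_loss(w$sim$cohort, p, pri, seed = 5L)
  expect_near(sum(gl$breakdown$contribution), gl$total, 1e-10)

  # all lambdas zero -> total = -ELBO + weight decay (here weight 0 -> -ELBO)
  pri0 <- clinical_priors(loss_weights = lapply(default_loss_weights(), function(x) 0))
  gl0 <- total_generator_loss(w$sim$cohort, p, pri0, seed = 5L)
  ev <- gl0$breakdown$value[gl0$breakdown$term == "elbo"]
  expect_near(gl0$total, -ev, 1e-12)

  # doubling lambda_corridor doubles exactly the corridor contribution
  pri2 <- pri
  pri2$loss_weights$lambda_corridor <- 2 * pri$loss_weights$lambda_corridor
  gl2 <- total_generator_loss(w$sim$cohort, p, pri2, seed = 5L)
  ctr <- function(g, term) g$breakdown$contribution[g$breakdown$term == term]
  expect_near(ctr(gl2, "corridor"), 2 * ctr(gl, "corridor"), 1e-12)
  same <- setdiff(gl$breakdown$term, "corridor")
  expect_near(gl2$breakdown$contribution[gl2$breakdown$term %in% same],
              gl$breakdown$contribution[gl$breakdown$term %in% same], 1e-12)
})

test_that("analytic gradients of the total and each term pass, and the check detects faults", {
  w <- train_world()
  trs <- as_trajectories(w$sim$cohort)[1:4]
  ch <- cohort_from_trajectories(trs)
  p <- init_params(w$truth$ontology, d_x = 3L, k = 1L, d_z = 2L, m = 2L,
                   d_h = 3L, n_h = 3L, n_d = 3L, seed = 4L)
  set.seed(31)
  p$gen <- lapply(p$gen, function(v) v + 0.05 * rnorm(length(v)))
  expect_lte(length(unlist(p$gen)), 500L)
  pri <- clinical_priors(anchor_mean = c(0, 0), anchor_var = c(1, 1),
                         safe_region = list(type = "ball", center = c(0, 0),
                                            radius = 0.05),
                         decay_rho = 0.8,
                         loss_weights = default_loss_weights(
                           lambda_drift = 0.05, lambda_shift = 0.05,
                           lambda_ent = 0.02))
  for (term in c("total", "elbo", "consistency", "disc", "anchor", "corridor",
                 "disc_psi")) {
    gc <- gradient_check(p, ch, term = term, priors = pri, seed = 6L)
    expect_lt(gc$max_rel_err, 1e-3, label = paste("term", term))
  }
  # negative control: a corrupted gradient is flagged far above threshold
  gc <- gradient_check(p, ch, term = "elbo", priors = pri, seed = 6L)
  corrupted <- gc$analytic + 0.5
  rel <- abs(corrupted - gc$numeric) / pmax(1e-6, abs(corrupted) + abs(gc$numeric))
  expect_gt(max(rel), 1e-1)
  # zero perturbation has zero error by definition
  expect_near(gc$analytic - gc$analytic, 0, 1e-15)
})

test_that("training is bitwise reproducible given the seed", {
  w <- train_world()
  f1 <- fit_treatdyn(w$sim$cohort, w$truth$ontology, config = small_fit_config(seed = 9L),
                     d_z = 2L, m = 2L, d_h = 4L)
  f2 <- fit_treatdyn(w$sim$cohort, w$truth$ontology, config = small_fit_config(seed = 9L),
                     d_z = 2L, m = 2L, d_h = 4L)
  expect_identical(f1$params$gen, f2$params$gen)
  expect_identical(f1$params$disc, f2$params$disc)
  expect_identical(f1$history, f2$history)
  # and the serialized checkpoints agree byte for byte
  c1 <- withr::local_tempfile(); c2 <- withr::local_tempfile()
  save_checkpoint(f1$params, c1); save_checkpoint(f2$params, c2)
  expect_identical(readLines(c1), readLines(c2))
})

test_that("with lambda_disc = 0 discriminator updates don't touch the generator", {
  w <- train_world()
  pri0 <- clinical_priors(loss_weights = default_loss_weights(lambda_disc = 0))
  fa <- fit_treatdyn(w$sim$cohort, w$truth$ontology, priors = pri0,
                     config = small_fit_config(seed = 10L, adversarial = TRUE),
                     d_z = 2L, m = 2L, d_h = 4L)
  fb <- fit_treatdyn(w$sim$cohort, w$truth$ontology, priors = pri0,
                     config = small_fit_config(seed = 10L, adversarial = FALSE),
                     d_z = 2L, m = 2L, d_h = 4L)
  expect_identical(fa$params$gen, fb$params$gen)
  expect_identical(fa$history, fb$history)
  # ... while the discriminators differ (one was trained)
  expect_false(identical(fa$params$disc, fb$params$disc))
})

test_that("-ELBO decreases over the first 10 epochs for nearly all seeds", {
  cfg <- sim_config(n_patients = 50L, T_steps = 8L, d_z = 2L, d_x = 3L, k = 1L,
                    n_classes = 2L, treatments_per_class = 2L, seed = 55L)
  truth <- make_ground_truth(cfg)
  sim <- simulate_cohort(truth, cfg)
  ok <- 0L
  for (s in 1:20) {
    fit <- fit_treatdyn(sim$cohort, truth$ontology,
                        config = train_config(epochs = 10L, batch_size = 50L,
                                              lr_gen = 0.02, seed = 300L + s),
                        d_z = 2L, m = 2L, d_h = 6L)
    neg_elbo <- -fit$history$value[fit$history$term == "elbo"]
    if (all(diff(neg_elbo) < 0)) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("checkpoint save/load/resume matches the uninterrupted loss curve", {
  w <- train_world()
  full <- fit_treatdyn(w$sim$cohort, w$truth$ontology,
                       config = train_config(epochs = 10L, batch_size = 24L,
                                             seed = 13L),
                       d_z = 2L, m = 2L, d_h = 4L)
  ckpt <- withr::local_tempfile(fileext = ".json")
  part <- fit_treatdyn(w$sim$cohort, w$truth$ontology,
                       config = train_config(epochs = 5L, batch_size = 24L,
                                             seed = 13L, checkpoint_every = 5L,
                                             checkpoint_path = ckpt),
                       d_z = 2L, m = 2L, d_h = 4L)
  resumed <- fit_treatdyn(w$sim$cohort, w$truth$ontology,
                          config = train_config(epochs = 10L, batch_size = 24L,
                                                seed = 13L),
                          resume_from = ckpt)
  expect_equal(resumed$history$value, full$history$value, tolerance = 1e-6)
  expect_equal(unlist(resumed$params$gen), unlist(full$params$gen),
               tolerance = 1e-6)
})

test_that("checkpoint loader refuses dimension mismatches", {
  w <- train_world()
  p <- init_params(w$truth$ontology, d_x = 3L, k = 1L, d_z = 2L, m = 2L,
                   d_h = 4L, seed = 1L)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(p, f)
  txt <- readLines(f)
  expect_identical(unlist(load_checkpoint(f)$gen), unlist(p$gen))
  bad <- sub('"d_z":2', '"d_z":3', txt, fixed = TRUE)
  writeLines(bad, f)
  expect_error(load_checkpoint(f), "dimension mismatch")
})

test_that("with knowledge weights off, the sequential VAE beats the mean predictor", {
  cfg <- sim_config(n_patients = 80L, T_steps = 8L, d_z = 2L, d_x = 3L, k = 1L,
                    n_classes = 2L, treatments_per_class = 2L, seed = 66L)
  truth <- make_ground_truth(cfg)
  sim <- simulate_cohort(truth, cfg)
  cfg_ho <- cfg; cfg_ho$seed <- 660L; cfg_ho$n_patients <- 40L
  heldout <- simulate_cohort(truth, cfg_ho)$cohort

  pri_vae <- clinical_priors(loss_weights = default_loss_weights(
    lambda_consist = 0, lambda_corridor = 0, lambda_anchor = 0,
    lambda_disc = 0, lambda_temp = 0, lambda_sym = 0, lambda_align = 0,
    lambda_smooth = 0, lambda_wd = 0))
  fit <- fit_treatdyn(sim$cohort, truth$ontology, priors = pri_vae,
                      config = train_config(epochs = 60L, batch_size = 80L,
                                            lr_gen = 0.02, seed = 14L,
                                            adversarial = FALSE),
                      d_z = 2L, m = 2L, d_h = 8L)
  ev_model <- evaluate_prediction(fit, heldout, horizon = 1L, seed = 3L)
  ev_base <- evaluate_prediction(baseline_mean_model(sim$cohort), heldout,
                                 horizon = 1L)
  expect_gt(ev_model$metrics$log_lik, ev_base$metrics$log_lik)
  expect_lt(ev_model$metrics$rmse, ev_base$metrics$rmse)
})

test_that("divergence aborts with the last completed epoch's parameters", {
  w <- train_world()
  p_bad <- init_params(w$truth$ontology, d_x = 3L, k = 1L, d_z = 2L, m = 2L,
                       d_h = 4L, seed = 15L)
  p_bad$gen$W_y <- p_bad$gen$W_y * 1e200  # overflows the squared residual
  expect_warning(
    fit <- fit_treatdyn(w$sim$cohort, w$truth$ontology, params = p_bad,
                        config = train_config(epochs = 3L, batch_size = 24L,
                                              seed = 15L)),
    "non-finite")
  expect_true(fit$diverged)
  expect_identical(fit$params$gen, p_bad$gen)
})
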