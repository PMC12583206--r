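# Ground-truth simulator: determinism, structure, missingness, policy,
# counterfactual twins with common random numbers.

test_that("ground truth and cohorts are pure functions of (config, seed)", {
  cfg <- sim_config(n_patients = 5L, T_steps = 4L, seed = 42L)
  t1 <- make_ground_truth(cfg)
  t2 <- make_ground_truth(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_cohort(t1, cfg)
  s2 <- simulate_cohort(t2, cfg)
  expect_identical(s1, s2)
  # serialized form identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_ground_truth(t1, f1); write_ground_truth(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("vocabulary structure follows the config", {
  cfg <- sim_config(n_classes = 2L, treatments_per_class = 3L, d_z = 4L, seed = 1L)
  tr <- make_ground_truth(cfg)
  expect_length(tr$ontology$vocabulary, 6L)
  expect_equal(as.integer(table(unname(tr$ontology$class_of))), c(3L, 3L))
  expect_error(sim_config(n_classes = 5L, d_z = 3L), "config error")
})

test_that("within_class_spread = 0 collapses treatments onto the class effect", {
  cfg <- sim_config(within_class_spread = 0, seed = 2L)
  tr <- make_ground_truth(cfg)
  expect_true(all(vapply(tr$specific_offsets, function(v) all(v == 0), TRUE)))
})

test_that("specific offsets scale with within_class_spread", {
  cfg <- sim_config(within_class_spread = 0.3, effect_norm = 2, seed = 2L)
  tr <- make_ground_truth(cfg)
  norms <- vapply(tr$specific_offsets, function(v) sqrt(sum(v^2)), 0)
  expect_equal(unname(norms), rep(0.3 * 2, length(norms)))
})

test_that("miss_rate = 0 gives all-ones masks; empirical rate matches otherwise", {
  cfg0 <- sim_config(n_patients = 10L, T_steps = 5L, miss_rate = 0, seed = 3L)
  tr0 <- make_ground_truth(cfg0)
  s0 <- simulate_cohort(tr0, cfg0)
  expect_true(all(as.matrix(s0$cohort[, c("m1", "m2")]) == 1))

  # 10,000 mask entries at p_miss = 0.2: within 5 binomial SDs
  cfg <- sim_config(n_patients = 500L, T_steps = 10L, k = 1L, miss_rate = 0.2,
                    seed = 4L)
  tr <- make_ground_truth(cfg)
  s <- simulate_cohort(tr, cfg)
  n <- 500L * 10L
  rate <- 1 - mean(as.matrix(s$cohort[, "m1"]))
  expect_lt(abs(rate - 0.2), 5 * sqrt(0.2 * 0.8 / n))
})

test_that("noise-free identity dynamics give constant covariates", {
  onto <- toy_ontology()
  d_z <- 2L
  tr <- new_ground_truth(A = diag(d_z),
                         class_effects = list(cA = rep(0, d_z), cB = rep(0, d_z)),
                         specific_offsets = stats::setNames(
                           rep(list(rep(0, d_z)), 4), onto$vocabulary),
                         C = matrix(c(1, 0, 0, 1, 1, 1), 3, 2),
                         D = matrix(1, 1, 2),
                         sigma_z = 1e-14, sigma_x = 1e-14, sigma_y = 1e-14,
                         z1_mean = c(0.5, -1), z1_var = c(1e-28, 1e-28),
                         policy = list(type = "logit",
                                       W = matrix(0, 4, 2), strength = 0),
                         miss_rate = 0, ontology = onto, validate = FALSE)
  cfg <- sim_config(n_patients = 3L, T_steps = 6L, d_x = 3L, k = 1L,
                    n_classes = 2L, treatments_per_class = 2L, seed = 9L)
  s <- simulate_cohort(tr, cfg)
  for (tj in as_trajectories(s$cohort))
    expect_lt(max(abs(sweep(tj$x, 2L, tj$x[1, ]))), 1e-10)
})

test_that("unconfounded assignment is uniform over the vocabulary", {
  cfg <- sim_config(n_patients = 200L, T_steps = 10L,
                    confounding_strength = 0, seed = 6L)
  tr <- make_ground_truth(cfg)
  s <- simulate_cohort(tr, cfg)
  counts <- table(s$cohort$a)
  n <- sum(counts); p <- 1 / length(tr$ontology$vocabulary)
  expect_length(counts, length(tr$ontology$vocabulary))
  expect_true(all(abs(counts / n - p) < 5 * sqrt(p * (1 - p) / n)))
})

test_that("confounded assignment departs from uniform", {
  cfg <- sim_config(n_patients = 200L, T_steps = 10L,
                    confounding_strength = 3, seed = 6L)
  tr <- make_ground_truth(cfg)
  s <- simulate_cohort(tr, cfg)
  counts <- table(s$cohort$a)
  expect_gt(stats::chisq.test(counts)$statistic, stats::qchisq(0.999, 8))
})

test_that("counterfactual twins share history and noise", {
  cfg <- sim_config(n_patients = 6L, T_steps = 8L, seed = 7L)
  tr <- make_ground_truth(cfg)
  s <- simulate_cohort(tr, cfg)
  trs <- as_trajectories(s$cohort)
  fa_a <- trs[[3]]$a
  alt <- setdiff(tr$ontology$vocabulary, fa_a[4])[1]
  tw <- simulate_counterfactual_pair(tr, cfg, patient = 3L, s = 4L, alt = alt)

  # factual twin is the cohort trajectory
  expect_equal(tw$factual$x, trs[[3]]$x, ignore_attr = TRUE)
  expect_equal(tw$factual$y, trs[[3]]$y, ignore_attr = TRUE)
  # identical before the intervention
  expect_identical(tw$factual$x[1:4, ], tw$counterfactual$x[1:4, ])
  expect_identical(tw$factual$y[1:4, ], tw$counterfactual$y[1:4, ])
  expect_identical(tw$factual$m, tw$counterfactual$m)
  expect_identical(tw$counterfactual$a[4], alt)
  # downstream influence only: latent paths differ after s
  expect_gt(max(abs(tw$factual$z[5:8, ] - tw$counterfactual$z[5:8, ])), 0)

  # identity intervention: twins coincide entirely
  tw2 <- simulate_counterfactual_pair(tr, cfg, 3L, 4L, fa_a[4])
  expect_identical(tw2$factual, tw2$counterfactual)

  expect_error(simulate_counterfactual_pair(tr, cfg, 3L, 4L, "nope"),
               "unknown treatment")
  expect_error(simulate_counterfactual_pair(tr, cfg, 3L, 99L, alt), "horizon")
})

test_that("zero treatment effects give identical twin outcome paths", {
  cfg <- sim_config(n_patients = 4L, T_steps = 6L, effect_norm = 0,
                    within_class_spread = 0, seed = 8L)
  tr <- make_ground_truth(cfg)
  alt <- tr$ontology$vocabulary[1]
  tw <- simulate_counterfactual_pair(tr, cfg, 2L, 3L,
                                     alt = tr$ontology$vocabulary[5])
  expect_equal(tw$factual$y, tw$counterfactual$y, tolerance = 1e-12)
})

test_that("one-step twin difference equals the effect difference (A = 0, D = I)", {
  onto <- toy_ontology()
  d_z <- 2L
  eff <- list(cA = c(1, 0), cB = c(0, 2))
  tr <- new_ground_truth(A = matrix(0, 2, 2),
                         class_effects = eff,
                         specific_offsets = stats::setNames(
                           rep(list(rep(0, d_z)), 4), onto$vocabulary),
                         C = diag(2), D = diag(2),
                         sigma_z = 1e-14, sigma_x = 1e-14, sigma_y = 1e-14,
                         z1_mean = c(0, 0), z1_var = c(1, 1),
                         policy = list(type = "logit",
                                       W = matrix(0, 4, 2), strength = 0),
                         miss_rate = 0, ontology = onto, validate = FALSE)
  cfg <- sim_config(n_patients = 2L, T_steps = 4L, d_x = 2L, k = 2L,
                    n_classes = 2L, treatments_per_class = 2L, seed = 11L)
  tw <- simulate_counterfactual_pair(tr, cfg, 1L, 2L, alt = "b1")
  fa <- tw$factual; cf <- tw$counterfactual
  d_true <- eff[[onto$class_of[["b1"]]]] - eff[[onto$class_of[[fa$a[2]]]]]
  if (fa$a[2] == "b1") d_true <- c(0, 0)
  expect_equal(cf$y[3, ] - fa$y[3, ], d_true, tolerance = 1e-10)
})
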