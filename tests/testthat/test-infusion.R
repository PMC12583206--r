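# Knowledge-infusion losses: consistency, cumulative influence, corridor
# projection, drift, KL anchoring, stage penalty — each against brute-force
# loop oracles and closed forms.

rand_params <- function(seed) {
  p <- toy_params(seed = seed)
  p$gen$W_lin <- matrix(rnorm(8, sd = 0.4), 4, 2)
  p$gen$W_h2 <- matrix(rnorm(6, sd = 0.4), 3, 2)
  p
}

test_that("consistency loss: degenerate cases and loop oracle", {
  p <- rand_params(3L)
  Z <- matrix(rnorm(10), 5, 2)

  # equal embeddings on every edge -> identical shifts -> 0
  p0 <- p
  p0$gen$E_spec <- 0 * p0$gen$E_spec
  expect_near(consistency_loss(Z, p0), 0, 1e-12)

  # empty edge set -> 0
  pne <- p
  pne$ontology <- ontology(p$ontology$class_of)
  expect_identical(consistency_loss(Z, pne), 0)

  # loop oracle over edges and samples
  oracle <- 0
  for (r in seq_len(nrow(p$ontology$similarity_edges))) {
    e <- p$ontology$similarity_edges[r, ]
    for (i in seq_len(nrow(Z))) {
      di <- latent_shift(Z[i, ], e[1], p)
      dj <- latent_shift(Z[i, ], e[2], p)
      oracle <- oracle + sum((di - dj)^2) / nrow(Z)
    }
  }
  expect_near(consistency_loss(Z, p), oracle, 1e-10)

  # hand case: single edge, single z, shifts (1,0) vs (0,1) -> 2
  o2 <- ontology(c(u = "c1", v = "c1"), similarity_edges = rbind(c("u", "v")))
  p2 <- init_params(o2, d_x = 1L, k = 1L, d_z = 2L, m = 2L, d_h = 2L, seed = 1L)
  p2 <- identity_transition(p2)
  p2$gen$W_lin <- rbind(matrix(0, 2, 2), diag(2))  # f(z, e) = z + e
  p2$gen$E_sym <- matrix(0, 1, 2)
  p2$gen$E_spec <- rbind(c(1, 0), c(0, 1))
  expect_near(consistency_loss(matrix(c(0.3, -1), 1, 2), p2), 2, 1e-12)
})

test_that("cumulative influence applies geometric decay weights", {
  o2 <- ontology(c(u = "c1", v = "c1"))
  p <- init_params(o2, d_x = 1L, k = 1L, d_z = 2L, m = 2L, d_h = 2L, seed = 1L)
  p <- identity_transition(p)
  p$gen$W_lin <- rbind(matrix(0, 2, 2), diag(2))  # shift = e(a)
  p$gen$E_sym <- matrix(0, 1, 2)
  p$gen$E_spec <- rbind(c(1, 0), c(0, 2))

  z <- matrix(0, 2, 2)
  # T = 2, rho = 0.5, shifts (1,0) then (0,2) -> (0.5, 2.0)
  expect_equal(cumulative_influence(z, c("u", "v"), p, rho = 0.5), c(0.5, 2))
  # rho = 1 -> plain sum
  expect_equal(cumulative_influence(z, c("u", "v"), p, rho = 1), c(1, 2))
  # T = 1 -> single shift, weight rho^0 = 1
  expect_equal(cumulative_influence(matrix(0, 1, 2), "u", p, rho = 0.3), c(1, 0))

  # random instance vs loop oracle
  p2 <- rand_params(5L)
  Z <- matrix(rnorm(8), 4, 2)
  trt <- c("a1", "b2", "a2", "b1")
  rho <- 0.7
  oracle <- c(0, 0)
  for (t in 1:4) oracle <- oracle + rho^(4 - t) * latent_shift(Z[t, ], trt[t], p2)
  expect_near(cumulative_influence(Z, trt, p2, rho), oracle, 1e-10)
})

test_that("corridor loss uses the exact Euclidean projection", {
  box <- list(type = "box", lower = c(-1, -1), upper = c(1, 1))
  expect_identical(corridor_loss(c(0.2, -0.9), box), 0)
  expect_equal(project_safe(c(2, 0), box), c(1, 0))
  expect_equal(corridor_loss(c(2, 0), box), 1)

  ball <- list(type = "ball", center = c(0, 0), radius = 1)
  expect_equal(project_safe(c(0, 3), ball), c(0, 1))
  expect_equal(corridor_loss(c(0, 3), ball), 4)

  set.seed(8)
  for (i in 1:30) {
    g <- rnorm(3, sd = 2)
    lo <- sort(rnorm(3))
    b3 <- list(type = "box", lower = lo, upper = lo + runif(3, 0, 2))
    pr <- project_safe(g, b3)
    # idempotence + membership
    expect_identical(project_safe(pr, b3), pr)
    expect_true(all(pr >= b3$lower - 1e-12 & pr <= b3$upper + 1e-12))
    # independent oracle: bounded least-squares projection
    op <- stats::optim(pmin(pmax(g, b3$lower), b3$upper),
                       function(u) sum((g - u)^2), method = "L-BFGS-B",
                       lower = b3$lower, upper = b3$upper)
    expect_near(corridor_loss(g, b3), op$value, 1e-8)

    bl <- list(type = "ball", center = rnorm(3), radius = runif(1, 0.1, 2))
    pb <- project_safe(g, bl)
    expect_near(project_safe(pb, bl), pb, 1e-12)
    expect_lte(sqrt(sum((pb - bl$center)^2)), bl$radius + 1e-12)
    # loop oracle: scalar geometry computed independently
    dist <- sqrt(sum((g - bl$center)^2))
    expect_near(corridor_loss(g, bl), max(0, dist - bl$radius)^2, 1e-12)
  }
})

test_that("drift loss penalises changes in consecutive shifts", {
  p <- rand_params(9L)
  # constant latent and treatment -> identical consecutive shifts -> 0
  Zc <- matrix(rep(c(0.4, -0.2), each = 5), 5, 2)
  expect_near(drift_loss(Zc, rep("a1", 5), p), 0, 1e-12)
  expect_identical(drift_loss(matrix(0, 1, 2), "a1", p), 0)

  # hand case: shifts (1,1) then (0,1) -> 1
  o2 <- ontology(c(u = "c1", v = "c1"))
  p2 <- init_params(o2, d_x = 1L, k = 1L, d_z = 2L, m = 2L, d_h = 2L, seed = 1L)
  p2 <- identity_transition(p2)
  p2$gen$W_lin <- rbind(matrix(0, 2, 2), diag(2))
  p2$gen$E_sym <- matrix(0, 1, 2)
  p2$gen$E_spec <- rbind(c(1, 1), c(0, 1))
  expect_near(drift_loss(matrix(0, 2, 2), c("u", "v"), p2), 1, 1e-12)

  # loop oracle
  Z <- matrix(rnorm(10), 5, 2)
  trt <- c("a1", "a2", "b1", "b2", "a1")
  oracle <- 0
  for (t in 2:5)
    oracle <- oracle + sum((latent_shift(Z[t, ], trt[t], p) -
                              latent_shift(Z[t - 1, ], trt[t - 1], p))^2)
  expect_near(drift_loss(Z, trt, p), oracle, 1e-10)
})

test_that("anchoring KL matches closed forms and numerical integration", {
  # q = pi -> 0
  post <- list(mean = rbind(c(0.3, -1), c(2, 0)), var = rbind(c(1, 2), c(0.5, 3)))
  expect_near(anchor_kl(post, post$mean, post$var), 0, 1e-12)

  # 1-d: KL(N(1,1) || N(0,1)) = 0.5
  expect_equal(anchor_kl(list(mean = 1, var = 1), 0, 1), 0.5)
  # 1-d: KL(N(0,2) || N(0,1)) = (2 - 1 - ln 2) / 2
  expect_equal(anchor_kl(list(mean = 0, var = 2), 0, 1), 0.5 * (2 - 1 - log(2)))

  expect_error(anchor_kl(list(mean = 0, var = 1), 0, -1), "positive")

  # numerical integration oracle on random 1-d cases
  set.seed(12)
  for (i in 1:10) {
    qm <- rnorm(1); qv <- runif(1, 0.3, 2)
    pm <- rnorm(1); pv <- runif(1, 0.3, 2)
    f <- function(x) dnorm(x, qm, sqrt(qv)) *
      (dnorm(x, qm, sqrt(qv), log = TRUE) - dnorm(x, pm, sqrt(pv), log = TRUE))
    num <- stats::integrate(f, qm - 12 * sqrt(qv), qm + 12 * sqrt(qv),
                            rel.tol = 1e-10)$value
    expect_near(anchor_kl(list(mean = qm, var = qv), pm, pv), num, 1e-4)
  }

  # per-timestep prior rows; loop oracle over t and dimensions
  qm <- matrix(rnorm(6), 3, 2); qv <- matrix(runif(6, 0.2, 2), 3, 2)
  pm <- matrix(rnorm(6), 3, 2); pv <- matrix(runif(6, 0.2, 2), 3, 2)
  oracle <- 0
  for (t in 1:3) for (d in 1:2) {
    oracle <- oracle + 0.5 * (log(pv[t, d] / qv[t, d]) +
                                (qv[t, d] + (qm[t, d] - pm[t, d])^2) / pv[t, d] - 1)
  }
  expect_near(anchor_kl(list(mean = qm, var = qv), pm, pv), oracle, 1e-10)
})

test_that("stage penalty is the squared distance to the stage curve", {
  pri <- clinical_priors(stage_curves = list(early = matrix(0, 5, 1),
                                             late = matrix(1:5, 5, 1)))
  expect_identical(stage_penalty(matrix(1:5, 5, 1), "late", pri), 0)
  # k = 1, T = 2, y = (1, 2), mu = (0, 0) -> 5
  expect_equal(stage_penalty(matrix(c(1, 2), 2, 1), "early", pri), 5)
  # homogeneity in the residuals
  y <- matrix(rnorm(5), 5, 1)
  expect_equal(stage_penalty(3 * y, "early", pri),
               9 * stage_penalty(y, "early", pri))
  expect_error(stage_penalty(y, "unknown", pri), "no stage curve")
})
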