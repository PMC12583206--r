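# Composite objective, dual-loop adversarial optimisation, gradient checks.

#' Training configuration
#'
#' @param epochs number of passes over the cohort (>= 1).
#' @param batch_size patients per minibatch.
#' @param lr_gen,lr_disc Adam step sizes for generator and discriminator.
#' @param n_critic discriminator ascent steps per generator step (>= 1).
#' @param mc_samples Monte-Carlo samples for the ELBO during training.
#' @param seed master seed; the run is a pure function of (data, config).
#' @param transition_mode `"first_order"` or `"second_order"` transition
#'   density in the ELBO.
#' @param adversarial set `FALSE` to skip discriminator updates entirely
#'   (the per-batch random draws are unchanged, so generator trajectories
#'   with `lambda_disc = 0` match an adversarial run exactly).
#' @param consist_max_rows cap on latent samples used by the consistency /
#'   discriminator / entropy batch estimates.
#' @param checkpoint_every save a checkpoint every this many epochs
#'   (0 = off); `checkpoint_path` names the file.
#' @param verbose print per-epoch progress.
#' @export
train_config <- function(epochs = 150L, batch_size = 100L, lr_gen = 0.01,
                         lr_disc = 0.05, n_critic = 1L, mc_samples = 1L,
                         seed = 1L, transition_mode = "first_order",
                         adversarial = TRUE, consist_max_rows = 256L,
                         checkpoint_every = 0L, checkpoint_path = NULL,
                         verbose = FALSE) {
  stopifnot(epochs >= 1L, lr_gen > 0, lr_disc > 0, n_critic >= 1L,
            mc_samples >= 1L, batch_size >= 1L)
  transition_mode <- match.arg(transition_mode, c("first_order", "second_order"))
  structure(as.list(environment()), class = "td_train_config")
}

GEN_WEIGHT_MATS <- c("W_g", "U_g", "W_r", "U_r", "W_n", "U_n", "W_mu", "W_lv",
                     "W_lin", "W_h1", "W_h2", "W_y", "W_v", "W_x",
                     "E_sym", "E_spec", "P_attn")

TERM_WEIGHTS <- c(elbo = NA, consistency = "lambda_consist",
                  corridor = "lambda_corridor", anchor = "lambda_anchor",
                  disc = "lambda_disc", temporal = "lambda_temp",
                  margin = "lambda_sym", alignment = "lambda_align",
                  smoothness = "lambda_smooth", stage = "lambda_stage",
                  drift = "lambda_drift", shift = "lambda_shift",
                  entropy = "lambda_ent", weight_decay = "lambda_wd")

# All generator-side loss terms on one padded batch. `gp` may hold tape
# variables (training) or plain arrays (evaluation); `dp` is always treated
# as constant here. `eps` (reparameterisation noise) and `cf_Aidx` (sampled
# alternative treatments) are supplied so the map params -> loss is
# deterministic, which the finite-difference checks rely on.
gen_loss_terms <- function(batch, gp, dp, params, priors, config, eps, cf_Aidx,
                           active = NULL) {
  w <- priors$loss_weights
  need <- function(term) {
    if (!is.null(active)) return(term %in% active)
    key <- TERM_WEIGHTS[[term]]
    is.na(key) || w[[key]] > 0
  }
  B <- batch$B; Tm <- batch$T_max
  terms <- list()

  er <- elbo_rows(batch, gp, params, eps[[1L]], config$transition_mode)
  elbo_sum <- ad_sum(er$elbo)
  if (length(eps) > 1L) {
    for (s in 2:length(eps))
      elbo_sum <- ad_add(elbo_sum,
                         ad_sum(elbo_rows(batch, gp, params, eps[[s]],
                                          config$transition_mode)$elbo))
  }
  terms$elbo <- ad_div(elbo_sum, B * length(eps))
  enc <- er$enc; Evocab <- er$Evocab

  # pooled valid posterior-mean latents (row order: t-major, then patient)
  vmask <- as.vector(t(batch$valid)) == 1
  pool_idx <- which(vmask)
  if (length(pool_idx) > config$consist_max_rows) {
    pool_idx <- pool_idx[round(seq(1L, length(pool_idx),
                                   length.out = config$consist_max_rows))]
  }
  Zpool <- NULL
  get_pool <- function() {
    if (is.null(Zpool)) Zpool <<- ad_rows(ad_rbind(enc$mu), pool_idx)
    Zpool
  }
  Aflat <- as.vector(batch$Aidx)  # t-major: matches ad_rbind stacking
  cfAflat <- as.vector(cf_Aidx)

  if (need("consistency"))
    terms$consistency <- consistency_core(get_pool(), gp, params, Evocab)

  # per-timestep shifts at the posterior means (corridor / drift / shift)
  Dl <- NULL
  get_shifts <- function() {
    if (is.null(Dl)) Dl <<- lapply(seq_len(Tm), function(t)
      ad_sub(forward_transition(enc$mu[[t]], batch$Aidx[t, ], gp, params, Evocab),
             enc$mu[[t]]))
    Dl
  }

  if (need("corridor")) {
    if (is.null(priors$safe_region)) {
      terms$corridor <- 0
    } else {
      wts <- outer(seq_len(Tm), batch$T_len,
                   function(t, Ti) ifelse(t <= Ti, priors$decay_rho^(Ti - t), 0))
      Dls <- get_shifts()
      Gm <- 0
      for (t in seq_len(Tm))
        Gm <- ad_add(Gm, ad_mulcol(Dls[[t]], matrix(wts[t, ], ncol = 1L)))
      terms$corridor <- ad_div(ad_sum(corridor_rows(Gm, priors$safe_region)), B)
    }
  }

  if (need("anchor")) {
    if (is.null(priors$anchor_mean)) {
      terms$anchor <- 0
    } else {
      terms$anchor <- ad_div(ad_sum(anchor_kl_rows(enc, batch$valid,
                                                   priors$anchor_mean,
                                                   priors$anchor_var, params)), B)
    }
  }

  if (need("disc")) {
    sc <- disc_loss_core(get_pool(), Aflat[pool_idx],
                         get_pool(), cfAflat[pool_idx], gp, dp, params, eps = 1e-12)
    terms$disc <- sc
  }

  if (need("temporal")) {
    tot <- 0
    for (t in 2:max(2L, Tm)) {
      if (t > Tm) break
      d2 <- ad_rowsums(ad_square(ad_sub(enc$mu[[t]], enc$mu[[t - 1L]])))
      tot <- ad_add(tot, ad_sum(ad_mul(d2, matrix(batch$valid[t, ], ncol = 1L))))
    }
    terms$temporal <- ad_div(tot, B)
  }

  if (need("margin"))
    terms$margin <- margin_loss_core(Evocab, params$ontology, priors$margin)
  if (need("alignment"))
    terms$alignment <- align_loss_core(Evocab, params$ontology)

  dec_mu <- NULL
  get_dec <- function() {
    if (is.null(dec_mu)) dec_mu <<- lapply(seq_len(Tm), function(t)
      forward_decode(enc$mu[[t]], gp, params))
    dec_mu
  }

  if (need("smoothness")) {
    tot <- 0
    dm <- get_dec()
    for (t in 2:max(2L, Tm)) {
      if (t > Tm) break
      d2 <- ad_rowsums(ad_square(ad_sub(dm[[t]]$x_hat, dm[[t - 1L]]$x_hat)))
      tot <- ad_add(tot, ad_sum(ad_mul(d2, matrix(batch$valid[t, ], ncol = 1L))))
    }
    terms$smoothness <- ad_div(tot, B)
  }

  if (need("stage")) {
    has_curve <- !is.na(batch$stages) &
      batch$stages %in% names(priors$stage_curves %||% list())
    if (!any(has_curve)) {
      terms$stage <- 0
    } else {
      tot <- 0
      dm <- get_dec()
      for (st in unique(batch$stages[has_curve])) {
        sel <- (batch$stages == st & has_curve) * 1
        curve <- priors$stage_curves[[st]]
        for (t in seq_len(min(Tm, nrow(curve)))) {
          tgt <- matrix(curve[t, ], B, params$k, byrow = TRUE)
          d2 <- ad_rowsums(ad_square(ad_sub(dm[[t]]$y_mean, tgt)))
          tot <- ad_add(tot, ad_sum(ad_mul(d2, matrix(batch$valid[t, ] * sel,
                                                      ncol = 1L))))
        }
      }
      terms$stage <- ad_div(tot, B)
    }
  }

  if (need("drift")) {
    tot <- 0
    Dls <- get_shifts()
    for (t in 2:max(2L, Tm)) {
      if (t > Tm) break
      d2 <- ad_rowsums(ad_square(ad_sub(Dls[[t]], Dls[[t - 1L]])))
      tot <- ad_add(tot, ad_sum(ad_mul(d2, matrix(batch$valid[t, ], ncol = 1L))))
    }
    terms$drift <- ad_div(tot, B)
  }

  if (need("shift")) {
    Zp <- get_pool()
    d_real <- ad_sub(forward_transition(Zp, Aflat[pool_idx], gp, params, Evocab), Zp)
    d_cf <- ad_sub(forward_transition(Zp, cfAflat[pool_idx], gp, params, Evocab), Zp)
    terms$shift <- ad_mean(ad_rowsums(ad_square(ad_sub(d_real, d_cf))))
  }

  if (need("entropy")) {
    alpha <- attention_rows(get_pool(), gp, params)
    terms$entropy <- ad_mean(neg_entropy_rows(alpha))
  }

  if (need("weight_decay")) {
    wd <- 0
    for (nm in GEN_WEIGHT_MATS) wd <- ad_add(wd, ad_sum(ad_square(gp[[nm]])))
    terms$weight_decay <- wd
  }

  for (nm in names(TERM_WEIGHTS)) if (is.null(terms[[nm]])) terms[[nm]] <- 0
  terms
}

compose_total <- function(terms, w) {
  total <- ad_neg(terms$elbo)
  for (nm in names(TERM_WEIGHTS)) {
    key <- TERM_WEIGHTS[[nm]]
    if (is.na(key)) next
    lam <- w[[key]]
    if (lam > 0 || (!is.numeric(terms[[nm]]) || vof(terms[[nm]]) != 0))
      total <- ad_add(total, ad_mul(lam, terms[[nm]]))
  }
  total
}

# seeded per-batch constants: reparameterisation noise and alternative
# treatments sampled uniformly from the vocabulary excluding the factual one
draw_batch_noise <- function(batch, params, config) {
  eps <- lapply(seq_len(config$mc_samples), function(s)
    lapply(seq_len(batch$T_max), function(t)
      matrix(stats::rnorm(batch$B * params$d_z), batch$B, params$d_z)))
  n_treat <- length(params$ontology$vocabulary)
  cf <- batch$Aidx
  if (n_treat > 1L) {
    u <- matrix(sample.int(n_treat - 1L, length(cf), replace = TRUE),
                nrow(cf), ncol(cf))
    cf <- ifelse(u < cf, u, u + 1L)  # uniform over vocabulary \ {factual}
  }
  list(eps = eps, cf_Aidx = cf)
}

#' Composite generator objective with per-term breakdown
#'
#' Computes the total loss the generator descends:
#' `-ELBO + lambda_consist L_consist + lambda_corridor R_corridor +
#'  lambda_anchor R_anchor + lambda_disc L_disc + lambda_temp R_temp`
#' plus the auxiliary embedding, smoothness, stage, drift, shift-alignment,
#' attention-entropy and weight-decay terms. The discriminator term enters
#' with positive weight because the generator *descends* `L_disc`
#' (adversarially shrinking the discriminator's objective) while the
#' discriminator ascends it.
#'
#' @param cohort a `td_cohort` (the evaluation batch).
#' @param params a `td_params`.
#' @param priors a [clinical_priors()] carrying the loss weights.
#' @param config a [train_config()] (transition mode, seeds).
#' @param seed seed for the Monte-Carlo draws inside the objective.
#' @return `list(total, breakdown)` where `breakdown` is a tibble with one
#'   row per term (`term`, `value`, `weight`, `contribution`); contributions
#'   sum to `total` exactly.
#' @export
total_generator_loss <- function(cohort, params, priors = clinical_priors(),
                                 config = train_config(), seed = 1L) {
  trs <- as_trajectories(cohort)
  batch <- make_batch(trs, params)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  nz <- draw_batch_noise(batch, params, config)
  terms <- gen_loss_terms(batch, params$gen, params$disc, params, priors,
                          config, nz$eps, nz$cf_Aidx)
  w <- priors$loss_weights
  vals <- vapply(names(TERM_WEIGHTS), function(nm) as.numeric(vof(terms[[nm]])), 0)
  for (nm in names(vals)) if (!is.finite(vals[[nm]]))
    stop("non-finite loss term: ", nm)
  weights <- vapply(names(TERM_WEIGHTS), function(nm) {
    key <- TERM_WEIGHTS[[nm]]
    if (is.na(key)) -1 else w[[key]]
  }, 0)
  contribution <- vals * weights
  total <- sum(contribution)
  list(total = total,
       breakdown = tibble::tibble(term = names(TERM_WEIGHTS),
                                  value = unname(vals),
                                  weight = unname(weights),
                                  contribution = unname(contribution)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Adam -----------------------------------------------------------------

adam_init <- function(pl) {
  list(m = lapply(pl, function(p) p * 0), v = lapply(pl, function(p) p * 0),
       t = 0L)
}

adam_update <- function(pl, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pl)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    pl[[nm]] <- pl[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(pl = pl, state = state)
}

# ---- training loop --------------------------------------------------------

#' Fit the model by dual-loop adversarial optimisation
#'
#' Alternates `n_critic` discriminator ascent steps on the adversarial
#' objective with one generator descent step on the composite objective, per
#' minibatch of patients. Fully reproducible given `config$seed`
#' (single-threaded, one RNG stream). If the loss becomes non-finite the run
#' aborts and returns the parameters from the last completed epoch.
#'
#' @param cohort a `td_cohort`.
#' @param ontology a [ontology()] covering the cohort's treatments.
#' @param priors a [clinical_priors()].
#' @param config a [train_config()].
#' @param params optional warm-start `td_params`; initialised from
#'   (`ontology`, dimensions, `config$seed`) when `NULL`.
#' @param d_z,m,d_h latent / embedding / recurrent sizes for initialisation.
#' @param resume_from path to a checkpoint written by this function; training
#'   continues from its stored epoch, optimiser and RNG state.
#' @return a `td_fit`: `list(params, history, config, priors, diverged)`.
#'   `history` is a long tibble (epoch, term, value) of every objective term.
#' @export
fit_treatdyn <- function(cohort, ontology, priors = clinical_priors(),
                         config = train_config(), params = NULL,
                         d_z = 4L, m = 4L, d_h = 16L, resume_from = NULL) {
  trs <- as_trajectories(cohort)
  start_epoch <- 1L
  adam_g <- adam_d <- NULL
  history <- list()
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    params <- ck
    extra <- ck$extra
    start_epoch <- extra$epoch + 1L
    adam_g <- restore_adam(extra$adam_gen)
    adam_d <- restore_adam(extra$adam_disc)
    history <- list(tibble::as_tibble(extra$history))
    set_rng_state(as.integer(extra$rng))
  } else if (is.null(params)) {
    params <- init_params(ontology, d_x = attr(cohort, "d_x"),
                          k = attr(cohort, "k"), d_z = d_z, m = m, d_h = d_h,
                          seed = config$seed)
  }
  if (is.null(adam_g)) adam_g <- adam_init(params$gen)
  if (is.null(adam_d)) adam_d <- adam_init(params$disc)
  if (is.null(resume_from)) set.seed(config$seed)

  n <- length(trs)
  w <- priors$loss_weights
  diverged <- FALSE
  last_good <- params

  for (epoch in seq.int(start_epoch, config$epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    epoch_terms <- NULL
    for (b in seq_len(nb)) {
      idx <- ord[seq.int((b - 1L) * config$batch_size + 1L,
                         min(b * config$batch_size, n))]
      batch <- make_batch(trs[idx], params)
      nz <- draw_batch_noise(batch, params, config)

      # discriminator ascent on L_disc (inputs detached: numeric forward)
      if (config$adversarial) {
        vmask <- which(as.vector(t(batch$valid)) == 1)
        if (length(vmask) > config$consist_max_rows)
          vmask <- vmask[round(seq(1L, length(vmask),
                                   length.out = config$consist_max_rows))]
        encn <- forward_encoder(batch, params$gen, params)
        Zn <- do.call(rbind, encn$mu)[vmask, , drop = FALSE]
        ar <- as.vector(batch$Aidx)[vmask]
        ac <- as.vector(nz$cf_Aidx)[vmask]
        for (cstep in seq_len(config$n_critic)) {
          tape <- ad_tape()
          dv <- tape_vars(tape, params$disc)
          dloss <- ad_neg(disc_loss_core(Zn, ar, Zn, ac, params$gen, dv,
                                         params, eps = 1e-12))
          gd <- grads_for(ad_backward(dloss), dv)
          names(gd) <- names(params$disc)
          up <- adam_update(params$disc, gd, adam_d, config$lr_disc)
          params$disc <- up$pl; adam_d <- up$state
        }
      }

      # generator descent on the composite objective
      tape <- ad_tape()
      gv <- tape_vars(tape, params$gen)
      terms <- gen_loss_terms(batch, gv, params$disc, params, priors, config,
                              nz$eps, nz$cf_Aidx)
      total <- compose_total(terms, w)
      tv <- vof(total)
      if (!is.finite(tv)) { diverged <- TRUE; break }
      gg <- grads_for(ad_backward(total), gv)
      names(gg) <- names(params$gen)
      up <- adam_update(params$gen, gg, adam_g, config$lr_gen)
      params$gen <- up$pl; adam_g <- up$state

      vals <- vapply(names(TERM_WEIGHTS), function(nm)
        as.numeric(vof(terms[[nm]])), 0)
      vals["total"] <- tv
      epoch_terms <- rbind(epoch_terms, vals)
    }
    if (diverged) {
      warning("non-finite loss at epoch ", epoch,
              "; returning last completed epoch")
      params <- last_good
      break
    }
    last_good <- params
    hrow <- tibble::tibble(epoch = epoch,
                           term = colnames(epoch_terms),
                           value = unname(colMeans(epoch_terms)))
    history[[length(history) + 1L]] <- hrow
    if (config$verbose)
      message(sprintf("epoch %d  -ELBO %.4f  total %.4f", epoch,
                      -hrow$value[hrow$term == "elbo"],
                      hrow$value[hrow$term == "total"]))
    if (config$checkpoint_every > 0L && !is.null(config$checkpoint_path) &&
        epoch %% config$checkpoint_every == 0L) {
      save_checkpoint(params, config$checkpoint_path,
                      extra = list(epoch = epoch, adam_gen = adam_g,
                                   adam_disc = adam_d,
                                   rng = get_rng_state(),
                                   history = dplyr::bind_rows(history)))
    }
  }

  structure(list(params = params, history = dplyr::bind_rows(history),
                 config = config, priors = priors, diverged = diverged),
            class = "td_fit")
}

restore_adam <- function(x) {
  list(m = restore_shapes(x$m), v = restore_shapes(x$v), t = as.integer(x$t))
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradient of one objective term (or the total) with
#' central finite differences, entry by entry, over the generator parameters
#' (`term = "disc_psi"` checks the discriminator's own gradient instead).
#' Intended for small fixtures (a few hundred parameters).
#'
#' @param params a `td_params`.
#' @param cohort a small `td_cohort`.
#' @param term one of the objective term names (see
#'   [total_generator_loss()]'s breakdown), `"total"`, or `"disc_psi"`.
#' @param priors,config as in [fit_treatdyn()].
#' @param seed seed fixing the Monte-Carlo draws inside the objective.
#' @param h finite-difference step.
#' @return a `td_gradcheck` list: `max_rel_err`, plus flattened `analytic`
#'   and `numeric` gradient vectors.
#' @export
gradient_check <- function(params, cohort, term = "total",
                           priors = clinical_priors(), config = train_config(),
                           seed = 1L, h = 1e-5) {
  trs <- as_trajectories(cohort)
  batch <- make_batch(trs, params)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  nz <- draw_batch_noise(batch, params, config)
  w <- priors$loss_weights

  disc_side <- identical(term, "disc_psi")
  value_of <- function(gen, disc) {
    p2 <- params; p2$gen <- gen; p2$disc <- disc
    if (disc_side) {
      vmask <- which(as.vector(t(batch$valid)) == 1)
      encn <- forward_encoder(batch, gen, p2)
      Zn <- do.call(rbind, lapply(encn$mu, vof))[vmask, , drop = FALSE]
      return(vof(disc_loss_core(Zn, as.vector(batch$Aidx)[vmask], Zn,
                                as.vector(nz$cf_Aidx)[vmask], gen, disc, p2,
                                eps = 1e-12)))
    }
    terms <- gen_loss_terms(batch, gen, disc, p2, priors, config, nz$eps,
                            nz$cf_Aidx,
                            active = if (term == "total") NULL else term)
    if (term == "total") vof(compose_total(terms, w)) else vof(terms[[term]])
  }

  # analytic
  tape <- ad_tape()
  if (disc_side) {
    dv <- tape_vars(tape, params$disc)
    vmask <- which(as.vector(t(batch$valid)) == 1)
    encn <- forward_encoder(batch, params$gen, params)
    Zn <- do.call(rbind, encn$mu)[vmask, , drop = FALSE]
    obj <- disc_loss_core(Zn, as.vector(batch$Aidx)[vmask], Zn,
                          as.vector(nz$cf_Aidx)[vmask], params$gen, dv,
                          params, eps = 1e-12)
    ga <- grads_for(ad_backward(obj), dv)
    target <- params$disc
  } else {
    gv <- tape_vars(tape, params$gen)
    terms <- gen_loss_terms(batch, gv, params$disc, params, priors, config,
                            nz$eps, nz$cf_Aidx,
                            active = if (term == "total") NULL else term)
    obj <- if (term == "total") compose_total(terms, w) else terms[[term]]
    if (!is_advar(obj)) { # term identically zero for this fixture
      ga <- lapply(params$gen, function(p) 0 * p)
    } else {
      ga <- grads_for(ad_backward(obj), gv)
    }
    target <- params$gen
  }
  names(ga) <- names(target)

  gn <- lapply(target, function(p) 0 * p)
  for (nm in names(target)) {
    p <- target[[nm]]
    for (i in seq_along(p)) {
      hp <- h * max(1, abs(p[i]))
      pp <- p; pp[i] <- pp[i] + hp
      pm <- p; pm[i] <- pm[i] - hp
      tp <- target; tp[[nm]] <- pp
      tm <- target; tm[[nm]] <- pm
      fp <- if (disc_side) value_of(params$gen, tp) else value_of(tp, params$disc)
      fm <- if (disc_side) value_of(params$gen, tm) else value_of(tm, params$disc)
      gn[[nm]][i] <- (fp - fm) / (2 * hp)
    }
  }
  av <- unlist(ga); nv <- unlist(gn)
  rel <- abs(av - nv) / pmax(1e-6, abs(av) + abs(nv))
  structure(list(term = term, max_rel_err = max(rel),
                 analytic = av, numeric = nv),
            class = "td_gradcheck")
}
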