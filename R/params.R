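#' Initialise model parameters
#'
#' Builds the full learnable parameter set: the gated-recurrent recognition
#' network (posterior encoder), the latent transition network
#' `f_theta(z, e(a)) = z + [z, e] W_lin + b_lin + tanh([z, e] W_h1 + b_h1) W_h2 + b_h2`
#' (a linear pathway plus a nonlinear residual; zeroing the residual gives an
#' exactly linear transition, zeroing everything gives the identity), the
#' heteroscedastic outcome decoder and covariate decoder, the compositional
#' treatment embedding tables (class-shared `E_sym` plus treatment-specific
#' `E_spec`), the latent-to-embedding attention projection, the
#' second-order coupling scalar `gamma`, the transition noise scale, the
#' initial-state prior, and the factual/counterfactual discriminator.
#'
#' Positive quantities (noise scales, variances) are parameterised through
#' softplus links with small floors.
#'
#' @param ontology a [ontology()]; embeddings cover its vocabulary.
#' @param d_x,k observed covariate / outcome dimensions.
#' @param d_z latent dimension.
#' @param m treatment-embedding dimension.
#' @param d_h recurrent hidden size; `n_h` transition hidden size; `n_d`
#'   discriminator hidden size.
#' @param y_act,x_act decoder mean activations; `"relu"` / `"tanh"` are the
#'   standard forms, `"identity"` yields an exactly linear decoder (used to
#'   realise linear-Gaussian members of the model family for validation).
#' @param gate_attention if `TRUE` the transition consumes `e(a_t)` scaled by
#'   the class-attention weight of `a_t`'s class (an interpretation of
#'   attention-modulated treatment influence; off by default).
#' @param seed integer seed for the random initialisation.
#' @return a `td_params` list with components `gen` (generator), `disc`
#'   (discriminator) and architecture metadata.
#' @export
init_params <- function(ontology, d_x, k, d_z = 4L, m = 4L, d_h = 16L,
                        n_h = 16L, n_d = 8L, y_act = "relu", x_act = "tanh",
                        gate_attention = FALSE, seed = 1L) {
  stopifnot(inherits(ontology, "td_ontology"))
  y_act <- match.arg(y_act, c("relu", "identity"))
  x_act <- match.arg(x_act, c("tanh", "identity"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  n_treat <- length(ontology$vocabulary)
  n_class <- length(ontology$classes)
  d_in <- d_x + 2L * k + m
  rmat <- function(a, b, scale = 1 / sqrt(a)) matrix(stats::rnorm(a * b, sd = scale), a, b)

  gen <- list(
    # GRU recognition network
    W_g = rmat(d_in, d_h), U_g = rmat(d_h, d_h), b_g = rep(0, d_h),
    W_r = rmat(d_in, d_h), U_r = rmat(d_h, d_h), b_r = rep(0, d_h),
    W_n = rmat(d_in, d_h), U_n = rmat(d_h, d_h), b_n = rep(0, d_h),
    W_mu = rmat(d_h, d_z), b_mu = rep(0, d_z),
    W_lv = rmat(d_h, d_z), b_lv = rep(0, d_z),
    # transition: linear pathway initialised to zero (f ~ identity at init)
    W_lin = matrix(0, d_z + m, d_z), b_lin = rep(0, d_z),
    W_h1 = rmat(d_z + m, n_h), b_h1 = rep(0, n_h),
    W_h2 = matrix(0, n_h, d_z), b_h2 = rep(0, d_z),
    sigma_raw = softplus_inv(0.2),
    gamma = 0.5,
    # decoders
    W_y = rmat(d_z, k), b_y = rep(0, k),
    W_v = matrix(0, d_z, k), b_v = rep(softplus_inv(0.5), k),
    W_x = rmat(d_z, d_x), b_x = rep(0, d_x),
    x_logvar_raw = softplus_inv(0.5),
    # embeddings and attention projection
    E_sym = rmat(n_class, m, 0.3), E_spec = rmat(n_treat, m, 0.1),
    P_attn = rmat(d_z, m),
    # initial-state prior
    mu0 = rep(0, d_z), lv0 = rep(softplus_inv(1), d_z)
  )
  disc <- list(
    W_d1 = rmat(d_z + m, n_d), b_d1 = rep(0, n_d),
    W_d2 = rmat(n_d, 1L), b_d2 = 0
  )
  structure(list(gen = gen, disc = disc,
                 d_x = d_x, k = k, d_z = d_z, m = m, d_h = d_h,
                 n_h = n_h, n_d = n_d, y_act = y_act, x_act = x_act,
                 gate_attention = gate_attention,
                 var_floor_y = 1e-4, var_floor_q = 1e-6,
                 class_idx = unname(class_index(ontology$vocabulary, ontology)),
                 ontology = ontology),
            class = "td_params")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON archive holding every parameter array at
#' full precision plus a sidecar block (dimensions, activation choices,
#' creation seed hash, package version). `load_checkpoint()` refuses files
#' whose dimensions do not match their own sidecar.
#'
#' @param params a `td_params`.
#' @param path file path.
#' @param extra optional named list stored alongside (e.g. optimiser state).
#' @export
save_checkpoint <- function(params, path, extra = NULL) {
  meta <- params[c("d_x", "k", "d_z", "m", "d_h", "n_h", "n_d",
                   "y_act", "x_act", "gate_attention",
                   "var_floor_y", "var_floor_q", "class_idx")]
  obj <- list(meta = meta,
              version = as.character(utils::packageVersion("treatdyn")),
              gen = params$gen, disc = params$disc,
              ontology = list(class_of = as.list(params$ontology$class_of),
                              similarity_edges = apply(params$ontology$similarity_edges,
                                                       1L, as.list, simplify = FALSE)),
              extra = extra)
  writeLines(as.character(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  onto <- ontology(vapply(o$ontology$class_of, as.character, ""),
                   similarity_edges = edges_from_json(o$ontology$similarity_edges))
  gen <- restore_shapes(o$gen)
  disc <- restore_shapes(o$disc)
  p <- structure(c(list(gen = gen, disc = disc), o$meta,
                   list(ontology = onto)),
                 class = "td_params")
  chk <- function(cond, what) if (!cond) stop("checkpoint dimension mismatch: ", what)
  chk(ncol(gen$W_mu) == p$d_z, "W_mu/d_z")
  chk(nrow(gen$W_g) == p$d_x + 2L * p$k + p$m, "encoder input width")
  chk(nrow(gen$E_spec) == length(onto$vocabulary), "E_spec vocabulary size")
  chk(nrow(gen$E_sym) == length(onto$classes), "E_sym class count")
  chk(nrow(gen$W_y) == p$d_z && ncol(gen$W_y) == p$k, "outcome decoder")
  chk(ncol(gen$W_x) == p$d_x, "covariate decoder")
  p$extra <- o$extra
  p
}

restore_shapes <- function(lst) {
  lapply(lst, function(v) if (is.matrix(v)) v else if (length(v) == 1L) as.numeric(v) else as.numeric(v))
}

# flatten generator parameters into advar leaves on a tape
gen_vars <- function(tape, params) tape_vars(tape, params$gen)
disc_vars <- function(tape, params) tape_vars(tape, params$disc)

sigma_of <- function(gp) ad_add(ad_softplus(gp$sigma_raw), 1e-4)
xvar_of <- function(gp) ad_add(ad_softplus(gp$x_logvar_raw), 1e-4)

# embedding matrix for the whole vocabulary: row i = E_sym[class(i)] + E_spec[i]
vocab_embeddings <- function(gp, class_idx) {
  ad_add(ad_rows(gp$E_sym, class_idx), gp$E_spec)
}

#' Embed a linear-Gaussian ground truth in the model family
#'
#' Constructs a `td_params` whose generative part equals the simulator's
#' linear-Gaussian process exactly: identity-activation decoders with
#' `W_y = D`, `W_x = C`, constant outcome variance `sigma_y^2`, a purely
#' linear transition with `W_lin = [A - I; I]` and treatment embeddings
#' (`m = d_z`) equal to the true class effects plus offsets, transition noise
#' `sigma_z`, and the true initial-state prior. The recognition network stays
#' randomly initialised: any posterior gives a valid lower bound on the exact
#' (Kalman) evidence of this generative model.
#'
#' @param truth a `td_ground_truth`.
#' @param d_h recognition-network hidden size.
#' @param seed seed for the encoder initialisation.
#' @return a `td_params`.
#' @export
params_from_truth <- function(truth, d_h = 8L, seed = 1L) {
  d_z <- length(truth$z1_mean)
  p <- init_params(truth$ontology, d_x = nrow(truth$C), k = nrow(truth$D),
                   d_z = d_z, m = d_z, d_h = d_h,
                   y_act = "identity", x_act = "identity", seed = seed)
  g <- p$gen
  g$W_lin <- rbind(t(truth$A) - diag(d_z), diag(d_z))
  g$b_lin <- rep(0, d_z)
  g$W_h2 <- 0 * g$W_h2  # no nonlinear residual
  g$b_h2 <- rep(0, d_z)
  g$E_sym <- do.call(rbind, truth$class_effects[truth$ontology$classes])
  g$E_spec <- do.call(rbind, truth$specific_offsets[truth$ontology$vocabulary])
  g$W_y <- t(truth$D); g$b_y <- rep(0, nrow(truth$D))
  g$W_x <- t(truth$C); g$b_x <- rep(0, nrow(truth$C))
  g$W_v <- 0 * g$W_v
  g$b_v <- rep(softplus_inv(truth$sigma_y^2 - p$var_floor_y), nrow(truth$D))
  g$x_logvar_raw <- softplus_inv(truth$sigma_x^2 - 1e-4)
  g$sigma_raw <- softplus_inv(truth$sigma_z - 1e-4)
  g$mu0 <- truth$z1_mean
  g$lv0 <- softplus_inv(truth$z1_var - p$var_floor_q)
  p$gen <- g
  p
}
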