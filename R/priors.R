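#' Default loss weights
#'
#' Weights for the composite generator objective: `lambda_consist`,
#' `lambda_corridor`, `lambda_anchor`, `lambda_disc`, `lambda_temp` (the five
#' core penalties, default 0.1 each) plus the auxiliary weights
#' `lambda_sym`, `lambda_align`, `lambda_smooth` (default 1e-2),
#' `lambda_stage`, `lambda_drift`, `lambda_shift`, `lambda_ent` (default 0)
#' and the weight-decay coefficient `lambda_wd` (default 1e-4). Setting all
#' auxiliary weights to zero recovers the five-term composite objective.
#'
#' @param ... overrides by name.
#' @export
default_loss_weights <- function(...) {
  w <- list(lambda_consist = 0.1, lambda_corridor = 0.1, lambda_anchor = 0.1,
            lambda_disc = 0.1, lambda_temp = 0.1,
            lambda_sym = 1e-2, lambda_align = 1e-2, lambda_smooth = 1e-2,
            lambda_stage = 0, lambda_drift = 0, lambda_shift = 0,
            lambda_ent = 0, lambda_wd = 1e-4)
  over <- list(...)
  bad <- setdiff(names(over), names(w))
  if (length(bad)) stop("unknown loss weight(s): ", paste(bad, collapse = ", "))
  w[names(over)] <- over
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0")
  w
}

#' Clinical priors for knowledge infusion
#'
#' Bundles the domain-knowledge inputs of the knowledge-infusion losses: the
#' anchoring prior `pi(z)` (a diagonal Gaussian, either one `(mu0, var0)` pair
#' used at every timestep or per-timestep rows), the safety corridor `C_safe`
#' for cumulative latent deviation (axis-aligned box or L2 ball), optional
#' per-stage expected outcome curves `mu_stage(t)`, the geometric decay rate
#' `rho` of the cumulative-influence weights `w_t = rho^(T-t)`, the composite
#' loss weights, and the intra-class margin `delta`.
#'
#' @param anchor_mean numeric vector (length d_z) or T x d_z matrix.
#' @param anchor_var strictly positive; same shape as `anchor_mean`.
#' @param safe_region `list(type = "box", lower, upper)` or
#'   `list(type = "ball", center, radius)`.
#' @param stage_curves named list: stage label -> T x k matrix (or length-T
#'   vector when k = 1) of expected outcomes.
#' @param decay_rho real in (0, 1].
#' @param loss_weights see [default_loss_weights()].
#' @param margin intra-class embedding margin `delta >= 0`.
#' @return a `td_priors` list.
#' @export
clinical_priors <- function(anchor_mean = NULL, anchor_var = NULL,
                            safe_region = NULL, stage_curves = NULL,
                            decay_rho = 1, loss_weights = default_loss_weights(),
                            margin = 0.1) {
  if (!is.null(anchor_mean)) {
    if (is.null(anchor_var)) stop("anchor_var required with anchor_mean")
    anchor_mean <- as_matrix_rows(anchor_mean)
    anchor_var <- as_matrix_rows(anchor_var)
    if (!identical(dim(anchor_mean), dim(anchor_var)))
      stop("anchor_mean and anchor_var must have the same shape")
    if (any(anchor_var <= 0)) stop("anchor_var must be strictly positive")
  }
  if (!is.null(safe_region)) safe_region <- check_safe_region(safe_region)
  if (!is.null(stage_curves)) {
    if (is.null(names(stage_curves))) stop("stage_curves must be a named list")
    stage_curves <- lapply(stage_curves, function(cv)
      if (is.matrix(cv)) cv else matrix(cv, ncol = 1L))
  }
  if (!(decay_rho > 0 && decay_rho <= 1)) stop("decay_rho must lie in (0, 1]")
  if (margin < 0) stop("margin delta must be >= 0")
  structure(list(anchor_mean = anchor_mean, anchor_var = anchor_var,
                 safe_region = safe_region, stage_curves = stage_curves,
                 decay_rho = decay_rho, loss_weights = loss_weights,
                 margin = margin),
            class = "td_priors")
}

as_matrix_rows <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1L)

check_safe_region <- function(region) {
  if (is.null(region$type)) stop("safe_region needs a 'type' ('box' or 'ball')")
  if (region$type == "box") {
    if (length(region$lower) != length(region$upper))
      stop("box lower/upper lengths differ")
    if (any(region$lower > region$upper))
      stop("box requires lower <= upper elementwise")
  } else if (region$type == "ball") {
    if (is.null(region$center) || is.null(region$radius))
      stop("ball region needs center and radius")
    if (region$radius <= 0) stop("ball radius must be > 0")
  } else stop("unknown safe_region type: ", region$type)
  region
}

#' Build clinical priors from a configuration list
#'
#' Converts the `priors:` block of a run configuration (e.g. parsed from
#' YAML) into a [clinical_priors()] object. The schema, annotated:
#'
#' ```yaml
#' priors:
#'   anchor:                 # anchoring prior pi(z), diagonal Gaussian
#'     mean: [0, 0, 0, 0]    #   one row used at every timestep
#'     var: [1, 1, 1, 1]     #   (or T x d_z matrices for per-timestep priors)
#'   safe_region:            # safety corridor C_safe
#'     type: box             #   "box" (lower/upper) or "ball" (center/radius)
#'     lower: [-2, -2, -2, -2]
#'     upper: [2, 2, 2, 2]
#'   stage_curves:           # expected outcome per disease stage, length T
#'     early: [[0.1], [0.2], [0.3]]
#'   decay_rho: 0.9          # geometric decay of cumulative influence
#'   margin: 0.1             # intra-class embedding margin delta
#'   weights:                # composite-loss weights (lambda_*)
#'     lambda_consist: 0.1
#'     lambda_disc: 0.1
#' ```
#'
#' @param x a named list (typically `yaml::read_yaml(f)$priors`).
#' @return a `td_priors`.
#' @export
priors_from_config <- function(x) {
  if (is.null(x)) return(clinical_priors())
  w <- do.call(default_loss_weights, as.list(x$weights %||% list()))
  sc <- if (!is.null(x$stage_curves))
    lapply(x$stage_curves, function(cv) {
      if (is.list(cv)) do.call(rbind, lapply(cv, as.numeric)) else as.matrix(cv)
    })
  sr <- if (!is.null(x$safe_region)) {
    r <- x$safe_region
    lapply(r, function(v) if (is.list(v)) unlist(v) else v)
  }
  clinical_priors(anchor_mean = if (!is.null(x$anchor)) to_mat(x$anchor$mean),
                  anchor_var = if (!is.null(x$anchor)) to_mat(x$anchor$var),
                  safe_region = sr, stage_curves = sc,
                  decay_rho = x$decay_rho %||% 1,
                  loss_weights = w, margin = x$margin %||% 0.1)
}

to_mat <- function(v) {
  if (is.null(v)) return(NULL)
  if (is.list(v)) do.call(rbind, lapply(v, as.numeric)) else as.numeric(v)
}
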