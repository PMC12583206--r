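#' Longitudinal treatment-response cohorts
#'
#' A cohort is a long-format tibble with one row per patient-timestep and
#' columns `patient_id`, `t`, covariates `x1..x<d_x>`, the treatment id `a`,
#' outcomes `y1..y<k>`, and the binary outcome-availability mask `m1..m<k>`
#' (1 = observed). An optional `stage` column carries a per-patient disease
#' stage label. Time is an integer index `t = 1..T` per patient; trajectory
#' lengths may differ between patients.
#'
#' @param data a data frame in the long schema above.
#' @param d_x,k covariate and outcome dimensions; inferred from column names
#'   when `NULL`.
#' @return a `td_cohort` tibble.
#' @export
cohort <- function(data, d_x = NULL, k = NULL) {
  df <- tibble::as_tibble(data)
  if (is.null(d_x)) d_x <- sum(grepl("^x[0-9]+$", names(df)))
  if (is.null(k)) k <- sum(grepl("^y[0-9]+$", names(df)))
  need <- c("patient_id", "t", paste0("x", seq_len(d_x)), "a",
            paste0("y", seq_len(k)), paste0("m", seq_len(k)))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$t <- as.integer(df$t)
  df$a <- as.character(df$a)
  for (cl in c(paste0("x", seq_len(d_x)), paste0("y", seq_len(k)),
               paste0("m", seq_len(k))))
    df[[cl]] <- as.numeric(df[[cl]])
  df <- dplyr::arrange(df, .data$patient_id, .data$t)
  structure(df, d_x = d_x, k = k,
            class = c("td_cohort", class(tibble::tibble())))
}

#' @export
dim_x <- function(cohort) attr(cohort, "d_x")
#' @export
dim_y <- function(cohort) attr(cohort, "k")

xcols <- function(ch) paste0("x", seq_len(attr(ch, "d_x")))
ycols <- function(ch) paste0("y", seq_len(attr(ch, "k")))
mcols <- function(ch) paste0("m", seq_len(attr(ch, "k")))

#' Split a cohort into per-patient trajectories
#'
#' @param cohort a `td_cohort`.
#' @return a named list with one element per patient:
#'   `list(patient_id, x (T x d_x), a (length-T character), y (T x k),
#'   m (T x k), stage)`.
#' @export
as_trajectories <- function(cohort) {
  d_x <- attr(cohort, "d_x"); k <- attr(cohort, "k")
  sp <- split(as.data.frame(cohort), cohort$patient_id)
  out <- lapply(sp, function(df) {
    df <- df[order(df$t), , drop = FALSE]
    list(patient_id = df$patient_id[1],
         x = as.matrix(df[, paste0("x", seq_len(d_x)), drop = FALSE]),
         a = df$a,
         y = as.matrix(df[, paste0("y", seq_len(k)), drop = FALSE]),
         m = as.matrix(df[, paste0("m", seq_len(k)), drop = FALSE]),
         stage = if ("stage" %in% names(df)) df$stage[1] else NA_character_)
  })
  out[unique(cohort$patient_id)]
}

#' Assemble a cohort from a list of trajectories
#' @param trajectories list in the `as_trajectories()` format.
#' @export
cohort_from_trajectories <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    T_ <- nrow(tr$x)
    df <- tibble::tibble(patient_id = tr$patient_id, t = seq_len(T_))
    x <- tr$x; colnames(x) <- paste0("x", seq_len(ncol(x)))
    y <- tr$y; colnames(y) <- paste0("y", seq_len(ncol(y)))
    m <- tr$m; colnames(m) <- paste0("m", seq_len(ncol(m)))
    df <- dplyr::bind_cols(df, tibble::as_tibble(x))
    df$a <- tr$a
    df <- dplyr::bind_cols(df, tibble::as_tibble(y), tibble::as_tibble(m))
    if (!is.null(tr$stage) && !is.na(tr$stage)) df$stage <- tr$stage
    df
  })
  cohort(dplyr::bind_rows(rows),
         d_x = ncol(trajectories[[1]]$x), k = ncol(trajectories[[1]]$y))
}

#' Read a cohort from JSON Lines
#'
#' One JSON object per patient:
#' `{"patient_id": str, "x": [[...]], "a": [str,...], "y": [[...]], "m": [[0/1,...]]}`,
#' with optional `"stage": str`.
#'
#' @param path file path.
#' @param ontology optional [ontology()]; when supplied every treatment id is
#'   checked against its vocabulary.
#' @return a validated `td_cohort`.
#' @export
read_cohort <- function(path, ontology = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trajectories: cohort file is empty")
  trajs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop("parse error on line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    for (f in c("patient_id", "x", "a", "y", "m"))
      if (is.null(rec[[f]])) stop("parse error on line ", i, ": missing field '", f, "'")
    list(patient_id = as.character(rec$patient_id),
         x = as_T_matrix(rec$x), a = as.character(rec$a),
         y = as_T_matrix(rec$y), m = as_T_matrix(rec$m),
         stage = if (is.null(rec$stage)) NA_character_ else as.character(rec$stage))
  })
  ch <- cohort_from_trajectories(trajs)
  validate_cohort(ch, ontology)
  ch
}

as_T_matrix <- function(v) {
  if (is.matrix(v)) v else matrix(as.numeric(v), ncol = 1L)
}

#' Write a cohort to JSON Lines
#' @param cohort a `td_cohort`.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  trs <- as_trajectories(cohort)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (tr in trs) {
    obj <- list(patient_id = jsonlite::unbox(tr$patient_id),
                x = tr$x, a = tr$a, y = tr$y, m = tr$m)
    if (!is.na(tr$stage)) obj$stage <- jsonlite::unbox(tr$stage)
    writeLines(as.character(jsonlite::toJSON(obj, digits = I(17))), con)
  }
  invisible(path)
}

#' Read a cohort from long-format CSV
#'
#' Columns `patient_id, t, x1.., a, y1.., m1..` (underscored variants
#' `x_1, y_1, m_1` are accepted), optional `stage`.
#' @inheritParams read_cohort
#' @export
read_cohort_csv <- function(path, ontology = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("^(x|y|m)_([0-9]+)$", "\\1\\2", names(df))
  ch <- cohort(df)
  validate_cohort(ch, ontology)
  ch
}

#' Validate a cohort and summarise its missingness
#'
#' Raises an error on any invariant violation (empty cohort, non-binary mask,
#' non-finite covariates/masked-in outcomes, duplicated timesteps, treatments
#' outside the ontology vocabulary); otherwise returns a summary report.
#'
#' @param cohort a `td_cohort`.
#' @param ontology optional [ontology()] used to check treatment ids.
#' @return a list with `n_patients`, `n_timesteps`, and a tibble
#'   `missingness` with the per-outcome-dimension missingness rate
#'   (`1 - mean(mask)`).
#' @export
validate_cohort <- function(cohort, ontology = NULL) {
  d_x <- attr(cohort, "d_x"); k <- attr(cohort, "k")
  if (is.null(d_x) || is.null(k)) stop("not a td_cohort: use cohort() first")
  if (!nrow(cohort)) stop("no trajectories: cohort is empty")
  mm <- as.matrix(cohort[, mcols(cohort), drop = FALSE])
  if (!all(mm %in% c(0, 1))) stop("validation error: outcome_mask entries must be exactly 0 or 1")
  xx <- as.matrix(cohort[, xcols(cohort), drop = FALSE])
  if (!all(is.finite(xx))) stop("validation error: non-finite covariate values")
  yy <- as.matrix(cohort[, ycols(cohort), drop = FALSE])
  if (!all(is.finite(yy[mm == 1]))) stop("validation error: non-finite masked-in outcome values")
  bad_t <- cohort |>
    dplyr::count(.data$patient_id, .data$t) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(bad_t)) stop("validation error: duplicated timesteps for patient ",
                        bad_t$patient_id[1])
  tmin <- tapply(cohort$t, cohort$patient_id, min)
  if (any(tmin != 1L)) stop("validation error: trajectories must start at t = 1")
  if (!is.null(ontology)) {
    unknown <- setdiff(unique(cohort$a), ontology$vocabulary)
    if (length(unknown)) stop("validation error: unknown treatment id(s): ",
                              paste(unknown, collapse = ", "))
  }
  list(n_patients = dplyr::n_distinct(cohort$patient_id),
       n_timesteps = nrow(cohort),
       missingness = tibble::tibble(outcome = ycols(cohort),
                                    rate = unname(1 - colMeans(mm))))
}
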