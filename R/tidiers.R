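# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x a `td_fit`.
#' @param ... unused.
#' @return long tibble with `epoch`, `term`, `value`.
#' @method tidy td_fit
#' @export
tidy.td_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x a `td_fit`.
#' @param ... unused.
#' @method glance td_fit
#' @export
glance.td_fit <- function(x, ...) {
  last <- x$history[x$history$epoch == max(x$history$epoch), ]
  tibble::tibble(epochs = max(x$history$epoch),
                 elbo = last$value[last$term == "elbo"],
                 total = last$value[last$term == "total"],
                 diverged = x$diverged)
}

#' @method tidy td_recovery
#' @export
tidy.td_recovery <- function(x, ...) x$table

#' @method glance td_recovery
#' @export
glance.td_recovery <- function(x, ...) {
  tibble::tibble(mean_cosine = x$mean_cosine,
                 mean_cosine_identity = x$mean_cosine_identity,
                 within_dist = x$within_dist, between_dist = x$between_dist)
}

#' @method tidy td_eval
#' @export
tidy.td_eval <- function(x, ...) x$metrics

#' @method tidy td_cf_eval
#' @export
tidy.td_cf_eval <- function(x, ...) x$metrics

#' Loss curves of a fitted model
#'
#' @param object a `td_fit`.
#' @param terms which objective terms to show.
#' @param ... unused.
#' @method autoplot td_fit
#' @export
autoplot.td_fit <- function(object, terms = c("total", "elbo"), ...) {
  df <- object$history[object$history$term %in% terms, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "objective term value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted versus observed outcomes
#'
#' Masked-in predictions with central 90% interval whiskers.
#' @param object a `td_eval` from [evaluate_prediction()].
#' @param ... unused.
#' @method autoplot td_eval
#' @export
autoplot.td_eval <- function(object, ...) {
  df <- object$predictions[object$predictions$m == 1, ]
  z <- stats::qnorm(0.95)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - z * .data$sd,
                                        ymax = .data$mean + z * .data$sd),
                           colour = "grey70", width = 0) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~dim, scales = "free") +
    ggplot2::labs(x = "observed outcome", y = "predicted (90% interval)") +
    ggplot2::theme_minimal()
}

#' @export
print.td_fit <- function(x, ...) {
  g <- glance(x)
  cat("<td_fit> ", g$epochs, " epochs;  ELBO ", signif(g$elbo, 5),
      ";  total loss ", signif(g$total, 5),
      if (g$diverged) "  (diverged, last good epoch)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.td_recovery <- function(x, ...) {
  cat("<td_recovery>  mean matched cosine:", signif(x$mean_cosine, 4),
      "\n  within-class shift distance:", signif(x$within_dist, 4),
      "  between-class:", signif(x$between_dist, 4), "\n")
  print(x$table)
  invisible(x)
}

#' @export
print.td_gradcheck <- function(x, ...) {
  cat("<td_gradcheck> term:", x$term,
      " max relative error:", format(x$max_rel_err, digits = 4), "\n")
  invisible(x)
}
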