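# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch training history of a property model
#'
#' @param x a fitted `property_model` (from [train_property_model()]).
#' @param ... unused.
#' @return the per-epoch metrics tibble in long-friendly wide form.
#' @exportS3Method generics::tidy
tidy.property_model <- function(x, ...) {
  if (is.null(x$metrics)) stop("model has no training history")
  x$metrics
}

#' One-row summary of a fitted property model
#'
#' @inheritParams tidy.property_model
#' @return tibble with the configuration, checkpoint epoch, validation and
#'   test RMSE, and the fitted robust-loss shape/scale.
#' @exportS3Method generics::glance
glance.property_model <- function(x, ...) {
  tibble::tibble(
    depth = x$config$depth, hidden_dim = x$config$hidden_dim,
    ffn_layers = x$config$ffn_layers, dropout = x$config$dropout,
    loss = x$loss, best_epoch = x$best_epoch %||% NA_integer_,
    val_rmse = if (!is.null(x$metrics)) min(x$metrics$val_rmse) else NA_real_,
    test_rmse = x$test_rmse %||% NA_real_,
    alpha = if (x$loss == "robust") x$loss_params$alpha else NA_real_,
    c = if (x$loss == "robust") x$loss_params$c else NA_real_
  )
}

#' Training curves of a property model
#'
#' @param object a fitted `property_model`.
#' @param ... unused.
#' @return a ggplot of validation/test RMSE by epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.property_model <- function(object, ...) {
  m <- tidy(object)
  long <- tidyr::pivot_longer(m[, c("epoch", "val_rmse", "test_rmse")],
                              -"epoch", names_to = "split",
                              values_to = "rmse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$rmse,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "RMSE (pKi)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy the iteration log of a policy training run
#'
#' @param x a `gcpn_run` from [train_gcpn()].
#' @param ... unused.
#' @return the per-iteration log tibble.
#' @exportS3Method generics::tidy
tidy.gcpn_run <- function(x, ...) x$log

#' One-row summary of a policy training run
#'
#' @inheritParams tidy.gcpn_run
#' @return tibble with iteration count, first/last/best mean rewards and the
#'   overall validity rate.
#' @exportS3Method generics::glance
glance.gcpn_run <- function(x, ...) {
  lg <- x$log
  tibble::tibble(
    iterations = nrow(lg),
    first_reward = lg$mean_reward[1],
    last_reward = lg$mean_reward[nrow(lg)],
    best_reward = max(lg$mean_reward),
    validity = mean(lg$validity)
  )
}

#' Reward curve of a policy training run
#'
#' @param object a `gcpn_run`.
#' @param ... unused.
#' @return a ggplot of mean episode reward by iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.gcpn_run <- function(object, ...) {
  ggplot2::ggplot(object$log,
                  ggplot2::aes(x = .data$iteration, y = .data$mean_reward)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "mean episode reward") +
    ggplot2::theme_minimal()
}

#' Plot a nearest-reference similarity distribution
#'
#' @param dist tibble from [similarity_distribution()].
#' @return a ggplot histogram.
#' @export
plot_similarity <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                     y = .data$count)) +
    ggplot2::geom_col(width = 0.045) +
    ggplot2::labs(x = "Tanimoto similarity to nearest reference",
                  y = "count") +
    ggplot2::theme_minimal()
}

#' Plot two objectives with their Pareto front
#'
#' @param points two-column matrix or data frame of objective values.
#' @param senses `"max"`/`"min"` per objective.
#' @return a ggplot with the non-dominated points highlighted.
#' @export
plot_pareto <- function(points, senses = c("max", "max")) {
  pts <- as.data.frame(points)
  names(pts)[1:2] <- c("x", "y")
  front <- pareto_front(pts, senses)
  pts$front <- seq_len(nrow(pts)) %in% front
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$front)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(colour = "Pareto front") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
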