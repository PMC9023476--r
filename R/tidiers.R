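#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted screening logistic model
#'
#' @param x a `screen_logit` from [fit_logistic()].
#' @param ... unused.
#' @return A tibble with one row per term: `term`, `estimate`,
#'   `std_error`, `wald`, `p_value`.
#' @export
tidy.screen_logit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$se),
    wald = unname(x$wald),
    p_value = unname(x$p_values)
  )
}

#' One-row summary of a fitted screening logistic model
#'
#' @param x a `screen_logit`.
#' @param ... unused.
#' @return A one-row tibble: `n`, `log_likelihood`, `null_log_likelihood`,
#'   `model_chi2`, `model_df`, `model_p`, `nagelkerke_r2`, `converged`,
#'   `separation`.
#' @export
glance.screen_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    log_likelihood = x$log_likelihood,
    null_log_likelihood = x$null_log_likelihood,
    model_chi2 = x$model_chi2,
    model_df = x$model_df,
    model_p = x$model_p,
    nagelkerke_r2 = x$nagelkerke_r2,
    converged = x$converged,
    separation = x$separation
  )
}

#' Tidy an ROC curve
#'
#' @param x a `screen_roc` from [roc_curve()].
#' @param ... unused.
#' @return The threshold/sensitivity/specificity tibble.
#' @export
tidy.screen_roc <- function(x, ...) x$curve

#' One-row summary of an ROC analysis
#'
#' @param x a `screen_roc`.
#' @param ... unused.
#' @return A one-row tibble: `auroc`, `n_case`, `n_control` and the
#'   operating-point metrics.
#' @export
glance.screen_roc <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, n_case = x$n_case, n_control = x$n_control,
    x$operating_point
  )
}

#' Plot an ROC curve
#'
#' Sensitivity against 1 - specificity with the chance diagonal, the
#' AUROC in the subtitle, and the reported operating point marked.
#'
#' @param object a `screen_roc`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.screen_roc <- function(object, ...) {
  o <- object$operating_point
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_point(
      data = tibble::tibble(x = 1 - o$specificity, y = o$sensitivity),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "#b2182b", size = 2
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "ROC curve",
      subtitle = sprintf("AUROC = %.3f (%d cases, %d controls)",
                         object$auroc, object$n_case, object$n_control)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a spatio-temporal image
#'
#' Raster view of the kymograph: arc length on x, time on y; advecting
#' aggregates appear as oblique dark streaks whose slope is the axial
#' velocity.
#'
#' @param object an `sti` from [build_sti()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sti <- function(object, ...) {
  V <- object$values
  df <- tidyr::expand_grid(
    t_s = (seq_len(nrow(V)) - 1) * object$dt_s,
    s_um = (seq_len(ncol(V)) - 1) * object$ds_um
  )
  df$intensity <- as.vector(t(V))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_um, y = .data$t_s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Arc length (um)", y = "Time (s)",
                  title = "Spatio-temporal image") +
    ggplot2::theme_minimal()
}

#' Plot per-frame registration shifts
#'
#' @param object a `registration_result` from [register_frames()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.registration_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$shifts, c("dx", "dy"),
                            names_to = "axis", values_to = "shift_px")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$shift_px,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$reference_index,
                        linetype = "dotted") +
    ggplot2::labs(x = "Frame", y = "Estimated shift (px)",
                  title = "Frame-to-reference registration shifts") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
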