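#' Plot module sizes
#'
#' @param object A `module_assignment`.
#' @param ... Unused.
#' @return A ggplot: bar chart of module sizes (module 0 = unassigned genes).
#' @export
autoplot.module_assignment <- function(object, ...) {
  d <- tidy(object) |> dplyr::count(.data$module)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$module), y = .data$n,
                                  fill = .data$module == 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "grey75")) +
    ggplot2::labs(x = "module (0 = unassigned)", y = "genes",
                  title = "Coexpression module sizes") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation criterion trace of a tuned TGDR fit
#'
#' @param object A `tgdr_fit` produced by [tgdr_tune()].
#' @param ... Unused.
#' @return A ggplot of the cross-validated partial-likelihood criterion
#'   against the iteration count, one line per threshold.
#' @export
autoplot.tgdr_fit <- function(object, ...) {
  if (is.null(object$cv)) stopf("fit has no tuning trace; use tgdr_tune()")
  ggplot2::ggplot(object$cv$cv_trace,
                  ggplot2::aes(x = .data$K, y = .data$cvl,
                               group = .data$tau, colour = .data$tau)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::annotate("point", x = object$cv$K, y = object$cv$criterion,
                      shape = 21, size = 3, colour = "red") +
    ggplot2::labs(x = "iterations K", y = "cross-validated partial likelihood",
                  colour = "tau",
                  title = sprintf("TGDR tuning (tau* = %.2f, K* = %d)",
                                  object$cv$tau, object$cv$K)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of the median-split risk groups
#'
#' @param object A `cv_evaluation` from [cv_predict()].
#' @param ... Unused.
#' @return A ggplot of the two risk groups' Kaplan-Meier survival curves.
#' @export
autoplot.cv_evaluation <- function(object, ...) {
  high <- object$scores$score > median(object$scores$score)
  sf <- survival::survfit(survival::Surv(object$time, object$status) ~ high)
  d <- tibble::tibble(
    time = sf$time, surv = sf$surv,
    group = rep(c("low risk", "high risk"), sf$strata))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "survival probability", colour = NULL,
                  title = sprintf("%s risk groups: logrank %.2f, concordance %.3f",
                                  object$kind, object$logrank$statistic,
                                  object$concordance)) +
    ggplot2::theme_minimal()
}
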