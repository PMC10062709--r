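# ggplot2 visualisations of the result classes

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_errorbar labs
#'   scale_x_log10 facet_wrap theme_minimal
NULL

#' Plot anisotropy traces
#'
#' Time courses of measured anisotropy, one panel per probe concentration,
#' colored by BBV dilution.
#'
#' @param traces Output of [fa_traces()] / [experiment_traces()].
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  ggplot(traces, aes(x = .data$time_s / 60, y = .data$fa,
                     color = factor(signif(.data$bbv_dilution, 3)),
                     group = .data$well)) +
    geom_line(alpha = 0.8) +
    facet_wrap(~probe_nM, labeller = ggplot2::label_both) +
    labs(x = "time (min)", y = "anisotropy",
         color = "BBV dilution") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fa_sigmoid_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  pos <- d$conc > 0
  p <- ggplot(d[pos, ], aes(x = .data$conc)) +
    geom_point(aes(y = .data$response)) +
    geom_line(aes(y = .data$fitted)) +
    scale_x_log10() +
    labs(x = "competitor (nM)", y = "response",
         title = sprintf("Log(IC50) = %.2f", sigmoid_coef(object, "log_ic50"))) +
    theme_minimal()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.fa_saturation_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot(d, aes(x = .data$bbv_dilution, color = .data$condition)) +
    geom_point(aes(y = .data$fa)) +
    geom_line(aes(y = .data$fitted, group = interaction(.data$condition,
                                                        .data$probe_nM))) +
    scale_x_log10() +
    facet_wrap(~probe_nM, labeller = ggplot2::label_both) +
    labs(x = "BBV dilution", y = "anisotropy") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fa_global_fit <- function(object, ...) {
  r <- object$residuals
  ggplot(r, aes(x = .data$time_s / 60, group = .data$well)) +
    geom_point(aes(y = .data$fa), size = 0.4, alpha = 0.4) +
    geom_line(aes(y = .data$pred), color = "red", alpha = 0.6) +
    labs(x = "time (min)", y = "anisotropy",
         title = sprintf("global fit, loss %.3g", object$final_loss)) +
    theme_minimal()
}

#' Plot a Log(IC50) time course with optional stabilization fit
#'
#' @param object An `fa_ic50_timecourse`.
#' @param decay_fit Optional [fit_ic50_decay()] result to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fa_ic50_timecourse <- function(object, decay_fit = NULL, ...) {
  d <- object[is.finite(object$log_ic50), ]
  p <- ggplot(d, aes(x = .data$time_s / 60, y = .data$log_ic50)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$log_ic50 - .data$se,
                      ymax = .data$log_ic50 + .data$se), width = 0) +
    labs(x = "time (min)", y = "Log(IC50)") +
    theme_minimal()
  if (!is.null(decay_fit)) {
    est <- setNames(decay_fit$estimates$estimate, decay_fit$estimates$term)
    tt <- seq(min(d$time_s), max(d$time_s), length.out = 200)
    curve <- tibble(time_s = tt,
                    log_ic50 = ic50_decay_model(tt / 60,
                                                est[["log_ic50_t0"]],
                                                est[["log_ic50_eq"]],
                                                est[["k_per_min"]]))
    p <- p + geom_line(data = curve, color = "red")
  }
  p
}
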