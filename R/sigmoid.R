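#' Sigmoid concentration-response fit (log inhibitor vs. response)
#'
#' Fits the monotone decreasing logistic model
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{h\,(\log_{10} c - LogIC50)}}}
#' with Hill slope `h` fixed at 1 (`three_param`, the default) or free
#' (`four_param`). Zero-concentration points are retained and act as the
#' unconstrained anchor of the upper plateau (`log10(0) = -Inf` makes the
#' model value exactly `top` there).
#'
#' @param curve A data frame with columns `conc` (nM, may include 0) and
#'   `response` (FA or any monotone signal), optionally `weight`.
#' @param variant `"three_param"` or `"four_param"`.
#' @return An object of class `fa_sigmoid_fit` with `estimates` (tibble of
#'   term, estimate, std.error), `fitted`, `residual_sd`, `variant`, `data`.
#' @examples
#' cv <- tibble::tibble(conc = c(0, 10^seq(-1, 3, 0.5)),
#'                      response = 1 - 1 / (1 + 10 / c(Inf, 10^seq(-1, 3, 0.5))))
#' fit_sigmoid(cv)$estimates
#' @export
fit_sigmoid <- function(curve, variant = c("three_param", "four_param")) {
  variant <- match.arg(variant)
  curve <- as_tibble(curve)
  if (!all(c("conc", "response") %in% names(curve))) {
    abort("`curve` needs columns conc and response.")
  }
  if (anyDuplicated(curve$conc)) {
    curve <- curve |>
      dplyr::group_by(.data$conc) |>
      dplyr::summarise(response = mean(.data$response),
                       weight = if ("weight" %in% names(curve))
                         mean(.data$weight) else 1,
                       .groups = "drop")
  }
  if (!"weight" %in% names(curve)) curve$weight <- 1
  curve <- dplyr::arrange(curve, .data$conc)
  if (nrow(curve) < 4L) abort("need at least 4 distinct concentrations.")
  logc <- log10(curve$conc) # -Inf allowed for conc = 0
  y <- curve$response
  w <- curve$weight

  model <- function(th) {
    h <- if (variant == "four_param") th[["hill"]] else 1
    th[["bottom"]] + (th[["top"]] - th[["bottom"]]) /
      (1 + 10^(h * (logc - th[["log_ic50"]])))
  }
  # data-driven start: plateaus from the extremes, midpoint by interpolation
  top0 <- mean(y[seq_len(min(2L, length(y)))])
  bot0 <- mean(y[seq(length(y) - 1L, length(y))])
  half <- (top0 + bot0) / 2
  fin <- is.finite(logc)
  mid0 <- tryCatch(
    stats::approx(y[fin], logc[fin], xout = half, ties = "ordered")$y,
    error = function(e) NA_real_)
  if (!is.finite(mid0)) mid0 <- stats::median(logc[fin])
  start <- c(top = top0, bottom = bot0, log_ic50 = mid0)
  if (variant == "four_param") start <- c(start, hill = 1)

  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(th) sqrt(w) * (y - model(th)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  resid_sd <- sqrt(sum(fit$fvec^2) / max(1, length(y) - length(est)))
  # judge the window over the observed concentration range (|top - bottom|
  # alone is unbounded when an unconstrained plateau runs away)
  window_obs <- diff(range(model(est)))
  if (window_obs < 3 * resid_sd) {
    abort("no displacement detected: response window smaller than 3x residual noise.")
  }
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * resid_sd^2 * 2),
                 error = function(e) rep(NA_real_, length(est)))
  # nls.lm hessian is 2 * J'J at convergence for 0.5*ssq; guard via summary
  se2 <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) se)
  structure(list(
    estimates = tibble(term = names(est), estimate = unname(est),
                       std.error = unname(se2)),
    fitted = model(est),
    residual_sd = resid_sd,
    variant = variant,
    data = curve,
    converged = fit$info %in% 1:4
  ), class = "fa_sigmoid_fit")
}

#' @export
print.fa_sigmoid_fit <- function(x, ...) {
  cat(sprintf("<fa_sigmoid_fit: %s, %d concentrations>\n",
              x$variant, nrow(x$data)))
  print(x$estimates)
  invisible(x)
}

sigmoid_coef <- function(fit, term) {
  fit$estimates$estimate[fit$estimates$term == term]
}
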