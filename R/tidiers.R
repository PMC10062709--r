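# broom-style tidiers for the fitted-object classes

#' @exportS3Method generics::tidy
tidy.fa_sigmoid_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.fa_sigmoid_fit <- function(x, ...) {
  tibble(variant = x$variant, residual_sd = x$residual_sd,
         nobs = nrow(x$data), converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.fa_saturation_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.fa_saturation_fit <- function(x, ...) {
  tibble(residual_sd = x$residual_sd, nobs = nrow(x$data),
         converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.fa_global_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.fa_global_fit <- function(x, ...) {
  tibble(final_loss = x$final_loss, nobs = nrow(x$residuals),
         n_free = nrow(x$estimates), n_evals = x$n_evals, seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.fa_ic50_decay <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.fa_ic50_decay <- function(x, ...) {
  tibble(nobs = nrow(x$data), weighted = x$weighted)
}

#' @exportS3Method generics::tidy
tidy.fa_zprime <- function(x, ...) {
  tibble(term = c("mu_pos", "mu_neg", "sigma_pos", "sigma_neg", "z_prime"),
         estimate = c(x$mu_pos, x$mu_neg, x$sigma_pos, x$sigma_neg,
                      x$z_prime))
}

#' @exportS3Method generics::glance
glance.fa_zprime <- function(x, ...) {
  tibble(z_prime = x$z_prime, n_pos = x$n_pos, n_neg = x$n_neg)
}
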