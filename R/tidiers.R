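#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a branch-site fit
#'
#' @param x A `bs_fit`.
#' @param ... Unused.
#' @return The per-start tibble: starting omega, log-likelihood,
#'   convergence code and converged parameters.
#' @export
tidy.bs_fit <- function(x, ...) {
  x$starts
}

#' @rdname tidy.bs_fit
#' @return For `glance`: a one-row tibble with the best run's parameters,
#'   log-likelihood and data dimensions.
#' @export
glance.bs_fit <- function(x, ...) {
  tibble::tibble(model = if (x$null) "null" else "alternative",
                 logLik = x$best$logLik,
                 kappa = x$best$kappa, omega0 = x$best$omega0,
                 omega2 = x$best$omega2, p0 = x$best$p0, p1 = x$best$p1,
                 p2a = x$best$p2a, p2b = x$best$p2b,
                 n_sites = x$n_sites, n_species = x$n_species)
}

#' Tidy a likelihood ratio test
#'
#' @param x A `bs_lrt`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `significant`,
#'   `loglik_null`, `loglik_alt`.
#' @export
tidy.bs_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 significant = x$significant,
                 loglik_null = x$loglik_null, loglik_alt = x$loglik_alt)
}

#' Tidy a full branch-site test
#'
#' @param x A `bs_test`.
#' @param ... Unused.
#' @return One-row tibble combining the LRT and the alternative fit's
#'   parameter estimates.
#' @export
tidy.bs_test <- function(x, ...) {
  dplyr::bind_cols(tidy(x$lrt),
                   tibble::tibble(omega2_hat = x$alt$best$omega2,
                                  omega0_hat = x$alt$best$omega0,
                                  kappa_hat = x$alt$best$kappa))
}
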