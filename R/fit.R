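# Parameter transforms: unconstrained vector <-> model parameters.
# kappa via log; omega0 via logit (0 < omega0 < 1); (p0, p1) via a logit
# pair (f = p0+p1, g = p0/f); omega2 (alternative only) optimized directly
# under an L-BFGS-B lower bound of 1 so the null boundary is reachable.
bs_theta_to_params <- function(theta, null) {
  kappa <- exp(theta[1])
  omega0 <- stats::plogis(theta[2])
  f <- stats::plogis(theta[3])
  g <- stats::plogis(theta[4])
  p0 <- f * g
  p1 <- f * (1 - g)
  omega2 <- if (null) 1 else theta[5]
  list(kappa = kappa, omega0 = omega0, omega2 = omega2, p0 = p0, p1 = p1)
}

bs_params_to_theta <- function(kappa, omega0, omega2, p0, p1, null) {
  clamp <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)
  f <- clamp(p0 + p1)
  g <- clamp(p0 / (p0 + p1))
  th <- c(log(kappa), stats::qlogis(clamp(omega0)),
          stats::qlogis(f), stats::qlogis(g))
  if (!null) th <- c(th, max(omega2, 1))
  th
}

#' Fit the branch-site model (alternative or null) by maximum likelihood
#'
#' Maximizes the model A log-likelihood over `(kappa, omega0, p0, p1)` and,
#' in the alternative model, `omega2 >= 1`; the null fixes `omega2 = 1`.
#' Following the multi-start protocol used in genome scans, each starting
#' omega value seeds an optimization run through the initial value of the
#' free foreground ratio (`omega2 = max(start, 1)`); duplicate effective
#' starts are collapsed (under the null, where `omega2` is fixed, all
#' starts coincide and one run is performed), and the run with the best
#' log-likelihood is kept, ties broken by start order. Branch lengths are held fixed (estimate them beforehand,
#' e.g. with [estimate_branch_lengths_m0()]).
#'
#' @param caln A [codon_alignment()].
#' @param tree A [label_foreground()] tree with branch lengths.
#' @param null Logical; fit the null model (`omega2` fixed at 1)?
#' @param omega2_starts Numeric vector of starting omega values.
#' @param pi Codon frequencies; defaults to F3x4 from the alignment.
#' @param init Optional named list overriding base initial values
#'   (`kappa`, `p0`, `p1`, `omega0`, `omega2`), e.g. a null fit's estimates
#'   to warm-start the alternative.
#' @param control Optimizer control passed to [stats::optim()]
#'   (`method = "L-BFGS-B"`); defaults give a log-likelihood tolerance
#'   around 1e-8.
#' @return Object of class `bs_fit`: list with `starts` (tibble of
#'   per-start results), `best` (parameter list with `logLik`), `null`,
#'   `pi`, `n_sites`, `n_species`, `convergence`.
#' @export
fit_branch_site <- function(caln, tree, null = FALSE,
                            omega2_starts = c(0.5, 1, 2),
                            pi = NULL, init = NULL, control = list()) {
  if (is.null(pi)) pi <- estimate_codon_frequencies_f3x4(caln)
  pi <- as.numeric(pi)
  prep <- bs_prepare(caln, tree)
  if (is.null(prep$fg_edge)) {
    abort("`tree` must be a labeled_tree with a foreground branch.")
  }
  base <- list(kappa = 2, omega0 = 0.5, omega2 = 1.5, p0 = 0.7, p1 = 0.2)
  base[names(init)] <- init

  # per-fit cache: eigendecompositions and background passes are reused
  # across optimizer steps (edge lengths are fixed within a fit)
  cache <- new.env(parent = emptyenv())
  last <- new.env(parent = emptyenv())
  negll <- function(theta) {
    p <- bs_theta_to_params(theta, null)
    v <- -bs_loglik_engine(prep, p$kappa, p$omega0, p$omega2, p$p0, p$p1,
                           pi, cache = cache)
    last$theta <- theta
    last$value <- v
    v
  }
  # forward-difference gradient reusing the cached objective value; the
  # omega2 coordinate's perturbation hits the background-pass cache
  fd_step <- 1e-6
  negll_grad <- function(theta) {
    f0 <- if (!is.null(last$theta) && identical(last$theta, theta)) {
      last$value
    } else {
      negll(theta)
    }
    vapply(seq_along(theta), function(k) {
      th <- theta
      th[k] <- th[k] + fd_step
      (negll(th) - f0) / fd_step
    }, numeric(1))
  }

  # each start value seeds the free omega2 (clamped into its >= 1 box) and
  # the initial omega0 (min(start, 0.9)). A warm-start `init` applies only
  # to starts at the omega2 = 1 boundary; larger starts keep their own
  # diversified initial values so genuine multi-start exploration remains.
  # Duplicate effective starts collapse (in particular the null, where
  # omega2 is fixed, runs each distinct omega0 start once).
  defaults <- list(kappa = 2, omega0 = 0.5, omega2 = 1.5, p0 = 0.7,
                   p1 = 0.2)
  thetas <- lapply(omega2_starts, function(s) {
    if (!is.null(init) && s <= 1) {
      bs_params_to_theta(base$kappa, base$omega0, 1, base$p0, base$p1,
                         null)
    } else {
      bs_params_to_theta(defaults$kappa, min(s, 0.9), max(s, 1),
                         defaults$p0, defaults$p1, null)
    }
  })
  keep <- !duplicated(vapply(thetas, paste, character(1), collapse = ","))
  starts_used <- omega2_starts[keep]
  thetas <- thetas[keep]

  ctl <- utils::modifyList(list(maxit = 500, factr = 4.5e7), control)
  lower <- if (null) rep(-Inf, 4) else c(rep(-Inf, 4), 1)
  runs <- vector("list", length(thetas))
  for (k in seq_along(thetas)) {
    runs[[k]] <- tryCatch(
      optim(thetas[[k]], negll, gr = negll_grad, method = "L-BFGS-B",
            lower = lower, control = ctl),
      error = function(e) list(par = thetas[[k]], value = Inf,
                               convergence = 99L,
                               message = conditionMessage(e))
    )
  }
  lls <- -vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(lls))) {
    abort("all optimization starts failed for the branch-site fit.")
  }
  best_k <- which.max(replace(lls, !is.finite(lls), -Inf))
  bp <- bs_theta_to_params(runs[[best_k]]$par, null)
  best <- branch_site_params(bp$kappa, bp$omega0, bp$omega2, bp$p0, bp$p1)
  best$logLik <- lls[best_k]

  starts <- tibble::tibble(
    start = starts_used,
    logLik = lls,
    convergence = vapply(runs, function(r) as.integer(r$convergence),
                         integer(1)),
    kappa = vapply(runs, function(r) bs_theta_to_params(r$par, null)$kappa,
                   numeric(1)),
    omega0 = vapply(runs, function(r) bs_theta_to_params(r$par, null)$omega0,
                    numeric(1)),
    omega2 = vapply(runs, function(r) bs_theta_to_params(r$par, null)$omega2,
                    numeric(1)),
    p0 = vapply(runs, function(r) bs_theta_to_params(r$par, null)$p0,
                numeric(1)),
    p1 = vapply(runs, function(r) bs_theta_to_params(r$par, null)$p1,
                numeric(1))
  )
  structure(list(starts = starts, best = best, null = null, pi = pi,
                 n_sites = prep$n_sites, n_species = prep$ntip,
                 convergence = runs[[best_k]]$convergence),
            class = "bs_fit")
}

#' @export
print.bs_fit <- function(x, ...) {
  cat(sprintf("<bs_fit> branch-site model %s, lnL = %.4f\n",
              if (x$null) "A null (omega2 = 1)" else "A (alternative)",
              x$best$logLik))
  cat(sprintf("  kappa = %.3f, omega0 = %.3f, omega2 = %.3f, p0 = %.3f, p1 = %.3f\n",
              x$best$kappa, x$best$omega0, x$best$omega2,
              x$best$p0, x$best$p1))
  invisible(x)
}

#' Estimate branch lengths under the one-ratio (M0) codon model
#'
#' Fits a single-omega codon model, optimizing `kappa`, `omega` and all
#' branch lengths, and returns the tree with the estimated lengths. These
#' lengths are then held fixed during the branch-site fits, the usual
#' desk-scale protocol for genome scans.
#'
#' @param caln A [codon_alignment()].
#' @param tree An `ape::phylo` (any existing branch lengths are used as the
#'   starting point; otherwise 0.1 per branch).
#' @param pi Codon frequencies; defaults to F3x4 from the alignment.
#' @param control Passed to [stats::nlminb()].
#' @return List of class `m0_fit`: `tree` (with estimated lengths),
#'   `kappa`, `omega`, `logLik`, `convergence`.
#' @export
fit_m0 <- function(caln, tree, pi = NULL, control = list()) {
  if (inherits(tree, "labeled_tree")) tree <- tree$tree
  if (is.null(pi)) pi <- estimate_codon_frequencies_f3x4(caln)
  pi <- as.numeric(pi)
  tr <- tree
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0.1, nrow(tr$edge))
  }
  tr$edge.length <- pmax(tr$edge.length, 1e-4)
  prep <- bs_prepare(caln, tr)
  nedge <- prep$nedge

  negll <- function(theta) {
    kappa <- exp(theta[1])
    omega <- exp(theta[2])
    el <- exp(theta[-(1:2)])
    -m0_loglik_engine(prep, kappa, omega, pi, edge_len = el)
  }
  theta0 <- c(log(2), log(0.3), log(prep$edge_len))
  ctl <- utils::modifyList(list(rel.tol = 1e-9, eval.max = 4000,
                                iter.max = 1000), control)
  res <- nlminb(theta0, negll,
                lower = c(log(1e-3), log(1e-4), rep(log(1e-7), nedge)),
                upper = c(log(100), log(5), rep(log(20), nedge)),
                control = ctl)
  el <- exp(res$par[-(1:2)])
  # map estimated lengths (in prep's postorder) back onto the input tree
  post <- ape::reorder.phylo(tr, "postorder")
  post$edge.length <- el
  out_tree <- tree
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_post <- paste(post$edge[, 1], post$edge[, 2])
  out_tree$edge.length <- el[match(key_in, key_post)]
  structure(list(tree = out_tree, kappa = exp(res$par[1]),
                 omega = exp(res$par[2]), logLik = -res$objective,
                 convergence = res$convergence),
            class = "m0_fit")
}

#' @rdname fit_m0
#' @export
estimate_branch_lengths_m0 <- function(caln, tree, pi = NULL,
                                       control = list()) {
  fit_m0(caln, tree, pi = pi, control = control)$tree
}

#' Likelihood ratio test for positive selection
#'
#' Compares the alternative branch-site fit with its null: the statistic is
#' `max(0, 2 * (lnL_alt - lnL_null))`, referred by default to a chi-square
#' distribution with one degree of freedom; significance at `p < alpha`
#' (strict inequality). Because the null places `omega2` on the boundary,
#' the 50:50 mixture of a point mass at 0 and chi-square(1) is available as
#' a more conservative reference via `mixture = TRUE`.
#'
#' @param loglik_alt,loglik_null Maximized log-likelihoods. Fitted `bs_fit`
#'   objects are also accepted.
#' @param alpha Significance cutoff (default 0.05).
#' @param mixture Use the boundary mixture null distribution?
#' @param tol Tolerance below which `loglik_alt < loglik_null` is treated
#'   as numerical noise (optimizer termination slack) rather than an
#'   optimization failure; the statistic is clamped at 0 either way.
#' @return Object of class `bs_lrt`: list with `statistic`, `df`,
#'   `p_value`, `significant`, `loglik_alt`, `loglik_null`.
#' @export
likelihood_ratio_test <- function(loglik_alt, loglik_null, alpha = 0.05,
                                  mixture = FALSE, tol = 1e-4) {
  if (inherits(loglik_alt, "bs_fit")) loglik_alt <- loglik_alt$best$logLik
  if (inherits(loglik_null, "bs_fit")) loglik_null <- loglik_null$best$logLik
  if (loglik_alt < loglik_null - tol) {
    abort(sprintf(
      "alternative lnL (%.6f) below null lnL (%.6f): optimization failure.",
      loglik_alt, loglik_null))
  }
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) {
    p <- if (stat <= 0) 1 else 0.5 * p
  }
  # strict p < alpha with an epsilon guard so a statistic sitting on the
  # chi-square quantile (to printed precision) reads as the boundary
  structure(list(statistic = stat, df = 1L, p_value = p,
                 significant = (alpha - p) > 1e-8,
                 loglik_alt = loglik_alt, loglik_null = loglik_null),
            class = "bs_lrt")
}

#' @export
print.bs_lrt <- function(x, ...) {
  cat(sprintf("<bs_lrt> 2*dlnL = %.4f, df = 1, p = %.4g%s\n",
              x$statistic, x$p_value,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Run the full branch-site test for one gene
#'
#' Convenience wrapper: fits the null, warm-starts the alternative from the
#' null's estimates, and performs the LRT.
#'
#' @inheritParams fit_branch_site
#' @inheritParams likelihood_ratio_test
#' @return Object of class `bs_test`: list with `null`, `alt` (both
#'   `bs_fit`) and `lrt` (`bs_lrt`).
#' @export
branch_site_test <- function(caln, tree, omega2_starts = c(0.5, 1, 2),
                             pi = NULL, alpha = 0.05, mixture = FALSE,
                             control = list()) {
  if (is.null(pi)) pi <- estimate_codon_frequencies_f3x4(caln)
  fit0 <- fit_branch_site(caln, tree, null = TRUE,
                          omega2_starts = omega2_starts, pi = pi,
                          control = control)
  warm <- list(kappa = fit0$best$kappa, p0 = fit0$best$p0,
               p1 = fit0$best$p1, omega0 = fit0$best$omega0)
  fit1 <- fit_branch_site(caln, tree, null = FALSE,
                          omega2_starts = omega2_starts, pi = pi,
                          init = warm, control = control)
  lrt <- likelihood_ratio_test(fit1, fit0, alpha = alpha, mixture = mixture)
  structure(list(null = fit0, alt = fit1, lrt = lrt), class = "bs_test")
}
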