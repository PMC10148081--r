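# Equilibrium analysis. For the stepwise reaction
#   alpha_n beta_6 + alpha  <=>  alpha_{n+1} beta_6
# the equilibrium constant is Kc = [alpha_{n+1}beta_6] / ([alpha_n beta_6] [alpha]).
# Free [alpha] is unobservable in the images but assumed constant, so the
# product Kc[alpha] = [alpha_{n+1}beta_6] / [alpha_n beta_6] is estimable as
# the particle-count ratio N_{n+1} / N_n.

#' Stepwise association attributes Kc[alpha]
#'
#' Computes the six count ratios `r_n = N_{n+1} / N_n` (n = 0..5), each an
#' estimate of the product of the stepwise equilibrium constant and the
#' (constant, unobservable) free alpha-subunit concentration. With
#' `pseudocount = 0` a ratio is undefined (NA, `defined = FALSE`) when
#' `N_n = 0`; a Haldane-style `pseudocount = 0.5` can be used for sparse
#' histograms, in which case `r_n = (N_{n+1} + c) / (N_n + c)`.
#'
#' @param dist A `pcc_formula_dist` with positive total.
#' @param pseudocount Nonnegative real added to numerator and denominator.
#' @return A data.frame with columns `n` (0..5), `ratio` and `defined`.
#' @export
#' @examples
#' d <- new_formula_dist(c(0, 0, 0, 0, 10, 20, 40))
#' stepwise_ratios(d)
stepwise_ratios <- function(dist, pseudocount = 0) {
  stopifnot(inherits(dist, "pcc_formula_dist"))
  if (dist$total <= 0) stop("distribution has zero total")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || is.na(pseudocount) ||
      pseudocount < 0) {
    stop("`pseudocount` must be a single nonnegative number")
  }
  N <- dist$counts
  num <- N[2:7] + pseudocount
  den <- N[1:6] + pseudocount
  defined <- den > 0
  ratio <- ifelse(defined, num / den, NA_real_)
  data.frame(n = 0:5, ratio = as.numeric(ratio), defined = as.logical(defined))
}

#' Fit an exponential decay to the stepwise ratios
#'
#' Ordinary least squares of `ln r_n` on `n`, modelling
#' `r_n = A * exp(-lambda * n)`. Only defined ratios are used; any defined
#' non-positive ratio, or fewer than two usable points, signals a histogram
#' too sparse to fit and raises an error. An optional count-weighted fit
#' (weights proportional to the harmonic mean of the two counts entering
#' each ratio) is available via `weights`.
#'
#' @param ratios A data.frame from [stepwise_ratios()] or a numeric vector
#'   of 6 ratios (NA = undefined).
#' @param weights Optional nonnegative weights, one per ratio, for a
#'   weighted fit. Default unweighted.
#' @return List with `fit_A` (prefactor), `fit_lambda` (decay rate per added
#'   alpha-subunit), `r_squared` (on the log scale) and `n_used`.
#' @export
#' @examples
#' fit_exponential_decay(4 * exp(-0.5 * (0:5)))
fit_exponential_decay <- function(ratios, weights = NULL) {
  if (is.data.frame(ratios)) {
    r <- ratios$ratio
    n <- ratios$n
    defined <- ratios$defined
  } else {
    r <- as.numeric(ratios)
    n <- 0:(length(r) - 1L)
    defined <- !is.na(r)
  }
  if (any(defined & !is.na(r) & r <= 0)) {
    stop("non-positive ratio among defined values; distribution too sparse to fit")
  }
  use <- defined & !is.na(r) & r > 0
  if (sum(use) < 2L) stop("need at least 2 defined positive ratios to fit")
  x <- n[use]
  y <- log(r[use])
  w <- if (is.null(weights)) rep(1, sum(use)) else {
    stopifnot(length(weights) == length(r), all(weights >= 0))
    weights[use]
  }
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  yhat <- cbind(1, x) %*% fit$coefficients
  wm <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - wm)^2)
  ss_res <- sum(w * (y - yhat)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(
    fit_A = unname(exp(fit$coefficients[1L])),
    fit_lambda = unname(-fit$coefficients[2L]),
    r_squared = r2,
    n_used = sum(use)
  )
}

#' Independent-site (statistical factor) ratio sequence
#'
#' Under identical, independent sites the abundance of formula n is
#' proportional to `choose(6, n) * theta^n`, where `theta` is the per-site
#' occupancy odds. The stepwise ratios are then
#' `r_n = ((6 - n) / (n + 1)) * theta` — the purely combinatorial
#' "statistical factor" decline of stepwise association as sites fill.
#'
#' @param theta Positive per-site occupancy odds `p / (1 - p)`.
#' @return Numeric vector of 6 ratios, strictly decreasing in n.
#' @export
#' @examples
#' independent_site_ratios(1)  # 6, 2.5, 4/3, 0.75, 0.4, 1/6
independent_site_ratios <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0) {
    stop("`theta` must be a single positive number")
  }
  n <- 0:5
  (6 - n) / (n + 1) * theta
}

#' Estimate the per-site occupancy odds
#'
#' Maximum-likelihood inverse of the independent-site model: under
#' `Binomial(6, p)` the MLE is `p_hat = sum(n * N_n) / (6 * total)`;
#' `theta_hat = p_hat / (1 - p_hat)` with a normal-approximation 95%
#' confidence interval on the logit scale.
#'
#' @param dist A `pcc_formula_dist` with positive total and occupancy mass
#'   strictly between 0 and 1.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `p_hat`, `theta_hat` and `theta_ci` (length-2 vector).
#' @export
estimate_theta <- function(dist, conf_level = 0.95) {
  stopifnot(inherits(dist, "pcc_formula_dist"))
  if (dist$total <= 0) stop("distribution has zero total")
  n_trials <- 6 * dist$total
  p_hat <- sum((0:6) * dist$counts) / n_trials
  if (p_hat <= 0 || p_hat >= 1) {
    stop("all sites empty or all sites full: occupancy odds are unbounded")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_logit <- sqrt(1 / (n_trials * p_hat * (1 - p_hat)))
  lo <- stats::qlogis(p_hat) - z * se_logit
  hi <- stats::qlogis(p_hat) + z * se_logit
  list(
    p_hat = p_hat,
    theta_hat = p_hat / (1 - p_hat),
    theta_ci = c(exp(lo), exp(hi))
  )
}

#' Full equilibrium report for a formula distribution
#'
#' Convenience wrapper: stepwise ratios, exponential-decay fit and
#' independent-site comparison in one object (the Fig. 4-style analysis).
#'
#' @inheritParams stepwise_ratios
#' @param fit Logical: attempt the exponential fit (errors propagate if the
#'   distribution is too sparse).
#' @return List of class `pcc_equilibrium`: `ratios` data.frame, `fit`
#'   (list or NULL), `theta` (list from [estimate_theta()] or NULL if
#'   degenerate), `expected_ratios` (independent-site sequence at
#'   `theta_hat`, or NULL).
#' @export
equilibrium_analysis <- function(dist, pseudocount = 0, fit = TRUE) {
  ratios <- stepwise_ratios(dist, pseudocount)
  fit_res <- if (fit) fit_exponential_decay(ratios) else NULL
  theta <- tryCatch(estimate_theta(dist), error = function(e) NULL)
  structure(list(
    ratios = ratios,
    fit = fit_res,
    theta = theta,
    expected_ratios = if (!is.null(theta)) independent_site_ratios(theta$theta_hat) else NULL
  ), class = "pcc_equilibrium")
}

#' @export
print.pcc_equilibrium <- function(x, ...) {
  cat("Stepwise Kc[alpha] ratios (N_{n+1}/N_n):\n")
  print(x$ratios, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat(sprintf("Exponential decay fit: A = %.4g, lambda = %.4g, R^2(log) = %.4f\n",
                x$fit$fit_A, x$fit$fit_lambda, x$fit$r_squared))
  }
  if (!is.null(x$theta)) {
    cat(sprintf("Independent-site occupancy odds: theta_hat = %.4g (95%% CI %.4g-%.4g)\n",
                x$theta$theta_hat, x$theta$theta_ci[1L], x$theta$theta_ci[2L]))
  }
  invisible(x)
}

#' Plot Kc[alpha] against n with the independent-site overlay
#'
#' @param x A `pcc_equilibrium` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pcc_equilibrium <- function(x, ...) {
  ok <- x$ratios$defined & x$ratios$ratio > 0
  graphics::plot(x$ratios$n[ok], x$ratios$ratio[ok], log = "y",
                 xlab = "n (alpha-subunits in product)",
                 ylab = expression(K[c] * "[" * alpha * "]"),
                 pch = 19, xlim = c(0, 5), ...)
  if (!is.null(x$fit)) {
    nn <- seq(0, 5, length.out = 101)
    graphics::lines(nn, x$fit$fit_A * exp(-x$fit$fit_lambda * nn), lty = 1)
  }
  if (!is.null(x$expected_ratios)) {
    graphics::points(0:5, x$expected_ratios, pch = 1, col = "grey40")
    graphics::lines(0:5, x$expected_ratios, lty = 2, col = "grey40")
  }
  invisible(x)
}
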