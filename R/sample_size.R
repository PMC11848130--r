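#' Convert a C-statistic to a Cox-Snell R-squared
#'
#' Assumes a binormal linear predictor: within each outcome class the linear
#' predictor is normal with unit variance, the class means separated by
#' `sqrt(2) * qnorm(c)` so the implied concordance equals `c`. The implied
#' event probabilities follow from Bayes' rule at prevalence `phi`, and the
#' Cox-Snell R-squared is evaluated by a large Monte-Carlo average of the
#' model and null log-likelihoods. Class counts are fixed at their expected
#' values and antithetic normal draws are used, so the estimate is stable to
#' ~1e-3 at the default number of draws; deterministic given `seed`.
#'
#' @param c_statistic Anticipated C-statistic in (0.5, 1).
#' @param phi Outcome prevalence in (0, 1).
#' @param draws Monte-Carlo draws (>= 1e6 recommended).
#' @param seed RNG seed.
#' @return The Cox-Snell R-squared (scalar).
#' @export
cstat_to_r2cs <- function(c_statistic, phi, draws = 2e6, seed = 123456L) {
  if (!is.finite(c_statistic) || c_statistic <= 0.5 || c_statistic >= 1)
    stop("c_statistic must lie in (0.5, 1): no discrimination to convert")
  stopifnot(phi > 0, phi < 1)
  delta <- sqrt(2) * stats::qnorm(c_statistic)
  n1 <- round(phi * draws); n0 <- draws - n1
  with_seed(seed, {
    h0 <- stats::rnorm(ceiling(n0 / 2)); lp0 <- c(h0, -h0)[seq_len(n0)]
    h1 <- stats::rnorm(ceiling(n1 / 2)); lp1 <- delta + c(h1, -h1)[seq_len(n1)]
    # calibrated event probability given the linear predictor
    a <- log(phi / (1 - phi)) - delta^2 / 2
    ll_model <- (sum(stats::plogis(a + delta * lp1, log.p = TRUE)) +
                   sum(stats::plogis(a + delta * lp0, lower.tail = FALSE,
                                     log.p = TRUE))) / draws
    pbar <- n1 / draws
    ll_null <- pbar * log(pbar) + (1 - pbar) * log(1 - pbar)
    1 - exp(2 * (ll_null - ll_model))
  })
}

#' Minimum sample size for developing a binary prediction model
#'
#' The three standard minimum-n criteria for a new binary-outcome prediction
#' model, driven by an anticipated C-statistic:
#' \describe{
#'   \item{shrinkage (`n_shrinkage`)}{expected uniform shrinkage of at least
#'     `S = 0.9`: `n = p / ((S - 1) * ln(1 - R2_CS / S))`.}
#'   \item{optimism (`n_optimism`)}{apparent-to-adjusted R-squared optimism
#'     of at most `delta = 0.05`, via the shrinkage level
#'     `S = R2 / (R2 + delta * R2_max)` with
#'     `R2_max = 1 - (phi^phi (1-phi)^(1-phi))^2`.}
#'   \item{risk precision (`n_risk`)}{overall outcome risk estimated within
#'     `+-` `risk_margin`: `n = (z_{0.975} / margin)^2 * phi * (1 - phi)`.}
#' }
#' Each criterion is rounded up; the recommendation `n_final` is their
#' maximum. All three are printed so any single reported figure can be
#' traced to the criterion that produced it.
#'
#' @param c_statistic Anticipated C-statistic in (0.5, 1).
#' @param phi Outcome prevalence.
#' @param n_parameters Number of candidate predictor parameters.
#' @param shrinkage Shrinkage target S (default 0.9).
#' @param optimism_margin Allowed R-squared optimism (default 0.05).
#' @param risk_margin Margin of error on the overall risk (default 0.05).
#' @param draws,seed Monte-Carlo settings for [cstat_to_r2cs()].
#' @return A `sample_size_report`: `r2_cs`, `r2_max`, `n_shrinkage`,
#'   `n_optimism`, `n_risk`, `n_final`, `events_at_n_final`, `epp`
#'   (events per parameter), plus the inputs.
#' @export
min_sample_size <- function(c_statistic = 0.8, phi = 0.2, n_parameters = 3L,
                            shrinkage = 0.9, optimism_margin = 0.05,
                            risk_margin = 0.05, draws = 2e6, seed = 123456L) {
  stopifnot(n_parameters >= 1, shrinkage > 0, shrinkage < 1)
  r2 <- cstat_to_r2cs(c_statistic, phi, draws = draws, seed = seed)
  if (r2 >= shrinkage)
    stop("R2_CS (", round(r2, 3), ") >= shrinkage target; criterion undefined")
  n1 <- n_parameters / ((shrinkage - 1) * log(1 - r2 / shrinkage))
  r2_max <- 1 - (phi^phi * (1 - phi)^(1 - phi))^2
  s2 <- r2 / (r2 + optimism_margin * r2_max)
  n2 <- n_parameters / ((s2 - 1) * log(1 - r2 / s2))
  z <- stats::qnorm(0.975)
  n3 <- (z / risk_margin)^2 * phi * (1 - phi)
  ns <- c(n_shrinkage = as.integer(ceiling(n1)),
          n_optimism = as.integer(ceiling(n2)),
          n_risk = as.integer(ceiling(n3)))
  nf <- max(ns)
  structure(list(
    c_statistic = c_statistic, phi = phi, n_parameters = n_parameters,
    shrinkage = shrinkage, optimism_margin = optimism_margin,
    risk_margin = risk_margin,
    r2_cs = r2, r2_max = r2_max,
    n_shrinkage = unname(ns["n_shrinkage"]),
    n_optimism = unname(ns["n_optimism"]),
    n_risk = unname(ns["n_risk"]),
    n_final = nf,
    events_at_n_final = as.integer(ceiling(nf * phi)),
    epp = nf * phi / n_parameters
  ), class = "sample_size_report")
}

#' @export
print.sample_size_report <- function(x, ...) {
  cat("Minimum sample size for a binary prediction model\n")
  cat(sprintf("  inputs: C = %.3f, prevalence = %.3f, parameters = %d\n",
              x$c_statistic, x$phi, x$n_parameters))
  cat(sprintf("  Cox-Snell R2 = %.4f (max attainable %.4f)\n", x$r2_cs, x$r2_max))
  cat(sprintf("  criterion 1, shrinkage >= %.2f:        n = %d\n",
              x$shrinkage, x$n_shrinkage))
  cat(sprintf("  criterion 2, optimism <= %.2f:         n = %d\n",
              x$optimism_margin, x$n_optimism))
  cat(sprintf("  criterion 3, risk margin +- %.2f:      n = %d\n",
              x$risk_margin, x$n_risk))
  cat(sprintf("  recommendation (max): n = %d (%d events, %.1f per parameter)\n",
              x$n_final, x$events_at_n_final, x$epp))
  invisible(x)
}
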