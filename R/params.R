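#' Hyperparameters of the blinded hierarchical model
#'
#' The stage-1 hierarchical model places `d_j ~ N(mu_d, sigma_d^2)` on the
#' per-event treatment log-odds offsets, with hyperpriors
#' `mu_d ~ N(mu_d0, sigma_d0^2)` and `sigma_d ~ Unif(U_a, U_b)`. The defaults
#' are the weakly-informative application values of the case study:
#' `mu_d0 = 0`, `sigma_d0 = 2`, `U_a = 0`, `U_b = 3`.
#'
#' @param mu_d0 prior mean of `mu_d`.
#' @param sigma_d0 prior standard deviation of `mu_d` (positive).
#' @param U_a,U_b support of the uniform prior on `sigma_d`, `U_a < U_b`.
#' @return Object of class `blinded_hyperparams`.
#' @export
blinded_hyperparams <- function(mu_d0 = 0, sigma_d0 = 2, U_a = 0, U_b = 3) {
  stopifnot(sigma_d0 > 0, U_a < U_b)
  structure(list(mu_d0 = mu_d0, sigma_d0 = sigma_d0, U_a = U_a, U_b = U_b),
            class = "blinded_hyperparams")
}

#' Hyperparameters of the unblinded hierarchical logistic model
#'
#' Stage 2 places `beta0_j ~ N(logit(pi_M_j), sigma_b0^2)` on per-event
#' intercepts and `beta1_j ~ N(mu_b1, sigma_b1^2)` on dose slopes, with
#' `mu_b1 ~ N(mu_1, sigma_1^2)`, `sigma_b0 ~ Unif(U_1, U_2)` and
#' `sigma_b1 ~ Unif(U_3, U_4)`. Defaults are the case-study values
#' `mu_1 = 0`, `sigma_1 = 2`, bounds `(0, 3)` for both scales.
#'
#' @param mu_1 prior mean of the shared slope mean `mu_b1`.
#' @param sigma_1 prior standard deviation of `mu_b1` (positive).
#' @param U_1,U_2 support of the uniform prior on `sigma_b0`.
#' @param U_3,U_4 support of the uniform prior on `sigma_b1`.
#' @return Object of class `unblinded_hyperparams`.
#' @export
unblinded_hyperparams <- function(mu_1 = 0, sigma_1 = 2,
                                  U_1 = 0, U_2 = 3, U_3 = 0, U_4 = 3) {
  stopifnot(sigma_1 > 0, U_1 < U_2, U_3 < U_4)
  structure(list(mu_1 = mu_1, sigma_1 = sigma_1,
                 U_1 = U_1, U_2 = U_2, U_3 = U_3, U_4 = U_4),
            class = "unblinded_hyperparams")
}

#' Decision policy: posterior-probability critical values
#'
#' An adverse event is flagged at stage 1 when `P_S1 >= P_crit1` and a
#' flagged event is confirmed at stage 2 when `P_S2 >= P_crit2`; ties at the
#' boundary flag. The case study names `(0.9, 0.7)` liberal, `(0.9, 0.8)`
#' medium and `(0.9, 0.9)` conservative.
#'
#' @param P_crit1,P_crit2 critical values, each strictly in (0, 1).
#' @return Object of class `decision_policy` with a `label` field
#'   (`"liberal"`, `"medium"`, `"conservative"` or `"custom"`).
#' @export
decision_policy <- function(P_crit1 = 0.9, P_crit2 = 0.9) {
  stopifnot(P_crit1 > 0, P_crit1 < 1, P_crit2 > 0, P_crit2 < 1)
  label <- if (P_crit1 == 0.9 && P_crit2 == 0.7) "liberal"
    else if (P_crit1 == 0.9 && P_crit2 == 0.8) "medium"
    else if (P_crit1 == 0.9 && P_crit2 == 0.9) "conservative"
    else "custom"
  structure(list(P_crit1 = P_crit1, P_crit2 = P_crit2, label = label),
            class = "decision_policy")
}

#' MCMC sampler settings
#'
#' Budget and tuning settings for the adaptive random-walk
#' Metropolis-within-Gibbs sampler. The default budget (10,000 retained
#' draws after 1,000 burn-in, one chain) matches the simulation study the
#' package reproduces; [mcmc_control_reduced()] gives the reduced desk-scale
#' budget (2,000 / 500) used by default in replicated operating-
#' characteristic runs, which inflates the Monte Carlo standard error of a
#' posterior probability near 0.9 from about 0.003 to 0.007.
#'
#' @param draws retained posterior draws per chain (>= 100).
#' @param burn_in discarded adaptation draws (>= 0).
#' @param chains number of chains (1 by default; use >= 2 for split-R-hat).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param adapt_window iterations between proposal-scale updates during
#'   burn-in.
#' @param target_acceptance per-coordinate acceptance target of the
#'   adaptation (0.44 is standard for scalar random-walk updates).
#' @return Object of class `mcmc_control`.
#' @export
mcmc_control <- function(draws = 10000L, burn_in = 1000L, chains = 1L,
                         seed = NULL, adapt_window = 50L,
                         target_acceptance = 0.44) {
  stopifnot(draws >= 100, burn_in >= 0, chains >= 1,
            adapt_window >= 1, target_acceptance > 0, target_acceptance < 1)
  structure(list(draws = as.integer(draws), burn_in = as.integer(burn_in),
                 chains = as.integer(chains), seed = seed,
                 adapt_window = as.integer(adapt_window),
                 target_acceptance = target_acceptance),
            class = "mcmc_control")
}

#' @rdname mcmc_control
#' @param ... passed on to [mcmc_control()].
#' @export
mcmc_control_reduced <- function(...) {
  args <- list(...)
  args$draws <- args$draws %||% 2000L
  args$burn_in <- args$burn_in %||% 500L
  do.call(mcmc_control, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
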