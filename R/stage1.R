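#' Blinded pooled adverse-event counts
#'
#' Stage-1 input: one pooled count per adverse event out of the `N` subjects
#' enrolled at the interim, treatment assignments concealed. All events share
#' the same `N`.
#'
#' @param ae character vector of AE names.
#' @param y pooled number of subjects with each event, `0 <= y <= N`.
#' @param N total subjects enrolled at the interim.
#' @return Object of class `blinded_counts` (a data frame with columns
#'   `ae`, `y`, `n`).
#' @export
blinded_counts <- function(ae, y, N) {
  stopifnot(length(ae) == length(y), length(N) == 1L, N >= 1)
  y <- as.integer(y); N <- as.integer(N)
  if (any(y < 0 | y > N)) stop("counts must satisfy 0 <= y <= N", call. = FALSE)
  structure(data.frame(ae = as.character(ae), y = y, n = N,
                       stringsAsFactors = FALSE),
            class = c("blinded_counts", "data.frame"), N = N)
}

#' Posterior exceedance probability of the conjugate Beta-Binomial model
#'
#' With `Y ~ Binomial(N, pi)` and a `Beta(a, b)` prior, the posterior is
#' `Beta(Y + a, N - Y + b)` and the probability that the pooled incidence
#' rate exceeds the expected rate `pi_M` is available in closed form as the
#' upper regularized incomplete beta function. No sampling is involved.
#'
#' @param y pooled event count(s), `0 <= y <= n`.
#' @param n total enrolled; recycled against `y`.
#' @param pi_M expected pooled incidence rate(s), strictly in (0, 1).
#' @param a,b Beta prior parameters (default the uniform `Beta(1, 1)`).
#' @return `P(pi > pi_M | y)`, vectorized over the inputs.
#' @export
#' @examples
#' beta_binomial_exceedance(2, 53, 0.02)  # about 0.906
beta_binomial_exceedance <- function(y, n, pi_M, a = 1, b = 1) {
  if (any(pi_M <= 0 | pi_M >= 1))
    stop("pi_M must lie strictly in (0, 1)", call. = FALSE)
  if (any(y < 0 | y > n)) stop("need 0 <= y <= n", call. = FALSE)
  stats::pbeta(pi_M, y + a, n - y + b, lower.tail = FALSE)
}

#' Exact flag probability of the independent blinded rule
#'
#' For a true pooled rate `pi0`, enumerates `Y ~ Binomial(N, pi0)` and sums
#' the probability of the counts whose closed-form exceedance meets the
#' critical value, giving the flag probability of the independent
#' Beta-Binomial rule without simulation.
#'
#' @param pi0 true pooled incidence rate.
#' @inheritParams beta_binomial_exceedance
#' @param N subjects enrolled at the interim.
#' @param P_crit1 stage-1 critical value; ties flag.
#' @return Probability that the event is flagged, exactly.
#' @export
flag_probability_exact <- function(pi0, pi_M, N, P_crit1 = 0.9, a = 1, b = 1) {
  stopifnot(length(pi_M) == length(pi0) || length(pi_M) == 1L || length(pi0) == 1L)
  k <- max(length(pi0), length(pi_M))
  pi0 <- rep_len(pi0, k); pi_M <- rep_len(pi_M, k)
  vapply(seq_len(k), function(j) {
    yy <- 0:N
    flag <- beta_binomial_exceedance(yy, N, pi_M[j], a, b) >= P_crit1
    sum(stats::dbinom(yy[flag], N, pi0[j]))
  }, 0)
}

#' Stage 1: blinded safety-signal detection
#'
#' Screens pooled blinded counts for potential safety signals. Two models
#' are available. The independent model evaluates, per event, the
#' closed-form Beta-Binomial posterior probability that the pooled rate
#' exceeds its expected rate `pi_M` (no sampling; Monte Carlo standard
#' errors are zero). The hierarchical model assumes the control-arm rate
#' equals `pi_M`, writes the pooled rate as the randomization-weighted
#' mixture `pi_j = q_c * pi_M_j + q_t * pi_Trt_j` with
#' `logit(pi_Trt_j) = logit(pi_M_j) + d_j`, and shrinks the per-event
#' log-odds offsets `d_j` through shared hyperparameters
#' (`d_j ~ N(mu_d, sigma_d^2)`), which reduces multiplicity-driven false
#' flags across events. For the hierarchical model
#' `P_S1 = P(pi_Trt_j > pi_M_j | data)`, computed as the fraction of
#' retained draws with `d_j > 0` (the two events are identical because the
#' offset is a monotone transform).
#'
#' An event is flagged when `P_S1 >= P_crit1`; ties flag.
#'
#' @param counts a [blinded_counts()] object, aligned with `aes` by name.
#' @param aes an [ae_spec()].
#' @param model `"hierarchical"` (default) or `"independent"`.
#' @param design a [trial_design()]; required by the hierarchical model for
#'   the protocol control fraction `q_c`.
#' @param hp [blinded_hyperparams()] (hierarchical model only).
#' @param policy a [decision_policy()].
#' @param control an [mcmc_control()] (hierarchical model only).
#' @param prior `c(a, b)` Beta prior of the independent model.
#' @return Object of class `blinded_safety`: list with `table` (per event:
#'   `ae`, `y`, `n`, `pi_M`, `P_S1`, `mc_se`, `flagged`), `model`, `policy`,
#'   and for the hierarchical model `draws` (an `mcmc_draws` over
#'   `d_1..d_J, mu_d, sigma_d`), `diagnostics` and a `warning` flag set on
#'   apparent non-convergence (never an error).
#' @export
#' @examples
#' aes <- hobit_aes()
#' cnt <- blinded_counts(aes$name, c(2, 13, 21, 40, 40, 1, 5), 53)
#' fit <- blinded_safety(cnt, aes, model = "independent")
#' fit$table$P_S1
blinded_safety <- function(counts, aes,
                           model = c("hierarchical", "independent"),
                           design = NULL,
                           hp = blinded_hyperparams(),
                           policy = decision_policy(),
                           control = mcmc_control(),
                           prior = c(1, 1)) {
  model <- match.arg(model)
  stopifnot(inherits(aes, "ae_spec"))
  if (!inherits(counts, "blinded_counts"))
    counts <- blinded_counts(counts$ae, counts$y, unique(counts$n))
  if (!identical(counts$ae, aes$name)) {
    m <- match(aes$name, counts$ae)
    if (anyNA(m)) stop("blinded counts and AE specification are misaligned: ",
                       paste(setdiff(aes$name, counts$ae), collapse = ", "),
                       call. = FALSE)
    counts <- counts[m, , drop = FALSE]
  }
  N <- attr(counts, "N") %||% unique(counts$n)
  J <- nrow(aes)

  if (model == "independent") {
    P <- beta_binomial_exceedance(counts$y, N, aes$pi_M, prior[1], prior[2])
    tab <- data.frame(ae = aes$name, y = counts$y, n = N, pi_M = aes$pi_M,
                      P_S1 = P, mc_se = 0, flagged = P >= policy$P_crit1,
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, model = model, policy = policy,
                          prior = prior, warning = FALSE),
                     class = "blinded_safety"))
  }

  if (is.null(design)) stop("the hierarchical model needs 'design' for q_c",
                            call. = FALSE)
  q_c <- attr(design, "q_c"); q_t <- attr(design, "q_t")
  y <- counts$y; pi_M <- aes$pi_M; lpi <- stats::qlogis(pi_M)
  idx_d <- seq_len(J); idx_mu <- J + 1L; idx_sg <- J + 2L
  d_terms <- function(x) {
    pi_trt <- stats::plogis(lpi + x[idx_d])
    pij <- q_c * pi_M + q_t * pi_trt
    stats::dbinom(y, N, pij, log = TRUE) +
      stats::dnorm(x[idx_d], x[idx_mu], x[idx_sg], log = TRUE)
  }
  mu_terms <- function(x)
    sum(stats::dnorm(x[idx_d], x[idx_mu], x[idx_sg], log = TRUE)) +
      stats::dnorm(x[idx_mu], hp$mu_d0, hp$sigma_d0, log = TRUE)
  sg_terms <- function(x)
    sum(stats::dnorm(x[idx_d], x[idx_mu], x[idx_sg], log = TRUE)) +
      stats::dunif(x[idx_sg], hp$U_a, hp$U_b, log = TRUE)
  log_post <- function(x)
    sum(d_terms(x)) + stats::dnorm(x[idx_mu], hp$mu_d0, hp$sigma_d0, log = TRUE) +
      stats::dunif(x[idx_sg], hp$U_a, hp$U_b, log = TRUE)
  init <- c(rep(0, J), 0, (hp$U_a + hp$U_b) / 2)
  names(init) <- c(paste0("d_", seq_len(J)), "mu_d", "sigma_d")
  fit <- mcmc_sample(log_post, init,
                     lower = c(rep(-Inf, J + 1), hp$U_a),
                     upper = c(rep(Inf, J + 1), hp$U_b),
                     control = control,
                     groups = list(list(idx = idx_d, terms = d_terms),
                                   list(idx = idx_mu, terms = mu_terms),
                                   list(idx = idx_sg, terms = sg_terms)))
  dmat <- fit$draws[, idx_d, drop = FALSE]
  ndr <- nrow(dmat)
  P <- colMeans(dmat > 0)
  diag <- mcmc_diagnose(fit)
  ## warn on the decision-bearing offsets, not the slow-moving scales
  warn <- any(diag$ess[idx_d] < 50) || isFALSE(attr(diag, "converged"))
  tab <- data.frame(ae = aes$name, y = y, n = N, pi_M = pi_M, P_S1 = P,
                    mc_se = sqrt(P * (1 - P) / ndr),
                    flagged = P >= policy$P_crit1, stringsAsFactors = FALSE)
  structure(list(table = tab, model = model, policy = policy, hp = hp,
                 design = design, draws = fit, diagnostics = diag,
                 warning = warn),
            class = "blinded_safety")
}

#' Posterior draws of the treatment-arm incidence rates
#'
#' Maps the offset draws of a hierarchical [blinded_safety()] fit through
#' `pi_Trt_j = plogis(logit(pi_M_j) + d_j)`; columns are events.
#'
#' @param object a hierarchical `blinded_safety` fit.
#' @return Matrix of `pi_Trt` draws (rows = retained draws).
#' @export
treatment_rate_draws <- function(object) {
  stopifnot(inherits(object, "blinded_safety"), object$model == "hierarchical")
  J <- nrow(object$table)
  dmat <- object$draws$draws[, seq_len(J), drop = FALSE]
  out <- stats::plogis(sweep(dmat, 2, stats::qlogis(object$table$pi_M), "+"))
  colnames(out) <- object$table$ae
  out
}

#' @export
print.blinded_safety <- function(x, digits = 3, ...) {
  cat(sprintf("Stage-1 blinded safety screen (%s model), N = %d, P_crit1 = %g\n",
              x$model, x$table$n[1], x$policy$P_crit1))
  tab <- x$table
  tab$P_S1 <- round(tab$P_S1, digits)
  print.data.frame(tab[, c("ae", "y", "pi_M", "P_S1", "flagged")],
                   row.names = FALSE)
  if (isTRUE(x$warning))
    cat("note: sampler diagnostics suggest poor mixing; interpret with care\n")
  invisible(x)
}

#' @export
summary.blinded_safety <- function(object, ...) {
  out <- object$table
  if (object$model == "hierarchical") {
    J <- nrow(out)
    dmat <- object$draws$draws[, seq_len(J), drop = FALSE]
    out$d_mean <- colMeans(dmat)
    out$d_lo <- apply(dmat, 2, stats::quantile, 0.025)
    out$d_hi <- apply(dmat, 2, stats::quantile, 0.975)
  }
  structure(list(table = out, model = object$model, policy = object$policy,
                 n_flagged = sum(out$flagged)),
            class = "summary.blinded_safety")
}

#' @export
print.summary.blinded_safety <- function(x, ...) {
  cat(sprintf("Stage-1 %s model: %d of %d events flagged at P_crit1 = %g\n",
              x$model, x$n_flagged, nrow(x$table), x$policy$P_crit1))
  print.data.frame(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.blinded_safety <- function(object, ...) {
  if (object$model == "independent")
    return(stats::setNames(object$table$P_S1, object$table$ae))
  colMeans(object$draws$draws)
}

#' @export
plot.blinded_safety <- function(x, ...) {
  tab <- x$table
  bp <- graphics::barplot(tab$P_S1, names.arg = seq_len(nrow(tab)),
                          ylim = c(0, 1), ylab = "P(signal | blinded data)",
                          xlab = "adverse event", ...)
  graphics::abline(h = x$policy$P_crit1, lty = 2)
  invisible(bp)
}
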