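#' Unblinded per-arm adverse-event counts
#'
#' Stage-2 input: a tidy table with one row per adverse event and arm,
#' carrying the per-arm count, sample size and dose. Arm order must match
#' the trial design (control first).
#'
#' @param ae character vector of AE names (repeated per arm).
#' @param arm character vector of arm labels.
#' @param dose numeric per-row dose.
#' @param n per-arm sample sizes.
#' @param y per-arm event counts, `0 <= y <= n`.
#' @return Object of class `unblinded_counts` (a data frame).
#' @export
unblinded_counts <- function(ae, arm, dose, n, y) {
  stopifnot(length(ae) == length(arm), length(arm) == length(dose),
            length(dose) == length(n), length(n) == length(y))
  y <- as.integer(y); n <- as.integer(n)
  if (any(y < 0 | y > n)) stop("counts must satisfy 0 <= y <= n", call. = FALSE)
  structure(data.frame(ae = as.character(ae), arm = as.character(arm),
                       dose = as.numeric(dose), n = n, y = y,
                       stringsAsFactors = FALSE),
            class = c("unblinded_counts", "data.frame"))
}

#' Logistic dose-response incidence rate
#'
#' Evaluates `plogis(beta0 + beta1 * x)`, the per-arm incidence rate of the
#' stage-2 model; always strictly inside (0, 1) and monotone in `x` when
#' `beta1 > 0`.
#'
#' @param beta0 intercept on the logit scale (control-arm log-odds).
#' @param beta1 dose slope on the logit scale.
#' @param x dose covariate.
#' @return Incidence rate(s), vectorized.
#' @export
#' @examples
#' dose_response_rate(qlogis(0.4), 0, 5)        # 0.4: zero slope
#' dose_response_rate(-2, 10, 0.0952)           # about 0.2596
dose_response_rate <- function(beta0, beta1, x) {
  stats::plogis(beta0 + beta1 * x)
}

#' Collapse a multi-arm counts table to active vs. control
#'
#' Pools every non-control arm into one pseudo-arm and recodes the covariate
#' as the indicator `x = 0` (control) / `x = 1` (active). Events anticipated
#' to show a flat dose effect can be analyzed this way. Idempotent apart
#' from the covariate recoding.
#'
#' @param counts an [unblinded_counts()] object.
#' @param design the [trial_design()] identifying the control arm (default:
#'   the first arm label in `counts` is the control).
#' @return An `unblinded_counts` object with two arms per event and doses
#'   recoded to 0/1.
#' @export
two_arm_collapse <- function(counts, design = NULL) {
  stopifnot(inherits(counts, "unblinded_counts"))
  arms <- unique(counts$arm)
  if (length(arms) < 2) stop("need at least two arms to collapse", call. = FALSE)
  ctrl <- if (!is.null(design)) design$label[design$control] else arms[1]
  is_ctrl <- counts$arm == ctrl
  if (!any(is_ctrl)) stop("control arm not present in counts", call. = FALSE)
  agg <- function(df, lab, x) data.frame(
    ae = df$ae[1], arm = lab, dose = x, n = sum(df$n), y = sum(df$y),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(counts, counts$ae), function(df) {
    rbind(agg(df[df$arm == ctrl, , drop = FALSE], "control", 0),
          agg(df[df$arm != ctrl, , drop = FALSE], "active", 1))
  }))
  rownames(out) <- NULL
  ## preserve the event order of the input
  out <- out[order(match(out$ae, unique(counts$ae))), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("unblinded_counts", "data.frame"))
}

#' Stage 2: unblinded confirmation by hierarchical logistic dose-response
#'
#' Fits the Bayesian hierarchical logistic model to the unblinded per-arm
#' counts of the stage-1-flagged events: `Y_ij ~ Binomial(n_i, pi_ij)` with
#' `logit(pi_ij) = beta0_j + beta1_j * x_i`. Per-event intercepts have prior
#' `beta0_j ~ N(logit(pi_M_j), sigma_b0^2)` — the fixed prior mean lets
#' baseline incidence vary across event types while only the scale is
#' learned — and slopes `beta1_j ~ N(mu_b1, sigma_b1^2)` share the
#' hyperparameters `mu_b1`, `sigma_b1` across events. A signal is confirmed
#' when `P_S2 = P(beta1_j > 0 | data) >= P_crit2`.
#'
#' By default the flagged events are fit jointly so the hierarchy pools the
#' slope information; `joint = FALSE` fits one event at a time (each fit
#' then carries its own hyperparameter draws).
#'
#' The dose covariate defaults to the raw `dose` column of the counts
#' table. `dose_scale` divides it (e.g. `dose_scale = 100` analyzes dose/100);
#' the default of 1 keeps the stated slope priors weakly informative relative
#' to the per-unit-dose effects the monitored trial can exhibit.
#'
#' @param counts an [unblinded_counts()] for the flagged events (all arms).
#' @param aes an [ae_spec()]; only rows matching `counts` are used.
#' @param hp [unblinded_hyperparams()].
#' @param policy a [decision_policy()].
#' @param control an [mcmc_control()].
#' @param joint fit all events jointly (default) or one at a time.
#' @param dose_scale divisor applied to the dose covariate before fitting.
#' @return Object of class `unblinded_safety`: list with `table` (per event:
#'   `P_S2`, `mc_se`, `confirmed`, posterior means and central 95% intervals
#'   of `beta0_j`, `beta1_j`), `draws` (an `mcmc_draws`, or a list of them
#'   when `joint = FALSE`), `diagnostics`, `warning`, plus the inputs.
#' @export
unblinded_safety <- function(counts, aes,
                             hp = unblinded_hyperparams(),
                             policy = decision_policy(),
                             control = mcmc_control(),
                             joint = TRUE, dose_scale = 1) {
  stopifnot(inherits(counts, "unblinded_counts"), inherits(aes, "ae_spec"))
  ae_names <- unique(counts$ae)
  if (!length(ae_names)) stop("no flagged events to confirm", call. = FALSE)
  m <- match(ae_names, aes$name)
  if (anyNA(m)) stop("unknown AE in unblinded counts: ",
                     paste(ae_names[is.na(m)], collapse = ", "), call. = FALSE)
  aes <- aes[m, , drop = FALSE]
  split_counts <- split(counts, factor(counts$ae, levels = ae_names))
  arm_n <- vapply(split_counts, nrow, 0L)
  if (length(unique(arm_n)) != 1L)
    stop("all events must cover the same arms", call. = FALSE)
  Ymat <- t(vapply(split_counts, function(df) as.numeric(df$y),
                   numeric(arm_n[1])))
  nvec <- split_counts[[1]]$n
  xvec <- split_counts[[1]]$dose / dose_scale

  if (!joint && length(ae_names) > 1) {
    fits <- lapply(seq_along(ae_names), function(j)
      unblinded_safety(structure(split_counts[[j]],
                                 class = c("unblinded_counts", "data.frame")),
                       ae_spec(aes$name[j], aes$pi_M[j], aes$flat_dose_effect[j]),
                       hp = hp, policy = policy, control = control,
                       joint = TRUE, dose_scale = dose_scale))
    tab <- do.call(rbind, lapply(fits, `[[`, "table"))
    rownames(tab) <- NULL
    return(structure(list(table = tab, draws = lapply(fits, `[[`, "draws"),
                          joint = FALSE, policy = policy, hp = hp,
                          x = xvec, n = nvec,
                          warning = any(vapply(fits, `[[`, TRUE, "warning"))),
                     class = "unblinded_safety"))
  }

  J <- length(ae_names); I <- length(nvec)
  mb0 <- stats::qlogis(aes$pi_M)
  i_b0 <- seq_len(J); i_b1 <- J + seq_len(J)
  i_mu <- 2L * J + 1L; i_s0 <- 2L * J + 2L; i_s1 <- 2L * J + 3L
  lik_rows <- function(b0, b1) {
    eta <- outer(b0, rep(1, I)) + outer(b1, xvec)
    rowSums(stats::dbinom(Ymat, rep(nvec, each = J), stats::plogis(eta),
                          log = TRUE))
  }
  b0_terms <- function(x)
    lik_rows(x[i_b0], x[i_b1]) +
      stats::dnorm(x[i_b0], mb0, x[i_s0], log = TRUE)
  b1_terms <- function(x)
    lik_rows(x[i_b0], x[i_b1]) +
      stats::dnorm(x[i_b1], x[i_mu], x[i_s1], log = TRUE)
  mu_terms <- function(x)
    sum(stats::dnorm(x[i_b1], x[i_mu], x[i_s1], log = TRUE)) +
      stats::dnorm(x[i_mu], hp$mu_1, hp$sigma_1, log = TRUE)
  s0_terms <- function(x)
    sum(stats::dnorm(x[i_b0], mb0, x[i_s0], log = TRUE)) +
      stats::dunif(x[i_s0], hp$U_1, hp$U_2, log = TRUE)
  s1_terms <- function(x)
    sum(stats::dnorm(x[i_b1], x[i_mu], x[i_s1], log = TRUE)) +
      stats::dunif(x[i_s1], hp$U_3, hp$U_4, log = TRUE)
  log_post <- function(x)
    sum(lik_rows(x[i_b0], x[i_b1])) +
      sum(stats::dnorm(x[i_b0], mb0, x[i_s0], log = TRUE)) +
      sum(stats::dnorm(x[i_b1], x[i_mu], x[i_s1], log = TRUE)) +
      stats::dnorm(x[i_mu], hp$mu_1, hp$sigma_1, log = TRUE) +
      stats::dunif(x[i_s0], hp$U_1, hp$U_2, log = TRUE) +
      stats::dunif(x[i_s1], hp$U_3, hp$U_4, log = TRUE)
  init <- c(mb0, rep(0, J), 0, (hp$U_1 + hp$U_2) / 2, (hp$U_3 + hp$U_4) / 2)
  names(init) <- c(paste0("beta0_", seq_len(J)), paste0("beta1_", seq_len(J)),
                   "mu_b1", "sigma_b0", "sigma_b1")
  fit <- mcmc_sample(log_post, init,
                     lower = c(rep(-Inf, 2 * J + 1), hp$U_1, hp$U_3),
                     upper = c(rep(Inf, 2 * J + 1), hp$U_2, hp$U_4),
                     control = control,
                     groups = list(list(idx = i_b0, terms = b0_terms),
                                   list(idx = i_b1, terms = b1_terms),
                                   list(idx = i_mu, terms = mu_terms),
                                   list(idx = i_s0, terms = s0_terms),
                                   list(idx = i_s1, terms = s1_terms)))
  b0d <- fit$draws[, i_b0, drop = FALSE]
  b1d <- fit$draws[, i_b1, drop = FALSE]
  ndr <- nrow(b1d)
  P <- colMeans(b1d > 0)
  diag <- mcmc_diagnose(fit)
  warn <- any(diag$ess[i_b1] < 50) || isFALSE(attr(diag, "converged"))
  qs <- function(mat, p) apply(mat, 2, stats::quantile, p)
  tab <- data.frame(ae = ae_names, pi_M = aes$pi_M,
                    P_S2 = P, mc_se = sqrt(P * (1 - P) / ndr),
                    confirmed = P >= policy$P_crit2,
                    beta0_mean = colMeans(b0d),
                    beta0_lo = qs(b0d, 0.025), beta0_hi = qs(b0d, 0.975),
                    beta1_mean = colMeans(b1d),
                    beta1_lo = qs(b1d, 0.025), beta1_hi = qs(b1d, 0.975),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, draws = fit, joint = TRUE, policy = policy,
                 hp = hp, x = xvec, n = nvec, counts = counts,
                 diagnostics = diag, warning = warn),
            class = "unblinded_safety")
}

.beta_draws <- function(object, j) {
  if (isTRUE(object$joint)) {
    J <- nrow(object$table)
    list(b0 = object$draws$draws[, j],
         b1 = object$draws$draws[, J + j])
  } else {
    list(b0 = object$draws[[j]]$draws[, 1],
         b1 = object$draws[[j]]$draws[, 2])
  }
}

#' @export
print.unblinded_safety <- function(x, digits = 3, ...) {
  cat(sprintf("Stage-2 unblinded dose-response confirmation, P_crit2 = %g (%s)\n",
              x$policy$P_crit2, x$policy$label))
  tab <- x$table[, c("ae", "P_S2", "mc_se", "confirmed", "beta1_mean")]
  print.data.frame(format(tab, digits = digits), row.names = FALSE)
  if (isTRUE(x$warning))
    cat("note: sampler diagnostics suggest poor mixing; interpret with care\n")
  invisible(x)
}

#' @export
summary.unblinded_safety <- function(object, ...) {
  structure(list(table = object$table, policy = object$policy,
                 n_confirmed = sum(object$table$confirmed)),
            class = "summary.unblinded_safety")
}

#' @export
print.summary.unblinded_safety <- function(x, ...) {
  cat(sprintf("Stage-2: %d of %d flagged events confirmed at P_crit2 = %g\n",
              x$n_confirmed, nrow(x$table), x$policy$P_crit2))
  print.data.frame(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.unblinded_safety <- function(object, ...) {
  tab <- object$table
  out <- cbind(beta0 = tab$beta0_mean, beta1 = tab$beta1_mean)
  rownames(out) <- tab$ae
  out
}

#' Posterior dose-response curves
#'
#' Posterior mean and central 95% interval of the incidence rate at new
#' doses, per confirmed-stage event.
#'
#' @param object an [unblinded_safety()] fit.
#' @param newdata data frame with a `dose` column (default: the fitted
#'   doses).
#' @param ... unused.
#' @return Data frame with `ae`, `dose`, `rate`, `lo`, `hi`.
#' @export
predict.unblinded_safety <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata$dose
  out <- do.call(rbind, lapply(seq_len(nrow(object$table)), function(j) {
    dr <- .beta_draws(object, j)
    rates <- vapply(x, function(xi)
      dose_response_rate(dr$b0, dr$b1, xi), numeric(length(dr$b0)))
    data.frame(ae = object$table$ae[j], dose = x,
               rate = colMeans(rates),
               lo = apply(rates, 2, stats::quantile, 0.025),
               hi = apply(rates, 2, stats::quantile, 0.975),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.unblinded_safety <- function(x, ae = NULL, ...) {
  tab <- x$table
  j <- if (is.null(ae)) 1L else match(ae, tab$ae)
  if (is.na(j)) stop("unknown AE", call. = FALSE)
  grid <- data.frame(dose = seq(min(x$x), max(x$x), length.out = 50))
  pr <- predict(x, grid)
  pr <- pr[pr$ae == tab$ae[j], ]
  graphics::plot(pr$dose, pr$rate, type = "l", ylim = c(0, 1),
                 xlab = "dose", ylab = "incidence rate",
                 main = tab$ae[j], ...)
  graphics::lines(pr$dose, pr$lo, lty = 3)
  graphics::lines(pr$dose, pr$hi, lty = 3)
  graphics::abline(h = tab$pi_M[j], lty = 2, col = "grey40")
  invisible(pr)
}

#' Simulate posterior-predictive per-arm counts
#'
#' Draws replicated count tables from the posterior predictive distribution
#' of a stage-2 fit: for each simulation a retained posterior draw of
#' `(beta0_j, beta1_j)` is selected and `Y_ij ~ Binomial(n_i, pi_ij)` is
#' generated at the fitted doses.
#'
#' @param object an [unblinded_safety()] fit.
#' @param nsim number of replicated tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of `nsim` matrices (events x arms).
#' @export
simulate.unblinded_safety <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(object$table); I <- length(object$x)
  ndr <- length(.beta_draws(object, 1)$b0)
  lapply(seq_len(nsim), function(s) {
    k <- sample.int(ndr, 1)
    t(vapply(seq_len(J), function(j) {
      dr <- .beta_draws(object, j)
      p <- dose_response_rate(dr$b0[k], dr$b1[k], object$x)
      stats::rbinom(I, object$n, p)
    }, numeric(I)))
  })
}

#' @export
residuals.unblinded_safety <- function(object, ...) {
  if (is.null(object$counts))
    stop("residuals need the fitted counts (joint fit only)", call. = FALSE)
  J <- nrow(object$table)
  sc <- split(object$counts, factor(object$counts$ae, levels = object$table$ae))
  out <- t(vapply(seq_len(J), function(j) {
    dr <- .beta_draws(object, j)
    p <- dose_response_rate(mean(dr$b0), mean(dr$b1), object$x)
    y <- sc[[j]]$y; n <- sc[[j]]$n
    (y - n * p) / sqrt(pmax(n * p * (1 - p), .Machine$double.eps))
  }, numeric(length(object$x))))
  rownames(out) <- object$table$ae
  out
}
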