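test_that("closed-form exceedance matches independent oracles", {
  ## pure prior: uniform, symmetric about any median
  expect_equal(beta_binomial_exceedance(0, 0, 0.5), 0.5)
  ## every subject had the event
  expect_gt(beta_binomial_exceedance(53, 53, 0.02), 0.999)
  ## Beta-CDF / binomial-tail identity: P(Beta(y+1, n-y+1) > q) =
  ## P(Bin(n+1, q) <= y), summed exactly
  for (case in list(c(2, 53, 0.02), c(10, 53, 0.25), c(0, 10, 0.1),
                    c(40, 53, 0.75))) {
    y <- case[1]; n <- case[2]; q <- case[3]
    oracle <- sum(dbinom(0:y, n + 1, q))
    expect_equal(beta_binomial_exceedance(y, n, q), oracle, tolerance = 1e-12)
  }
  ## the frozen case-study value
  expect_equal(round(beta_binomial_exceedance(2, 53, 0.02), 3), 0.906)
  expect_error(beta_binomial_exceedance(2, 53, 0), "pi_M")
  expect_error(beta_binomial_exceedance(60, 53, 0.5), "y <= n")
})

test_that("exceedance is monotone in the count and in the expected rate", {
  N <- 53
  pi_grid <- c(0.01, 0.02, 0.10, 0.25, 0.40, 0.75)
  ## non-decreasing in y / non-increasing in pi_M over the whole grid
  ## (ties only where the probability saturates at machine precision)
  for (pm in pi_grid) {
    e <- beta_binomial_exceedance(0:N, N, pm)
    expect_true(all(diff(e) >= 0))
    expect_true(all(diff(e[e < 1 - 1e-12]) > 0))
  }
  for (y in 0:N) {
    e <- beta_binomial_exceedance(y, N, pi_grid)
    expect_true(all(diff(e) <= 0))
  }
})

test_that("closed form agrees with Monte Carlo Beta draws within 4 SE", {
  set.seed(42)
  for (case in list(c(2, 53, 0.02), c(15, 53, 0.25), c(5, 53, 0.10))) {
    y <- case[1]; n <- case[2]; q <- case[3]
    draws <- rbeta(40000, y + 1, n - y + 1)
    p_mc <- mean(draws > q)
    se <- sqrt(p_mc * (1 - p_mc) / 40000)
    expect_lt(abs(p_mc - beta_binomial_exceedance(y, n, q)), 4 * se)
  }
})

test_that("the independent screen flags by the >= rule, ties included", {
  aes <- hobit_aes()
  cnt <- blinded_counts(aes$name, c(2, 20, 30, 45, 45, 2, 10), 53)
  fit <- blinded_safety(cnt, aes, model = "independent")
  expect_equal(fit$table$flagged, fit$table$P_S1 >= 0.9)
  expect_equal(fit$table$mc_se, rep(0, 7))
  ## a tie at the critical value flags
  p_tie <- fit$table$P_S1[1]
  pol <- decision_policy(P_crit1 = p_tie, P_crit2 = 0.9)
  fit_tie <- blinded_safety(cnt, aes, model = "independent", policy = pol)
  expect_true(fit_tie$table$flagged[1])
})

test_that("zero counts never flag at the case-study expected rates", {
  aes <- hobit_aes()
  cnt <- blinded_counts(aes$name, rep(0, 7), 53)
  fit <- blinded_safety(cnt, aes, model = "independent")
  ## oracle: the closed form itself at y = 0 is (1 - pi_M)^(N+1)
  expect_equal(fit$table$P_S1, (1 - aes$pi_M)^54, tolerance = 1e-12)
  expect_false(any(fit$table$flagged))
})

test_that("misaligned AE tables are refused", {
  aes <- hobit_aes()
  cnt <- blinded_counts(c("Unknown event", aes$name[-1]), rep(1, 7), 53)
  expect_error(blinded_safety(cnt, aes, model = "independent"), "misaligned")
  expect_error(blinded_counts("x", 60, 53), "0 <= y <= N")
})

test_that("hierarchical fit honours the mixture identity in every draw", {
  aes <- hobit_aes(); des <- hobit_design()
  cnt <- hobit_blinded_at(hobit_rate_tiers("elevated"), seed = 8)
  fit <- blinded_safety(cnt, aes, design = des, control = quick_ctl(seed = 2))
  J <- nrow(aes)
  d <- fit$draws$draws[, 1:J]
  pi_trt <- treatment_rate_draws(fit)
  expect_true(all(pi_trt > 0 & pi_trt < 1))
  ## reconstruct pi_trt from the offsets independently
  expect_equal(pi_trt,
               plogis(sweep(d, 2, qlogis(aes$pi_M), "+")),
               ignore_attr = TRUE, tolerance = 1e-12)
  pij <- sweep(sweep(pi_trt, 2, 0.8, "*"), 2, 0.2 * aes$pi_M, "+")
  expect_true(all(pij > 0 & pij < 1))
  ## P_S1 is the share of positive offsets (treatment scale equivalence)
  expect_equal(fit$table$P_S1, unname(colMeans(d > 0)))
  ## a zero offset leaves the treatment rate at the expected rate
  expect_equal(plogis(qlogis(aes$pi_M) + 0), aes$pi_M)
})

test_that("counts at expectation stay well below the flagging threshold", {
  aes <- hobit_aes(); des <- hobit_design()
  for (s in 1:3) {
    cnt <- blinded_counts(aes$name, round(53 * aes$pi_M), 53)
    fit <- blinded_safety(cnt, aes, design = des,
                          control = quick_ctl(1000, 300, seed = s))
    expect_true(all(fit$table$P_S1 < 0.85))
    expect_false(any(fit$table$flagged))
  }
})

test_that("a strongly elevated pooled count flags with near certainty", {
  aes <- hobit_aes(); des <- hobit_design()
  cnt <- blinded_counts(aes$name, c(9, round(53 * aes$pi_M[-1])), 53)
  fit <- blinded_safety(cnt, aes, design = des,
                        control = quick_ctl(1500, 400, seed = 4))
  expect_gt(fit$table$P_S1[1], 0.9)  # 9/53 = 17% observed vs 2% expected
  expect_true(fit$table$flagged[1])
})

test_that("the single-event hierarchical fit approaches the conjugate answer", {
  ## with one event and a vague hyperprior there is nothing to shrink toward
  aes1 <- ae_spec("only", 0.10)
  des <- hobit_design()
  cnt <- blinded_counts("only", 10, 53)
  hp <- blinded_hyperparams(mu_d0 = 0, sigma_d0 = 10, U_a = 0, U_b = 3)
  fit <- blinded_safety(cnt, aes1, design = des, hp = hp,
                        control = quick_ctl(4000, 800, seed = 6))
  ## control component is pinned at pi_M, so pi_trt > pi_M iff pi > pi_M
  p_exact <- beta_binomial_exceedance(10, 53, 0.10)
  expect_lt(abs(fit$table$P_S1 - p_exact), 0.05)
})

test_that("the bespoke sampler agrees with an independent Gibbs backend", {
  ## same hierarchical blinded posterior, fit by rjags as the oracle
  library(rjags)
  aes <- hobit_aes(); des <- hobit_design()
  Y <- c(5, 17, 24, 41, 42, 2, 8)
  fit <- blinded_safety(blinded_counts(aes$name, Y, 53), aes, design = des,
                        control = mcmc_control(draws = 20000, burn_in = 2000,
                                               seed = 2))
  spec_jags <- "model {
    for (j in 1:J) {
      d[j] ~ dnorm(mu_d, tau_d)
      pij[j] <- 0.2 * piM[j] + 0.8 * ilogit(lpi[j] + d[j])
      Y[j] ~ dbin(pij[j], N)
    }
    mu_d ~ dnorm(0, 0.25)
    sigma_d ~ dunif(0, 3)
    tau_d <- 1 / (sigma_d * sigma_d)
  }"
  jm <- jags.model(textConnection(spec_jags),
                   data = list(J = 7, Y = Y, N = 53, piM = aes$pi_M,
                               lpi = qlogis(aes$pi_M)),
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 8),
                   n.chains = 1, quiet = TRUE)
  update(jm, 4000)
  m <- as.matrix(coda.samples(jm, c("d", "mu_d", "sigma_d"),
                              n.iter = 50000))
  expect_equal(fit$table$P_S1, unname(colMeans(m[, 1:7] > 0)),
               tolerance = 0.02)
  expect_equal(unname(colMeans(fit$draws$draws[, 1:7])),
               unname(colMeans(m[, 1:7])), tolerance = 0.03)
  ## the scale mixes slowest in both samplers; agreement is looser
  expect_equal(mean(fit$draws$draws[, "sigma_d"]),
               mean(m[, "sigma_d"]), tolerance = 0.15)
})
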