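test_that("the logistic dose-response rate behaves as a rate should", {
  expect_equal(dose_response_rate(qlogis(0.4), 0, 7.3), 0.4)
  expect_equal(dose_response_rate(-1.2, 3, 0), plogis(-1.2))
  expect_equal(dose_response_rate(-2, 10, 0.0952), 0.2596, tolerance = 5e-4)
  x <- seq(0, 10, by = 0.5)
  r <- dose_response_rate(-3, 0.4, x)
  expect_true(all(r > 0 & r < 1))
  expect_true(all(diff(r) > 0))          # monotone when beta1 > 0
  expect_true(all(diff(dose_response_rate(-3, -0.4, x)) < 0))
})

test_that("active arms collapse onto a 0/1 covariate", {
  des <- hobit_design(); aes <- hobit_aes()
  rates <- matrix(aes$pi_M, nrow = 7, ncol = 8)
  cnt <- hobit_unblinded_at(rates, seed = 1)
  cc <- two_arm_collapse(cnt, des)
  expect_equal(sort(unique(cc$arm)), c("active", "control"))
  one <- cc[cc$ae == aes$name[1], ]
  expect_equal(one$n[one$arm == "control"], 11L)
  expect_equal(one$n[one$arm == "active"], 42L)
  expect_equal(sort(unique(cc$dose)), c(0, 1))
  ## totals are preserved
  expect_equal(sum(cc$y), sum(cnt$y))
  ## event order preserved; idempotent apart from recoding
  expect_equal(unique(cc$ae), unique(cnt$ae))
  cc2 <- two_arm_collapse(cc)
  expect_equal(cc2$y, cc$y)
  expect_equal(cc2$n, cc$n)
  single <- cnt[cnt$arm == des$label[1], ]
  class(single) <- class(cnt)
  expect_error(two_arm_collapse(single), "two arms")
})

test_that("with no data the slope probability sits at its prior half", {
  aes1 <- ae_spec("only", 0.25)
  des <- hobit_design()
  cnt <- unblinded_counts(rep("only", 8), des$label, des$dose,
                          rep(0L, 8), rep(0L, 8))   # n = 0: flat likelihood
  fit <- unblinded_safety(cnt, aes1, control = quick_ctl(4000, 500, seed = 2))
  expect_lt(abs(fit$table$P_S2 - 0.5), 0.1)
})

test_that("a strong synthetic dose effect is confirmed with near certainty", {
  aes1 <- ae_spec("only", 0.02)
  des <- hobit_design()
  rising <- matrix(seq(0.02, 0.30, length.out = 8), nrow = 1)
  cnt <- hobit_unblinded_at(rising, aes = aes1, seed = 3, n_mult = 20)
  fit <- unblinded_safety(cnt, aes1, control = quick_ctl(2000, 500, seed = 3))
  expect_gt(fit$table$P_S2, 0.99)
  expect_true(fit$table$confirmed)
})

test_that("flat elevated rates are rarely confirmed", {
  aes1 <- ae_spec("only", 0.40)
  des <- hobit_design()
  cnt <- unblinded_counts(rep("only", 8), des$label, des$dose, des$n,
                          round(des$n * 0.49))
  fit <- unblinded_safety(cnt, aes1, control = quick_ctl(2000, 500, seed = 4))
  expect_lt(fit$table$P_S2, 0.9)
})

test_that("the hierarchy is exchangeable under relabeling of events", {
  aes <- hobit_aes()[c(2, 3, 7), ]
  class(aes) <- c("ae_spec", "data.frame")
  spec <- scenario_spec("custom", aes = aes, pi0 = c(0.35, 0.50, 0.20),
                        pattern = "increasing_in_dose")
  cnt <- hobit_unblinded_at(arm_rates(spec, aes, hobit_design())[, ],
                            aes = aes, seed = 5)
  fit1 <- unblinded_safety(cnt, aes, control = quick_ctl(3000, 500, seed = 6))
  perm <- c(3, 1, 2)
  cnt2 <- cnt[order(match(cnt$ae, aes$name[perm]),
                    match(cnt$arm, hobit_design()$label)), ]
  class(cnt2) <- class(cnt)
  aes2 <- aes[perm, ]; class(aes2) <- c("ae_spec", "data.frame")
  fit2 <- unblinded_safety(cnt2, aes2, control = quick_ctl(3000, 500, seed = 6))
  m <- match(fit1$table$ae, fit2$table$ae)
  expect_equal(fit1$table$P_S2, fit2$table$P_S2[m], tolerance = 0.05)
  expect_equal(fit1$table$beta1_mean, fit2$table$beta1_mean[m],
               tolerance = 0.05)
})

test_that("known slopes are recovered inside the credible interval", {
  des <- hobit_design()
  aes1 <- ae_spec("only", 0.10)
  b0_true <- qlogis(0.10); b1_true <- 0.25
  covered <- 0; reps <- 20
  for (r in seq_len(reps)) {
    rates <- matrix(dose_response_rate(b0_true, b1_true, des$dose), nrow = 1)
    cnt <- hobit_unblinded_at(rates, aes = aes1, seed = 100 + r, n_mult = 50)
    fit <- unblinded_safety(cnt, aes1,
                            control = quick_ctl(800, 300, seed = r))
    ok <- fit$table$beta1_lo <= b1_true & b1_true <= fit$table$beta1_hi
    covered <- covered + ok
  }
  expect_gte(covered / reps, 0.8)
})

test_that("separate fits carry their own hyperparameter draws", {
  aes <- hobit_aes()[1:2, ]; class(aes) <- c("ae_spec", "data.frame")
  rates <- matrix(c(0.05, 0.30), 2, 8)
  cnt <- hobit_unblinded_at(rates, aes = aes, seed = 9)
  fit <- unblinded_safety(cnt, aes, joint = FALSE,
                          control = quick_ctl(seed = 10))
  expect_false(fit$joint)
  expect_length(fit$draws, 2L)
  expect_equal(nrow(fit$table), 2L)
  expect_s3_class(fit$draws[[1]], "mcmc_draws")
})

test_that("posterior predictions and residuals are well-formed", {
  aes1 <- ae_spec("only", 0.10)
  des <- hobit_design()
  rates <- matrix(dose_response_rate(qlogis(0.1), 0.2, des$dose), nrow = 1)
  cnt <- hobit_unblinded_at(rates, aes = aes1, seed = 12, n_mult = 5)
  fit <- unblinded_safety(cnt, aes1, control = quick_ctl(seed = 13))
  pr <- predict(fit, data.frame(dose = c(0, 5, 10)))
  expect_equal(nrow(pr), 3L)
  expect_true(all(pr$rate > 0 & pr$rate < 1))
  expect_true(all(pr$lo <= pr$rate & pr$rate <= pr$hi))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3L)
  expect_true(all(sims[[1]] >= 0) && all(sims[[1]] <= des$n * 5))
  res <- residuals(fit)
  expect_equal(dim(res), c(1L, 8L))
  expect_true(all(is.finite(res)))
})
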