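test_that("scenario patterns expand to the intended true rates", {
  aes <- hobit_aes(); des <- hobit_design()
  ## no effect: every arm at the expected rate
  rI <- arm_rates(scenario_spec("I"), aes, des)
  expect_equal(unname(rI), matrix(aes$pi_M, 7, 8), ignore_attr = TRUE)
  ## increasing effect: control pinned, pooled rate hits the target
  sII <- scenario_spec("II")
  rII <- arm_rates(sII, aes, des)
  pooled <- as.vector(rII %*% des$n / attr(des, "N"))
  expect_equal(pooled[3], 0.48, tolerance = 1e-8)   # Pneumonia
  expect_equal(pooled[-6], sII$pi0[-6], tolerance = 1e-8)
  expect_equal(rII[, 1], aes$pi_M, ignore_attr = TRUE)
  expect_true(all(apply(rII, 1, function(r) all(diff(r) >= 0))))
  ## the rounding-degenerate event still gets the scenario's common effect
  expect_gt(attr(rII, "slope")[6], 0)
  expect_gt(rII[6, 8], aes$pi_M[6])
  ## flat elevated: control equals treatment, above expectation
  sV <- scenario_spec("V")
  rV <- arm_rates(sV, aes, des)
  expect_true(all(rV == matrix(sV$pi0, 7, 8)))
  ## control matches treatment and sits at or above expectation (the
  ## seizures row prints at its whole-percent expected rate)
  expect_true(all(rV[, 1] >= aes$pi_M))
  expect_gte(sum(rV[, 1] > aes$pi_M), 6L)
  ## scenario III elevates only the first three; IV flattens the
  ## active-vs-control events
  rIII <- arm_rates(scenario_spec("III"), aes, des)
  expect_true(all(rIII[4:7, ] == matrix(aes$pi_M[4:7], 4, 8)))
  expect_true(all(rIII[1:3, 8] > aes$pi_M[1:3]))
  sIV <- scenario_spec("IV")
  expect_equal(sIV$pattern[aes$flat_dose_effect], rep("flat_elevated", 3))
  expect_equal(sIV$pattern[!aes$flat_dose_effect],
               rep("increasing_in_dose", 4))
})

test_that("slope calibration is exact, bounded and fails loudly", {
  des <- hobit_design()
  b <- calibrate_slope(0.48, 0.40, des)
  r <- plogis(qlogis(0.40) + b * des$dose); r[1] <- 0.40
  expect_equal(sum(des$n * r) / 53, 0.48, tolerance = 1e-8)
  expect_equal(calibrate_slope(0.05, 0.10, des), 0)
  expect_error(calibrate_slope(0.95, 0.01, des), "not attainable")
})

test_that("simulated trials honour degenerate rates and the row-sum identity", {
  aes <- hobit_aes(); des <- hobit_design()
  zero <- matrix(0, 7, 8)
  sim0 <- simulate_trial(zero, aes, des, seed = 1)
  expect_true(all(sim0$blinded$y == 0))
  one <- matrix(1, 7, 8)
  sim1 <- simulate_trial(one, aes, des, seed = 1)
  expect_true(all(sim1$blinded$y == 53))
  simR <- simulate_trial(arm_rates(scenario_spec("II"), aes, des),
                         aes, des, seed = 2)
  expect_equal(simR$blinded$y, unname(rowSums(simR$Y)))
  simR2 <- simulate_trial(arm_rates(scenario_spec("II"), aes, des),
                          aes, des, seed = 2)
  expect_identical(simR$Y, simR2$Y)
})

test_that("pooled simulation means match the binomial mean", {
  aes <- hobit_aes(); des <- hobit_design()
  set.seed(3)
  reps <- 4000
  y <- matrix(rbinom(reps * 7, 53, rep(aes$pi_M, each = reps)), reps, 7)
  mean_rate <- colMeans(y) / 53
  se <- sqrt(aes$pi_M * (1 - aes$pi_M) / (53 * reps))
  expect_true(all(abs(mean_rate - aes$pi_M) < 3 * se))
})

test_that("the family-wise rate is the share of rows with any flag", {
  expect_equal(fwer(matrix(FALSE, 10, 3)), 0)
  expect_equal(fwer(matrix(TRUE, 10, 3)), 1)
  expect_error(fwer(matrix(logical(0), 0, 0)), "empty")
  set.seed(4)
  p <- c(0.29, 0.09, 0.12, 0.06, 0.06, 0.10, 0.16)
  reps <- 20000
  flags <- matrix(rbinom(reps * 7, 1, rep(p, each = reps)) == 1, reps, 7)
  closed <- 1 - prod(1 - p)
  expect_lt(abs(fwer(flags) - closed), 3 * sqrt(closed * (1 - closed) / reps))
})

test_that("operating characteristics are consistent and reproducible", {
  aes <- hobit_aes(); des <- hobit_design()
  oc <- run_oc(scenario_spec("V"), replicates = 12, seed = 5,
               P_crit2 = c(0.7, 0.8, 0.9),
               control = mcmc_control(draws = 400, burn_in = 200))
  per <- oc$per_ae
  ## overall is the product of the stage proportions wherever defined
  ok <- !is.na(per$unblinded)
  expect_equal(per$overall[ok], per$blinded[ok] * per$unblinded[ok])
  expect_true(all(per$overall[!ok] == 0))
  ## confirmations can only shrink as the stage-2 bar rises
  fw <- oc$familywise[order(oc$familywise$P_crit2), ]
  expect_true(all(diff(fw$fw_confirmed) <= 0))
  ov <- matrix(per$overall[order(per$P_crit2, per$ae)], ncol = 3)
  expect_true(all(apply(ov, 1, function(z) all(diff(z) <= 0))))
  ## every reported number is reproducible from the stored decision log
  re <- oc_aggregate(oc$log, P_crit1 = 0.9, P_crit2 = c(0.7, 0.8, 0.9))
  expect_equal(re$per_ae$overall, per$overall)
  expect_equal(re$familywise$fw_confirmed, oc$familywise$fw_confirmed)
  ## and the whole run is reproducible from the seed
  oc2 <- run_oc(scenario_spec("V"), replicates = 12, seed = 5,
                P_crit2 = c(0.7, 0.8, 0.9),
                control = mcmc_control(draws = 400, burn_in = 200))
  expect_identical(oc$log, oc2$log)
})

test_that("the flat-effect events can be routed through the two-arm collapse", {
  aes <- hobit_aes(); des <- hobit_design()
  oc <- run_oc(scenario_spec("IV"), replicates = 6, seed = 6,
               control = mcmc_control(draws = 400, burn_in = 200),
               flat_collapse = TRUE)
  expect_s3_class(oc, "oc_result")
  expect_equal(nrow(oc$per_ae), 7L)
  expect_true(all(oc$per_ae$overall >= 0 & oc$per_ae$overall <= 1))
})
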