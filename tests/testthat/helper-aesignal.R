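## shared fixtures: everything is generated in code at test time

quick_ctl <- function(draws = 400, burn_in = 200, seed = 1)
  mcmc_control(draws = draws, burn_in = burn_in, seed = seed)

hobit_blinded_at <- function(rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aes <- hobit_aes()
  blinded_counts(aes$name, rbinom(nrow(aes), 53, rates), 53)
}

## per-arm counts table for a subset of AEs at given true per-arm rates
hobit_unblinded_at <- function(rate_mat, aes = hobit_aes(),
                               design = hobit_design(), seed = NULL,
                               n_mult = 1) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n * n_mult
  J <- nrow(rate_mat); I <- nrow(design)
  y <- matrix(rbinom(J * I, rep(n, each = J), rate_mat), J, I)
  unblinded_counts(ae = rep(aes$name[seq_len(J)], times = I),
                   arm = rep(design$label, each = J),
                   dose = rep(design$dose, each = J),
                   n = rep(n, each = J), y = as.vector(y))
}
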