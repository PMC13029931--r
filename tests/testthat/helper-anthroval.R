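# Brute-force ICC(A,1) oracle built directly from the two-way ANOVA
# sum-of-squares definitions (explicit loops, no mean-square shortcuts)
# so it stays independent of the implementation it checks.
icc_oracle <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) ss_total <- ss_total + (m[i, j] - grand)^2
  }
  ss_rows <- 0
  for (i in seq_len(n)) {
    ss_rows <- ss_rows + k * (sum(m[i, ]) / k - grand)^2
  }
  ss_cols <- 0
  for (j in seq_len(k)) {
    ss_cols <- ss_cols + n * (sum(m[, j]) / n - grand)^2
  }
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# a small valid cohort row set with all ten sites present
make_site_args <- function(value = 10) {
  sites <- skinfold_sites()
  stats::setNames(as.list(rep(value, length(sites))), sites)
}

noise_free_params <- function(n = 20, seed = 11,
                              reference_equation = "oliver") {
  cohort_params(n = n, seed = seed, dxa_fm_bias = 0,
                dxa_fm_noise_sd = 0, dxa_heteroscedasticity = 0,
                replicate_cv = 0,
                reference_equation = reference_equation)
}
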