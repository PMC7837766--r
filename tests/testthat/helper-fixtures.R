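# shared fixtures: random valid DVHs, tiny cohorts and fast model settings

random_dvh <- function(max_dose_gy = 70) {
  dvh(sort(runif(100, 0, max_dose_gy), decreasing = TRUE))
}

linear_dvh <- function(top = 60) dvh(seq(top, 0, length.out = 100))

# small single-organ cohort spec for fast tests
tiny_profiles <- function(eta = 0) {
  list(test_oar = list(M = 40, w = rep(c(1, 0.6, 0.8), 3),
                       gamma = seq(0.8, 2.4, length.out = 9),
                       c = rep(1 / 9, 9), eta = eta))
}

tiny_cohort <- function(n = 10, seed = 7, eta = 0) {
  generate_cohort(cohort_spec(n_patients = n, seed = seed,
                              oar_profiles = tiny_profiles(eta),
                              train_fraction = 0.6))
}

tiny_oar <- function(loss_k = 2) {
  oar_config("test_oar", loss_k = loss_k, eud_a = 8, serial = TRUE,
             dose_cap = 70)
}

fast_spec <- function(hidden = 8, layers = 1, seed = 1, dropout = 0.5) {
  model_spec(hidden_size = hidden, num_layers = layers, dropout_p = dropout,
             seed = seed)
}

fast_cfg <- function(epochs = 40, seed = 2, k = NULL) {
  train_config(epochs = epochs, seed = seed, k = k)
}

# independent brute-force Wilcoxon signed-rank oracle: enumerate all sign
# assignments of the nonzero paired differences
brute_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.vector(signs %*% r)
  min(1, 2 * min(mean(stats >= v_obs), mean(stats <= v_obs)))
}
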