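# Independent brute-force oracles and small fixture builders shared across
# test files. The ICC oracle computes the defining sums of squares with
# explicit loops and applies the published absolute-agreement formulas; it
# shares no code with the package implementation.

oracle_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  msr <- 0
  for (i in seq_len(n)) msr <- msr + k * (sum(m[i, ]) / k - grand)^2
  msc <- 0
  for (j in seq_len(k)) msc <- msc + n * (sum(m[, j]) / n - grand)^2
  mse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      mse <- mse + (m[i, j] - sum(m[i, ]) / k - sum(m[, j]) / n + grand)^2
    }
  }
  list(msr = msr / (n - 1), msc = msc / (k - 1),
       mse = mse / ((n - 1) * (k - 1)), n = n, k = k)
}

oracle_icc21 <- function(m) {
  o <- oracle_mean_squares(m)
  (o$msr - o$mse) /
    (o$msr + (o$k - 1) * o$mse + o$k * (o$msc - o$mse) / o$n)
}

oracle_icc2k <- function(m) {
  o <- oracle_mean_squares(m)
  (o$msr - o$mse) / (o$msr + (o$msc - o$mse) / o$n)
}

# A minimal procedure design table for hand-built configs.
tiny_procedures <- function(n_proc = 5, bias_etiv = 0, bias_sbtiv = 0,
                            noise_etiv = 1e-9, noise_sbtiv = 1e-9,
                            protocol = NULL) {
  data.frame(
    procedure_id = paste0("PR", seq_len(n_proc)),
    site = paste0("S", seq_len(n_proc)),
    machine = paste0("M", seq_len(n_proc)),
    vendor = "V1",
    protocol = if (is.null(protocol))
      rep(c("HARP", "CRHD", "SRPB_iso", "SRPB_aniso"),
          length.out = n_proc) else rep(protocol, length.out = n_proc),
    weight = 1,
    bias_etiv = rep(bias_etiv, length.out = n_proc),
    bias_sbtiv = rep(bias_sbtiv, length.out = n_proc),
    noise_etiv = rep(noise_etiv, length.out = n_proc),
    noise_sbtiv = rep(noise_sbtiv, length.out = n_proc),
    ts_eligible = TRUE,
    stringsAsFactors = FALSE
  )
}

# A noiseless, bias-free, failure-free configuration.
quiet_config <- function(n_participants = 50, n_proc = 5, seed = 1, ...) {
  synthetic_config(
    n_participants = n_participants,
    procedures = tiny_procedures(n_proc),
    failure_prob = 0, seed = seed, ...)
}
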