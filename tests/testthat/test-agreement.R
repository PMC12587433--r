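test_that("deviation and absolute error are per-row identities", {
  tab <- simulate_cohort(synthetic_config(n_participants = 100, seed = 15))
  out <- compute_deviation(tab)
  expect_equal(out$deviation_mm3, tab$etiv_mm3 - tab$sbtiv_mm3)
  expect_equal(out$abs_error_mm3, abs(tab$etiv_mm3 - tab$sbtiv_mm3))

  same <- tab; same$etiv_mm3 <- same$sbtiv_mm3
  out2 <- compute_deviation(same)
  expect_true(all(out2$deviation_mm3 == 0))

  # published overall means reproduce the published mean deviation
  ref <- reference_summary_table()
  ov <- ref[ref$procedure_id == "Overall", ]
  expect_equal(ov$etiv_mean - ov$sbtiv_mean, ov$deviation_mean)
})

test_that("the small-eTIV split is an exhaustive, boundary-correct partition", {
  tab <- simulate_cohort(synthetic_config(n_participants = 800,
                                          failure_prob = 0.03, seed = 16))
  sp <- split_small_etiv(tab)
  expect_equal(nrow(sp$small) + nrow(sp$nonsmall), nrow(tab))
  expect_equal(nrow(sp$small), sum(tab$etiv_mm3 <= 1200000))
  expect_equal(intersect(sp$small$participant_id, sp$nonsmall$participant_id),
               character(0))

  edge <- tab[1:2, ]
  edge$etiv_mm3 <- c(1200000, 1200000.01)
  sp2 <- split_small_etiv(edge)
  expect_equal(nrow(sp2$small), 1L)  # "more than" defines non-small
  expect_equal(sp2$small$etiv_mm3, 1200000)
})

test_that("the procedure summary matches a hand-rolled group-by oracle", {
  cfg <- synthetic_config(n_participants = 150,
                          procedures = tiny_procedures(
                            3, noise_etiv = 50000, noise_sbtiv = 30000),
                          failure_prob = 0, seed = 17)
  tab <- simulate_cohort(cfg)
  out <- procedure_summary_table(tab)
  expect_identical(out$procedure_id[1], "Overall")
  expect_equal(sum(out$n[-1]), out$n[1])
  for (i in seq_len(nrow(out))) {
    d <- if (out$procedure_id[i] == "Overall") tab
         else tab[tab$procedure_id == out$procedure_id[i], ]
    expect_equal(out$n[i], nrow(d))
    expect_equal(out$mean_etiv[i], mean(d$etiv_mm3))
    expect_equal(out$sd_sbtiv[i], sd(d$sbtiv_mm3))
    expect_equal(out$mean_abs_error[i], mean(abs(d$etiv_mm3 - d$sbtiv_mm3)))
    expect_equal(out$icc_2_1[i],
                 oracle_icc21(cbind(d$etiv_mm3, d$sbtiv_mm3)),
                 tolerance = 1e-10)
    # linearity identity, exact before any rounding
    expect_equal(out$mean_deviation[i], out$mean_etiv[i] - out$mean_sbtiv[i],
                 tolerance = 1e-9)
  }
})

test_that("noise-free tables give perfect agreement rows", {
  tab <- simulate_cohort(quiet_config(n_participants = 90, seed = 18))
  out <- procedure_summary_table(tab)
  expect_true(all(abs(out$mean_deviation) < 1e-6))
  expect_true(all(out$icc_2_1[out$n >= 2] > 1 - 1e-9))
})

test_that("procedures with one scan report NA ICC instead of failing", {
  tab <- simulate_cohort(quiet_config(n_participants = 40, seed = 19))
  tab$procedure_id[1] <- "LONER"
  tab$protocol[1] <- "HARP"
  out <- procedure_summary_table(tab)
  expect_true(is.na(out$icc_2_1[out$procedure_id == "LONER"]))
})

test_that("the ICC factor model finds a protocol shift", {
  set.seed(20)
  rows <- data.frame(
    procedure_id = sprintf("P%02d", 1:24),
    protocol = rep(c("SRPB_iso", "HARP", "CRHD"), each = 8),
    machine = rep(paste0("M", 1:4), 6),
    stringsAsFactors = FALSE)
  rows$icc_2_1 <- 0.8 + 0.1 * (rows$protocol == "SRPB_iso") +
    rnorm(24, sd = 0.02)
  fit <- icc_factor_model(rows, reference_procedure = "P10")  # a HARP row
  co <- fit$coefficients
  hit <- co[co$term == "protocolSRPB_iso", ]
  expect_lt(abs(hit$B - 0.1), 2 * hit$SE)

  flat <- rows; flat$icc_2_1 <- 0.8
  co0 <- suppressWarnings(icc_factor_model(flat, "P10"))$coefficients
  expect_true(all(abs(co0$B[-1]) < 1e-10))

  single <- rows[rows$protocol == "HARP", ]
  expect_error(icc_factor_model(single, "P10"), "2 protocol levels")

  conf <- rows; conf$machine <- conf$protocol  # machine aliases protocol
  expect_error(icc_factor_model(conf, "P10"), "confounded")
})

test_that("the deviation mixed model recovers an injected protocol bias", {
  procs <- tiny_procedures(6, noise_etiv = 40000, noise_sbtiv = 30000,
                           protocol = c("HARP", "HARP", "SRPB_iso",
                                        "SRPB_iso", "SRPB_iso", "SRPB_iso"))
  procs$bias_etiv <- ifelse(procs$protocol == "HARP", 60000, 0)
  procs$machine <- "M1"
  cfg <- synthetic_config(n_participants = 500, procedures = procs,
                          failure_prob = 0, seed = 21)
  tab <- simulate_cohort(cfg)
  fit <- deviation_factor_model(tab, "deviation",
                                reference = list(protocol = "SRPB_iso"))
  row <- recover_effects(fit, "protocolHARP")
  expect_lt(abs(row$B - 60000), 2 * row$SE)
})

test_that("an all-zero absolute error is handled as a degenerate fit", {
  tab <- simulate_cohort(quiet_config(n_participants = 60, seed = 22))
  tab$etiv_mm3 <- tab$sbtiv_mm3
  fit <- deviation_factor_model(tab, "abs_error")
  expect_true(fit$degenerate)
  expect_true(all(fit$coefficients$B == 0))
  expect_true(all(fit$var_components == 0))
})

test_that("triple subsampling respects eligibility and the sampling law", {
  cfg <- quiet_config(n_participants = 10, n_proc = 6, seed = 23)
  ts <- simulate_traveling_subjects(cfg, 20, c(2, 6))
  counts <- table(ts$participant_id)
  m <- subsample_triples(ts, "etiv", seed = 1)
  expect_equal(nrow(m), sum(counts >= 3))
  expect_equal(ncol(m), 3L)

  # participants with exactly 3 scans always contribute their full set
  exact3 <- names(counts)[counts == 3]
  if (length(exact3) > 0) {
    pid <- exact3[1]
    full <- sort(ts$etiv_mm3[ts$participant_id == pid])
    for (s in 1:5) {
      ms <- subsample_triples(ts, "etiv", seed = s)
      expect_equal(sort(unname(ms[pid, ])), full)
    }
  }

  few <- ts[ts$participant_id %in% names(counts)[counts < 3], ]
  expect_error(subsample_triples(few, "etiv"), "3 or more")
})

test_that("each of five scans enters a triple with frequency 3/5", {
  cfg <- quiet_config(n_participants = 10, n_proc = 6, seed = 24)
  ts <- simulate_traveling_subjects(cfg, 2, c(5, 5))
  ts$etiv_mm3 <- as.numeric(seq_len(nrow(ts)))  # tag scans by value
  first <- ts$participant_id == sort(unique(ts$participant_id))[1]
  tags <- ts$etiv_mm3[first]
  hits <- numeric(5)
  n_draws <- 600
  set.seed(99)
  for (r in seq_len(n_draws)) {
    m <- subsample_triples(ts, "etiv")
    got <- match(m[1, ], tags)
    hits[got] <- hits[got] + 1
  }
  freq <- hits / n_draws
  # each frequency ~ Binomial(600, 0.6)/600: SE ~ 0.02
  expect_true(all(abs(freq - 0.6) < 0.08))
})

test_that("resampled ICC(2,k) is seed-deterministic and matches theory", {
  cfg <- synthetic_config(n_participants = 10,
                          procedures = tiny_procedures(
                            8, noise_etiv = 80000, noise_sbtiv = 80000),
                          sigma_subject = 160000, beta_sex = 0,
                          beta_height = 0, failure_prob = 0, seed = 25)
  ts <- simulate_traveling_subjects(cfg, 120, c(3, 8))
  r1 <- resampled_icc2k(ts, "etiv", n_reps = 200, seed = 7)
  r2 <- resampled_icc2k(ts, "etiv", n_reps = 200, seed = 7)
  expect_identical(r1$per_replicate_icc, r2$per_replicate_icc)
  expect_equal(r1$mean_icc, mean(r1$per_replicate_icc))
  expect_equal(r1$sd_icc, sd(r1$per_replicate_icc))
  # no bias, no column structure: ICC(2,3) = s^2 / (s^2 + e^2/3)
  pop <- 160000^2 / (160000^2 + 80000^2 / 3)
  expect_lt(abs(r1$mean_icc - pop), 0.03)
})

test_that("replicate spread collapses when every traveler has exactly 3 scans", {
  cfg <- quiet_config(n_participants = 10, n_proc = 5, seed = 26)
  ts <- simulate_traveling_subjects(cfg, 15, c(3, 3))
  set.seed(260)
  ts$etiv_mm3 <- ts$etiv_mm3 + rnorm(nrow(ts), 0, 20000)  # avoid degeneracy
  # the sampled triples are pinned; only the random column assignment can
  # move the estimate, and ICC(2,k) treats columns as exchangeable
  r <- resampled_icc2k(ts, "etiv", n_reps = 50, seed = 8)
  expect_lt(r$sd_icc, 0.01)
  varied <- simulate_traveling_subjects(cfg, 15, c(3, 5), seed = 27)
  set.seed(261)
  varied$etiv_mm3 <- varied$etiv_mm3 + rnorm(nrow(varied), 0, 20000)
  rv <- resampled_icc2k(varied, "etiv", n_reps = 50, seed = 8)
  expect_lt(r$sd_icc, rv$sd_icc)
})

test_that("body-size correlations match the covariance formula", {
  tab <- simulate_cohort(synthetic_config(n_participants = 300, seed = 27))
  out <- covariate_correlations(tab)
  expect_equal(nrow(out), 6L)
  direct <- cor(tab$sbtiv_mm3, tab$body_height_cm)
  got <- out[out$method == "sbtiv" & out$covariate == "body_height_cm", ]
  expect_equal(got$r, direct, tolerance = 1e-12)
  expect_gt(got$r, 0.2)  # beta_height > 0 by construction

  exact <- tab
  exact$etiv_mm3 <- 2 * exact$body_height_cm * 1000
  out2 <- covariate_correlations(exact, "body_height_cm")
  expect_equal(out2$r[out2$method == "etiv"], 1, tolerance = 1e-12)

  const <- tab; const$body_height_cm <- 170
  expect_error(covariate_correlations(const), "constant")
})

test_that("the elderly model recovers the height slope at its true scale", {
  cfg <- synthetic_config(n_participants = 2000, beta_height = 11000,
                          failure_prob = 0, seed = 28)
  tab <- simulate_cohort(cfg)
  fit <- elderly_model(tab, min_age = 60)
  expect_gt(fit$n, 100)
  hb <- fit$sbtiv[fit$sbtiv$term == "body_height_cm", ]
  expect_lt(abs(hb$B - 11000), 2 * hb$SE)
})
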