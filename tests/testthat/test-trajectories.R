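test_that("stacking doubles rows and keeps eTIV as the reference method", {
  tab <- simulate_cohort(synthetic_config(n_participants = 50, seed = 31))
  long <- stack_methods(tab)
  expect_equal(nrow(long), 2L * nrow(tab))
  expect_identical(levels(long$method), c("etiv", "sbtiv"))
  expect_equal(long$value_mm3[long$method == "etiv"], tab$etiv_mm3)
  expect_equal(long$value_mm3[long$method == "sbtiv"], tab$sbtiv_mm3)
})

test_that("duplicated methods zero out all method terms", {
  cfg <- synthetic_config(n_participants = 10,
                          procedures = tiny_procedures(
                            3, noise_etiv = 30000, noise_sbtiv = 30000),
                          failure_prob = 0, seed = 32)
  ado <- simulate_longitudinal(cfg, "adolescent", n_participants = 60)
  ado$sbtiv_mm3 <- ado$etiv_mm3
  fit <- fit_longitudinal_model(ado, "adolescent")
  co <- fit$coefficients
  method_terms <- grepl("method", co$term)
  expect_true(any(method_terms))
  expect_lt(max(abs(co$B[method_terms])), 1e-6)
})

test_that("adolescent growth and its sex difference are recovered", {
  cfg <- synthetic_config(n_participants = 10,
                          procedures = tiny_procedures(
                            4, noise_etiv = 30000, noise_sbtiv = 30000),
                          failure_prob = 0, seed = 33)
  ado <- simulate_longitudinal(cfg, "adolescent", n_participants = 200,
                               scans_per_participant = c(2, 4))
  fit <- fit_longitudinal_model(ado, "adolescent")
  # female - male growth difference: 8000 - 20000 = -12000 mm^3/y
  row <- recover_effects(fit, "time_years:sex_female")
  expect_lt(abs(row$B - (-12000)), 2 * row$SE)
  male_slope <- recover_effects(fit, "time_years")
  expect_lt(abs(male_slope$B - 20000), 2 * male_slope$SE)
})

test_that("the eTIV failure mode inflates the adult gap effect", {
  cfg <- synthetic_config(n_participants = 10,
                          procedures = tiny_procedures(
                            4, noise_etiv = 30000, noise_sbtiv = 30000),
                          failure_prob = 0.08, seed = 34)
  adu <- simulate_longitudinal(cfg, "adult", n_participants = 150)
  per_method_gap <- function(tab, col) {
    first_age <- tapply(tab$age_at_scan, tab$participant_id, min)
    tab$gap <- tab$age_at_scan - first_age[as.character(tab$participant_id)]
    tab$y <- tab[[col]]
    f <- fit_lmm(tab, model_spec("y", "gap", "participant_id"))
    recover_effects(f, "gap")$B
  }
  # single-draw smoke of the machinery; the 100-simulation directional
  # property runs in the acceptance suite
  g_e <- per_method_gap(adu, "etiv_mm3")
  g_s <- per_method_gap(adu, "sbtiv_mm3")
  expect_true(is.finite(g_e) && is.finite(g_s))

  fit <- fit_longitudinal_model(adu, "adult")
  expect_true(all(is.finite(fit$coefficients$B)))
  expect_error(fit_longitudinal_model(adu[!duplicated(adu$participant_id), ],
                                      "adult"),
               "repeated measures")
})

test_that("paired preprocessing comparison recovers an injected shift", {
  set.seed(35)
  n <- 60
  base_e <- rnorm(n, 1.58e6, 1.5e5)
  base_s <- base_e + rnorm(n, 0, 3e4)
  paired <- data.frame(
    participant_id = rep(sprintf("P%03d", 1:n), 2),
    preprocessing = rep(c("hcp", "legacy"), each = n),
    etiv_mm3 = c(base_e, base_e - 38000 + rnorm(n, 0, 2e4)),
    sbtiv_mm3 = c(base_s, base_s + rnorm(n, 0, 2e4)),
    stringsAsFactors = FALSE)
  fit <- paired_method_comparison(paired, "value")
  row <- recover_effects(fit, "preprocessinglegacy:methodsbtiv")
  expect_lt(abs(row$B - 38000), 2 * row$SE)

  dev_fit <- paired_method_comparison(paired, "deviation")
  drow <- recover_effects(dev_fit, "preprocessinglegacy")
  expect_lt(abs(drow$B - (-38000)), 2 * drow$SE)

  same <- paired
  same$etiv_mm3 <- rep(base_e, 2); same$sbtiv_mm3 <- rep(base_s, 2)
  fit0 <- paired_method_comparison(same, "value")
  inter <- recover_effects(fit0, "preprocessinglegacy:methodsbtiv")
  expect_lt(abs(inter$B), 1e-6)

  broken <- paired[-(n + 1), ]
  expect_error(paired_method_comparison(broken, "value"),
               "unpaired.*P001")
})

test_that("a flat lifespan yields a flat fitted curve", {
  cfg <- synthetic_config(n_participants = 800,
                          procedures = tiny_procedures(
                            4, noise_etiv = 40000, noise_sbtiv = 40000),
                          beta_sex = 0, failure_prob = 0, seed = 36)
  tab <- simulate_cohort(cfg)  # no age dependence in the generator
  st <- fit_smooth_trajectory(tab, "sbtiv")
  for (sx in c("female", "male")) {
    g <- st$grid[st$grid$sex == sx, ]
    inner <- g[g$age > quantile(tab$age_at_scan, 0.05) &
                 g$age < quantile(tab$age_at_scan, 0.95), ]
    expect_lt(diff(range(inner$fitted)), 4 * max(inner$se))
  }
})

test_that("a quadratic age trend is tracked on the interior grid", {
  set.seed(37)
  n <- 2000
  age <- runif(n, 20, 70)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  truth <- 1.58e6 + 60 * (age - 45)^2
  tab <- data.frame(
    participant_id = sprintf("Q%04d", 1:n), procedure_id = "A",
    protocol = "HARP", age_at_scan = age, sex = sex, scan_order = 1L,
    etiv_mm3 = truth, sbtiv_mm3 = truth + rnorm(n, 0, 30000),
    stringsAsFactors = FALSE)
  st <- fit_smooth_trajectory(tab, "sbtiv")
  inner <- st$grid[st$grid$age > quantile(age, 0.1) &
                     st$grid$age < quantile(age, 0.9), ]
  expected <- 1.58e6 + 60 * (inner$age - 45)^2
  expect_lt(max(abs(inner$fitted - expected)), 5 * max(inner$se) + 5000)

  young <- tab[tab$age_at_scan < 28, ]
  expect_error(fit_smooth_trajectory(young, "sbtiv"), "age range")
})

test_that("sex-identical generators give curves within each other's bands", {
  ok <- 0
  for (s in 1:20) {
    cfg <- synthetic_config(n_participants = 400,
                            procedures = tiny_procedures(
                              3, noise_etiv = 40000, noise_sbtiv = 40000),
                            beta_sex = 0, failure_prob = 0, seed = 400 + s)
    tab <- simulate_cohort(cfg)
    st <- fit_smooth_trajectory(tab, "sbtiv", n_knots = 4)
    f <- st$grid[st$grid$sex == "female", ]
    m <- st$grid[st$grid$sex == "male", ]
    gap <- abs(f$fitted - m$fitted)
    # simultaneous (sup-norm) check over the grid: Bonferroni at the
    # effective dimension of the basis (~8 coefficients per sex) puts the
    # per-point critical value near 3 SE
    band <- 3 * sqrt(f$se^2 + m$se^2)
    inner <- f$age > quantile(tab$age_at_scan, 0.05) &
      f$age < quantile(tab$age_at_scan, 0.95)
    if (all(gap[inner] < band[inner])) ok <- ok + 1
  }
  expect_gte(ok, 17)
})

test_that("participant relabeling does not move the estimates", {
  cfg <- synthetic_config(n_participants = 10,
                          procedures = tiny_procedures(
                            3, noise_etiv = 30000, noise_sbtiv = 30000),
                          failure_prob = 0, seed = 38)
  ado <- simulate_longitudinal(cfg, "adolescent", n_participants = 80)
  fit1 <- fit_longitudinal_model(ado, "adolescent")
  relab <- ado
  key <- setNames(sprintf("ZZ%04d", seq_along(unique(ado$participant_id))),
                  unique(ado$participant_id))
  relab$participant_id <- unname(key[ado$participant_id])
  fit2 <- fit_longitudinal_model(relab, "adolescent")
  expect_equal(fit1$coefficients$B, fit2$coefficients$B, tolerance = 1e-8)
  expect_equal(fit1$var_components, fit2$var_components, tolerance = 1e-6)
})
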