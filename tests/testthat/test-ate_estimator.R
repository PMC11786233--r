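# The weighted estimator against a brute-force oracle, trimming contracts,
# bootstrap behavior and negative-control diagnostics.

# Independent oracle: the same estimand computed with explicit loops over
# episodes, never sharing code with ate_estimate().
ipw_oracle <- function(y, t, d, e, pi, form) {
  n <- length(y)
  s1 <- s0 <- w1 <- w0 <- 0
  for (i in seq_len(n)) {
    if (d[i] == 1L && t[i] == 1L) {
      s1 <- s1 + y[i] / (e[i] * pi[i])
      w1 <- w1 + 1 / (e[i] * pi[i])
    }
    if (d[i] == 1L && t[i] == 0L) {
      s0 <- s0 + y[i] / ((1 - e[i]) * pi[i])
      w0 <- w0 + 1 / ((1 - e[i]) * pi[i])
    }
  }
  if (form == "horvitz_thompson") s1 / n - s0 / n else s1 / w1 - s0 / w0
}

test_that("hand-computed estimator examples are reproduced", {
  # uniform weights reduce to a difference of arm means
  est_ht <- ate_estimate(c(1, 0, 1, 1), c(1, 1, 0, 0), rep(1L, 4),
                         rep(0.5, 4), 1, form = "horvitz_thompson")
  est_h <- ate_estimate(c(1, 0, 1, 1), c(1, 1, 0, 0), rep(1L, 4),
                        rep(0.5, 4), 1, form = "hajek")
  expect_identical(est_ht, -0.5)
  expect_identical(est_h, -0.5)

  # symmetric two-episode case
  expect_identical(
    ate_estimate(c(1, 1), c(1, 0), c(1L, 1L), rep(0.5, 2), 1), 0)

  # unequal propensities, Hajek weighted mean: (1.25*1 + 2.5*0)/3.75 = 1/3
  y <- c(1, 0, 0, 0); t <- c(1, 1, 0, 0); e <- c(0.8, 0.4, 0.5, 0.2)
  expect_equal(ate_estimate(y, t, rep(1L, 4), e, 1, form = "hajek"), 1 / 3)
  expect_equal(ate_estimate(y, t, rep(1L, 4), e, 1, form = "hajek"),
               ipw_oracle(y, t, rep(1L, 4), e, rep(1, 4), "hajek"))
})

test_that("censored episodes contribute zero weight, not zero outcome", {
  y <- c(1, NA, 1, 0); t <- c(1, 1, 0, 0); d <- c(1L, 0L, 1L, 1L)
  e <- rep(0.5, 4); pi <- c(0.8, 0.8, 0.9, 0.6)
  for (form in c("hajek", "horvitz_thompson")) {
    expect_equal(ate_estimate(y, t, d, e, pi, form),
                 ipw_oracle(y, t, d, e, pi, form), label = form)
  }
  expect_error(ate_estimate(c(NA, 1), c(1, 0), c(1L, 1L), rep(0.5, 2), 1),
               "present")
  expect_error(ate_estimate(c(1, 1), c(1, 1), c(1L, 1L), rep(0.5, 2), 1),
               "zero total weight")
})

test_that("with e=0.5, pi=1, D=1 both forms equal the naive difference", {
  set.seed(31)
  for (rep in 1:5) {
    # Hajek reduces for any arm split; the unnormalized form needs
    # balanced arms for 1/(n e) to equal 1/n_arm
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.4)
    t <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    naive <- mean(y[t == 1]) - mean(y[t == 0])
    expect_equal(ate_estimate(y, t, rep(1L, n), rep(0.5, n), 1,
                              form = "hajek"), naive)

    m <- 2 * sample(3:15, 1)
    yb <- rbinom(m, 1, 0.4)
    tb <- sample(rep(0:1, m / 2))
    naive_b <- mean(yb[tb == 1]) - mean(yb[tb == 0])
    expect_equal(ate_estimate(yb, tb, rep(1L, m), rep(0.5, m), 1,
                              form = "horvitz_thompson"), naive_b)
    expect_equal(ate_estimate(yb, tb, rep(1L, m), rep(0.5, m), 1,
                              form = "hajek"), naive_b)
  }
})

test_that("trimming keeps the closed interval and reports counts", {
  scores <- c(0.01, 0.05, 0.50, 0.95, 0.96)
  keep <- trim_propensity(scores, c(0.05, 0.95), t_ind = c(1, 1, 0, 0, 1))
  expect_identical(as.integer(keep), c(2L, 3L, 4L))
  cnt <- attr(keep, "counts")
  expect_equal(cnt$n_total, 5L)
  expect_equal(cnt$n_trimmed, 2L)
  expect_equal(cnt$kept_treated, 1L)
  expect_equal(cnt$kept_control, 2L)

  expect_length(trim_propensity(rep(0.5, 10), c(0.05, 0.95)), 10L)
  expect_error(trim_propensity(c(0.01, 0.99), c(0.4, 0.6)), "every episode")

  set.seed(7)
  u <- runif(10000)
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
  frac <- length(trim_propensity(u, c(0.4, 0.6))) / 10000
  expect_lt(abs(frac - 0.2), 0.02)

  # narrowing the bounds never increases the retained count
  wide <- length(trim_propensity(u, c(0.05, 0.95)))
  mid <- length(trim_propensity(u, c(0.2, 0.8)))
  narrow <- length(trim_propensity(u, c(0.4, 0.6)))
  expect_true(wide >= mid && mid >= narrow)
})

test_that("degenerate data give a zero-width interval at the estimate", {
  n <- 40
  pb <- ipw_problem(y = as.numeric(rep(c(1, 0), 20)),
                    t_ind = rep(c(1L, 0L), 20), d = rep(1L, n),
                    person_id = 1:n, e = rep(0.5, n))
  cfg <- estimator_config(n_bootstrap = 50, refit_in_bootstrap = FALSE,
                          seed = 3)
  r <- bootstrap_ate(pb, cfg)
  expect_equal(r$ate, 1)
  expect_equal(r$ci, c(1, 1))
  expect_true(r$significant)

  r2 <- bootstrap_ate(pb, cfg)
  expect_identical(r$bootstrap_draws, r2$bootstrap_draws)
})

test_that("the result invariants hold on a simulated run", {
  r <- estimate_on_simulated(sim_config_confounded(4000, -0.02, seed = 91),
                             n_bootstrap = 100, design = "compact")
  expect_true(r$ci[1] <= r$adjusted && r$adjusted <= r$ci[2])
  expect_identical(r$significant, r$ci[1] > 0 || r$ci[2] < 0)
})

test_that("negative controls pass when clean and fail when planted", {
  cfg <- sim_config_confounded(4000, -0.02, seed = 101)
  b <- simulate_claims(cfg)
  co <- build_cohort(b)
  cc <- contrast_cohort(co)
  fm <- build_expert_features(cc, b)
  nc <- negative_control_suite(
    cc, fm, b, estimator_config(n_bootstrap = 100, seed = 5))
  expect_equal(nrow(nc), 6L)
  expect_setequal(nc$window_days, c(30L, 90L))
  # the two windows of one control share events, so count distinct
  # controls with any interval excluding zero: at most one false alarm
  ctrl <- sub("_(30|90)d$", "", nc$endpoint)
  expect_lte(length(unique(ctrl[!nc$pass])), 1L)

  cfg2 <- sim_config_confounded(4000, -0.02, seed = 102,
                                negative_control_effect = 0.15)
  b2 <- simulate_claims(cfg2)
  co2 <- build_cohort(b2)
  cc2 <- contrast_cohort(co2)
  fm2 <- build_expert_features(cc2, b2)
  nc2 <- negative_control_suite(
    cc2, fm2, b2, estimator_config(n_bootstrap = 100, seed = 5))
  expect_true(all(!nc2[nc2$window_days == 90L]$pass))
})

test_that("run_contrast recovers the simulated effect end to end", {
  # no background antibiotic history: prior episodes stay untreated, so the
  # beta-lactam arm is genuinely empty for the error contract below
  cfg <- sim_config_confounded(8000, -0.02, seed = 111,
                               history_antibiotic_rate = 0)
  b <- simulate_claims(cfg)
  rep <- run_contrast(
    b, endpoints = default_endpoints()["composite_failure"],
    est_cfg = estimator_config(n_bootstrap = 100, seed = 9),
    negative_controls = FALSE)
  res <- rep$results
  expect_equal(nrow(res), 1L)
  expect_true(res$ci_low <= -0.02 && -0.02 <= res$ci_high)
  # the unadjusted contrast is far outside the adjusted interval
  expect_lt(rep$naive$naive_rd, res$ci_low)
  expect_error(
    run_contrast(b, contrast = "first_line_vs_beta_lactam",
                 endpoints = default_endpoints()["composite_failure"]),
    "empty")
})
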