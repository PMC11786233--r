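# Splits, model selection, score calibration and Shapley attributions.

test_that("splits have the stated proportions and are person-clustered", {
  co <- data.table::data.table(
    episode_id = sprintf("e%d", 1:100), person_id = 1:100)
  plan <- make_splits(co, seed = 5)
  expect_length(plan$train_idx, 80L)
  expect_length(plan$test_idx, 20L)
  expect_length(plan$dev_idx, 60L)
  expect_length(plan$val_idx, 20L)
  expect_setequal(c(plan$train_idx, plan$test_idx), 1:100)
  expect_setequal(c(plan$dev_idx, plan$val_idx), plan$train_idx)

  # a person's episodes never straddle a split
  co2 <- data.table::data.table(
    episode_id = sprintf("e%d", 1:60),
    person_id = rep(1:20, each = 3))
  plan2 <- make_splits(co2, seed = 5)
  side <- ifelse(seq_len(60) %in% plan2$train_idx, "train", "test")
  expect_true(all(tapply(side, co2$person_id, uniqueN) == 1L))

  expect_identical(make_splits(co, seed = 5)[c("train_idx", "dev_idx")],
                   plan[c("train_idx", "dev_idx")])
  expect_error(make_splits(co[1:10], seed = 1), "at least 20")
})

test_that("the rank AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  score <- runif(300)
  label <- rbinom(300, 1, plogis(3 * score - 1.5))
  got <- uticausal:::auc_mw(score, label)
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

sep_fixture <- function(n = 400, seed = 1, signal = TRUE) {
  set.seed(seed)
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.4))
  y <- if (signal) as.integer(x[, "a"] + 0.5 * x[, "b"] > 0)
       else rbinom(n, 1, 0.5)
  list(x = x, y = y,
       co = data.table::data.table(episode_id = sprintf("e%d", 1:n),
                                   person_id = 1:n))
}

test_that("selection finds near-perfect models on separable labels", {
  fx <- sep_fixture(signal = TRUE)
  plan <- make_splits(fx$co, seed = 3)
  fit <- select_and_fit(fx$x, fx$y, plan, target = "treatment")
  expect_gte(max(fit$cv_auroc), 0.99)
  expect_true(all(fit$scores > 0 & fit$scores < 1))
  expect_length(fit$scores, 400L)
})

test_that("labels independent of features give chance-level AUROC", {
  fx <- sep_fixture(seed = 9, signal = FALSE)
  plan <- make_splits(fx$co, seed = 3)
  fit <- select_and_fit(fx$x, fx$y, plan, target = "treatment")
  expect_lt(abs(fit$cv_auroc[[fit$chosen_family]] - 0.5), 0.06)
})

test_that("selection is deterministic and rejects degenerate labels", {
  fx <- sep_fixture(seed = 4)
  plan <- make_splits(fx$co, seed = 3)
  f1 <- select_and_fit(fx$x, fx$y, plan, target = "treatment")
  f2 <- select_and_fit(fx$x, fx$y, plan, target = "treatment")
  expect_identical(f1$chosen_family, f2$chosen_family)
  expect_identical(f1$scores, f2$scores)
  expect_error(select_and_fit(fx$x, rep(1L, 400), plan), "degenerate")
})

test_that("propensity scores are calibrated on simulated assignment", {
  b <- simulate_claims(sim_config_confounded(20000, -0.02, seed = 51))
  co <- build_cohort(b)
  cc <- contrast_cohort(co)
  fm <- build_expert_features(cc, b)
  x <- fm_matrix(fm)
  e <- uticausal:::clip_prob(
    uticausal:::predict_logistic(uticausal:::fit_logistic(x, cc$T_ind), x))
  bins <- cut(e, quantile(e, 0:10 / 10), include.lowest = TRUE)
  pred <- tapply(e, bins, mean)
  obs <- tapply(cc$T_ind, bins, mean)
  slope <- coef(lm(obs ~ pred))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("propensity AUROC grows with the assignment signal", {
  # held-out AUROC: fit on half the episodes, score the other half, so the
  # null model sits at chance instead of its overfit in-sample value
  aucs <- vapply(c(0, 1, 2), function(scale) {
    cfg <- quick_sim(
      n = 5000, seed = 61, prior_uti_rate = 0.1,
      treatment_model = c(intercept = 0.4, age = -0.9 * scale,
                          year = 0.7 * scale, comorbid = -0.25 * scale,
                          specialty = -0.5 * scale, prior_uti = -0.2 * scale))
    b <- simulate_claims(cfg)
    co <- build_cohort(b)
    cc <- contrast_cohort(co)
    x <- fm_matrix(build_expert_features(cc, b))
    set.seed(1)
    tr <- sample(nrow(x), nrow(x) %/% 2)
    beta <- uticausal:::fit_logistic(x[tr, ], cc$T_ind[tr])
    e <- uticausal:::predict_logistic(beta, x[-tr, ])
    uticausal:::auc_mw(e, cc$T_ind[-tr])
  }, 0)
  expect_lt(abs(aucs[1] - 0.5), 0.05)
  expect_gt(aucs[2], aucs[1] + 0.05)
  expect_gt(aucs[3], aucs[2] + 0.05)
})

test_that("a near-null censoring model yields near-uniform IPCW weights", {
  cfg <- quick_sim(
    n = 4000, seed = 71,
    censoring_model = c(intercept = qlogis(0.15), age = 0, year = 0,
                        comorbid = 0, specialty = 0, prior_uti = 0,
                        treat = 0, treat_comorbid = 0))
  b <- simulate_claims(cfg)
  co <- build_cohort(b)
  cc <- contrast_cohort(co)
  fm <- build_expert_features(cc, b)
  x <- fm_matrix(fm)[, c("age", "year_frac", "uti_past_year",
                         "specialty_internal_medicine")]
  lab <- label_outcome(cc, b, default_endpoints()$composite_failure)
  xt <- x * cc$T_ind
  colnames(xt) <- paste0("t_x_", colnames(x))
  x_obs <- cbind(x, t_ind = cc$T_ind, xt)
  pi <- uticausal:::predict_logistic(uticausal:::fit_logistic(x_obs, lab$D),
                                     x_obs)
  expect_lt(sd(pi), 0.03)
  expect_lt(abs(mean(pi) - 0.85), 0.03)
})

test_that("Shapley attributions decompose tree and linear models", {
  fx <- sep_fixture(seed = 13)
  x <- cbind(fx$x, dead = rep(1, nrow(fx$x)))  # zero-variance column
  plan <- make_splits(fx$co, seed = 3)

  gbt <- select_and_fit(x, fx$y, plan,
                        grid = default_grid()["gradient_boosted_trees"])
  attr_tab <- shapley_attributions(gbt, x)
  expect_equal(attr_tab$feature[1], "a")   # the dominant signal ranks first
  expect_equal(
    attr_tab[attr_tab$feature == "dead", ]$mean_abs_attribution, 0)
  am <- attr(attr_tab, "attributions")
  pred <- predict(gbt$model$fit, xgboost::xgb.DMatrix(x))
  recon <- plogis(rowSums(am) + attr(attr_tab, "base_value"))
  expect_equal(recon, pred, tolerance = 1e-5, ignore_attr = TRUE)

  lin <- select_and_fit(x, fx$y, plan,
                        grid = list(regularized_linear = list(
                          list(alpha = 0, lambda = 0))))
  attr_lin <- shapley_attributions(lin, x)
  am <- attr(attr_lin, "attributions")
  eta <- drop(cbind(1, x) %*% lin$model$beta)  # link-scale prediction
  expect_equal(rowSums(am) + attr(attr_lin, "base_value"), eta,
               tolerance = 1e-8, ignore_attr = TRUE)

  rf <- select_and_fit(x, fx$y, plan,
                       grid = list(random_forest = list(
                         list(num_trees = 50, min_node_size = 10))))
  expect_message(attr_rf <- shapley_attributions(rf, x), "permutation")
  expect_equal(attr_rf$feature[1], "a")
})

test_that("simulated drivers of treatment rank at the top of attributions", {
  b <- simulate_claims(sim_config_confounded(6000, -0.02, seed = 81))
  co <- build_cohort(b)
  cc <- contrast_cohort(co)
  fm <- build_expert_features(cc, b)
  x <- fm_matrix(fm)
  plan <- make_splits(cc, seed = 7)
  fit <- select_and_fit(x, cc$T_ind, plan,
                        grid = default_grid()["gradient_boosted_trees"],
                        target = "treatment")
  top5 <- shapley_attributions(fit, x)$feature[1:5]
  expect_true(any(c("age", "year_frac") %in% top5))
  expect_true("age" %in% top5)
})
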