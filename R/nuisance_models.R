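# Nuisance models: treatment propensity e(X) and observation probability
# pi(X), fit with the split / grid-search / cross-validated-AUROC protocol.
#
# Model selection runs in two stages: hyperparameters per learner family on
# a development/validation split of the training set, then the family with
# the highest 3-fold cross-validated AUROC on the training set wins and is
# refit on the full training set. All splits and folds are person-clustered
# so repeated episodes of one patient never straddle a split.

#' Person-clustered train/test and development/validation splits
#'
#' 80% of persons form the training set and 20% the test set; within the
#' training set, 75% of persons form the development and 25% the
#' validation subset used for hyperparameter search. All episodes of a
#' person land on the same side of every split.
#'
#' @param cohort episode rows (needs `person_id`).
#' @param seed integer seed; the same seed reproduces the plan exactly.
#' @return a `split_plan`: integer row-index vectors `train_idx`,
#'   `test_idx`, `dev_idx`, `val_idx` (dev/val partition train), plus the
#'   cohort's `person_id` vector and the seed.
#' @export
make_splits <- function(cohort, seed = 1L) {
  co <- as.data.table(cohort)
  if (nrow(co) < 20L) stop("need at least 20 episodes to split")
  persons <- unique(co$person_id)
  if (length(persons) < 10L) stop("too few persons to split")
  set.seed(derive_seed(seed, "split"))
  persons <- sample(persons)
  n_train <- floor(0.8 * length(persons))
  train_persons <- persons[seq_len(n_train)]
  test_persons <- persons[-seq_len(n_train)]
  n_dev <- floor(0.75 * n_train)
  dev_persons <- train_persons[seq_len(n_dev)]
  val_persons <- train_persons[-seq_len(n_dev)]

  idx_of <- function(p) which(co$person_id %in% p)
  structure(
    list(
      train_idx = idx_of(train_persons), test_idx = idx_of(test_persons),
      dev_idx = idx_of(dev_persons), val_idx = idx_of(val_persons),
      person_id = co$person_id, seed = as.integer(seed)
    ),
    class = "split_plan"
  )
}

#' Default hyperparameter grids for the three learner families
#'
#' Deliberately small grids (well under a dozen candidates per family) so
#' the full two-stage selection stays fast at interactive scale; grids are
#' configuration, not claims, and can be widened freely.
#'
#' @return a named list of lists of hyperparameter sets.
#' @export
default_grid <- function() {
  list(
    regularized_linear = list(
      list(alpha = 0, lambda = 0),
      list(alpha = 0, lambda = 1e-3),
      list(alpha = 1, lambda = 1e-3),
      list(alpha = 0, lambda = 1e-2)
    ),
    random_forest = list(
      list(num_trees = 200, min_node_size = 20),
      list(num_trees = 200, min_node_size = 100)
    ),
    gradient_boosted_trees = list(
      list(nrounds = 100, max_depth = 2, eta = 0.1),
      list(nrounds = 100, max_depth = 3, eta = 0.1),
      list(nrounds = 50, max_depth = 3, eta = 0.3)
    )
  )
}

fit_family <- function(family, x, y, hp, seed = 1L) {
  model <- switch(
    family,
    regularized_linear = {
      if (hp$lambda == 0) {
        list(kind = "glm", beta = fit_logistic(x, y))
      } else {
        list(kind = "glmnet",
             fit = glmnet::glmnet(x, y, family = "binomial",
                                  alpha = hp$alpha, lambda = hp$lambda,
                                  standardize = TRUE))
      }
    },
    random_forest = {
      d <- as.data.frame(x)
      d$.y <- factor(y, levels = c(0, 1))
      list(kind = "ranger",
           fit = ranger::ranger(
             dependent.variable.name = ".y", data = d, probability = TRUE,
             num.trees = hp$num_trees, min.node.size = hp$min_node_size,
             seed = seed, num.threads = 1, respect.unordered.factors = TRUE))
    },
    gradient_boosted_trees = {
      set.seed(seed)
      dm <- xgboost::xgb.DMatrix(x, label = y)
      list(kind = "xgb",
           fit = xgboost::xgb.train(
             params = list(objective = "binary:logistic",
                           max_depth = hp$max_depth, eta = hp$eta,
                           nthread = 1),
             data = dm, nrounds = hp$nrounds, verbose = 0))
    },
    stop("unknown learner family: ", family)
  )
  model$family <- family
  model$hp <- hp
  model$feature_names <- colnames(x)
  model
}

predict_family <- function(model, x) {
  x <- x[, model$feature_names, drop = FALSE]
  p <- switch(
    model$kind,
    glm = predict_logistic(model$beta, x),
    glmnet = drop(predict(model$fit, newx = x, type = "response")),
    ranger = {
      pr <- predict(model$fit, data = as.data.frame(x),
                    num.threads = 1)$predictions
      pr[, "1"]
    },
    xgb = predict(model$fit, xgboost::xgb.DMatrix(x))
  )
  unname(p)
}

#' Select and fit a nuisance model
#'
#' Stage 1: for each learner family, every hyperparameter set is fit on
#' the development subset and scored by AUROC on the validation subset;
#' the best set per family survives. Stage 2: each family (at its chosen
#' hyperparameters) is scored by person-clustered 3-fold cross-validated
#' AUROC on the full training set, and the best family is refit on the
#' training set. Scores are produced for every episode and clipped to
#' `[1e-4, 1 - 1e-4]` so downstream inverse-probability weights stay
#' finite.
#'
#' @param features a `feature_matrix` or numeric matrix, rows aligned with
#'   `labels`.
#' @param labels binary 0/1 vector (treatment indicator or observation
#'   indicator).
#' @param plan a [make_splits()] plan for the same rows.
#' @param grid hyperparameter grids as in [default_grid()]; only the
#'   families named in the grid are considered.
#' @param target `"treatment"` or `"observation"`, recorded in the result.
#' @return a `nuisance_fit`: chosen family and hyperparameters, per-family
#'   validation and CV AUROCs, the fitted model, and clipped per-episode
#'   `scores`.
#' @export
select_and_fit <- function(features, labels, plan, grid = default_grid(),
                           target = c("treatment", "observation")) {
  target <- match.arg(target)
  x <- if (inherits(features, "feature_matrix")) fm_matrix(features)
       else as.matrix(features)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(x))
  if (length(unique(y[plan$train_idx])) < 2L) {
    stop("degenerate labels: training set contains a single class")
  }

  ## stage 1: hyperparameters on dev/val
  best_hp <- list()
  val_auc <- list()
  for (fam in names(grid)) {
    aucs <- vapply(seq_along(grid[[fam]]), function(k) {
      m <- fit_family(fam, x[plan$dev_idx, , drop = FALSE], y[plan$dev_idx],
                      grid[[fam]][[k]],
                      seed = derive_seed(plan$seed, paste0(fam, k)))
      auc_mw(predict_family(m, x[plan$val_idx, , drop = FALSE]),
             y[plan$val_idx])
    }, 0)
    best_hp[[fam]] <- grid[[fam]][[which.max(aucs)]]
    val_auc[[fam]] <- aucs
  }

  ## stage 2: family by clustered 3-fold CV AUROC on train
  folds <- clustered_folds(plan$person_id[plan$train_idx], 3L,
                           derive_seed(plan$seed, "cvfolds"))
  cv_auc <- vapply(names(grid), function(fam) {
    mean(vapply(1:3, function(f) {
      tr <- plan$train_idx[folds != f]
      te <- plan$train_idx[folds == f]
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      m <- fit_family(fam, x[tr, , drop = FALSE], y[tr], best_hp[[fam]],
                      seed = derive_seed(plan$seed, paste0("cv", fam, f)))
      auc_mw(predict_family(m, x[te, , drop = FALSE]), y[te])
    }, 0), na.rm = TRUE)
  }, 0)
  chosen <- names(which.max(cv_auc))

  final <- fit_family(chosen, x[plan$train_idx, , drop = FALSE],
                      y[plan$train_idx], best_hp[[chosen]],
                      seed = derive_seed(plan$seed, "final"))
  scores <- clip_prob(predict_family(final, x))

  structure(
    list(
      target = target, chosen_family = chosen,
      hyperparameters = best_hp[[chosen]],
      cv_auroc = cv_auc, val_auroc = val_auc,
      scores = scores, model = final, labels = y,
      feature_names = colnames(x), plan_seed = plan$seed
    ),
    class = "nuisance_fit"
  )
}

#' @export
print.nuisance_fit <- function(x, ...) {
  cat("<nuisance_fit>", x$target, "model; chosen family:", x$chosen_family,
      sprintf("(CV AUROC %.3f)\n", x$cv_auroc[[x$chosen_family]]))
  invisible(x)
}

# Refit the chosen family at fixed hyperparameters on new data (used inside
# the bootstrap); returns a plain score function.
refit_scores <- function(fit, x, y, seed = 1L) {
  if (length(unique(y)) < 2L) return(NULL)
  m <- fit_family(fit$chosen_family, x, y, fit$hyperparameters, seed = seed)
  clip_prob(predict_family(m, x))
}

#' Shapley-value feature attributions for a nuisance model
#'
#' Gradient-boosted trees use exact TreeSHAP contributions; linear models
#' use the closed-form linear Shapley decomposition
#' `phi_j = beta_j (x_j - mean(x_j))` on the link scale. For random
#' forests, where no exact decomposition is available here, the function
#' falls back to a permutation-based importance (mean absolute change in
#' prediction when a column is permuted) and says so in a message.
#'
#' @param fit a [select_and_fit()] result.
#' @param features the feature matrix the fit was produced from.
#' @return a data.table `(feature, mean_abs_attribution)` sorted
#'   descending, with the per-episode attribution matrix in attribute
#'   `"attributions"` (exact methods only).
#' @export
shapley_attributions <- function(fit, features) {
  x <- if (inherits(features, "feature_matrix")) fm_matrix(features)
       else as.matrix(features)
  x <- x[, fit$feature_names, drop = FALSE]
  model <- fit$model
  attr_mat <- NULL
  if (model$kind == "xgb") {
    contrib <- predict(model$fit, xgboost::xgb.DMatrix(x),
                       predcontrib = TRUE)
    bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
    attr_mat <- contrib[, setdiff(colnames(contrib), bias_col),
                        drop = FALSE]
    base <- contrib[1, bias_col]
  } else if (model$kind %in% c("glm", "glmnet")) {
    beta <- if (model$kind == "glm") {
      model$beta[-1]
    } else {
      drop(as.matrix(coef(model$fit)))[-1]
    }
    beta <- beta[fit$feature_names]
    beta[is.na(beta)] <- 0
    mu <- colMeans(x)
    attr_mat <- sweep(x, 2L, mu) %*% diag(beta, ncol(x))
    colnames(attr_mat) <- fit$feature_names
    base <- sum(beta * mu) + if (model$kind == "glm") model$beta[1] else
      drop(as.matrix(coef(model$fit)))[1]
  } else {
    message("exact Shapley attributions unavailable for family '",
            fit$chosen_family, "'; using permutation importance")
    set.seed(derive_seed(fit$plan_seed, "perm"))
    p0 <- predict_family(model, x)
    imp <- vapply(fit$feature_names, function(cn) {
      xp <- x
      xp[, cn] <- sample(xp[, cn])
      mean(abs(predict_family(model, xp) - p0))
    }, 0)
    out <- data.table(feature = names(imp), mean_abs_attribution = unname(imp))
    setorder(out, -mean_abs_attribution)
    return(out)
  }
  imp <- colMeans(abs(attr_mat))
  out <- data.table(feature = names(imp), mean_abs_attribution = unname(imp))
  setorder(out, -mean_abs_attribution)
  setattr(out, "attributions", attr_mat)
  setattr(out, "base_value", base)
  out
}
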