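# Internal helpers: seeding, probability hygiene, AUROC, fast logistic fits.

# Derive a reproducible substream seed from a master seed and a stage label.
# Keeps everything inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 7919 + 1) %% .Machine$integer.max)
}

# Clip probabilities away from 0/1 so inverse-probability weights stay finite.
clip_prob <- function(p, eps = 1e-4) {
  pmin(pmax(p, eps), 1 - eps)
}

# Rank-based AUROC (Mann-Whitney form). Ties handled by midranks.
auc_mw <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Unpenalized logistic regression on a plain numeric matrix via compiled
# IRLS (see src/logistic_irls.cpp). `start` warm-starts the iterations,
# which is what keeps per-replicate refits in the bootstrap cheap. A tiny
# ridge keeps the solve well-posed when a column is constant (its
# coefficient is then pulled to ~0 and prediction still works).
fit_logistic <- function(x, y, start = NULL) {
  x1 <- cbind(`(Intercept)` = 1, x)
  if (is.null(start) || length(start) != ncol(x1)) {
    start <- numeric(ncol(x1))
    start[1] <- qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  }
  # ridge scaled with n: negligible shrinkage, but keeps the solve
  # well-posed when one-hot blocks are collinear with the intercept
  fit <- .irls_logistic(x1, as.numeric(y), as.numeric(start),
                        ridge = 1e-7 * nrow(x1))
  beta <- drop(fit$beta)
  names(beta) <- colnames(x1)
  beta
}

predict_logistic <- function(beta, x) {
  plogis(drop(cbind(1, x) %*% beta))
}

# Split row indices into k person-clustered folds: all rows of a person
# land in the same fold.
clustered_folds <- function(person_id, k, seed) {
  persons <- unique(person_id)
  set.seed(seed)
  fold_of_person <- sample(rep_len(seq_len(k), length(persons)))
  names(fold_of_person) <- as.character(persons)
  unname(fold_of_person[as.character(person_id)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a serialized R object, used for run provenance.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
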