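#' Specification for the regularized response classifier
#'
#' Bundles the hyperparameters of the L2-regularized logistic-regression
#' response model: the inverse-regularization grid `C` searched by inner
#' stratified 5-fold cross-validation, balanced class weights (inversely
#' proportional to class frequencies), the inner-CV scoring metric, and the
#' RNG seed that makes every fit reproducible.
#'
#' @param C_grid Inverse regularization strengths; default `0.1, 0.2, ..., 1.0`.
#' @param inner_folds Inner cross-validation folds for the grid search
#'   (default 5).
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @param inner_scoring `"accuracy"` (default) or `"auc"`.
#' @param rng_seed Integer seed controlling fold assignment and any sampling.
#' @return An object of class `netbio_model_spec`.
#' @export
model_spec <- function(C_grid = seq(0.1, 1, by = 0.1), inner_folds = 5L,
                       class_weight = c("balanced", "none"),
                       inner_scoring = c("accuracy", "auc"), rng_seed = 1L) {
  assert_that(length(C_grid) > 0 && all(C_grid > 0), "C_grid must be non-empty and positive")
  structure(
    list(C_grid = sort(unique(C_grid)), inner_folds = as.integer(inner_folds),
         class_weight = match.arg(class_weight),
         inner_scoring = match.arg(inner_scoring),
         rng_seed = as.integer(rng_seed)),
    class = "netbio_model_spec"
  )
}

balanced_weights <- function(y, class_weight = "balanced") {
  n <- length(y)
  if (class_weight == "none") return(rep(1, n))
  tab <- table(factor(y, levels = c(0, 1)))
  w <- n / (2 * as.numeric(tab))
  names(w) <- names(tab)
  unname(w[as.character(y)])
}

stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# Penalized logistic fit by BFGS on the explicit objective; used where the
# coordinate-descent fitter refuses (a class with < 2 training samples, as
# happens in leave-one-out on tiny cohorts).
ridge_logistic_small <- function(X, y, w, lambda) {
  obj <- function(par) {
    eta <- par[1] + as.numeric(X %*% par[-1])
    ll <- w * (y * eta - log1p(exp(eta)))
    -sum(ll) / nrow(X) + lambda / 2 * sum(par[-1]^2)
  }
  gr <- function(par) {
    r <- w * (y - plogis(par[1] + as.numeric(X %*% par[-1])))
    c(-sum(r) / nrow(X), -as.numeric(crossprod(X, r)) / nrow(X) + lambda * par[-1])
  }
  opt <- stats::optim(rep(0, ncol(X) + 1L), obj, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(a0 = opt$par[1], beta = setNames(opt$par[-1], colnames(X)))
}

# Fit the ridge-penalized logistic path at the lambdas matching the C grid.
# The sklearn-style objective 0.5||w||^2 + C * sum_i s_i loss_i corresponds to
# glmnet's (1/n) sum_i w_i loss_i + lambda/2 ||w||^2 at lambda = 1/(n*C) with
# weights summing to n. glmnet requires >= 2 predictors, so a single-feature
# design is padded with an all-zero column whose coefficient is discarded.
fit_l2_path <- function(X, y, C_values, weights) {
  padded <- FALSE
  if (ncol(X) == 1L) {
    X <- cbind(X, `..pad..` = 0)
    padded <- TRUE
  }
  n <- nrow(X)
  lambdas <- 1 / (n * C_values)           # increasing C -> decreasing lambda
  lam_seq <- sort(unique(lambdas), decreasing = TRUE)
  small <- min(table(y)) < 2
  if (small) {
    fits <- lapply(lam_seq, function(l) ridge_logistic_small(X, y, weights, l))
  } else {
    fit <- withCallingHandlers(
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = lam_seq, weights = weights,
                     standardize = FALSE, thresh = 1e-10, maxit = 1e6),
      warning = function(w) {
        if (grepl("dangerous ground", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    fits <- NULL
  }
  list(fit = if (small) NULL else fit, small_fits = fits, small = small,
       lam_seq = lam_seq, lambdas = lambdas, padded = padded, n = n,
       features = colnames(X))
}

path_coef <- function(path, C_value) {
  lam <- 1 / (path$n * C_value)
  if (path$small) {
    i <- which.min(abs(path$lam_seq - lam))
    res <- path$small_fits[[i]]
  } else {
    beta <- as.numeric(coef(path$fit, s = lam, exact = FALSE))
    res <- list(a0 = beta[1L], beta = setNames(beta[-1L], rownames(path$fit$beta)))
  }
  if (path$padded) res$beta <- res$beta[names(res$beta) != "..pad.."]
  res
}

predict_path <- function(path, X, C_value, n_train) {
  co <- path_coef(path, C_value)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X <- X[, names(co$beta), drop = FALSE]
  as.numeric(plogis(co$a0 + X %*% co$beta))
}

score_predictions <- function(y, prob, metric) {
  if (metric == "auc") {
    if (length(unique(y)) < 2) return(NA_real_)
    roc_auc(y, prob)
  } else {
    mean((prob >= 0.5) == y)
  }
}

#' Fit the L2-regularized logistic-regression response classifier
#'
#' Selects the inverse regularization strength `C` from the spec's grid by
#' stratified inner k-fold cross-validation on the training data (ties are
#' broken toward the smallest `C`, i.e. the strongest regularization), then
#' refits on all training samples with balanced class weights. Features are
#' assumed to be standardized already.
#'
#' @param X Numeric matrix, samples in rows, features in columns (named).
#' @param y Binary labels (1 = responder, 0 = non-responder).
#' @param spec A [model_spec()].
#' @return An object of class `netbio_model` with `feature_names`,
#'   `coefficients`, `intercept`, `chosen_C` and the inner-CV score table.
#' @export
fit_classifier <- function(X, y, spec = model_spec()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.integer(y)
  assert_that(length(unique(y)) == 2, "both classes must be present to fit the classifier")
  assert_that(nrow(X) == length(y), "X and y disagree on the number of samples")
  n <- nrow(X)
  w <- balanced_weights(y, spec$class_weight)

  n_min <- min(table(y))
  folds_k <- spec$inner_folds
  if (n_min < folds_k) {
    folds_k <- max(2L, min(n_min, folds_k))
    if (n_min < 2L) folds_k <- 1L
    warning(sprintf("fit_classifier: reducing inner folds to %d (minority class has %d samples)",
                    folds_k, n_min))
  }

  Cs <- spec$C_grid
  if (length(Cs) > 1L && folds_k >= 2L) {
    folds <- stratified_folds(y, folds_k, spec$rng_seed)
    scores <- matrix(NA_real_, folds_k, length(Cs))
    for (f in seq_len(folds_k)) {
      tr <- folds != f
      path <- fit_l2_path(X[tr, , drop = FALSE], y[tr], Cs, w[tr])
      for (ci in seq_along(Cs)) {
        pr <- predict_path(path, X[!tr, , drop = FALSE], Cs[ci], sum(tr))
        scores[f, ci] <- score_predictions(y[!tr], pr, spec$inner_scoring)
      }
    }
    mean_score <- colMeans(scores, na.rm = TRUE)
    best <- which(mean_score >= max(mean_score) - 1e-12)
    chosen_C <- Cs[min(best)]                # tie -> smallest C
    cv_table <- data.frame(C = Cs, score = mean_score)
  } else {
    chosen_C <- min(Cs)
    cv_table <- data.frame(C = chosen_C, score = NA_real_)
  }

  path <- fit_l2_path(X, y, Cs, w)
  co <- path_coef(path, chosen_C)
  structure(
    list(feature_names = names(co$beta), coefficients = co$beta,
         intercept = co$a0, chosen_C = chosen_C, cv_table = cv_table,
         spec = spec),
    class = "netbio_model"
  )
}

#' Predict response probabilities from a fitted classifier
#'
#' @param object A `netbio_model`.
#' @param newdata Numeric matrix, samples in rows; must contain all model
#'   features (matched by column name when present).
#' @param ... Unused.
#' @return Named numeric vector of responder probabilities.
#' @export
predict.netbio_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    assert_that(all(object$feature_names %in% colnames(X)),
                "newdata lacks some model features")
    X <- X[, object$feature_names, drop = FALSE]
  } else {
    assert_that(ncol(X) == length(object$feature_names),
                "newdata has the wrong number of feature columns")
  }
  eta <- object$intercept + as.numeric(X %*% object$coefficients)
  setNames(plogis(eta), rownames(X))
}

#' @export
print.netbio_model <- function(x, ...) {
  cat(sprintf("L2 logistic response model: %d features, C = %.2f\n",
              length(x$feature_names), x$chosen_C))
  invisible(x)
}

prediction_frame <- function(samples, prob, threshold = 0.5) {
  data.frame(sample = as.character(samples), probability = as.numeric(prob),
             predicted_label = as.integer(prob >= threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leave-one-out cross-validation of the response classifier
#'
#' For each sample the classifier (including its inner grid search) is
#' refitted on all other samples and the held-out responder probability is
#' recorded. Metrics are computed once over the full vector of held-out
#' predictions, including a two-sided Fisher exact test on the 2x2
#' predicted-by-observed table.
#'
#' @inheritParams fit_classifier
#' @return A list with `predictions` (data.frame `sample`, `probability`,
#'   `predicted_label`), `metrics` (see [compute_metrics()]) and `chosen_C`
#'   per fold.
#' @export
loocv <- function(X, y, spec = model_spec()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (n < 10 || min(table(y)) < 10) {
    warning("loocv: fewer than 10 samples per class; estimates will be unstable")
  }
  prob <- numeric(n)
  chosen <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_classifier(X[-i, , drop = FALSE], y[-i], spec)
    prob[i] <- predict(m, X[i, , drop = FALSE])
    chosen[i] <- m$chosen_C
  }
  samples <- rownames(X) %||% as.character(seq_len(n))
  list(predictions = prediction_frame(samples, prob),
       metrics = compute_metrics(y, prob),
       chosen_C = chosen)
}

make_mc_splits <- function(y, n_iter, train_frac, seed) {
  n <- length(y)
  splits <- vector("list", n_iter)
  resampled <- 0L
  for (it in seq_len(n_iter)) {
    attempt <- 0L
    repeat {
      tr <- logical(n)
      with_seed(stage_seed(seed + it, paste0("mc_split", attempt)), {
        for (cl in unique(y)) {
          idx <- which(y == cl)
          n_tr <- round(train_frac * length(idx))
          n_tr <- max(1L, min(length(idx) - 1L, n_tr))
          tr[sample(idx, n_tr)] <- TRUE
        }
      })
      ok <- length(unique(y[tr])) == 2 && length(unique(y[!tr])) == 2
      if (ok) break
      attempt <- attempt + 1L
      resampled <- resampled + 1L
    }
    splits[[it]] <- which(tr)
  }
  if (resampled > 0) {
    message(sprintf("monte_carlo_cv: resampled %d degenerate split(s)", resampled))
  }
  splits
}

#' Monte-Carlo cross-validation (repeated stratified 80/20 splits)
#'
#' Repeats `n_iter` random splits in which `train_frac` of the samples
#' (stratified by class, so every split sees both classes on both sides)
#' train the classifier and the rest are predicted. Split membership depends
#' only on the spec seed and the iteration index, so two feature sets
#' evaluated with the same spec share identical splits — pass `splits` from a
#' previous run for an explicitly paired comparison.
#'
#' @inheritParams fit_classifier
#' @param n_iter Number of random splits (default 100).
#' @param train_frac Fraction of samples used for training (default 0.8).
#' @param splits Optional list of training-index vectors to reuse.
#' @return A list with `per_iteration` (data.frame of metrics by iteration),
#'   `summary` (mean and sd per metric) and `splits`.
#' @export
monte_carlo_cv <- function(X, y, spec = model_spec(), n_iter = 100,
                           train_frac = 0.8, splits = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(splits)) splits <- make_mc_splits(y, n_iter, train_frac, spec$rng_seed)
  rows <- lapply(seq_along(splits), function(it) {
    tr <- splits[[it]]
    m <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec)
    pr <- predict(m, X[-tr, , drop = FALSE])
    mt <- compute_metrics(y[-tr], pr)
    data.frame(iteration = it, accuracy = mt$accuracy, f1 = mt$f1,
               auc_roc = mt$auc_roc, auprc = mt$auprc)
  })
  per_iter <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "f1", "auc_roc", "auprc")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(per_iter[metric_cols], mean, numeric(1)),
    sd = vapply(per_iter[metric_cols], sd, numeric(1)),
    row.names = NULL
  )
  list(per_iteration = per_iter, summary = summ, splits = splits)
}

#' Train on one cohort, predict an independent cohort
#'
#' Fits the classifier on the full training cohort and emits responder
#' probabilities for the test cohort over the features common to both (each
#' cohort is expected to have been z-scored independently beforehand; dropped
#' features are reported).
#'
#' @param X_train,y_train Training-cohort features and labels.
#' @param X_test Test-cohort features (samples x features, named columns).
#' @param spec A [model_spec()].
#' @return A list with `predictions` (data.frame) and the fitted `model`.
#' @export
across_study_predict <- function(X_train, y_train, X_test, spec = model_spec()) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  common <- intersect(colnames(X_train), colnames(X_test))
  if (length(common) == 0) stop("no common features between cohorts", call. = FALSE)
  dropped <- (ncol(X_train) - length(common)) + (ncol(X_test) - length(common))
  if (dropped > 0) {
    message(sprintf("across_study_predict: %d feature column(s) outside the common set dropped", dropped))
  }
  m <- fit_classifier(X_train[, common, drop = FALSE], y_train, spec)
  pr <- predict(m, X_test[, common, drop = FALSE])
  samples <- rownames(X_test) %||% as.character(seq_len(nrow(X_test)))
  list(predictions = prediction_frame(samples, pr), model = m)
}

#' Data-driven feature selection by one-way ANOVA F statistic
#'
#' Ranks features by the F statistic of a one-way ANOVA between the two
#' response classes (between-group mean square over within-group mean
#' square), the classical `f_classif` selector, and returns the top `k`
#' names (ties broken by ascending name). Features with zero within-group
#' variance but distinct group means receive infinite F and rank first.
#' Selection must be computed on training data only.
#'
#' @param X Numeric matrix, samples x features (named columns).
#' @param y Binary labels.
#' @param k Number of features to keep.
#' @return Character vector of `k` feature names, best first.
#' @export
anova_select_k <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.integer(y)
  assert_that(k >= 1 && k <= ncol(X), "k must lie in [1, n_features]")
  n <- nrow(X)
  g1 <- y == 1
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  mall <- colMeans(X)
  ssb <- n1 * (m1 - mall)^2 + n0 * (m0 - mall)^2
  ssw <- colSums((X[g1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((X[!g1, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  inf <- ssw == 0 & ssb > 0
  if (any(inf)) {
    f[inf] <- Inf
    warning(sprintf("anova_select_k: %d feature(s) with zero within-group variance ranked first", sum(inf)))
  }
  f[ssw == 0 & ssb == 0] <- 0
  nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
  out <- nm[order(-f, nm)][seq_len(k)]
  attr(out, "F") <- setNames(f, nm)
  out
}

#' Network-guided versus data-driven feature selection, across study
#'
#' Mirrors the repeated-subsampling comparison of prior-knowledge feature
#' selection against purely data-driven selection: for each iteration a
#' stratified fraction of the training cohort is drawn; one classifier is
#' trained on the network-selected pathway features, a second on the top-K
#' pathways ranked by ANOVA F on that same subsample (K = number of
#' network-selected pathways, selection on training data only); both predict
#' the independent test cohort, so the AUROC difference isolates the feature
#' selection. Splits are shared between the two arms (paired design).
#'
#' @param activity_train,activity_test All-pathway activity matrices
#'   (pathways x samples), each cohort z-scored independently.
#' @param netbio_pathways Names of the network-selected pathways.
#' @param y_train,y_test Binary labels per cohort (named or aligned).
#' @param spec A [model_spec()].
#' @param n_iter Number of subsampling iterations (default 100).
#' @param train_frac Fraction of training samples used per iteration
#'   (default 0.8).
#' @return A list with `per_iteration` (data.frame `auc_netbio`,
#'   `auc_datadriven`), means of both arms, and the paired two-sided t-test
#'   p-value.
#' @export
feature_selection_benchmark <- function(activity_train, activity_test,
                                        netbio_pathways, y_train, y_test,
                                        spec = model_spec(), n_iter = 100,
                                        train_frac = 0.8) {
  netbio_pathways <- intersect(netbio_pathways, rownames(activity_train))
  assert_that(length(netbio_pathways) > 0, "no network-selected pathway found in the activity matrix")
  k <- length(netbio_pathways)
  X_tr_all <- t(activity_train)
  X_te_all <- t(activity_test)
  if (!is.null(names(y_train))) y_train <- y_train[rownames(X_tr_all)]
  if (!is.null(names(y_test))) y_test <- y_test[rownames(X_te_all)]
  splits <- make_mc_splits(y_train, n_iter, train_frac, spec$rng_seed)
  rows <- lapply(seq_along(splits), function(it) {
    tr <- splits[[it]]
    Xs <- X_tr_all[tr, , drop = FALSE]
    ys <- y_train[tr]
    m_nb <- fit_classifier(Xs[, netbio_pathways, drop = FALSE], ys, spec)
    auc_nb <- roc_auc(y_test, predict(m_nb, X_te_all[, netbio_pathways, drop = FALSE]))
    dd <- anova_select_k(Xs, ys, k)
    m_dd <- fit_classifier(Xs[, dd, drop = FALSE], ys, spec)
    auc_dd <- roc_auc(y_test, predict(m_dd, X_te_all[, dd, drop = FALSE]))
    data.frame(iteration = it, auc_netbio = auc_nb, auc_datadriven = auc_dd)
  })
  per_iter <- do.call(rbind, rows)
  d <- per_iter$auc_netbio - per_iter$auc_datadriven
  p <- if (sd(d) == 0) 1 else t.test(per_iter$auc_netbio, per_iter$auc_datadriven,
                                     paired = TRUE)$p.value
  list(per_iteration = per_iter,
       mean_auc_netbio = mean(per_iter$auc_netbio),
       mean_auc_datadriven = mean(per_iter$auc_datadriven),
       paired_p = p)
}

#' Area under the ROC curve
#'
#' Rank-based AUROC (the Mann-Whitney statistic scaled to `[0, 1]`); tied
#' scores receive half credit via average ranks.
#'
#' @param y_true Binary labels (1 = responder).
#' @param prob Predicted scores or probabilities.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, prob) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  assert_that(n1 > 0 && n0 > 0, "AUC is undefined with a single observed class")
  r <- rank(prob)                            # average ranks give ties half credit
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-function integration of precision over recall, grouping tied scores
#' at a single threshold (no trapezoidal interpolation).
#'
#' @inheritParams roc_auc
#' @return AUPRC in `(0, 1]`.
#' @export
pr_auc <- function(y_true, prob) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  assert_that(n1 > 0, "AUPRC is undefined with no positive samples")
  o <- order(-prob)
  ys <- y_true[o]
  ps <- prob[o]
  grp_end <- which(ps != c(ps[-1], NA) | seq_along(ps) == length(ps))
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(1 - ys)[grp_end]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  prev_recall <- c(0, recall[-length(recall)])
  sum((recall - prev_recall) * precision)    # step integration, no trapezoids
}

#' Classification metrics for responder predictions
#'
#' AUROC is computed by Mann-Whitney concordant-pair counting with half
#' credit for ties; AUPRC by step integration of the precision-recall curve;
#' accuracy and F1 (responders positive) at probability threshold 0.5; and a
#' two-sided Fisher exact test on the 2x2 predicted-by-observed table.
#'
#' @param y_true Observed binary labels.
#' @param probabilities Predicted responder probabilities.
#' @param threshold Probability cutoff for the hard label (default 0.5).
#' @return A list: `accuracy`, `f1`, `auc_roc`, `auprc`, `fisher_p`,
#'   `confusion` (rows Pred R/NR, columns Obs R/NR).
#' @export
compute_metrics <- function(y_true, probabilities, threshold = 0.5) {
  y_true <- as.integer(y_true)
  assert_that(length(unique(y_true)) == 2, "both classes must be present in y_true")
  pred <- as.integer(probabilities >= threshold)
  tab <- table(factor(pred, levels = c(1, 0)), factor(y_true, levels = c(1, 0)))
  dimnames(tab) <- list(predicted = c("R", "NR"), observed = c("R", "NR"))
  tp <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(
    accuracy = mean(pred == y_true),
    f1 = f1,
    auc_roc = roc_auc(y_true, probabilities),
    auprc = pr_auc(y_true, probabilities),
    fisher_p = fisher.test(tab)$p.value,
    confusion = unclass(tab)
  )
}

#' Rank model features by coefficient magnitude
#'
#' @param model A fitted `netbio_model`.
#' @param top_n Number of features to return (default 10).
#' @param sign Restrict to features with `"positive"` or `"negative"`
#'   coefficients, or use `"both"`.
#' @return A data.frame with `feature` and `coefficient`, largest magnitude
#'   first (ties broken by feature name).
#' @export
feature_importance <- function(model, top_n = 10, sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  co <- model$coefficients
  co <- switch(sign,
    positive = co[co > 0],
    negative = co[co < 0],
    both = co[co != 0]
  )
  if (length(co) == 0) {
    warning("feature_importance: no feature matches the requested sign (all-zero coefficients?)")
    return(data.frame(feature = character(0), coefficient = numeric(0)))
  }
  ord <- order(-abs(co), names(co))
  co <- co[ord][seq_len(min(top_n, length(co)))]
  data.frame(feature = names(co), coefficient = unname(co),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-group comparison of feature values
#'
#' Two-sided Student's t test (pooled variance by default, Welch optional) or
#' Mann-Whitney U test, as used to contrast pathway expression between
#' predicted or reclassified patient groups.
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @param test `"t_test"` or `"mann_whitney"`.
#' @param welch Use the Welch (unequal-variance) t test instead of the pooled
#'   Student's t test.
#' @return A list with `statistic`, `p_value` and `test`.
#' @export
compare_groups <- function(values_a, values_b, test = c("t_test", "mann_whitney"),
                           welch = FALSE) {
  test <- match.arg(test)
  if (test == "t_test") {
    assert_that(length(values_a) >= 2 && length(values_b) >= 2,
                "the t test needs at least 2 values per group")
    if (var(values_a) == 0 && var(values_b) == 0) {
      stop("t test undefined: zero variance in both groups", call. = FALSE)
    }
    ht <- t.test(values_a, values_b, var.equal = !welch)
  } else {
    assert_that(length(values_a) >= 1 && length(values_b) >= 1,
                "the Mann-Whitney test needs at least 1 value per group")
    ht <- suppressWarnings(wilcox.test(values_a, values_b))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
}
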