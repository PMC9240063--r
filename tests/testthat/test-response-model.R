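test_that("the classifier separates a linearly separable toy and is deterministic", {
  toy <- separable_toy()
  spec <- model_spec(rng_seed = 3)
  m <- fit_classifier(toy$X, toy$y, spec)
  pr <- predict(m, toy$X)
  expect_equal(mean((pr >= 0.5) == toy$y), 1.0)
  expect_true(m$chosen_C %in% spec$C_grid)

  m2 <- fit_classifier(toy$X, toy$y, spec)
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$chosen_C, m2$chosen_C)

  expect_error(fit_classifier(toy$X, rep(1, nrow(toy$X)), spec), "both classes")
})

test_that("duplicated feature columns split weight symmetrically", {
  toy <- separable_toy()
  spec <- model_spec(rng_seed = 3)
  X_dup <- cbind(toy$X, f1b = toy$X[, "f1"])
  m2 <- fit_classifier(X_dup, toy$y, spec)
  expect_equal(unname(m2$coefficients["f1"]), unname(m2$coefficients["f1b"]),
               tolerance = 1e-5)
  # swapping the two identical columns must not change any prediction
  X_swap <- X_dup[, c("f2", "f1b", "f1")]
  colnames(X_swap) <- c("f2", "f1", "f1b")
  expect_equal(unname(predict(m2, X_dup)), unname(predict(m2, X_swap)),
               tolerance = 1e-10)
})

test_that("balanced class weights keep the minority class from collapsing", {
  set.seed(21)
  n <- 60
  y <- c(rep(0L, 54), rep(1L, 6))
  X <- cbind(sig = y * 3 + rnorm(n, sd = 0.4), noise = rnorm(n))
  m <- fit_classifier(X, y, model_spec(rng_seed = 5))
  pr <- predict(m, X)
  expect_equal(mean(pr[y == 1] >= 0.5), 1.0)  # minority recall = 1
})

test_that("LOOCV held-out predictions match a hand-run of the per-sample fits", {
  set.seed(8)
  X <- cbind(a = c(0.1, 1.2, -0.4, 0.9), b = c(1, -1, 0.5, -0.2))
  rownames(X) <- paste0("P", 1:4)
  y <- c(0L, 1L, 0L, 1L)
  spec <- model_spec(rng_seed = 2)
  res <- suppressWarnings(loocv(X, y, spec))
  manual <- vapply(1:4, function(i) {
    m <- suppressWarnings(fit_classifier(X[-i, ], y[-i], spec))
    unname(predict(m, X[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(res$predictions$probability, manual, tolerance = 1e-12)
})

test_that("LOOCV on pure-noise features behaves like chance", {
  set.seed(77)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  res <- loocv(X, y, model_spec(rng_seed = 7))
  expect_gte(res$metrics$accuracy, 0.3)
  expect_lte(res$metrics$accuracy, 0.7)
  expect_gte(res$metrics$auc_roc, 0.3)
  expect_lte(res$metrics$auc_roc, 0.7)
})

test_that("Monte-Carlo CV uses stratified 80/20 splits and reproducible, shareable split sets", {
  set.seed(1)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(s = y * 2 + rnorm(n, sd = 0.8), r = rnorm(n))
  spec <- model_spec(rng_seed = 11)
  res <- monte_carlo_cv(X, y, spec, n_iter = 8)
  expect_true(all(vapply(res$splits, length, integer(1)) == 24))
  res2 <- monte_carlo_cv(X, y, spec, n_iter = 8)
  expect_identical(res$per_iteration, res2$per_iteration)
  expect_identical(res$splits, res2$splits)

  # paired contract: a second feature set evaluated on the same splits
  res3 <- monte_carlo_cv(X[, 1, drop = FALSE], y, spec, splits = res$splits)
  expect_identical(res3$splits, res$splits)
  expect_equal(nrow(res3$per_iteration), 8)
})

test_that("across-study prediction restricts to common features and refits in-sample at the identity", {
  toy <- separable_toy()
  spec <- model_spec(rng_seed = 3)
  xs <- across_study_predict(toy$X, toy$y, toy$X, spec)
  m <- fit_classifier(toy$X, toy$y, spec)
  expect_equal(xs$predictions$probability, unname(predict(m, toy$X)), tolerance = 1e-12)

  X_other <- toy$X
  colnames(X_other) <- c("g1", "g2")
  expect_error(across_study_predict(toy$X, toy$y, X_other, spec), "common features")
})

test_that("ANOVA-F selection reproduces the textbook F and ranks planted features first", {
  X <- cbind(flat = c(1, 2, 1, 2), diff = c(1, 2, 3, 4))
  y <- c(0L, 0L, 1L, 1L)
  sel <- anova_select_k(X, y, 2)
  f <- attr(sel, "F")
  expect_equal(unname(f["diff"]), 8.0)
  expect_equal(sel[1], "diff")

  Xc <- cbind(same = c(3, 3, 3, 3), diff = c(1, 2, 3, 4))
  f0 <- attr(anova_select_k(Xc, y, 1), "F")
  expect_equal(unname(f0["same"]), 0)

  # zero within-group variance with distinct means -> infinite F, ranked first
  Xi <- cbind(perfect = c(0, 0, 1, 1), noisy = c(0.2, -0.1, 0.8, 1.4))
  expect_warning(sel_i <- anova_select_k(Xi, y, 1), "zero within-group")
  expect_equal(sel_i[1], "perfect")

  set.seed(41)
  n <- 50
  yy <- rep(c(0L, 1L), each = n / 2)
  XX <- matrix(rnorm(n * 10), n, dimnames = list(NULL, sprintf("f%02d", 1:10)))
  XX[, "f03"] <- XX[, "f03"] + yy * 2
  expect_true("f03" %in% anova_select_k(XX, yy, 2))
})

test_that("metrics match their worked values and enumeration oracles", {
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc_roc, 1.0)
  expect_equal(compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))$auc_roc, 0.75)

  mt <- compute_metrics(c(1, 1, 1, 0, 0, 0), c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_equal(unclass(mt$confusion), matrix(c(3, 0, 0, 3), 2,
               dimnames = list(predicted = c("R", "NR"), observed = c("R", "NR"))),
               ignore_attr = FALSE)
  expect_equal(mt$fisher_p, 0.1, tolerance = 1e-12)
  expect_equal(mt$accuracy, 1)
  expect_equal(mt$f1, 1)
  expect_equal(mt$auprc, 1)

  set.seed(55)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)                  # frequent ties
    mt <- compute_metrics(y, p)
    expect_equal(mt$auc_roc, oracle_auc_pairs(y, p), tolerance = 1e-12)
    expect_equal(mt$fisher_p, oracle_fisher_2x2(mt$confusion), tolerance = 1e-9)
  }
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.6)), "both classes")
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(40, 1, 0.4)
  p <- runif(40)
  expect_equal(compute_metrics(y, p)$auc_roc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("feature importance ranks by magnitude within the requested sign", {
  m <- structure(list(coefficients = c(up2 = 2, down3 = -3, up1 = 1),
                      feature_names = c("up2", "down3", "up1")),
                 class = "netbio_model")
  pos <- feature_importance(m, 2, "positive")
  expect_equal(pos$feature, c("up2", "up1"))
  neg <- feature_importance(m, 5, "negative")
  expect_equal(neg$feature, "down3")
  both <- feature_importance(m, 5, "both")
  expect_equal(both$feature, c("down3", "up2", "up1"))

  m0 <- structure(list(coefficients = c(a = 0, b = 0)), class = "netbio_model")
  expect_warning(empty <- feature_importance(m0, 3, "positive"), "no feature")
  expect_equal(nrow(empty), 0)
})

test_that("group comparisons reproduce exact small-sample results", {
  id <- compare_groups(c(1, 2, 3), c(1, 2, 3), "mann_whitney")
  expect_equal(id$p_value, 1)
  tt0 <- compare_groups(c(1, 2, 3), c(1, 2, 3), "t_test")
  expect_equal(unname(tt0$statistic), 0)

  mw <- compare_groups(c(1, 2, 3), c(4, 5, 6), "mann_whitney")
  expect_equal(unname(mw$statistic), 0)          # U = 0
  expect_equal(mw$p_value, 0.1, tolerance = 1e-12)
  expect_equal(mw$p_value, oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)

  a <- c(0, 0, 0, 1); b <- c(1, 1, 1, 0)
  tt <- compare_groups(a, b, "t_test")
  # pooled-variance Student's t computed from the textbook formula
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(unname(tt$statistic), t_manual, tolerance = 1e-12)

  expect_error(compare_groups(c(1, 1), c(2, 2), "t_test"), "zero variance")
})
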