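test_that("TMB doubles truncating counts and is linear in both counts", {
  expect_equal(compute_tmb(2, 3), 7.0)
  expect_equal(compute_tmb(0, 0), 0)
  expect_equal(compute_tmb(c(1, 4), c(2, 0)), c(4, 8))

  # linearity: TMB(a+b) = TMB(a) + TMB(b), and scaling counts scales TMB
  t1 <- c(1, 2); nt1 <- c(3, 0)
  t2 <- c(4, 1); nt2 <- c(0, 5)
  expect_equal(compute_tmb(t1 + t2, nt1 + nt2),
               compute_tmb(t1, nt1) + compute_tmb(t2, nt2))
  expect_equal(compute_tmb(3 * t1, 3 * nt1), 3 * compute_tmb(t1, nt1))

  expect_error(compute_tmb(1, c(1, 2)), "same length")
  expect_error(compute_tmb(-1, 0), "non-negative")
  expect_error(compute_tmb(1.5, 0), "integers")
})

test_that("variant classification maps MAF classes to the two burden groups", {
  trunc_cls <- c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
                 "Splice_Site")
  nontrunc_cls <- c("Missense_Mutation", "In_Frame_Del", "In_Frame_Ins",
                    "Nonstop_Mutation")
  expect_equal(as.character(classify_variant(trunc_cls)),
               rep("truncating", 4))
  expect_equal(as.character(classify_variant(nontrunc_cls)),
               rep("non_truncating", 4))
  expect_message(out <- classify_variant(c("Silent", "Intron", "Missense_Mutation")),
                 "2 variant")
  expect_equal(as.character(out), c("excluded", "excluded", "non_truncating"))
  expect_equal(levels(out), c("truncating", "non_truncating", "excluded"))
})

test_that("per-sample TMB from a MAF table counts each class correctly", {
  maf <- data.frame(
    sample = c("P1", "P1", "P1", "P2", "P2", "P2"),
    Variant_Classification = c("Nonsense_Mutation", "Missense_Mutation", "Silent",
                               "Frame_Shift_Del", "Splice_Site", "In_Frame_Ins"),
    stringsAsFactors = FALSE
  )
  res <- suppressMessages(tmb_from_maf(maf))
  expect_equal(res$sample, c("P1", "P2"))
  expect_equal(res$T, c(1L, 2L))
  expect_equal(res$NT, c(1L, 1L))
  expect_equal(res$tmb, c(3, 5))

  # the alternative barcode column name is accepted
  maf2 <- maf
  names(maf2)[1] <- "Tumor_Sample_Barcode"
  expect_equal(suppressMessages(tmb_from_maf(maf2))$tmb, res$tmb)

  expect_error(tmb_from_maf(data.frame(x = 1)), "sample and Variant_Classification")
})

test_that("Kaplan-Meier matches hand computation and the loop oracle", {
  # n = 2, both events: S drops 1 -> 0.5 -> 0
  km2 <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km2$surv, c(0.5, 0))

  # hand table, n = 6 with censoring:
  # t=1 (6 at risk, 1 event) -> 5/6
  # t=2 censored
  # t=3 (4 at risk, 1 event) -> 5/6 * 3/4
  # t=5 (2 at risk, 1 event) -> 5/6 * 3/4 * 1/2
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 0, 1, 0)
  km6 <- km_estimate(time, event)
  drops <- km6$surv[km6$n_event > 0]
  expect_equal(drops, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2),
               tolerance = 1e-12)
  orc <- oracle_km(time, event)
  expect_equal(km6$time[km6$n_event > 0], orc$time)
  expect_equal(drops, orc$surv, tolerance = 1e-12)

  # Greenwood plain bands bracket the estimate
  ok <- !is.na(km6$lower)
  expect_true(all(km6$lower[ok] <= km6$surv[ok] + 1e-12))
  expect_true(all(km6$surv[ok] <= km6$upper[ok] + 1e-12))

  # all censored: curve never drops
  km_c <- km_estimate(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "at least one")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("survival_at reads left- and right-continuous step values", {
  km <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(survival_at(km, 0.5), 1)
  # at an event time the default (left) excludes that drop
  expect_equal(survival_at(km, 3), 5 / 6, tolerance = 1e-12)
  expect_equal(survival_at(km, 3, side = "right"), 5 / 6 * 3 / 4, tolerance = 1e-12)
  expect_equal(survival_at(km, 100), 5 / 6 * 3 / 4 * 1 / 2, tolerance = 1e-12)
})

test_that("log-rank test matches the observed-minus-expected oracle and is rank-based", {
  # identical groups -> chi-square 0, p = 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  same <- logrank_test(t0, e0, t0, e0)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  set.seed(64)
  ta <- rexp(20, 1 / 100); ea <- rbinom(20, 1, 0.8)
  tb <- rexp(20, 1 / 40);  eb <- rbinom(20, 1, 0.8)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$chi_square, oracle_logrank(ta, ea, tb, eb), tolerance = 1e-9)
  expect_equal(lr$p, pchisq(lr$chi_square, 1, lower.tail = FALSE), tolerance = 1e-12)

  # multiplying every time by 10 leaves the rank-based statistic unchanged
  lr10 <- logrank_test(10 * ta, ea, 10 * tb, eb)
  expect_equal(lr10$chi_square, lr$chi_square, tolerance = 1e-9)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
  expect_error(logrank_test(numeric(0), numeric(0), c(1), c(1)), "non-empty")
})

test_that("survival stratification separates a planted hazard difference", {
  set.seed(17)
  n <- 60
  lab <- rep(c(1L, 0L), each = n / 2)
  # predicted responders live ~3x longer (exponential, median 365 vs 120 days)
  time <- ifelse(lab == 1, rexp(n, log(2) / 365), rexp(n, log(2) / 120))
  event <- rbinom(n, 1, 0.8)
  samples <- sprintf("S%02d", seq_len(n))
  preds <- data.frame(sample = samples, predicted_label = lab)
  surv <- data.frame(sample = samples, os_time = time, os_event = event)

  st <- survival_stratify(preds, surv)
  expect_lt(st$logrank$p, 0.05)
  expect_gt(st$survival_at_horizon$responder,
            st$survival_at_horizon$non_responder)
  expect_equal(st$survival_at_horizon$difference,
               st$survival_at_horizon$responder -
                 st$survival_at_horizon$non_responder)
  expect_equal(unname(st$n), c(30L, 30L))

  # identical survival in both strata -> p = 1
  surv_same <- data.frame(sample = samples,
                          os_time = rep(c(100, 200, 300), n / 3),
                          os_event = rep(c(1, 0, 1), n / 3))
  st_same <- survival_stratify(preds, surv_same)
  expect_equal(st_same$logrank$p, 1, tolerance = 1e-12)

  # single-class predictions are rejected
  preds_one <- data.frame(sample = samples, predicted_label = rep(1L, n))
  expect_error(survival_stratify(preds_one, surv), "fewer than 2")
})

test_that("combined TMB + pathway model reduces to known special cases", {
  set.seed(23)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  samples <- sprintf("S%02d", seq_len(n))
  act <- rbind(pwA = y * 2 + rnorm(n, sd = 0.5), pwB = rnorm(n))
  colnames(act) <- samples
  names(y) <- samples
  spec <- model_spec(rng_seed = 9)

  # constant TMB carries no signal after z-scoring: equal to activity-only run
  tmb_const <- setNames(rep(10, n), samples)
  res_const <- suppressWarnings(combined_tmb_netbio(act, tmb_const, y, spec))
  res_act <- loocv(t(zscore_standardize(act)), y, spec)
  expect_equal(res_const$predictions$probability,
               res_act$predictions$probability, tolerance = 1e-8)

  # TMB-only model: activity = NULL uses just the z-scored burden row
  tmb_sig <- setNames(y * 8 + rpois(n, 4), samples)
  res_tmb <- combined_tmb_netbio(NULL, tmb_sig, y, spec)
  expect_gt(res_tmb$metrics$auc_roc, 0.8)
  expect_equal(nrow(res_tmb$predictions), n)

  # samples without a TMB value are dropped with a message
  expect_message(res_drop <- combined_tmb_netbio(act, tmb_sig[-(1:2)], y, spec),
                 "dropped 2")
  expect_equal(nrow(res_drop$predictions), n - 2)
})

test_that("reclassification sets partition exactly the flipped labels", {
  a <- data.frame(sample = c("P1", "P2", "P3", "P4"),
                  predicted_label = c(1L, 0L, 1L, 0L))
  b <- data.frame(sample = c("P4", "P3", "P2", "P1"),   # different order on purpose
                  predicted_label = c(1L, 0L, 1L, 1L))
  rc <- reclassification_sets(a, b)
  expect_setequal(rc$R2NR, "P3")
  expect_setequal(rc$NR2R, c("P2", "P4"))
  expect_length(intersect(rc$R2NR, rc$NR2R), 0)

  b_miss <- b[1:3, ]
  expect_error(reclassification_sets(a, b_miss), "different samples")
})
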