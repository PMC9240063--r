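#' Tumor mutational burden from truncating / non-truncating counts
#'
#' Truncating mutations (nonsense, frame-shift insertion/deletion,
#' splice-site) are weighted twice as heavily as non-truncating ones
#' (missense, in-frame insertion/deletion, nonstop):
#' `TMB = 2 * T + 1 * NT`.
#'
#' @param truncating Non-negative integer vector of truncating-mutation
#'   counts per sample.
#' @param non_truncating Non-negative integer vector of non-truncating
#'   counts, same length.
#' @return Numeric vector of TMB values.
#' @export
compute_tmb <- function(truncating, non_truncating) {
  assert_that(length(truncating) == length(non_truncating),
              "count vectors must have the same length")
  assert_that(all(truncating >= 0) && all(non_truncating >= 0),
              "mutation counts must be non-negative")
  assert_that(all(truncating == round(truncating)) && all(non_truncating == round(non_truncating)),
              "mutation counts must be integers")
  truncating * 2.0 + non_truncating * 1.0
}

#' Classify a MAF variant class as truncating or non-truncating
#'
#' Maps MAF-style `Variant_Classification` strings: nonsense, frame-shift
#' insertion/deletion and splice-site variants are truncating; missense,
#' in-frame insertion/deletion and nonstop variants are non-truncating.
#' Anything else (silent, UTR, intron, ...) is excluded from the burden and
#' the excluded count is reported.
#'
#' @param variant_classification Character vector of MAF classification
#'   strings.
#' @return Factor with levels `truncating`, `non_truncating`, `excluded`.
#' @export
classify_variant <- function(variant_classification) {
  x <- as.character(variant_classification)
  truncating <- c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site")
  non_truncating <- c("Missense_Mutation", "In_Frame_Del", "In_Frame_Ins", "Nonstop_Mutation")
  out <- ifelse(x %in% truncating, "truncating",
                ifelse(x %in% non_truncating, "non_truncating", "excluded"))
  n_exc <- sum(out == "excluded")
  if (n_exc > 0) {
    message(sprintf("classify_variant: %d variant(s) excluded from the burden", n_exc))
  }
  factor(out, levels = c("truncating", "non_truncating", "excluded"))
}

#' Per-sample TMB from a MAF-like variant table
#'
#' @param maf Data.frame with columns `sample` (or `Tumor_Sample_Barcode`)
#'   and `Variant_Classification`.
#' @return Data.frame with `sample`, `T`, `NT`, `tmb`.
#' @export
tmb_from_maf <- function(maf) {
  sample_col <- if ("sample" %in% names(maf)) "sample" else "Tumor_Sample_Barcode"
  assert_that(sample_col %in% names(maf) && "Variant_Classification" %in% names(maf),
              "MAF table needs sample and Variant_Classification columns")
  cls <- classify_variant(maf$Variant_Classification)
  samples <- sort(unique(as.character(maf[[sample_col]])))
  Tn <- vapply(samples, function(s) {
    sum(cls[maf[[sample_col]] == s] == "truncating")
  }, integer(1))
  NTn <- vapply(samples, function(s) {
    sum(cls[maf[[sample_col]] == s] == "non_truncating")
  }, integer(1))
  data.frame(sample = samples, T = unname(Tn), NT = unname(NTn),
             tmb = compute_tmb(unname(Tn), unname(NTn)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit survival curve with symmetric 95% confidence bands
#' from the Greenwood variance formula.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event observed, 0 = censored).
#' @return An object of class `netbio_km`: data.frame-like list with `time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`, plus the underlying
#'   `survfit` object.
#' @export
km_estimate <- function(time, event) {
  assert_that(length(time) >= 1, "need at least one survival record")
  assert_that(all(time >= 0), "survival times must be non-negative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain", conf.int = 0.95)
  structure(
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         surv = fit$surv, lower = fit$lower, upper = fit$upper, fit = fit),
    class = "netbio_km"
  )
}

#' Survival probability at a time point
#'
#' Reads the step value of a Kaplan-Meier curve. The default `"left"` side
#' returns the left-continuous value `S(t-)` (drops occurring exactly at `t`
#' are not counted); `"right"` returns the conventional right-continuous
#' `S(t)`.
#'
#' @param curve A `netbio_km` object.
#' @param t Time point (same units as the input times).
#' @param side `"left"` (default) or `"right"`.
#' @return Survival probability in `[0, 1]`.
#' @export
survival_at <- function(curve, t, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(curve, "netbio_km"))
  drop_times <- curve$time[curve$n_event > 0]
  surv_at_drops <- curve$surv[curve$n_event > 0]
  idx <- if (side == "left") which(drop_times < t) else which(drop_times <= t)
  if (length(idx) == 0) return(1)
  surv_at_drops[max(idx)]
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square comparing observed with expected
#' event counts at every distinct event time, with a 1-degree-of-freedom
#' upper-tail p-value and no continuity correction. The statistic is
#' rank-based: monotone transforms of time leave it unchanged.
#'
#' @param time_a,event_a Times and event indicators for group A.
#' @param time_b,event_b Times and event indicators for group B.
#' @return A list with `chi_square` and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  assert_that(length(time_a) >= 1 && length(time_b) >= 1, "both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0) {
    stop("log-rank test undefined: no events in either group", call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  group <- c(rep(0L, length(time_a)), rep(1L, length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Survival stratification by predicted response
#'
#' Splits patients into predicted responders and predicted non-responders,
#' estimates a Kaplan-Meier curve per group, compares the groups with the
#' log-rank test, and reports the survival probability of each group at a
#' fixed horizon (1 year by default) together with their difference.
#'
#' @param predictions Data.frame with `sample` and `predicted_label`
#'   (1 = predicted responder), e.g. from [loocv()].
#' @param survival_df Data.frame with `sample`, `os_time`, `os_event`
#'   (times in days unless `year_days` is changed).
#' @param year_days Horizon for the percent-survival readout (default 365).
#' @return A list: `km` (per-group `netbio_km`), `logrank`, `survival_at_horizon`
#'   (per group, plus `difference` = responder minus non-responder), `n` per
#'   group.
#' @export
survival_stratify <- function(predictions, survival_df, year_days = 365) {
  df <- merge(predictions, survival_df, by = "sample")
  assert_that(nrow(df) >= 4, "too few samples with both predictions and survival data")
  grp_r <- df[df$predicted_label == 1, ]
  grp_nr <- df[df$predicted_label == 0, ]
  if (nrow(grp_r) < 2) stop("predicted-responder group has fewer than 2 samples", call. = FALSE)
  if (nrow(grp_nr) < 2) stop("predicted-non-responder group has fewer than 2 samples", call. = FALSE)
  km_r <- km_estimate(grp_r$os_time, grp_r$os_event)
  km_nr <- km_estimate(grp_nr$os_time, grp_nr$os_event)
  lr <- logrank_test(grp_r$os_time, grp_r$os_event, grp_nr$os_time, grp_nr$os_event)
  s_r <- survival_at(km_r, year_days)
  s_nr <- survival_at(km_nr, year_days)
  list(
    km = list(responder = km_r, non_responder = km_nr),
    logrank = lr,
    survival_at_horizon = list(responder = s_r, non_responder = s_nr,
                               difference = s_r - s_nr, horizon_days = year_days),
    n = c(responder = nrow(grp_r), non_responder = nrow(grp_nr))
  )
}

#' Leave-one-out predictions from combined TMB and pathway features
#'
#' Builds the combined feature matrix — z-scored pathway activities plus the
#' z-scored TMB as one extra column — and evaluates it with [loocv()].
#' Samples without a TMB value are dropped (with a message). Passing
#' `activity = NULL` gives the TMB-only model.
#'
#' @param activity Pathways-by-samples activity matrix (or `NULL` for the
#'   TMB-only model).
#' @param tmb Named numeric vector of per-sample TMB values.
#' @param y Named (or activity-aligned) binary response labels.
#' @param spec A [model_spec()].
#' @param zscore Standardize both blocks before training (default TRUE, as
#'   required when mixing feature families).
#' @return The [loocv()] result over the combined features.
#' @export
combined_tmb_netbio <- function(activity, tmb, y, spec = model_spec(), zscore = TRUE) {
  assert_that(!is.null(names(tmb)), "tmb must be a named per-sample vector")
  samples <- if (is.null(activity)) names(tmb) else colnames(activity)
  have_tmb <- samples %in% names(tmb)
  if (any(!have_tmb)) {
    message(sprintf("combined_tmb_netbio: dropped %d sample(s) without a TMB value", sum(!have_tmb)))
    samples <- samples[have_tmb]
  }
  if (!is.null(names(y))) y <- y[samples] else y <- y[have_tmb]
  tmb_row <- matrix(tmb[samples], nrow = 1, dimnames = list("TMB", samples))
  if (zscore) tmb_row <- suppressWarnings(zscore_standardize(tmb_row))
  if (is.null(activity)) {
    feat <- tmb_row
  } else {
    act <- activity[, samples, drop = FALSE]
    if (zscore) act <- zscore_standardize(act)
    feat <- rbind(act, tmb_row)
  }
  loocv(t(feat), y, spec)
}

#' Samples reclassified between the TMB-only and combined models
#'
#' `R2NR` holds samples predicted responder by the TMB-only model but
#' non-responder by the combined model; `NR2R` is the converse. The two sets
#' are disjoint by construction and together count every flipped label.
#'
#' @param pred_tmb_only,pred_combined Prediction data.frames (`sample`,
#'   `predicted_label`) over the same sample universe.
#' @return A list with character vectors `R2NR` and `NR2R`.
#' @export
reclassification_sets <- function(pred_tmb_only, pred_combined) {
  assert_that(setequal(pred_tmb_only$sample, pred_combined$sample),
              "the two prediction sets cover different samples")
  a <- pred_tmb_only[order(pred_tmb_only$sample), ]
  b <- pred_combined[order(pred_combined$sample), ]
  list(
    R2NR = a$sample[a$predicted_label == 1 & b$predicted_label == 0],
    NR2R = a$sample[a$predicted_label == 0 & b$predicted_label == 1]
  )
}
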