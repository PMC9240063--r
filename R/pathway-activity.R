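#' Single-sample gene-set enrichment scores
#'
#' Scores every gene set in every sample independently with the
#' rank-weighted running-sum statistic of single-sample GSEA. Within a
#' sample, genes are ordered by descending expression (ties broken by
#' ascending gene symbol, so results are deterministic across platforms) and
#' assigned the rank statistic `r_g = N - position + 1`. For a set S the
#' enrichment score is the accumulated difference between the weighted hit
#' distribution and the uniform miss distribution:
#' `ES(S) = sum_i [P_hit(i) - P_miss(i)]` with
#' `P_hit(i) = sum_{g in S, pos(g) <= i} r_g^alpha / sum_{g in S} r_g^alpha`
#' and `P_miss(i) = |{g not in S, pos(g) <= i}| / (N - |S|)`.
#' Because the statistic is rank-based, any strictly monotone transform of a
#' sample's expression leaves its scores unchanged.
#'
#' @param expr Numeric matrix, genes (rownames) by samples (colnames), of
#'   normalized expression.
#' @param collection Gene-set collection (named list of character vectors).
#'   Sets are intersected with the expression genes first; sets left with no
#'   gene, or with every gene, cannot be scored and are dropped with a
#'   warning.
#' @param alpha Rank-weighting exponent (default 0.25, the customary ssGSEA
#'   weight).
#' @return A pathways-by-samples numeric matrix with attribute
#'   `stage = "raw_es"`.
#' @export
ssgsea_es <- function(expr, collection, alpha = 0.25) {
  validate_expression(expr)
  genes <- rownames(expr)
  N <- length(genes)
  in_expr <- lapply(collection, intersect, y = genes)
  sz <- lengths(in_expr)
  drop <- sz == 0 | sz == N
  if (any(drop)) {
    warning(sprintf("ssgsea_es: dropped %d gene set(s) with zero or complete overlap with the expression genes: %s",
                    sum(drop), paste(names(in_expr)[drop], collapse = ", ")))
    in_expr <- in_expr[!drop]
  }
  assert_that(length(in_expr) > 0, "no scorable gene set remains")

  n_sets <- length(in_expr)
  out <- matrix(NA_real_, n_sets, ncol(expr),
                dimnames = list(names(in_expr), colnames(expr)))
  r_stat <- (N - seq_len(N) + 1)^alpha
  set_idx <- lapply(in_expr, match, table = genes)
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes)
    pos_of_gene <- integer(N)
    pos_of_gene[ord] <- seq_len(N)
    for (s in seq_len(n_sets)) {
      hit_pos <- pos_of_gene[set_idx[[s]]]
      hit <- logical(N)
      hit[hit_pos] <- TRUE
      w <- r_stat * hit
      p_hit <- cumsum(w) / sum(w)
      p_miss <- cumsum(!hit) / (N - length(hit_pos))
      out[s, j] <- sum(p_hit - p_miss)
    }
  }
  attr(out, "stage") <- "raw_es"
  out
}

#' Normalize enrichment scores by the global score range
#'
#' The normalized enrichment score (NES) divides every raw ES by the range of
#' the entire matrix, `max(ES) - min(ES)` over all pathways and samples, so
#' scores are comparable across pathways within a cohort. Rankings within
#' each pathway are preserved (positive affine scaling).
#'
#' @param esm A `raw_es` matrix from [ssgsea_es()].
#' @return The NES matrix with attribute `stage = "nes"`.
#' @export
normalize_es <- function(esm) {
  assert_that(identical(attr(esm, "stage"), "raw_es"),
              "normalize_es expects a raw_es matrix from ssgsea_es()")
  rng <- range(esm)
  assert_that(rng[2] > rng[1], "cannot normalize a constant enrichment-score matrix")
  out <- esm / (rng[2] - rng[1])
  attr(out, "stage") <- "nes"
  out
}

#' Z-score standardize features across samples of one cohort
#'
#' Each row (gene or pathway) is centered by its mean and scaled by its
#' population standard deviation (denominator `n`, not `n - 1`) across the
#' cohort's samples. Rows with zero variance are mapped to all-zeros with a
#' warning. Standardizing per cohort reduces batch differences before
#' classifiers are trained or applied across cohorts.
#'
#' @param m Numeric matrix, features in rows, samples in columns (at least 2
#'   samples).
#' @return Matrix of the same shape; if the input carried `stage = "nes"` the
#'   output carries `stage = "zscored"`.
#' @export
zscore_standardize <- function(m) {
  assert_that(ncol(m) >= 2, "z-score standardization needs at least 2 samples")
  mu <- rowMeans(m)
  centered <- m - mu
  sdev <- sqrt(rowMeans(centered^2))
  zero <- sdev == 0
  if (any(zero)) {
    warning(sprintf("zscore_standardize: %d zero-variance row(s) mapped to zeros", sum(zero)))
  }
  sdev[zero] <- 1
  out <- centered / sdev
  out[zero, ] <- 0
  dimnames(out) <- dimnames(m)
  if (identical(attr(m, "stage"), "nes")) attr(out, "stage") <- "zscored"
  out
}
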