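#' Linear weighted combination of two prediction scores
#'
#' Combines the network-biomarker responder probability with an external
#' per-sample score (for example a synthetic-lethality-derived score) as
#' `combined = w * netbio + (1 - w) * external`. By default the external
#' score is min-max rescaled to `[0, 1]` first so that the weight is
#' comparable across score families.
#'
#' @param netbio_score Named numeric vector of responder probabilities in
#'   `[0, 1]`.
#' @param external_score Named numeric vector over the same samples.
#' @param w Linear weight in `[0, 1]`.
#' @param rescale_external Min-max rescale the external score before
#'   combining (default TRUE).
#' @return Named numeric vector of combined scores.
#' @export
combine_scores <- function(netbio_score, external_score, w, rescale_external = TRUE) {
  assert_that(w >= 0 && w <= 1, "w must lie in [0, 1]")
  assert_that(!is.null(names(netbio_score)) && !is.null(names(external_score)),
              "scores must be named per-sample vectors")
  assert_that(setequal(names(netbio_score), names(external_score)),
              "sample sets of the two scores differ")
  external_score <- external_score[names(netbio_score)]
  if (rescale_external) {
    rng <- range(external_score)
    if (rng[2] > rng[1]) {
      external_score <- (external_score - rng[1]) / (rng[2] - rng[1])
    }
  }
  w * netbio_score + (1 - w) * external_score
}

#' AUROC of the combined score over the weight grid
#'
#' Evaluates [combine_scores()] at every weight in the grid and reports the
#' AUROC of each combined score against the observed responses, plus the
#' maximizing weight. At the endpoints `w = 0` and `w = 1` the AUROC equals
#' the single-score AUROCs.
#'
#' @param netbio_score,external_score As in [combine_scores()].
#' @param y Named or aligned binary response labels.
#' @param grid Weights to evaluate (default `0, 0.1, ..., 1`).
#' @param rescale_external Passed to [combine_scores()].
#' @return A list with `sweep` (data.frame `w`, `auc`) and `best_w`.
#' @export
combination_sweep <- function(netbio_score, external_score, y,
                              grid = seq(0, 1, by = 0.1), rescale_external = TRUE) {
  if (!is.null(names(y))) y <- y[names(netbio_score)]
  assert_that(length(unique(y)) == 2, "both response classes must be present")
  aucs <- vapply(grid, function(w) {
    roc_auc(y, combine_scores(netbio_score, external_score, w, rescale_external))
  }, numeric(1))
  sweep <- data.frame(w = grid, auc = aucs)
  list(sweep = sweep, best_w = grid[which.max(aucs)])
}

#' Spearman correlation between two prediction scores
#'
#' Rank correlation with average ranks for ties; the two-sided p-value comes
#' from exact permutation enumeration for n <= 9 and the t approximation
#' otherwise.
#'
#' @param score_a,score_b Numeric vectors over the same samples (aligned, or
#'   named).
#' @return A list with `rho` and `p_value`.
#' @export
score_correlation <- function(score_a, score_b) {
  if (!is.null(names(score_a)) && !is.null(names(score_b))) {
    assert_that(setequal(names(score_a), names(score_b)), "sample sets differ")
    score_b <- score_b[names(score_a)]
  }
  n <- length(score_a)
  assert_that(n >= 3, "need at least 3 paired scores")
  assert_that(sd(score_a) > 0 && sd(score_b) > 0, "constant score vector")
  ht <- suppressWarnings(
    cor.test(score_a, score_b, method = "spearman", exact = n <= 9)
  )
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Cross-cohort transcriptome similarity over a gene subset
#'
#' Restricts both expression matrices to the shared genes of `gene_subset`
#' (by default the direct network neighbors of the drug targets), then for
#' every patient of cohort A takes the maximum Spearman correlation to any
#' patient of cohort B, and vice versa. The two directions are asymmetric by
#' construction and both are reported with their medians.
#'
#' @param expr_a,expr_b Genes-by-samples expression matrices.
#' @param gene_subset Character vector of genes to compare on (>= 3 shared
#'   genes required).
#' @return A list with `a_to_b`, `b_to_a` (named per-patient maxima),
#'   `median_a_to_b`, `median_b_to_a`, `genes_used`.
#' @export
transcriptome_similarity <- function(expr_a, expr_b, gene_subset) {
  shared <- Reduce(intersect, list(unique(gene_subset), rownames(expr_a), rownames(expr_b)))
  if (length(shared) < 3) {
    stop("fewer than 3 subset genes shared by both cohorts", call. = FALSE)
  }
  ra <- apply(expr_a[shared, , drop = FALSE], 2, rank)
  rb <- apply(expr_b[shared, , drop = FALSE], 2, rank)
  rho <- cor(ra, rb, method = "pearson")   # Pearson of ranks = Spearman
  a_to_b <- apply(rho, 1, max)
  b_to_a <- apply(rho, 2, max)
  list(a_to_b = a_to_b, b_to_a = b_to_a,
       median_a_to_b = median(a_to_b), median_b_to_a = median(b_to_a),
       genes_used = shared)
}
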