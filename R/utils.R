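#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor mad median p.adjust pchisq phyper plogis predict
#'   quantile rbinom rexp rnorm rpois runif sd setNames t.test var wilcox.test
#'   cor.test fisher.test
#' @importFrom utils head read.table write.table
NULL

# Derive a stage-specific RNG seed from a root seed so that each pipeline
# stage is independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(root_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(root_seed) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
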