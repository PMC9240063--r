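#' Read gene sets from a GMT file
#'
#' GMT is the MSigDB gene-set distribution format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description column is
#' discarded and duplicate genes within a set are collapsed.
#'
#' @param gmt_file Path to a GMT file.
#' @param source_label Free-text label recorded on the collection (defaults to
#'   the file name).
#' @return A named list of character vectors (class `netbio_genesets`), with a
#'   `source_label` attribute.
#' @export
read_gmt <- function(gmt_file, source_label = basename(gmt_file)) {
  lines <- readLines(gmt_file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop(sprintf("parse error at line %d of '%s': expected name, description and at least one gene",
                   i, gmt_file), call. = FALSE)
    }
    nms[i] <- parts[1L]
    sets[[i]] <- unique(parts[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate pathway name(s) in '%s': %s", gmt_file,
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")), call. = FALSE)
  }
  names(sets) <- nms
  gene_set_collection(sets, source_label)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors; no empty sets, unique names.
#' @param source_label Free-text origin label (for example a file path).
#' @return A `netbio_genesets` object (named list of character vectors).
#' @export
gene_set_collection <- function(sets, source_label = "") {
  assert_that(length(sets) > 0, "collection must contain at least one gene set")
  assert_that(!is.null(names(sets)) && all(nzchar(names(sets))), "every gene set needs a name")
  assert_that(!anyDuplicated(names(sets)), "gene-set names must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  assert_that(all(lengths(sets) > 0), "empty gene sets are not allowed")
  structure(sets, source_label = source_label, class = c("netbio_genesets", "list"))
}

#' Write a gene-set collection to GMT
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` pathway genes when `n` genes are drawn
#' without replacement from a universe of `N` genes of which `K` belong to the
#' pathway: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param N Universe size.
#' @param K Pathway genes in the universe.
#' @param n Drawn (target-proximal) genes in the universe.
#' @param k Overlap between the pathway and the drawn genes.
#' @return The upper-tail p-value in `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(N, K, n, k) {
  assert_that(all(c(N, K, n, k) >= 0), "counts must be non-negative")
  assert_that(K <= N && n <= N, "K and n cannot exceed the universe size N")
  assert_that(k <= min(K, n), "overlap k cannot exceed min(K, n)")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Sorts the p-values ascending, applies the Sidak-type per-step adjustment
#' `1 - (1 - p_(i))^(m - i + 1)`, enforces monotonicity with a running
#' maximum, caps at 1, and returns the adjusted values in the original input
#' order.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
holm_sidak_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Select pathways enriched with target-proximal genes
#'
#' The core biomarker-selection step: each pathway is tested for
#' over-representation of the network-proximal genes with an upper-tail
#' hypergeometric test over a common gene universe, p-values are adjusted
#' jointly with the Holm-Sidak procedure, and pathways with adjusted p below
#' `alpha` are flagged as selected (the NetBio pathways). Pathways with no
#' gene in the universe cannot be tested and are skipped before correction
#' (their count is reported).
#'
#' @param proximal Character vector of target-proximal genes (e.g. the top-200
#'   influence-score genes); intersected with the universe before testing.
#' @param collection A gene-set collection (named list of character vectors).
#' @param universe Character vector: the gene population both the proximal
#'   draw and the pathway memberships are referred to. See
#'   [netbio_universe()].
#' @param alpha Adjusted-p selection threshold (default 0.01).
#' @param min_size,max_size Optional pathway-size filter applied after
#'   intersection with the universe (default: no filter).
#' @return A data.frame with columns `pathway`, `N`, `K`, `n`, `k`, `p_raw`,
#'   `p_adjusted`, `selected`, sorted by ascending adjusted p then pathway
#'   name.
#' @export
select_netbio_pathways <- function(proximal, collection, universe, alpha = 0.01,
                                   min_size = 1L, max_size = Inf) {
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  universe <- unique(as.character(universe))
  proximal <- intersect(unique(as.character(proximal)), universe)
  assert_that(length(proximal) > 0, "no proximal genes fall inside the universe")
  N <- length(universe)
  n <- length(proximal)

  in_univ <- lapply(collection, intersect, y = universe)
  sizes <- lengths(in_univ)
  skipped <- sum(sizes == 0)
  if (skipped > 0) {
    message(sprintf("select_netbio_pathways: skipped %d pathway(s) with no gene in the universe", skipped))
  }
  keep <- sizes >= max(1L, min_size) & sizes <= max_size
  in_univ <- in_univ[keep]
  assert_that(length(in_univ) > 0, "no testable pathway after universe intersection")

  K <- lengths(in_univ)
  k <- vapply(in_univ, function(s) length(intersect(s, proximal)), integer(1))
  p_raw <- vapply(seq_along(in_univ), function(i) hypergeometric_pvalue(N, K[i], n, k[i]),
                  numeric(1))
  p_adj <- holm_sidak_adjust(p_raw)
  res <- data.frame(
    pathway = names(in_univ), N = N, K = as.integer(K), n = n, k = as.integer(k),
    p_raw = p_raw, p_adjusted = p_adj, selected = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res[order(res$p_adjusted, res$pathway), , drop = FALSE]
}

#' Gene universe for the enrichment test
#'
#' Both the drawn genes (proximal set) and the urn (pathway membership) must
#' live in one population. The default intersects the network's genes with
#' the union of all collection genes; `"network"` and `"collection"` use each
#' side alone.
#'
#' @param net Undirected igraph graph (usually the largest connected
#'   component).
#' @param collection Gene-set collection.
#' @param mode One of `"intersection"` (default), `"network"`,
#'   `"collection"`.
#' @return Character vector of universe genes.
#' @export
netbio_universe <- function(net, collection, mode = c("intersection", "network", "collection")) {
  mode <- match.arg(mode)
  net_genes <- igraph::V(net)$name
  coll_genes <- unique(unlist(collection, use.names = FALSE))
  switch(mode,
    intersection = intersect(net_genes, coll_genes),
    network = net_genes,
    collection = coll_genes
  )
}
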