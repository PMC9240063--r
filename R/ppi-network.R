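#' Load a scored protein-protein interaction network (STRING dialect)
#'
#' Reads a whitespace/tab-delimited edge list with two identifier columns and
#' one integer combined-score column (0-1000), as distributed by STRING
#' (`protein1 protein2 combined_score`, optional header). Edges at or below
#' the score threshold are discarded, self-loops are dropped and duplicate
#' undirected pairs are collapsed. High-confidence networks use scores
#' strictly greater than 700; set `inclusive = TRUE` for a `>=` predicate
#' (community usage of the threshold is ambiguous, and reported node/edge
#' counts should be checked under both).
#'
#' @param edge_file Path to the edge list.
#' @param score_threshold Integer score cutoff (default 700).
#' @param aliases Optional path to a two-column TSV mapping raw protein
#'   identifiers (e.g. `9606.ENSP...`) to gene symbols. Edges with an
#'   unmapped endpoint are dropped and the count is reported.
#' @param inclusive If `TRUE`, keep edges with score `>= score_threshold`
#'   instead of the default strict `>`.
#' @return An undirected [igraph][igraph::igraph-package] graph with a
#'   `combined_score` edge attribute; nodes are the endpoints of retained
#'   edges.
#' @export
load_string_network <- function(edge_file, score_threshold = 700, aliases = NULL,
                                inclusive = FALSE) {
  first <- data.table::fread(edge_file, nrows = 1L, header = FALSE,
                             showProgress = FALSE)
  assert_that(ncol(first) >= 3,
              sprintf("edge file '%s' must have at least 3 columns (node, node, score)", edge_file))
  # a header row is one whose third token is not numeric
  header_offset <- if (is.na(suppressWarnings(as.numeric(as.character(first[[3L]]))))) 1L else 0L
  dt <- data.table::fread(edge_file, header = header_offset == 1L,
                          data.table = TRUE, showProgress = FALSE)
  dt <- dt[, 1:3]
  data.table::setnames(dt, c("protein1", "protein2", "combined_score"))
  score_chr <- as.character(dt$combined_score)
  score_num <- suppressWarnings(as.numeric(score_chr))
  if (anyNA(score_num)) {
    bad <- which(is.na(score_num))[1L]
    stop(sprintf("parse error at line %d of '%s': non-numeric score '%s'",
                 bad + header_offset, edge_file, score_chr[bad]), call. = FALSE)
  }
  if (any(score_num != round(score_num))) {
    bad <- which(score_num != round(score_num))[1L]
    stop(sprintf("parse error at line %d of '%s': non-integer score '%s'",
                 bad + header_offset, edge_file, score_chr[bad]), call. = FALSE)
  }
  dt$combined_score <- as.integer(score_num)
  dt$protein1 <- as.character(dt$protein1)
  dt$protein2 <- as.character(dt$protein2)
  if (anyNA(dt$protein1) || anyNA(dt$protein2) || any(dt$protein1 == "") || any(dt$protein2 == "")) {
    bad <- which(is.na(dt$protein1) | is.na(dt$protein2) | dt$protein1 == "" | dt$protein2 == "")[1L]
    stop(sprintf("parse error at line %d of '%s': missing node identifier",
                 bad + header_offset, edge_file), call. = FALSE)
  }

  if (!is.null(aliases)) {
    am <- data.table::fread(aliases, header = FALSE, data.table = FALSE)[, 1:2]
    names(am) <- c("id", "symbol")
    map <- setNames(as.character(am$symbol), as.character(am$id))
    before <- nrow(dt)
    dt$protein1 <- unname(map[dt$protein1])
    dt$protein2 <- unname(map[dt$protein2])
    dt <- dt[!is.na(dt$protein1) & !is.na(dt$protein2), ]
    dropped <- before - nrow(dt)
    if (dropped > 0) {
      message(sprintf("load_string_network: dropped %d edge(s) with unmapped protein identifiers", dropped))
    }
  }

  keep <- if (inclusive) dt$combined_score >= score_threshold else dt$combined_score > score_threshold
  dt <- dt[keep, ]
  dt <- dt[dt$protein1 != dt$protein2, ]
  if (nrow(dt) == 0) {
    stop(sprintf("no edges remain after filtering '%s' at score threshold %d",
                 edge_file, score_threshold), call. = FALSE)
  }
  # canonical undirected orientation, then dedup
  a <- pmin(dt$protein1, dt$protein2)
  b <- pmax(dt$protein1, dt$protein2)
  ed <- data.frame(from = a, to = b, combined_score = dt$combined_score,
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$from, ed$to, sep = "\r")), ]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  g
}

#' Extract the largest connected component of a network
#'
#' Downstream propagation operates on the largest connected component. When
#' several components tie for the maximum size, the component containing the
#' lexicographically smallest node name is returned, so the result is
#' deterministic.
#'
#' @param net An undirected igraph graph.
#' @return The induced subgraph on the largest component.
#' @export
largest_connected_component <- function(net) {
  assert_that(igraph::vcount(net) > 0, "cannot take the largest component of an empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: pick the component holding the lexicographically smallest node
    nm <- igraph::V(net)$name
    first_node <- vapply(best, function(ci) min(nm[comp$membership == ci]), character(1))
    best <- best[order(first_node)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Spread seed influence over the network with personalized PageRank
#'
#' Runs a random walk with restart from the drug-target seed genes: each
#' undirected edge is treated as two directed edges, transition probabilities
#' are uniform over a node's neighbors (column-normalized by degree), and the
#' walker restarts with probability `1 - damping` at a seed chosen uniformly
#' among the seeds present in the network (personalization 1 on seeds, 0
#' elsewhere). Iteration stops when the L1 change drops below `tol` or after
#' `max_iter` sweeps; a non-converged run is flagged and warned about, never
#' silent. The stationary scores are probability masses summing to 1; genes
#' closer to the seeds receive higher influence scores.
#'
#' @param net Undirected igraph graph.
#' @param seeds Character vector of seed gene symbols (e.g. PDCD1, CD274,
#'   CTLA4). Seeds absent from the network are reported via a warning.
#' @param damping Damping factor in (0,1); default 0.85.
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter Maximum number of power iterations (default 100).
#' @param weighted If `TRUE`, transition probabilities are proportional to the
#'   `combined_score` edge attribute instead of uniform over neighbors.
#' @return An object of class `netbio_propagation`: a list with `scores`
#'   (named numeric over all nodes), `damping`, `seeds`, `missing_seeds`,
#'   `converged`, and `iterations`.
#' @export
propagate <- function(net, seeds, damping = 0.85, tol = 1e-6, max_iter = 100,
                      weighted = FALSE) {
  assert_that(length(seeds) > 0, "seed set must be non-empty")
  assert_that(damping > 0 && damping < 1, "damping must lie strictly in (0, 1)")
  nodes <- igraph::V(net)$name
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, nodes)
  missing <- setdiff(seeds, nodes)
  if (length(present) == 0) {
    stop("none of the seed genes are present in the network", call. = FALSE)
  }
  if (length(missing) > 0) {
    warning(sprintf("propagate: %d seed(s) absent from the network: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }

  n <- length(nodes)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE,
                                   attr = if (weighted) "combined_score" else NULL)
  A <- methods::as(A, "dMatrix")
  out_strength <- Matrix::colSums(A)
  inv <- ifelse(out_strength > 0, 1 / out_strength, 0)
  # column-stochastic transition matrix (dangling columns stay zero; their
  # mass is redistributed to the restart vector each sweep)
  P <- A %*% Matrix::Diagonal(n, inv)

  e <- numeric(n)
  e[match(present, nodes)] <- 1 / length(present)
  s <- e
  converged <- FALSE
  iter <- 0L
  dangling <- out_strength == 0
  while (iter < max_iter) {
    iter <- iter + 1L
    dangle_mass <- if (any(dangling)) sum(s[dangling]) else 0
    s_new <- as.numeric((1 - damping) * e + damping * (P %*% s + dangle_mass * e))
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("propagate: no convergence after %d iterations (L1 tolerance %g)",
                    max_iter, tol))
  }
  s <- s / sum(s)
  structure(
    list(scores = setNames(s, nodes), damping = damping, seeds = present,
         missing_seeds = missing, converged = converged, iterations = iter),
    class = "netbio_propagation"
  )
}

#' @export
print.netbio_propagation <- function(x, ...) {
  cat(sprintf("Personalized PageRank over %d genes (damping %.2f, %d iterations%s)\n",
              length(x$scores), x$damping, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  cat("Seeds:", paste(x$seeds, collapse = ", "), "\n")
  invisible(x)
}

#' Select target-proximal genes from a propagation result
#'
#' Returns the genes with the highest influence scores: sorted by descending
#' score, with ties (in particular at the k-th boundary) broken by ascending
#' gene symbol. Seed genes themselves are eligible.
#'
#' @param prop A `netbio_propagation` object.
#' @param k Number of genes to keep (default 200). When `k` exceeds the
#'   network size all genes are returned.
#' @return Character vector of gene symbols, highest influence first.
#' @export
select_proximal_genes <- function(prop, k = 200) {
  stopifnot(inherits(prop, "netbio_propagation"))
  assert_that(k >= 1, "k must be at least 1")
  sc <- prop$scores
  ord <- order(-sc, names(sc))
  names(sc)[ord][seq_len(min(k, length(sc)))]
}

#' First-degree network neighbors of a set of target genes
#'
#' Union of the direct interactors of all targets present in the network,
#' excluding the targets themselves.
#'
#' @param net Undirected igraph graph.
#' @param targets Character vector of target gene symbols.
#' @return Character vector of neighbor gene symbols (possibly empty, with a
#'   warning).
#' @export
direct_neighbors <- function(net, targets) {
  assert_that(length(targets) > 0, "target set must be non-empty")
  targets <- unique(as.character(targets))
  present <- intersect(targets, igraph::V(net)$name)
  if (length(present) == 0) {
    stop("none of the target genes are present in the network", call. = FALSE)
  }
  nb <- unique(unlist(lapply(present, function(t) {
    igraph::V(net)$name[igraph::neighbors(net, t)]
  })))
  nb <- setdiff(nb, targets)
  if (length(nb) == 0) {
    warning("direct_neighbors: targets have no neighbors in the network")
  }
  sort(nb)
}
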