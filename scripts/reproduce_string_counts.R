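#!/usr/bin/env Rscript

# Optional reproduction script (requires a local copy of the public
# protein-links release; it is not downloaded here and no test depends on it).
#
# Verifies that loading the human protein-links file (v11.0), keeping edges
# with combined score > 700, and taking the largest connected component
# yields 16,957 nodes and 420,381 edges.
#
# Usage:
#   Rscript scripts/reproduce_string_counts.R /path/to/9606.protein.links.v11.0.txt.gz

suppressPackageStartupMessages(library(netbio))

path <- commandArgs(trailingOnly = TRUE)
if (length(path) != 1L || !file.exists(path)) {
  stop("usage: Rscript scripts/reproduce_string_counts.R <protein.links file>",
       call. = FALSE)
}

g <- load_string_network(path, 700)
lcc <- largest_connected_component(g)
nodes <- igraph::vcount(lcc)
edges <- igraph::ecount(lcc)

cat(sprintf("largest component: %d nodes, %d edges\n", nodes, edges))
cat(sprintf("expected:          16957 nodes, 420381 edges\n"))
if (nodes == 16957L && edges == 420381L) {
  cat("MATCH\n")
} else {
  cat("MISMATCH (check the release version and file variant)\n")
}
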