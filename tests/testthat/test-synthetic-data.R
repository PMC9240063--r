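# one default-condition benchmark shared by the structural tests below
bench_default <- simulate_benchmark(synthetic_config(rng_seed = 1))

test_that("the generator is deterministic for a fixed seed and differs across seeds", {
  again <- simulate_benchmark(synthetic_config(rng_seed = 1))
  expect_identical(igraph::as_edgelist(bench_default$network),
                   igraph::as_edgelist(again$network))
  expect_identical(bench_default$seeds, again$seeds)
  expect_identical(unclass(bench_default$collection), unclass(again$collection))
  expect_identical(bench_default$cohorts$A$expression, again$cohorts$A$expression)
  expect_identical(bench_default$cohorts$A$clinical, again$cohorts$A$clinical)

  other <- simulate_benchmark(synthetic_config(rng_seed = 2))
  expect_false(identical(bench_default$cohorts$A$expression,
                         other$cohorts$A$expression))

  # the generator restores the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulate_benchmark(synthetic_config(rng_seed = 3,
    n_genes = 120L, pathway_size = c(5L, 10L), n_samples = 10L, n_pathways = 8L,
    n_planted = 2L)))
  expect_identical(rnorm(3), before)
})

test_that("the network is connected, scored above threshold, and heavy-tailed", {
  g <- bench_default$network
  expect_equal(igraph::vcount(g), 1000)
  expect_true(igraph::is_connected(g))
  sc <- igraph::E(g)$combined_score
  expect_true(all(sc > 700 & sc <= 1000))
  expect_true(all(sc == round(sc)))
  deg <- igraph::degree(g)
  expect_gte(max(deg), 5 * median(deg))   # scale-free heavy tail

  # targets sit at mid-degree nodes, not hubs
  qs <- quantile(deg, c(0.4, 0.8))
  expect_true(all(deg[bench_default$seeds] >= qs[1] &
                  deg[bench_default$seeds] <= qs[2]))
  expect_length(bench_default$seeds, 2)
})

test_that("the collection plants target-proximal pathways with signed effects", {
  coll <- bench_default$collection
  expect_length(coll, 50)
  expect_true(!anyDuplicated(names(coll)))
  sizes <- lengths(coll)
  expect_true(all(sizes >= 15 & sizes <= 60))
  expect_true(all(vapply(coll, function(s) !anyDuplicated(s), logical(1))))

  expect_length(bench_default$planted, 5)
  expect_true(all(bench_default$planted %in% names(coll)))
  expect_setequal(names(bench_default$signs), bench_default$planted)
  expect_true(all(bench_default$signs %in% c(-1, 1)))
  expect_equal(sum(bench_default$signs == -1), round(0.2 * 5))

  # planted sets draw >= 80% of their genes from the targets' 2-hop zone
  hop2 <- unique(unlist(lapply(
    igraph::ego(bench_default$network, order = 2, nodes = bench_default$seeds),
    names)))
  for (pw in bench_default$planted) {
    frac <- mean(coll[[pw]] %in% hop2)
    expect_gte(frac, 0.8)
  }
  # non-planted sets live outside that neighborhood
  others <- setdiff(names(coll), bench_default$planted)
  expect_true(all(vapply(others, function(pw) !any(coll[[pw]] %in% hop2),
                         logical(1))))
})

test_that("cohorts have the configured shape, labels, survival and burden shift", {
  co <- bench_default$cohorts$A
  expect_equal(dim(co$expression), c(1000, 100))
  expect_equal(nrow(co$clinical), 100)
  expect_equal(co$clinical$sample, colnames(co$expression))
  expect_equal(sum(co$clinical$response), round(0.35 * 100))
  expect_true(all(co$clinical$recist[co$clinical$response == 1] %in% c("CR", "PR")))
  expect_true(all(co$clinical$recist[co$clinical$response == 0] %in% c("SD", "PD")))
  expect_true(all(co$clinical$os_time >= 0))
  expect_true(all(co$clinical$os_event %in% 0:1))
  expect_true(all(co$mutations$T >= 0 & co$mutations$NT >= 0))

  # responders carry a higher mutational burden (log-mean shift of 1)
  tmb <- compute_tmb(co$mutations$T, co$mutations$NT)
  expect_gt(mean(tmb[co$clinical$response == 1]),
            mean(tmb[co$clinical$response == 0]))
})

test_that("the planted expression shift matches delta within sampling error", {
  co <- bench_default$cohorts$A
  eff <- co$ground_truth$gene_effects
  r <- co$clinical$response == 1
  for (s in c(1, -1)) {
    genes_s <- names(eff)[eff == s * 1.0]
    expect_gt(length(genes_s), 10)
    diffs <- rowMeans(co$expression[genes_s, r, drop = FALSE]) -
      rowMeans(co$expression[genes_s, !r, drop = FALSE])
    se <- sqrt(1 / sum(r) + 1 / sum(!r)) / sqrt(length(genes_s))
    expect_lt(abs(mean(diffs) - s * 1.0), 3 * se)
  }
  # unaffected genes show no shift
  null_genes <- names(eff)[eff == 0]
  diffs0 <- rowMeans(co$expression[null_genes, r]) -
    rowMeans(co$expression[null_genes, !r])
  se0 <- sqrt(1 / sum(r) + 1 / sum(!r)) / sqrt(length(null_genes))
  expect_lt(abs(mean(diffs0)), 4 * se0)
})

test_that("cohort pairs share the ground truth but not the samples", {
  A <- bench_default$cohorts$A
  B <- bench_default$cohorts$B
  expect_identical(A$ground_truth$planted, B$ground_truth$planted)
  expect_identical(A$ground_truth$signs, B$ground_truth$signs)
  expect_length(intersect(colnames(A$expression), colnames(B$expression)), 0)
  expect_identical(rownames(A$expression), rownames(B$expression))
  # cohort B's effect is attenuated by the configured factor
  expect_equal(max(abs(B$ground_truth$gene_effects)), 0.8, tolerance = 1e-12)
})

test_that("fixture files round-trip and are byte-identical across runs", {
  cfg <- synthetic_config(rng_seed = 5, n_genes = 150L, pa_m = 2L,
                          n_pathways = 10L, pathway_size = c(5L, 12L),
                          n_planted = 2L, n_samples = 12L)
  b1 <- simulate_benchmark(cfg)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  p1 <- write_benchmark_fixtures(b1, d1)
  p2 <- write_benchmark_fixtures(simulate_benchmark(cfg), d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # each fixture stays within the size budget
  expect_true(all(file.size(p1) <= 64 * 1024))

  # round-trip through the package readers
  g <- load_string_network(p1[["network"]], 700)
  expect_true(all(igraph::V(g)$name %in% igraph::V(b1$network)$name))
  coll <- read_gmt(p1[["genesets"]])
  expect_identical(lapply(unclass(coll), sort),
                   lapply(unclass(b1$collection), sort))
  expr <- read_expression_tsv(p1[["expression_A"]])
  expect_equal(expr, b1$cohorts$A$expression, tolerance = 1e-10)
  clin <- read_clinical_tsv(p1[["clinical_A"]])
  expect_equal(clin$sample, b1$cohorts$A$clinical$sample)
  unlink(c(d1, d2), recursive = TRUE)
})
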