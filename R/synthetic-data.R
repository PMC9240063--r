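#' Configuration for the synthetic benchmark generator
#'
#' Defines the study conditions emulated by the generator: a scale-free
#' interaction network with designated drug targets, a pathway collection in
#' which a few pathways are planted inside the targets' network
#' neighborhood, cohorts whose responders carry a mean shift on the planted
#' pathways' genes, exponential survival tied to response, and Poisson
#' mutation counts with a responder burden shift.
#'
#' @param rng_seed Root seed; every stage derives its own sub-seed from it.
#' @param n_genes Number of genes / network nodes (default 1000).
#' @param pa_m Preferential-attachment edges per new node (default 3).
#' @param n_targets Number of drug-target seed genes (default 2), placed at
#'   mid-degree nodes (40th-80th degree percentile) to avoid hub artifacts.
#' @param n_pathways Gene sets in the collection (default 50).
#' @param pathway_size Inclusive size range of the sets (default 15-60).
#' @param n_planted Pathways planted in the targets' neighborhood (default 5).
#' @param planted_frac Minimum fraction of a planted set drawn from the
#'   targets' <= 2-hop neighborhood (default 0.8).
#' @param negative_fraction Fraction of planted pathways whose responder
#'   shift is negative, emulating negatively associated signals (default 0.2).
#' @param n_samples Samples per cohort (default 100).
#' @param responder_fraction Fraction of responders (default 0.35, matching
#'   typical checkpoint-inhibitor response rates in solid tumors).
#' @param delta Responder mean shift on planted-pathway genes, in expression
#'   SD units (default 1.0); noise is standard normal.
#' @param tmb_effect Log-scale shift of responder mutation-count means
#'   (default 1.0).
#' @param hazard_ratio Responder-vs-non-responder hazard ratio of the
#'   exponential survival times (default 0.4).
#' @param censor_fraction Fraction of samples independently censored
#'   (default 0.2).
#' @param base_median_survival Median survival of non-responders in days
#'   (default 365).
#' @param attenuation Multiplier on `delta` for the second cohort of a pair,
#'   emulating cohort shift (default 0.8).
#' @return A list of class `netbio_sim_config`.
#' @export
synthetic_config <- function(rng_seed = 1L, n_genes = 1000L, pa_m = 3L,
                             n_targets = 2L, n_pathways = 50L,
                             pathway_size = c(15L, 60L), n_planted = 5L,
                             planted_frac = 0.8, negative_fraction = 0.2,
                             n_samples = 100L, responder_fraction = 0.35,
                             delta = 1.0, tmb_effect = 1.0, hazard_ratio = 0.4,
                             censor_fraction = 0.2, base_median_survival = 365,
                             attenuation = 0.8) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
              pa_m = as.integer(pa_m), n_targets = as.integer(n_targets),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_planted = as.integer(n_planted), planted_frac = planted_frac,
              negative_fraction = negative_fraction,
              n_samples = as.integer(n_samples),
              responder_fraction = responder_fraction, delta = delta,
              tmb_effect = tmb_effect, hazard_ratio = hazard_ratio,
              censor_fraction = censor_fraction,
              base_median_survival = base_median_survival,
              attenuation = attenuation)
  assert_that(all(unlist(cfg[c("n_genes", "pa_m", "n_targets", "n_pathways",
                               "n_planted", "n_samples")]) > 0),
              "all counts must be positive")
  assert_that(cfg$responder_fraction > 0 && cfg$responder_fraction < 1,
              "responder_fraction must lie in (0, 1)")
  assert_that(cfg$censor_fraction >= 0 && cfg$censor_fraction < 1,
              "censor_fraction must lie in [0, 1)")
  assert_that(max(cfg$pathway_size) < cfg$n_genes, "pathway sizes must be below n_genes")
  structure(cfg, class = c("netbio_sim_config", "list"))
}

#' Generate a scale-free scored interaction network with designated targets
#'
#' Builds a preferential-attachment graph (connected by construction, with
#' the heavy-tailed degree distribution typical of protein interaction
#' networks), samples integer combined scores in (700, 1000], and designates
#' the target genes among mid-degree nodes.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `network` (igraph) and `seeds` (character vector of
#'   target genes).
#' @export
generate_network <- function(cfg) {
  with_seed(stage_seed(cfg$rng_seed, "network"), {
    g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$pa_m, directed = FALSE)
    igraph::V(g)$name <- sprintf("G%04d", seq_len(cfg$n_genes))
    g <- igraph::simplify(g)
    igraph::E(g)$combined_score <- sample(701:1000, igraph::ecount(g), replace = TRUE)
    deg <- igraph::degree(g)
    qs <- quantile(deg, c(0.4, 0.8))
    mid <- igraph::V(g)$name[deg >= qs[1] & deg <= qs[2]]
    seeds <- sort(sample(mid, cfg$n_targets))
    list(network = g, seeds = seeds)
  })
}

#' Generate a pathway collection with planted target-proximal sets
#'
#' Planted pathways draw at least `planted_frac` of their genes from the
#' targets' <= 2-hop network neighborhood (favoring direct interactors 3:1
#' over 2-hop genes, the way curated pathways concentrate around a hub);
#' the remaining pathways are drawn uniformly from genes outside that
#' neighborhood. If the 2-hop neighborhood is too small it is enlarged to 3
#' hops with a warning. A configurable fraction of planted pathways carries a
#' negative responder effect.
#'
#' @param cfg A [synthetic_config()].
#' @param net The network from [generate_network()].
#' @param seeds Target genes from [generate_network()].
#' @return A list with `collection` (gene-set collection), `planted`
#'   (character vector of planted pathway names) and `signs` (named +1/-1
#'   per planted pathway).
#' @export
generate_genesets <- function(cfg, net, seeds) {
  with_seed(stage_seed(cfg$rng_seed, "genesets"), {
    genes <- igraph::V(net)$name
    hop1 <- unique(c(seeds, unlist(lapply(
      igraph::ego(net, order = 1, nodes = seeds), names))))
    hop2 <- unique(unlist(lapply(igraph::ego(net, order = 2, nodes = seeds), names)))
    need <- ceiling(cfg$planted_frac * max(cfg$pathway_size))
    if (length(hop2) < need) {
      warning("generate_genesets: 2-hop neighborhood too small, enlarging to 3 hops")
      hop2 <- unique(unlist(lapply(igraph::ego(net, order = 3, nodes = seeds), names)))
    }
    outside <- setdiff(genes, hop2)
    wts <- ifelse(hop2 %in% hop1, 3, 1)

    sizes <- sample(seq(cfg$pathway_size[1], cfg$pathway_size[2]),
                    cfg$n_pathways, replace = TRUE)
    planted_idx <- sort(sample(cfg$n_pathways, cfg$n_planted))
    sets <- vector("list", cfg$n_pathways)
    for (i in seq_len(cfg$n_pathways)) {
      sz <- sizes[i]
      if (i %in% planted_idx) {
        n_in <- min(length(hop2), ceiling(cfg$planted_frac * sz))
        inside <- sample(hop2, n_in, prob = wts)
        rest <- sample(outside, sz - n_in)
        sets[[i]] <- c(inside, rest)
      } else {
        sets[[i]] <- sample(outside, sz)
      }
    }
    names(sets) <- sprintf("PW_%03d", seq_len(cfg$n_pathways))
    planted <- names(sets)[planted_idx]
    n_neg <- round(cfg$negative_fraction * cfg$n_planted)
    signs <- setNames(rep(1, cfg$n_planted), planted)
    if (n_neg > 0) signs[sample(cfg$n_planted, n_neg)] <- -1
    list(collection = gene_set_collection(sets, "synthetic"),
         planted = planted, signs = signs)
  })
}

#' Generate one synthetic patient cohort
#'
#' Baseline expression is i.i.d. standard normal per gene and sample; genes
#' belonging to planted pathways are shifted by the pathway's signed `delta`
#' in responders. Response labels follow the configured responder fraction,
#' overall survival is exponential with the configured responder hazard
#' ratio plus independent censoring, and mutation counts are Poisson with a
#' log-mean burden shift in responders.
#'
#' @param cfg A [synthetic_config()].
#' @param genesets Result of [generate_genesets()].
#' @param genes Gene universe (row names of the expression matrix).
#' @param cohort_id Prefix for sample identifiers (default "A").
#' @param delta Responder shift; defaults to `cfg$delta`.
#' @param seed Seed for this cohort; defaults to a sub-seed derived from the
#'   config seed and `cohort_id`.
#' @return A list with `expression`, `clinical` (sample, recist, response,
#'   os_time, os_event), `mutations` (sample, T, NT), and `ground_truth`
#'   (`planted`, `signs`, `gene_effects`).
#' @export
generate_cohort <- function(cfg, genesets, genes, cohort_id = "A",
                            delta = cfg$delta,
                            seed = stage_seed(cfg$rng_seed, paste0("cohort_", cohort_id))) {
  with_seed(seed, {
    n <- cfg$n_samples
    samples <- sprintf("%s_S%03d", cohort_id, seq_len(n))
    n_r <- round(cfg$responder_fraction * n)
    response <- sample(c(rep(1L, n_r), rep(0L, n - n_r)))
    recist <- ifelse(response == 1, sample(c("CR", "PR"), n, replace = TRUE),
                     sample(c("SD", "PD"), n, replace = TRUE))

    # per-gene signed effect: first planted pathway containing the gene wins
    gene_effects <- setNames(numeric(length(genes)), genes)
    for (pw in genesets$planted) {
      gs <- intersect(genesets$collection[[pw]], genes)
      newly <- gs[gene_effects[gs] == 0]
      gene_effects[newly] <- genesets$signs[[pw]] * delta
    }

    expr <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                   dimnames = list(genes, samples))
    affected <- gene_effects != 0
    if (any(affected) && n_r > 0) {
      expr[affected, response == 1] <- expr[affected, response == 1] +
        gene_effects[affected]
    }

    rate_nr <- log(2) / cfg$base_median_survival
    rate <- ifelse(response == 1, rate_nr * cfg$hazard_ratio, rate_nr)
    t_event <- rexp(n, rate)
    censored <- rbinom(n, 1, cfg$censor_fraction) == 1
    os_time <- ifelse(censored, runif(n, 0, t_event), t_event)
    os_event <- as.integer(!censored)

    mu_t <- 5 * exp(cfg$tmb_effect * response)
    mu_nt <- 15 * exp(cfg$tmb_effect * response)
    mutations <- data.frame(sample = samples, T = rpois(n, mu_t),
                            NT = rpois(n, mu_nt), stringsAsFactors = FALSE)

    clinical <- data.frame(sample = samples, recist = recist,
                           response = response, os_time = os_time,
                           os_event = os_event, stringsAsFactors = FALSE)
    list(expression = expr, clinical = clinical, mutations = mutations,
         ground_truth = list(planted = genesets$planted, signs = genesets$signs,
                             gene_effects = gene_effects))
  })
}

#' Generate a pair of cohorts sharing the same ground truth
#'
#' Both cohorts share the network, collection and planted pathways but have
#' independent samples and noise; the second cohort's effect size is
#' attenuated (`cfg$attenuation`, default 0.8) to emulate cohort shift in
#' across-study prediction.
#'
#' @param cfg A [synthetic_config()].
#' @param genesets Result of [generate_genesets()].
#' @param genes Gene universe.
#' @return A list with cohorts `A` and `B`.
#' @export
generate_cohort_pair <- function(cfg, genesets, genes) {
  list(
    A = generate_cohort(cfg, genesets, genes, cohort_id = "A"),
    B = generate_cohort(cfg, genesets, genes, cohort_id = "B",
                        delta = cfg$delta * cfg$attenuation)
  )
}

#' Generate the full synthetic benchmark
#'
#' Convenience wrapper: network with targets, pathway collection with planted
#' truth, and a cohort pair. Fully deterministic given `cfg$rng_seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `network`, `seeds`, `collection`, `planted`, `signs`,
#'   `cohorts` (list `A`, `B`).
#' @export
simulate_benchmark <- function(cfg = synthetic_config()) {
  nw <- generate_network(cfg)
  gs <- generate_genesets(cfg, nw$network, nw$seeds)
  genes <- igraph::V(nw$network)$name
  cohorts <- generate_cohort_pair(cfg, gs, genes)
  list(network = nw$network, seeds = nw$seeds, collection = gs$collection,
       planted = gs$planted, signs = gs$signs, cohorts = cohorts)
}

#' Write the synthetic benchmark as plain-text fixture files
#'
#' Emits the graph as a scored edge-list TSV, the collection as GMT,
#' expression / clinical / mutation tables per cohort as TSV, and the ground
#' truth as JSON. Files are byte-identical across runs with the same config.
#'
#' @param bench Result of [simulate_benchmark()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_benchmark_fixtures <- function(bench, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    network = file.path(out_dir, "network.tsv"),
    seeds = file.path(out_dir, "seeds.txt"),
    genesets = file.path(out_dir, "pathways.gmt"),
    expression_A = file.path(out_dir, "expression_A.tsv"),
    expression_B = file.path(out_dir, "expression_B.tsv"),
    clinical_A = file.path(out_dir, "clinical_A.tsv"),
    clinical_B = file.path(out_dir, "clinical_B.tsv"),
    mutations_A = file.path(out_dir, "mutations_A.tsv"),
    mutations_B = file.path(out_dir, "mutations_B.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  ed <- igraph::as_data_frame(bench$network, what = "edges")
  names(ed) <- c("protein1", "protein2", "combined_score")
  write.table(ed, paths[["network"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bench$seeds, paths[["seeds"]])
  write_gmt(bench$collection, paths[["genesets"]])
  for (cid in c("A", "B")) {
    co <- bench$cohorts[[cid]]
    write_expression_tsv(co$expression, paths[[paste0("expression_", cid)]])
    write.table(co$clinical, paths[[paste0("clinical_", cid)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(co$mutations, paths[[paste0("mutations_", cid)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(planted = bench$planted, signs = as.list(bench$signs),
         seeds = bench$seeds),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
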