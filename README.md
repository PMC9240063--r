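# netbio

Network-based transcriptomic biomarkers for immunotherapy response.

Response to immune checkpoint inhibitors (antibodies against PD-1, PD-L1 or
CTLA4) is hard to predict from bulk tumor transcriptomes: single-cohort,
data-driven gene signatures tend not to transfer across studies. This package
implements an alternative: treat the drug targets as seeds in a
protein-protein interaction network, spread their influence with personalized
PageRank, and use the *pathways* enriched with high-influence genes as
classifier features. Pathway-level, network-anchored features are few,
interpretable, and defined independently of any training cohort's labels,
which is what makes them transferable.

The full chain:

1. **Network** — parse a protein-links file, keep interactions with combined
   score > 700, reduce to the largest connected component
   (`load_string_network()`, `largest_connected_component()`).
2. **Influence** — personalized PageRank from the drug targets
   (damping 0.85) and selection of the top 200 proximal genes
   (`propagate()`, `select_proximal_genes()`).
3. **Pathways** — hypergeometric enrichment of proximal genes per GMT
   pathway, Holm-Šidák correction, selection at adjusted p < 0.01
   (`select_netbio_pathways()`).
4. **Activity** — single-sample GSEA scores per pathway and sample,
   range-normalized and z-standardized (`ssgsea_es()`, `normalize_es()`,
   `zscore_standardize()`).
5. **Prediction** — balanced L2 logistic regression with an inner
   cross-validated ridge grid, evaluated by leave-one-out, Monte-Carlo or
   across-study protocols (`fit_classifier()`, `loocv()`,
   `monte_carlo_cv()`, `across_study_predict()`).
6. **Satellites** — survival stratification of predicted responders
   (`survival_stratify()`), tumor-mutational-burden models and the combined
   TMB + pathway classifier (`compute_tmb()`, `combined_tmb_netbio()`), and
   weighted integration with external scores (`combine_scores()`).

A synthetic-data generator with planted, network-proximal pathway signal
(`synthetic_config()`, `simulate_benchmark()`) makes the whole method
testable end to end without downloading patient cohorts.

## Worked example

The default synthetic benchmark plants 5 target-proximal pathways among 50 in
a 1,000-gene scale-free network; this example recovers them and classifies
the cohort. All numbers below are the actual output at root seed 1.

```r
library(netbio)

bench <- simulate_benchmark(synthetic_config(rng_seed = 1))
net   <- largest_connected_component(bench$network)

pr <- propagate(net, bench$seeds)
pr
#> Personalized PageRank over 1000 genes (damping 0.85, 31 iterations)
#> Seeds: G0441, G0665

proximal <- select_proximal_genes(pr, k = 200)
enr <- select_netbio_pathways(proximal, bench$collection,
                              netbio_universe(net, bench$collection))
enr[enr$selected, ]
#>    pathway   N  K   n  k    p_raw p_adjusted selected
#> 29  PW_029 860 51 165 36 1.37e-16   5.55e-15     TRUE
#> 47  PW_047 860 58 165 38 8.68e-16   4.35e-14     TRUE
#> 10  PW_010 860 33 165 26 5.22e-14   2.50e-12     TRUE
#> 50  PW_050 860 21 165 17 9.36e-10   4.40e-08     TRUE
#> 48  PW_048 860 21 165 14 1.87e-06   8.62e-05     TRUE

bench$planted
#> [1] "PW_010" "PW_029" "PW_047" "PW_048" "PW_050"
```

All five selected pathways are exactly the five planted ones (precision and
recall 1.0). Scoring their activity and running leave-one-out
cross-validation on cohort A:

```r
es  <- ssgsea_es(bench$cohorts$A$expression,
                 bench$collection[enr$pathway[enr$selected]])
act <- zscore_standardize(normalize_es(es))
y   <- setNames(bench$cohorts$A$clinical$response,
                bench$cohorts$A$clinical$sample)

res <- loocv(t(act), y, model_spec(rng_seed = 1))
res$metrics[c("auc_roc", "accuracy", "f1", "fisher_p")]
#> $auc_roc   1
#> $accuracy  1
#> $f1        1
#> $fisher_p  9.13e-28
```

At the default planted effect (δ = 1.0 SD) the synthetic cohort is strongly
separable; the δ = 0 null lands at chance (mean leave-one-out AUROC 0.483
over three replicate cohorts).

The same chain can be driven from one configuration file:

```r
run_end_to_end(list(
  network = "network.tsv", gmt = "pathways.gmt",
  expression = "expression_A.tsv", clinical = "clinical_A.tsv",
  seeds = "G0441,G0665", out_dir = "out"
), mode = "loocv")
```

which writes `proximal_genes.txt`, `enrichment.tsv`, `activity.tsv`,
`predictions.tsv`, `metrics.json` and a `manifest.json` with a content hash
per artifact. A thin command-line wrapper lives at `inst/cli/netbio.R`
(`simulate`, `run`, `tmb` subcommands).

## Reproduction

- **Test suite** (no network access, < 5 min):

  ```r
  testthat::test_dir("tests/testthat", package = "netbio",
                     load_package = "installed")
  ```

  The suite checks every statistical primitive against an independently
  coded oracle (dense-solve PageRank, enumerated hypergeometric / Fisher /
  Mann-Whitney, loop-coded ssGSEA and Kaplan-Meier, pair-counted AUROC), the
  worked constants above, planted-signal recovery on the default benchmark,
  and byte-identical reruns. `tests/testthat/test-acceptance.R` holds the
  acceptance blocks.

- **Headline quantities** (~2 min):

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  ```

  recomputes, among others: planted-recovery precision/recall 1.0/1.0,
  LOOCV AUROC 1.0, null mean AUROC 0.483, across-study AUROC 1.0, combined
  TMB + pathway AUROC 1.0 at seed 1. Every value is computed at run time;
  the root `--seed` drives all randomness through per-stage derived seeds.

- **Public-network pin** (optional, needs the human protein-links v11.0
  file locally):

  ```sh
  Rscript scripts/reproduce_string_counts.R 9606.protein.links.v11.0.txt.gz
  ```

  verifies that filtering at score > 700 and taking the largest connected
  component yields 16,957 nodes and 420,381 edges.

## Documentation

Function reference via roxygen comments in `R/`; the methods vignette
(`vignettes/methods.Rmd`) describes the model, parameter defaults, the
synthetic generator's scope, numerical choices, and limitations.
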