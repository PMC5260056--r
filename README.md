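# pccmi

Undirected gene regulatory network (GRN) inference from expression data by
**path-consistency pruning with conditional mutual information (CMI)**, with
automatic interaction-threshold selection and a full ROC/PR evaluation
suite. The package is aimed at systems biologists who have a genes ×
conditions expression matrix (optionally with a DREAM-style gold-standard
edge list) and want a relevance network that distinguishes direct
regulatory interactions from indirect correlations.

## Method

Dependence between genes is scored under a Gaussian model via covariance
determinants. For genes *X*, *Y* and a conditioning gene set *Z*,

```
I(X;Y|Z) = 1/2 · log [ |C(X,Z)| · |C(Y,Z)| / ( |C(Z)| · |C(X,Y,Z)| ) ]
```

in nats, where `|C(·)|` is the determinant of the sample covariance of the
listed variables; with empty *Z* this reduces to plain mutual information,
`-1/2 · log(1 − ρ²)` for correlation ρ. Inference proceeds in **orders**:

* **order 0** — every pair is scored with MI and pairs above the
  interaction cutoff become edges (a relevance network);
* **order k ≥ 1** — each surviving edge (X, Y) is re-scored with the
  *maximum* CMI over all size-*k* conditioning subsets drawn from its
  common neighbors (genes connected to both X and Y); the edge survives
  only if that maximum stays above the cutoff. An edge explained away by a
  shared regulator (conditional independence) drops to CMI ≈ 0 and is
  pruned.

The cutoff can be fixed, or chosen automatically: edge counts are scanned
over a cutoff grid (0 to 1 in steps of 0.02 by default), the decay is fit
with `a·exp(−b·x) + c`, and the cutoff is taken at the intersection of the
tangents at the start and end of the fitted curve — the inflection between
the steep mass of weak pairs and the flat tail of strong interactions.

Evaluation against a gold standard reports TPR/FPR/PPV/ACC at the retained
edge set and AUROC/AUPR over the ranked pair weights. A linear-Gaussian
network simulator (random DAG + structural-equation sampling) provides
seeded benchmarks with known ground truth, including hidden-common-cause
chain motifs.

## Worked example

`chain_fixture()` builds the canonical indirect-correlation testbed: gene Z
drives X and Y (true edges Z–X and Z–Y), so X and Y are marginally
correlated but conditionally independent given Z.

```r
library(pccmi)

fx <- chain_fixture(n_samples = 1000, seed = 1)
cv <- sample_covariance(fx$expression)
mutual_information(cv, 2, 3)                            # MI(X, Y)
#> 0.5306
conditional_mutual_information(fx$expression, 2, 3, 1)  # CMI(X, Y | Z)
#> 0.000247

net <- infer_network(fx$expression,
                     inference_config(max_order = 1, threshold = "auto"))
net
#> network_state: 3 genes, 2 edges, completed order 1
#> cutoffs used: 0.403283, 0.217465

evaluate_network(net, fx$gold)$metrics
#> TPR FPR PPV ACC
#>   1   0   1   1
```

The marginal MI between X and Y (0.53 nats, close to the population value
−½·log(0.36) ≈ 0.511) would put a spurious X–Y edge in any correlation
network; conditioning on Z collapses it to ~0.0002 nats, and the order-1
pass removes it while keeping both true edges — perfect accuracy on this
fixture. The two cutoffs are the automatic thresholds chosen at order 0
(MI scale) and order 1 (CMI scale).

The same run from a shell, via the bundled script:

```sh
exec/pccmi simulate --out sim --n-genes 20 --n-samples 500 --seed 1
exec/pccmi infer --expr sim_expression.tsv --out run --max-order 1 --threshold auto
exec/pccmi eval --interactions run_interaction.tsv --relations run_relation.tsv \
                --gold sim_gold.tsv --report report.tsv
```

Each subcommand writes a JSON manifest recording the resolved settings,
input digests and per-order cutoffs, sufficient to reproduce the run.

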