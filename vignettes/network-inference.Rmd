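---
title: "Inferring regulatory networks by conditional-mutual-information pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory networks by conditional-mutual-information pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccmi)
```

## The problem

Co-expression alone is a poor proxy for regulation: two genes driven by a
shared regulator are strongly correlated without interacting. Correlation-
or MI-based relevance networks therefore accumulate indirect edges.
`pccmi` addresses this with path-consistency pruning: an edge is kept only
if no small set of common network neighbors can explain its dependence
away, as judged by conditional mutual information (CMI). The output is an
undirected network — the method ranks and tests pairwise dependence but
carries no information about regulatory direction, which is a known
limitation of this family of algorithms.

## The Gaussian information estimator

Expression profiles are modeled as jointly Gaussian. Under that
assumption, the entropy of a *d*-dimensional variable set with covariance
matrix $C$ is

$$H = \tfrac{1}{2}\,\log\!\big[(2\pi e)^{d}\,\lvert C\rvert\big],$$

and the CMI of genes $X, Y$ given a set $Z$, defined through the entropy
combination $H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)$, collapses to a pure
determinant ratio because the $(2\pi e)$ factors cancel (the dimensions
satisfy $(1{+}k) + (1{+}k) - k - (2{+}k) = 0$):

$$I(X;Y\mid Z) \;=\; \tfrac{1}{2}\,
\log\frac{\lvert C(X,Z)\rvert\,\lvert C(Y,Z)\rvert}
         {\lvert C(Z)\rvert\,\lvert C(X,Y,Z)\rvert}.$$

That cancellation is also why the estimator's dimension factor must be the
size of the variable set rather than the number of experiments: only then
does the entropy-combination form agree with the determinant-ratio form,
an identity the test suite asserts to $10^{-10}$ on random positive-
definite covariances. For a single conditioning gene the same quantity
equals $-\tfrac12\log(1-\rho^2_{XY\cdot Z})$ with $\rho_{XY\cdot Z}$ the
first-order partial correlation, which serves as an independent oracle in
the tests. All values are reported in nats.

Numerical choices:

* covariances use the unbiased $n-1$ denominator (the choice cancels in
  the determinant ratio at fixed sample size);
* determinants are floored at $10^{-12}$; a query touching the floor is
  flagged degenerate rather than aborting, so a genome-scale run survives
  collinear or duplicated genes;
* zero-variance genes score 0 with a warning;
* tiny negative results from floating-point cancellation are clamped to 0;
* the empty conditioning set uses $\lvert C(\varnothing)\rvert := 1$, so
  order-0 CMI is exactly MI;
* sub-determinant indices are sorted before evaluation, making
  $I(X;Y\mid Z)$ bit-identical under exchange of $X$ and $Y$.

## The order-stepping inference loop

`infer_network()` builds the order-0 network by thresholding pairwise MI,
then applies one `prune_step()` per order $k = 1, \dots,$ `max_order`. At
order $k$, every edge whose common-neighbor pool (genes adjacent to both
endpoints) has at least $k$ members is re-scored with the maximum CMI over
all size-$k$ subsets of that pool; it is retained only if the maximum
exceeds the cutoff strictly. Edges with fewer than $k$ common neighbors
pass through unchanged, and the loop stops early once no edge is eligible.

Two semantics were genuinely open and are fixed as follows:

* **Batch (snapshot) updates.** All CMI queries within an order use the
  adjacency as it stood when the order began; removals take effect at the
  order's end. Sequential in-place removal would make the result depend on
  edge processing order and would break the worker-invariance contract.
  With batch semantics the edge list can be partitioned into contiguous
  chunks (`partition_pairs()`, sizes differing by at most one) and
  processed in any arrangement with bit-identical results — asserted
  directly for 1, 4 and 8 workers.
* **Conditioning sets of size exactly $k$** at order $k$, not up to $k$.
  This keeps the order-$k$ edge set nested inside the order-$(k{-}1)$ set
  (monotone pruning, a tested invariant) and matches the usual practice of
  conditioning on 0, 1, 2 or 3 neighbors.

The default `max_order = 1` reflects the standard accuracy/complexity
trade-off for this algorithm family: the accuracy gain beyond one
conditioning gene is marginal while the subset enumeration grows
combinatorially; orders above 3 trigger a warning.

## Automatic threshold selection

The number of pairs above a cutoff decays roughly exponentially as the
cutoff grows. `auto_threshold()` scans a grid (default 0 to 1 in steps of
0.02; if the largest weight exceeds 1 — MI in nats is unbounded — the grid
rescales to $[0, \max w]$ with the same 51 points), fits
$y = a e^{-bx} + c$ by bounded least squares ($a > 0$, $b > 0$, $c \ge 0$;
Levenberg–Marquardt via `minpack.lm`, tolerance $10^{-8}$, at most
10{,}000 evaluations), and returns the $x$ coordinate where the tangent at
the start of the curve meets the tangent at the end — the inflection
separating the steep mass of weak pairs from the flat tail of strong
interactions. The fit is on the raw count scale; the additive floor $c$ is
needed because genome-scale scans plateau well above zero. The
intersection is invariant under scaling the counts or adding a constant,
and for a distant end point it approaches $1/b$.

Initialization matters on step-like scans: $c_0$ is the final count, $a_0$
the first count minus $c_0$, and $b_0$ comes from a log-linear regression
restricted to counts still above the floor, with a half-decay estimate as
an alternative start (regressing floored zeros yields singular gradients).
If the fit still fails or the scan is flat, a deterministic fallback
returns the grid point lying farthest *below* the chord joining the scan's
endpoints — the knee of a convex decay. The signed distance matters: the
absolute variant latches onto the terminal cliff of small scans and
returns a cutoff above every weight.

**Per-order thresholds.** In automatic mode the cutoff is re-determined at
every order, and at order $k \ge 1$ it is determined from the *updated*
weights of that order's candidate edges — after the max-CMI re-scoring,
before retention. Conditioning can only reveal redundancy, so CMI values
sit systematically below the MI values they replace; a cutoff scanned from
the pre-update MI distribution would be on the wrong scale and over-prune
(on the three-gene chain fixture it empties the network). Re-scanning the
updated distribution keeps the cutoff matched to the scale it judges. A
fixed cutoff (or one per order) remains available through
`inference_config()`.

## Evaluation

Gold standards are symmetrized to unordered pairs — the inference is
undirected, so a directed reference edge $A \to B$ counts the pair
$\{A,B\}$ as positive — and the evaluation universe is every unordered
non-self pair over the gene labels. `confusion()` and
`classification_metrics()` give TPR, FPR, PPV and ACC (undefined ratios
are returned as `NA`); `roc_pr_curves()` ranks pairs by weight, treats
tied scores as a single threshold step, and integrates both curves
trapezoidally, without PR interpolation, so reported AUPRs are directly
reproducible. The ROC area is checked against the Mann–Whitney rank
statistic to $10^{-9}$.

Two evaluation-only concepts quantify threshold quality: the **true
threshold** — the accuracy-maximizing cutoff over a grid, found by
exhaustive search with ties broken toward the smallest cutoff — and the
**offset**, $\lvert\text{true} - \text{predicted}\rvert / (\max - \min)
\times 100\%$ of the grid range, with 5/10/20% read as stringent,
standard and moderate agreement.

## The synthetic benchmark

`random_dag()` draws a random topological order and includes each
earlier-to-later pair with probability `avg_degree / (n_genes − 1)`;
`simulate_expression()` then samples each gene as the weighted sum of its
parents plus independent Gaussian noise, in topological order. Defaults:
edge-weight magnitudes uniform on $[0.5, 1.5]$ with random signs (keeping
every true effect well away from zero, where recovery is ill-posed) and
noise standard deviation 0.5, matching the chain fixture's
signal-to-noise. The linear-Gaussian model is chosen deliberately: the
estimator's Gaussian assumption then holds *exactly*, and population MI
and CMI values are available in closed form for oracles (the chain's
$\rho_{XY} = 0.8$, MI $= 0.5108$ nats, CMI $= 0$).

That choice also bounds what the tests show. Passing them demonstrates
correct implementation of the estimator, pruning, thresholding and
scoring under the model's own assumptions; it does not certify
performance on real expression data, where regulation is nonlinear,
noise is non-Gaussian, feedback loops violate acyclicity and measured
genes are a subset of the true causal field. Kinetic/ODE-style simulators
and real compendia are the appropriate external checks.

Problem sizes used in the test suite were chosen to keep the full run
near ten seconds while leaving the statistics clearly resolved: chains at
$n = 1000$ over 20 seeds, recovery at 20 genes × 500 samples over 10
seeds, worker invariance at 50 genes, and null AUROC at 10,000 pairs.
Medians are compared, not tails, so individual seeds may fluctuate.

## Known limitations

* No edge directionality, by construction.
* The Gaussian estimator underestimates dependence that is strongly
  nonlinear or non-monotone; no binning/kernel estimator is provided.
* The automatic threshold assumes the count-vs-cutoff curve is broadly
  decay-shaped; adversarial weight distributions fall back to the elbow
  heuristic, which is deterministic but heuristic nonetheless.
* Conditioning sets are drawn from common neighbors only, so a regulator
  missing from the order-0 network can never be conditioned on
  (inherited from the path-consistency scheme).
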