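---
title: "Methods: KATZ walk counting for lncRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KATZ walk counting for lncRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katzlda)
```

## The prediction problem

Experimentally confirmed lncRNA–disease associations are sparse: curated
collections hold on the order of hundreds of pairs over comparable numbers
of lncRNAs and diseases, i.e. one to a few known partners per entity. The
method implemented here scores *every* unknown pair simultaneously by
measuring network proximity in a heterogeneous graph that couples the
known bipartite association network with similarity networks on each side.
The working assumption is the standard one in this literature: similar
diseases tend to associate with functionally similar lncRNAs, so a
candidate pair connected by many short paths through known associations
and strong similarity edges is likely real.

## The KATZ score

Let $A \in \{0,1\}^{nl \times nd}$ be the association adjacency, $LS$ and
$DS$ the integrated lncRNA and disease similarity matrices, and

$$A^\ast = \begin{pmatrix} LS & A \\ A^\top & DS \end{pmatrix}.$$

$(A^{\ast l})_{ij}$ accumulates products of edge weights over all
length-$l$ walks between nodes $i$ and $j$; the KATZ measure damps longer
walks geometrically and sums

$$S \;=\; \sum_{l \ge 1} \beta^l \, (A^\ast)^l
   \;=\; (I - \beta A^\ast)^{-1} - I
   \quad\text{for } \beta\,\rho(A^\ast) < 1,$$

of which the lncRNA × disease block is the score matrix. Both evaluation
routes are implemented and cross-checked against each other and against an
explicit walk-enumeration oracle in the test suite:

* `katz_scores_truncated()` — the series cut at order $k$;
* `katz_scores_closed_form()` — the resolvent form, which verifies the
  spectral condition at run time and refuses (reporting $\rho(A^\ast)$ and
  the largest admissible $\beta$) when it fails;
* `katz_scores()` — closed form with an automatic, warning-emitting
  fallback to the truncated series.

### Choice of $\beta$ and $k$

The damping factor is not identifiable from first principles — how best to
choose the walk-length weighting is an acknowledged open problem for KATZ-
type predictors. We default to $\beta = 0.01$ with closed-form evaluation
and truncation order $k = 4$ as the fallback, the common convention in the
KATZ link-prediction literature: $\beta$ must be small enough that
$\beta\,\rho(A^\ast) < 1$ for typical similarity-dense networks (where
$\rho$ grows roughly with the mean row sum), and at $\beta = 0.01$
contributions beyond length-4 walks are numerically negligible. Both are
plain arguments everywhere they occur. Scores are monotone in $\beta$ and
in $k$ (property-tested), so ranking behaviour degrades gracefully rather
than switching regimes as they vary.

## Similarity layers

### Disease semantic similarity (role `SS`)

Each annotated disease is represented by its ancestor-closed ontology DAG
$DAG(A) = (D(A), E(A))$. Rather than giving all terms of a DAG layer the
same weight, a term's contribution is its specificity in the corpus of
disease DAGs under study:

$$D(t) = -\log\!\big(\mathrm{count}(t) / N\big),$$

where $\mathrm{count}(t)$ is the number of disease DAGs containing $t$ and
$N$ the corpus size. A term present in every DAG (e.g. the root)
contributes nothing; a term unique to one disease contributes most. The
semantic value is $DV(A) = \sum_{t \in D(A)} D(t)$ and the similarity

$$SS(A,B) = \frac{\sum_{t \in D(A) \cap D(B)} \big(D(t) + D(t)\big)}
                 {DV(A) + DV(B)},$$

symmetric, in $[0,1]$, and $1$ on the diagonal. Design notes:

* The information-content form above is our formulation of the verbal
  requirement that more specific terms contribute more; the log base
  cancels in the ratio and is configurable.
* Occurrence counts are taken over the DAGs of the annotated disease set
  actually loaded, not over the full ontology — the corpus defines
  specificity relative to the diseases under study.
* If $DV(A) + DV(B) = 0$ (possible only when every shared term occurs in
  all DAGs, e.g. a single-disease corpus), the ratio is $0/0$; we define
  the result as 1 on the diagonal and 0 off it, with a warning, which
  preserves the unit-diagonal invariant of every similarity matrix.
* A disease mapped to several ontology terms gets the union of the
  closures as one DAG.

### Expression similarity (role `ES`)

Spearman rank correlation between lincRNA tissue-expression profiles
(midrank ties), with 0 for any pair involving an unprofiled lncRNA and for
constant profiles (undefined rank variance, logged). Negative correlations
are clamped to 0 by default: KATZ treats edge weights as nonnegative walk
capacities, and a negative capacity has no walk-counting meaning. Whether
anticorrelation should instead count as similarity (`"absolute"`) or be
kept signed (`"keep"`) is exposed for sensitivity analysis.

### Functional similarity (role `FS`)

Consumed precomputed (its derivation from lncRNA–miRNA–disease evidence is
out of scope here) and deliberately not renormalised: the upstream model's
output is treated as ground input. Loading only aligns identifiers,
symmetrizes asymmetries beyond $10^{-8}$ by averaging, and clamps to
$[0,1]$, warning in both repair cases.

### Gaussian interaction-profile kernels (roles `KD`, `KL`)

$K(a,b) = \exp(-\gamma \lVert IP(a) - IP(b)\rVert^2)$ over the binary
interaction profiles (rows/columns of $A$), with
$\gamma = \gamma' / \overline{\lVert IP \rVert^2}$ and $\gamma' = 1$ by
default, the convention of the interaction-profile-kernel literature. For
binary profiles the normaliser is just the mean association count per
entity, so the kernel adapts to network density.

An entity with an all-zero profile carries no interaction evidence, yet
the raw kernel would declare two such entities maximally similar
($\lVert 0 - 0 \rVert = 0$). The default `zero_profile = "isolate"` policy
therefore zeroes their off-diagonal kernel entries (diagonal 1), letting
the integration fall back to semantic/expression/functional sources. This
is what makes the predictor usable for new diseases and new lncRNAs and is
exercised every time cross-validation masks an entity's last association.

### Integration (roles `DS`, `LS`)

$$DS_{ij} = \begin{cases}\tfrac12 (SS_{ij} + KD_{ij}) & i,j \in IS\\
            KD_{ij} & \text{otherwise}\end{cases}
\qquad
LS_{ij} = \frac{we_{ij}\,ES_{ij} + wf_{ij}\,FS_{ij} + KL_{ij}}
               {we_{ij} + wf_{ij} + 1},$$

with $IS$ the ontology-annotated disease set and $we$/$wf$ the binary
pair indicators of expression/functional coverage. The combination
weights are deliberately trivial (equal): this family of methods has been
reported robust to the choice, and no held-out dataset is available here
to tune them against, so the defaults are uniform and the weight vectors
are exposed as arguments for sensitivity analysis rather than optimised.

## Evaluation protocol

All protocols rank held-out known associations among *candidate* pairs
(pairs without known evidence) and summarise with ROC/AUC where smaller
rank = better:

* **global LOOCV** — each known pair left out in turn, ranked against all
  unknown pairs;
* **local LOOCV** — ranked only against the unknown lncRNAs of the test
  pair's disease (candidate count $nl - \deg(d)$);
* **repeated k-fold** — associations partitioned at random (default 5
  folds), each fold masked together, per-division AUC pooled over folds;
  mean ± sd over divisions (default 100).

Masking removes held-out pairs from the adjacency handed to the scoring
closure, which by default recomputes the Gaussian kernels from the masked
network — the conservative, leakage-free reading; whether the original
protocol refit kernels per fold is unknowable, so a `"freeze"` policy is
provided for comparison. A test entity left with no remaining associations
is still scored via the zero-profile fallback, never skipped silently.

ROC points come from sweeping all achievable rank cutoffs. Because
candidate counts can differ across test samples (local LOOCV), pooling
happens on the normalised-rank scale $p = (\mathrm{rank}-1)/m$; the
trapezoidal area then equals the mean per-sample Mann–Whitney statistic
(ties counted half), which the suite verifies against an independent
pairwise-ordering oracle to $10^{-10}$. With equal candidate counts (the
global protocols) this coincides with score-scale pooling. A constant
scorer gets exactly AUC 0.5 under the midrank convention.

## Synthetic data generators

No real curated inputs ship with the package, so seeded generators emulate
each of the four input types, and all tests and the acceptance script run
on them:

* `random_network()` — i.i.d. Bernoulli bipartite adjacency;
* `synthetic_dag_corpus()` — a layered random ontology (root → module
  subtrees → internal levels → disease leaf terms; edges always point
  deeper, hence acyclic by construction), with a configurable fraction of
  diseases annotated;
* `synthetic_expression()` — block-structured log-normal profiles:
  modules share a latent tissue pattern plus noise;
* `synthetic_functional_similarity()` — block baseline plus bounded
  noise over a covered lncRNA subset;
* `planted_signal_network()` / `planted_fixture()` — the benchmark:
  lncRNA and disease modules are paired, and with
  $s = 2\cdot\mathrm{signal\_strength} - 1$ the outside-module association
  probability is $\mathrm{density}\cdot(1-s)$ while the inside probability
  is solved so the *overall* expected density stays fixed. Signal
  strength 0.5 therefore reduces exactly to an unstructured Bernoulli
  network and 1 to a block-diagonal one, so recovery can be read as a
  function of signal at constant sparsity. The ontology, expression and
  functional generators reuse the same module labels, so every similarity
  layer carries the planted signal the way real side information would.

Each generator derives its own sub-seed as
$(\mathrm{seed}\cdot 101 + \mathrm{offset}) \bmod (2^{31}-1)$ with a fixed
per-generator offset, so adding a generator never perturbs another's
output at the same master seed.

The default benchmark condition is $nl = 60$, $nd = 40$, density 0.05,
four paired modules, ontology depth 4, 22 tissues, 80% of diseases
annotated and 80% of lncRNAs profiled — sparse like real association data
(~2–3 partners per entity) yet small enough that full LOOCV plus 100
5-fold divisions complete in seconds on one CPU. The signal-recovery
analysis averages 5-fold AUC (2 divisions per network) over 10 generator
seeds per signal level.

What passing on these fixtures does **not** show: real association data
are not module-random — their degree distribution is heavy-tailed, name
curation is messy, and the similarity sources are biased toward
well-studied entities. The synthetic results validate the machinery
(scores equal walk counts, CV is calibrated and leak-free, signal present
in the inputs is recovered monotonically), not biological performance on
any particular database snapshot; headline AUCs on real curated data
depend on the data vintage and are not reproducible from this package
alone.

## Numerical choices and degenerate inputs

* Similarity matrices are validated (finite, symmetric within $10^{-10}$,
  then symmetrized exactly; range-checked per role) at construction.
* Identifier lists are sorted with C-locale radix order after loading, so
  matrix layouts are reproducible regardless of input row order and OS
  locale. Identifiers are whitespace-trimmed, case-sensitive by default
  (gene symbols are case-meaningful); a case-folding mode keeps the first
  spelling seen.
* Ties anywhere (expression ranks, candidate ranking, ROC) use the
  midrank convention consistently.
* The truncated/closed-form agreement is tested at $k$ chosen so
  $(\beta\rho)^k < 10^{-10}$, at tolerance $10^{-8}$.
* All-zero adjacency makes the kernel bandwidth undefined: a
  configuration error by design, since a network with no associations at
  all cannot anchor the method.

## Known limitations

* Association evidence enters only as 0/1; evidence strength and counts
  are discarded at load time (duplicates collapse).
* The equal integration weights and $\beta$ are conventions, not fitted
  values; results on real data will be sensitive to both.
* Entities absent from every similarity source *and* without associations
  are unrankable in any meaningful sense; they receive near-zero scores
  rather than being excluded.
* The kernel similarity is computed from the same association matrix the
  evaluation masks, so dense rows are favoured — a known bias of
  interaction-profile kernels that integration mitigates but does not
  remove.
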