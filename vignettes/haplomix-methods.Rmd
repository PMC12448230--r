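---
title: "Direct haplotype inference with haplomix: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct haplotype inference with haplomix: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomix)
```

## The problem

A K-ploid genome (or a mixture of cell populations) carries K haplotypes —
whole chromosome-scale sequences that differ from a common reference by
substitutions, insertions and deletions. The mainstream route to haplotypes
is two-stage: call variants first, then phase them. The weakness of that
route is that variant-calling uncertainty never reaches the phasing stage,
and with long-read data the elevated indel error rate makes both stages
fragile, especially at low coverage and higher ploidy.

haplomix instead treats the aligned reads themselves as the data and infers
the K consensus haplotypes directly, modelling *every* sequenced position —
not just candidate variant sites — so that the sequencing error profile is
estimated from the whole alignment and lends statistical strength to the
phasing.

## The generative model

Everything is indexed against a reference $r$ of length $L_0$ (positions
$1..L_0$; gap $g$ between positions $g$ and $g+1$).

**Evolution stage.** Each consensus $C_k$ evolves independently from $r$:
per position, no mutation / substitution / deletion with probabilities
$(\gamma_{k1}, \gamma_{k2}, \gamma_{k3})$ (a simplex); per gap, an
insertion with probability $\beta_k$. With event counts $n_{k,j}$ and $N_k$
insertion gaps,

$$P(C_k \mid r) = (1-\beta_k)^{L_0-1-N_k}\,\beta_k^{N_k}
  \prod_{j=1}^{3} \gamma_{k,j}^{\,n_{k,j}}.$$

**Sequencing stage.** A read $R_i$ drawn from $C_k$ (with prior
$\alpha_k$) covers $[s_i, e_i]$. Per comparable position it is emitted
correctly ($p_1$), mismatched ($p_2$), or starts a deletion segment
($p_3$), with $p_1+p_2+p_3=1$; per gap an insertion segment starts with
probability $p_4$. Indel segment lengths are shifted Poisson,
$L - 1 \sim \mathrm{Poi}(\lambda)$, with separate rates
$\lambda_{\mathrm{del}}, \lambda_{\mathrm{ins}}$. The read likelihood is
the product of the per-position terms, the per-segment terms
($p_3\,\mathrm{Poi}(L-1 \mid \lambda_{\mathrm{del}})$ per deletion
segment, $p_4\,\mathrm{Poi}(L-1\mid\lambda_{\mathrm{ins}})$ per insertion
segment) and $(1-p_4)$ per insertion-free gap.

**Base content.** The indicator form above does not by itself say *which*
alternative base a substitution or mismatch produces, nor the content of
inserted segments. haplomix resolves this uniformly: a
substituted/mismatched base is uniform over the 3 alternatives
($\log\frac13$ per event) and each inserted base uniform over 4
($\log\frac14$ per base). These constants make every likelihood a proper
probability of the observed sequence; they cancel from read
responsibilities only when competing consensuses agree, so they are always
included.

**Conventions for cases the indicator model leaves open.**

* A read base observed where the consensus is deleted is an insertion
  error at the adjacent gap; consensus-deleted positions are excluded from
  the per-position comparison.
* At a gap where both read and consensus carry insertions, matching
  strings are "no insertion error"; differing strings contribute one
  mismatch-equivalent per differing base. A consensus insertion absent
  from the read is one deletion segment of the inserted length.
* Reference `N` positions count as evolution matches and are excluded from
  read-emission events; read `N` states are likewise excluded.

## Fitting: Classification Annealing EM

The complete-data log-likelihood over hard assignments $z_{ik}$ sums
$\log\alpha_k + \log P(R_i \mid C_k, \psi)$ over reads and
$\log P(C_k \mid r)$ over haplotypes. The fitting loop alternates:

* **AE** — responsibilities $\propto (\alpha_k P(R_i \mid C_k, \psi))^{1/T}$,
  normalised per read in log space;
* **C** — hard labels;
* **M** — closed-form parameter updates from the classified counts
  ($\hat\alpha_k$ = count ratios, $(\hat p_1,\hat p_2,\hat p_3)$ = event
  ratios, $\hat p_4$ = insertion-gap ratio, $\hat\lambda$ = mean segment
  length minus one, $\hat\gamma, \hat\beta$ from consensus-vs-reference
  counts) and a consensus update.

**Annealing schedule.** The temperature starts at $T_0 = 10$ and cools
geometrically by $0.9$ per iteration to a floor of 1. Powering
responsibilities by $1/T$ does not change their argmax, so a deterministic
argmax classification would make the temperature inert; while $T > 1$ the
loop therefore *samples* each label from its annealed responsibilities — a
stochastic exploration that the cooling gradually hardens. At $T = 1$ the
classification is the deterministic argmax (ties to the lowest index), and
the resulting classification-EM iterations never decrease the objective.
Convergence is declared when the relative objective change at $T=1$ falls
below `tol` (default `1e-6`); `nRestarts` random restarts (default 10) are
run and the best final objective wins.

**Consensus update.** The M step over $C_k$ is coordinate ascent: a
vectorised per-position score (assigned-read emission counts plus the
evolution prior) proposes a state per position, and every proposed change
is then accepted only if the *exact* complete-data objective does not
decrease — the exactness guard is what makes the monotonicity property
hold even though deletion segments couple neighbouring positions.
Uncovered positions revert to the reference state (the prior argmax).
Insertions are called at gaps where at least half of the covering assigned
reads carry one, again by exact likelihood comparison (the modal inserted
string is the candidate). Empty components are re-seeded with the single
worst-fitting read rather than deleted, keeping K fixed during a fit.

**Numerical floors.** Probability estimates are floored at $10^{-12}$
(simplexes renormalised) and $\lambda$ at $10^{-6}$, so zero-count fits
keep finite log-likelihoods; tests of the monotone trace allow `1e-8`
slack for this clamping. Position-update ties carry a `1e-9` bonus for the
incumbent state to prevent churn.

**Choosing K.** AIC/BIC are unsuitable here (the consensus "parameter"
dimension rivals the sample size), so K is chosen by five-fold
cross-validation on held-out MECR: fit on four folds, score the held-out
reads against the fitted haplotypes, and pick the K minimising the mean.
Because held-out MECR keeps improving marginally past the true ploidy,
near-ties within one standard error of the minimiser resolve toward the
smaller K.

## Evaluation statistics

**CPR** (correct phasing ratio): the fraction of true-SNV alleles
reproduced by the inferred haplotypes under the optimal one-to-one
matching $\chi$ between inferred and true haplotypes (exhaustive over the
$K!$ permutations). The true SNV set of haplotype $k$ defaults to its
substitution positions relative to the reference.

**MECR** (minimum error correction ratio): per-read best-haplotype
inconsistency, $\sum_i \min_k \sum_{j \in O_i} 1(R_i(j) \neq \hat H_k(j))
/ \sum_i |O_i|$, with interest sets $O_i$ defaulting to all covered
positions and restrictable to a site list. MECR needs no truth, which is
what makes it usable on real data; on simulations it correlates negatively
with CPR (see the study below).

## The simulator

The simulator is the generative model run forward, plus the pragmatics of
long-read data:

* **Error presets.** Three aggregate levels (percent mismatch / insertion
  / deletion per position): Level 1 = (1.30, 0.087, 0.34), Level 3 =
  (1.68, 8.04, 3.16), Level 2 their midpoint (1.49, 4.0635, 1.75). The
  aggregate indel rates fold the per-segment start probability and the
  segment length together; haplomix fixes
  $\lambda_{\mathrm{ins}} = \lambda_{\mathrm{del}} = 1$ and solves
  $p_3 (1+\lambda_{\mathrm{del}})$ and $p_4 (1+\lambda_{\mathrm{ins}})$
  to match the aggregates — an interpretation, since only the aggregates
  are published.
* **Evolution presets.** $\gamma = (0.9989, 0.001, 0.0001)$ with
  $\beta = 10^{-4}$ for both haplotypes at K=2 (weights $(0.6, 0.4)$);
  K=3 adds a higher-mutation third haplotype
  $(0.98572, 0.0139, 0.00038)$, $\beta = 3.8\times10^{-4}$, weights
  $(0.4, 0.4, 0.2)$.
* **Read lengths.** The real panel's empirical length table is not
  available, so the default is log-normal (median 1500 bp, sdlog 0.35,
  clipped to $[500, L_0]$) — a realistic long-read panel shape; an
  explicit empirical table can be supplied.
* **Structural variants.** Optionally, long variations of the five
  classical types (insertion, deletion, duplication, inversion,
  translocation) at uniform loci with lengths uniform over
  $\{50, 100, 500\}$; per-type probabilities are configurable (uniform by
  default). The inference model deliberately does *not* model SVs — they
  enter simulations only as model misspecification stress.
* **Recorded truth.** Every read carries its source haplotype and the
  events the generator injected, kept by the generator's own bookkeeping;
  tests verify the event summariser re-derives them exactly. One
  simplification: a gap holding a true consensus insertion is copied
  verbatim into the read (no insertion error is layered on top of a true
  insertion); such gaps are rare at all presets ($\beta \le 3.8\times
  10^{-4}$ per gap).

What the simulator does **not** emulate: instrument-specific artifacts
(homopolymer-dependent errors, chimeric reads), base-quality strings, and
recombination between haplotypes. Tests passing on simulated data
therefore validate the estimator under its own model class (plus the SV
misspecification), not robustness to every real-data artifact.

## Validation studies shipped with the package

Each study is an exported function that generates its data, runs the
fitter and returns a tidy summary; `scripts/acceptance.R` re-runs them
from scratch. Problem sizes are the package's own choices, stated here:

* `microExhaustiveStudy()` — n = 6 reads, K = 2, $L_0 = 12$: the global
  optimum over all $2^n$ labelings (each at its conditionally optimal
  consensuses and parameters, M step iterated to a fixed point) is
  compared with the best of 20 CAEM restarts; the gap is ~0.
* `recoveryStudy()` — the reference recovery conditions: K = 2, Level-1
  errors, $L_0 = 6000$, 200 reads, 10 seeds; reports CPR and the relative
  error of $\hat p_2$ (typical medians: CPR 1.0, error ~1%).
* `selectionStudy()` — generating ploidy cycling {1, 2, 3} on a
  well-separated 300 bp backbone (substitution rate 0.02, 60 reads),
  selection over K ∈ 1..4 by five-fold CV-MECR.
* `anticorrelationStudy()` — 36 triploid datasets spanning error levels
  1–3 and coverages {18, 48} reads with single-restart fits; Spearman
  correlation between MECR and CPR. The low-coverage triploid regime is
  deliberate: the negative correlation is carried by datasets where fit
  quality varies, and at saturated coverage both scores pin to their
  ceilings and carry no rank signal.

The separated small-backbone conditions (elevated substitution rate
0.02/position) are used where the study needs many fits in little time;
they keep per-read haplotype information comparable to long reads on a
human-scale gene while making each fit hundreds of times cheaper.

## Known limitations

* Long variations are not modelled during inference (low evolutionary
  probability, breakpoints unidentifiable at low coverage); they are
  supported only as simulation stress.
* All haplotypes are assumed to descend from the single reference —
  recombination between haplotypes is outside the model.
* Base qualities are ignored; the emission model is sequence-only.
* For long contigs, ingest supports `region` slicing; fitting one
  multi-megabase contig in a single pass is not the intended use.

```{r session}
sessionInfo()
```
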