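---
title: "Assembling multistage tests under cognitive diagnosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling multistage tests under cognitive diagnosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cdmst builds computerized multistage tests (MST) on top of cognitive
diagnosis models (CDMs). A multistage test routes examinees through a panel
of difficulty-leveled modules — here three stages, with easy, medium and
hard second- and third-stage modules and three *primary pathways*
(medium→easy→easy, medium→medium→medium, medium→hard→hard). Classical MST
assembly leans on item-response-theory quantities (a difficulty parameter
`b` on the ability scale, Fisher information as the statistical target).
Neither exists in a CDM, where the latent variable is a discrete vector of
binary skills. The package therefore implements the two substitute indexes
that make CDM-based assembly possible — a probability-scale item-difficulty
index and a tetrachoric attribute-reliability target — and a greedy
heuristic (NWADH) that assembles parallel panels against them. This
vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the bundled simulation study demonstrates.

## The response model

Items follow the saturated identity-link G-DINA model. With `K` binary
attributes, an item measuring the attributes flagged in its Q-matrix row
splits examinees into `2^{K*}` *reduced patterns* (`K*` = number of
measured attributes), and

$$P(X_j = 1 \mid \alpha^*) \;=\; \delta_{j0} + \sum_k \delta_{jk}\alpha_k +
\sum_{k<k'} \delta_{jkk'}\alpha_k\alpha_{k'} + \dots$$

Each reduced pattern carries its own success probability; the delta
expansion and the probability table are exactly interconvertible (a Möbius
inversion over subsets, `delta_from_probs()` / `probs_from_delta()`), and
the package stores the table form. Monotonicity — mastering a superset of
measured attributes never lowers the success probability — is enforced by
construction in simulated items and is a tested invariant.

## The difficulty index and its binning

The CD difficulty of item `j` is its mean correct-response probability over
all `2^K` knowledge states,

$$\mathrm{Diff}_j = 2^{-K} \sum_{c} P_j(\alpha_c),$$

which reduces to the unweighted mean of the reduced-pattern table because
every reduced pattern covers equally many full states. Lower values mean
harder items. Because `Diff` lives on the probability scale it supports the
MST convention of splitting the bank into three equal-width difficulty
intervals between the realized minimum and maximum (`bin_difficulty()`);
the top interval is the *easy* bin. Intervals are half-open on the right
except the topmost, so every item gets exactly one label; a bank with zero
difficulty spread is rejected rather than binned arbitrarily.

The index is validated against the Rasch model: `rasch_calibrate()` fits
the one-parameter logistic model by marginal maximum likelihood and
`difficulty_correlation()` reports the (negative) Pearson correlation
between `Diff_j` and `b_j`. The acceptance suite requires the magnitude to
reach 0.85 at the study's size (100 items, 1000 examinees).

## Attribute reliability

The statistical assembly target is the test–retest style attribute
reliability: from the posterior over knowledge states (computed with the
items' true parameters and a uniform prior, `posterior_over_states()`),
marginal mastery probabilities $\hat p_{ek}$ give, per attribute, a 2×2
*replication table*

$$p_{11} = \overline{\hat p^2},\quad p_{10} = p_{01} =
\overline{\hat p(1-\hat p)},\quad p_{00} = \overline{(1-\hat p)^2},$$

whose tetrachoric correlation $u_k$ is the reliability of the attribute-`k`
classification. The assembly steers every $u_k$ toward a target (0.90 per
attribute in the bundled design).

Numerics: the bivariate-normal quadrant probability is computed through the
Plackett identity $\partial \Phi_2/\partial\rho = \phi_2$, with the
substitution $r = \sin\theta$ that removes the endpoint singularity; the
resulting smooth integrand is handled by a fixed 48-node Gauss–Legendre
rule, and the correlation is found by a safeguarded Newton iteration (exact
derivative, bisection fallback) to 1e-10 on the quadrant probability. The
replication table is symmetric with equal thresholds, which the fast path
exploits; `tetrachoric()` also accepts general tables. Since
$\overline{\hat p^2} \ge \overline{\hat p}^2$, fitted reliabilities are
nonnegative. A degenerate margin (an attribute classified with certainty
for every examinee) has no finite tetrachoric solution and is clamped to 1
with a warning.

Reliabilities during assembly are evaluated on a fixed simulated
*calibration sample* (default 1000 examinees, regenerated from the seed),
using the true generating parameters — the natural choice inside a
simulation study, and deterministic across candidate evaluations.

## The NWADH selection engine

Given `J` selected items with reliabilities $u^J$, the statistical
objective is the mean absolute deviation $d^J = \sum_k |T_k - u_k^J|/K$.
Scoring a candidate `i` appends its single likelihood factor to the cached
posterior (an incremental update, never a refit) and recomputes
$d_i^{J+1}$; the whole pool is scanned with a handful of matrix products in
compiled code. The normalized priority is $e_i = 1 - d_i^{J+1}/\sum d$ and,
with non-statistical constraints, $e_i^* = e_i + c_i/\sum c_i$, where the
content weight aggregates dynamic category weights:

$$c_i = \sum_g \left[v_{ig} W_g + (1 - v_{ig})\,\bar W\right],\qquad
\bar W = W^{max} - \tfrac1G\sum_g W_g .$$

$W_g$ is 2 while category `g` is below its minimum count, and 1 once the
minimum is met (or a finite maximum reached) — so at the start of a pathway
every minimum-bearing category is "hungry". The published form of the
content weight reads `v·W + (1+v)·W̄` with no sum over `g`; that variant
makes non-bearing items outweigh bearing ones and yields no scalar per
candidate, so the package implements the summed complement form above
(matching the NWADH literature) and keeps the published variant available
via `content_weight(form = "printed")` for comparison.

Ties on $e_i^*$ are broken by proximity to the target difficulty-bin
midpoint, then by lowest item id — deterministic and difficulty-coherent.

### Panel and pathway assembly

Assembly is top-down: targets and constraints are imposed per pathway.
For each panel:

1. **Stage 1** — five single-attribute items of medium difficulty, one per
   attribute, chosen by NWADH priority. Single-attribute first-stage items
   identify every attribute early; one per attribute is the minimal design
   achieving that.
2. **Pathways** — in order hard → medium → easy (configurable), stage-2/3
   modules are filled greedily from the pathway's difficulty bin, seeded
   from the shared stage-1 posterior. Stage sizes derive from the test
   length: 21 items → 5/8/8, 25 → 5/10/10.

Enemy items are a hard filter (the design allows zero co-occurring
enemies): a candidate sharing an enemy group with anything already in the
pathway is ineligible. Items never repeat within a panel. Across panels the
engine prefers unused items; because equal-width thirds of a bell-shaped
difficulty distribution leave outer bins with roughly 50–280 of 1000
items, a 10-panel run can exhaust an outer bin, and the engine then falls
back to items consumed by earlier panels rather than aborting. The same
fallback applies per constraint category: when a category is still below
its minimum and the unused eligible pool holds no item bearing it, reusable
bearers rejoin the candidate set — otherwise a late panel would be forced
into a violation the bank as a whole can still avoid. The number of reused
selections is reported (`glance()`), and it is zero whenever the bank
covers the demand — in particular throughout the 5-panel conditions. We prefer this graceful degradation to hard failure because
different panels are administered to different examinees, so limited
cross-panel sharing compromises exposure control only mildly while
preserving the stated design everywhere it is feasible.

Infeasibility that survives the fallback (an outer bin smaller than a
single module) raises a classed error naming the stage and the filters
that emptied the pool.

## Evaluation criteria

`evaluate_panels()` computes, per primary pathway: the signed reliability
deviations $D_{ik} = R_{ik} - T_{ik}$; per-category constraint-violation
indicators and their sum; the model-implied expected number-correct score
$\sum_j P_j(\alpha_e)$; and Cronbach's α. Score statistics and α are
reported at two granularities — per panel, and pooled over the run's panels
— because condition-level summaries of this design are only comparable at
the pooled level (a 5-panel 21-item condition pools 105 items per pathway).
`violation_rate()` likewise offers two accountings: per condition-category
(a category counts violated if any pathway of any panel violates it;
16 categories × 4 conditions = 64 cells in the full design) and per
pathway-category (192 cells). The condition accounting is the default.

Rasch difficulties for pathway comparisons are fitted once per condition on
the union of primary-pathway items and then summarized by pathway; fitting
each pathway separately would re-center each fit and erase the between-
pathway differences the comparison is about. The MML fit fixes ability at
N(0, 1), which identifies both location and scale, so no post-hoc centering
is applied. Items answered uniformly by everyone are dropped with a
warning; 41 Gauss–Hermite nodes (Golub–Welsch) and a 1e-6 convergence
tolerance on the largest difficulty change are the defaults.

## The simulation study

`study_config()` / `run_study()` reproduce the full design: per
replication, a fresh 1000-item, 5-attribute bank (Q-matrix rows uniform on
the 31 nonzero patterns; `P(0)` and `1 − P(1)` from U(0, 0.25)), a fresh
1000-examinee calibration sample drawn uniformly from the 32 knowledge
states, assembly under a 0.90 reliability target, and the evaluation suite,
over the 2 × 2 grid of test length (21/25) × panel count (5/10). All
randomness derives deterministically from one master seed; identical seeds
give identical studies, and failed replications are recorded without
stopping the run.

The generator pins only the endpoint probabilities of each item. The
remaining reduced-pattern probabilities are drawn i.i.d. U(P(0), P(1)) and
sort-projected onto mastery-count order, which preserves the endpoints,
guarantees a valid monotone item, and matches common G-DINA simulation
practice. Two consequences are worth knowing. First, item difficulty
concentrates around 0.5 (the mean of a monotone table with pinned
endpoints), so outer difficulty bins are much thinner than the medium bin —
the motivation for the reuse fallback above. Second, every simulated item
is highly discriminating between the no-mastery and full-mastery patterns;
real calibrated banks contain weak items, correlated attributes,
non-uniform knowledge-state distributions and estimation error in the item
parameters, none of which the generator emulates. Passing tests therefore
demonstrate the engine's behavior under the stated generating conditions,
not performance guarantees for operational banks.

Item features are not modeled by the generating papers' design beyond the
constraint table, so the generator assigns content category and answer key
uniformly on 1–4, item type uniformly on 1–2, and designates 2% of the bank
as enemy pairs — enough to exercise every constraint while keeping a
1000-item bank comfortably feasible.

### Problem sizes used by the tests and the acceptance script

The original study uses 100 replications per condition. The package default
is 10, and the bundled checks use: 10 replications of the 21-item/5-panel
condition plus 3 (test suite) or 5 (acceptance script) of each remaining
condition; the difficulty-index validation runs at the full 100 × 1000
size. These sizes were chosen so a complete run stays at desk scale while
leaving the Monte-Carlo error of the reported summaries (a max deviation,
a min α, a violation rate) well inside the decision bands they are compared
against. `run_study(replications = 100)` reproduces the full design.

## Known limitations

* The assembly is greedy: each step is locally optimal (and verified
  against exhaustive single-step scoring), but no global optimality is
  claimed — the design tolerates small constraint violations rather than
  enforcing them as hard bounds (enemy items excepted).
* Attribute reliability is computed with true item parameters; the package
  deliberately does not estimate G-DINA parameters from data.
* Secondary pathways (e.g. medium→easy→medium) inherit whatever the primary
  assembly leaves; they are not separately optimized.
* Routing examinees through assembled panels (adaptive administration) is
  out of scope; the package assembles and evaluates.
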