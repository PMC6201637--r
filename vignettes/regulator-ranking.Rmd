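---
title: "Ranking transcriptional regulators for metabolite overproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking transcriptional regulators for metabolite overproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regflux)
library(dplyr)
```

`regflux` ranks transcriptional regulators (TRs) as overexpression or
downregulation targets for overproducing a chosen metabolite. It treats
metabolism and regulation as two separately parameterised layers — a
constraint-based metabolic model on one side, a signed transcriptional
regulatory network (TRN) with two-condition expression data on the
other — and couples them through per-gene scores. This vignette explains
the model, its assumptions, the tunable parameters, the numerical
choices, and what the shipped synthetic instance does and does not
demonstrate.

## The metabolic layer: nRAP and nGAP

The model is a standard constraint-based reconstruction: stoichiometric
matrix $S$, steady state $S v = 0$, flux bounds
$\alpha_n \le v_n \le \beta_n$ (mmol gDW$^{-1}$ h$^{-1}$), a biomass
reaction and a product (target) exchange. For each gene-associated
reaction $r$, flux variability analysis under the growth constraint
$v_{biomass} \ge f \cdot v_{biomass}^{max}$ gives a feasible range
$[v_{min}, v_{max}]$; the reaction is then pinned at
$v_r = v_{min} + k\,(v_{max} - v_{min})$ for $k = 0, 0.1, \dots, 1$ and
the product flux is maximised at each of the 11 points. The slope of
$v_{target}$ against $k$ — the *normalized reaction activity on product
flux*, nRAP — is the reaction's score: positive for product-favouring
reactions, negative for product-competing ones, zero for neutral ones.
Sweeping the *fractional* position $k$ rather than absolute flux keeps
low-flux reactions from receiving inflated slopes.

Assumptions worth keeping in mind: the cell is at steady state and
growth-limited (the growth fraction $f$, default 0.5, encodes how much
growth the engineered strain must retain); and the slope summarises a
possibly nonlinear response by its least-squares fit. Running the FVA
*with* the growth constraint active guarantees that every sweep point is
feasible by construction — ranges and sweeps must therefore be computed
under the same fraction, and `compute_nrap()` refuses mismatched inputs.

Slopes are distributed over genes through the reaction's
gene–protein–reaction (GPR) rule. The rule's root carries weight 1; an
`or` node (isozymes) passes its weight unchanged to every child, since
any single branch forms a functional enzyme; an `and` node with $c$
children (complex subunits) passes weight $\times c$, since each subunit
contributes a $1/c$ share. The *GPR factor* of a gene is the weight
reaching its leaf, and $nGAP_{jr} = nRAP_r / GPRf_j$:

```{r gpr}
gpr_factors(parse_gpr("(A and (B or (C and D))) or E"))
```

When a gene appears in several leaves of one rule we keep the *minimum*
factor — its strongest stoichiometric contribution. (A harmonic-sum
combination would also be defensible; the minimum was chosen because it
never understates a gene's leverage, and duplicates are rare in curated
models.) Reactions without a GPR contribute reaction scores but no gene
scores, since the factor is undefined without a gene.

### Alternative routes

The sweep scores only reactions that the *optimal* route to the product
exposes: a reaction on a parallel branch can score 0 because the other
branch compensates for any flux forced through it. The optional
extension (`alternate_rounds > 0`, off by default) disables one
optimal-support reaction per round and re-sweeps the still-zero
reactions, recording newly nonzero slopes with provenance
`"alternate"` and never overwriting primary scores. Two design points
were genuinely open here. First, a literal "knock out the
highest-|nRAP| support reaction" would pick an upstream step essential
for *any* production, after which every sweep is zero; candidates are
therefore restricted to knockouts that keep both the product reachable
and the growth demand satisfiable. Second, each round's re-sweep applies
only its own knockout (rather than accumulating them), so a route
disabled in one round can itself be scored in a later one; the candidate
pool still advances across rounds by being drawn from the model with all
previously tried knockouts applied. The procedure is a deliberately
simple stand-in for exhaustive alternative-pathway enumeration, and its
outputs are flagged as such.

### Loopless flux ranges

Plain FVA extremes can ride thermodynamically infeasible internal
cycles. With `loopless = TRUE`, each FVA optimum is post-corrected to a
cycle-free distribution: exchange fluxes are fixed at the optimum,
internal fluxes are confined to the optimum's sign box, and the total
absolute internal flux is minimised. This collapses futile cycles while
preserving all net conversions. The corrected extreme is *an attainable
loopless value*, which may undershoot the true loopless optimum (the
correction depends on which optimum the solver returned); the exact
mixed-integer loopless FVA is out of scope.

## The regulatory layer: nRS

For an edge $i \to j$ of the TRN, the *normalized regulatory strength*
is

$$nRS_{ij} = \frac{Gene_{j,prod} - Gene_{j,n\text{-}prod}}
                  {TR_{i,prod} - TR_{i,n\text{-}prod}}
            \cdot \frac{TR_{i,n\text{-}prod}}{Gene_{j,n\text{-}prod}},$$

algebraically the ratio of *relative* expression changes of target and
regulator between the producer and non-producer conditions. The
normalization matters: without it, lowly expressed TRs would receive
systematically larger strengths than highly expressed ones with the same
relative effect. It also makes nRS invariant to per-gene rescaling
applied to both conditions (unit changes, probe effects), though *not*
to rescaling one condition alone — inputs are assumed to be already
normalized intensities.

Replicate columns are averaged (arithmetic mean) per condition before
the ratio. Edges are excluded — not clamped — when the regulator's
expression change is below tolerance ($|\Delta TR| < 10^{-8} \cdot
TR_{n\text{-}prod}$) or either partner is unmeasured or non-positive:
the statistic is a ratio of ratios, and pseudocounts would invent
regulation where none was measured. Edges whose measured sign
contradicts the curated annotation (activator with negative nRS,
repressor with positive) are removed; dual-sign (±) annotations pass
either way. The filter is per-edge by default — eliminating a whole TR
for one inconsistent edge would discard valid regulon members — but
`per_tr_filter = TRUE` restores the stricter whole-TR elimination for
users who want it. All exclusions are counted and reported by reason.

## Coupling and screening: TRE and the randomization filter

$TRE_i = \sum_{j,r} nRS_{ij} \cdot nGAP_{jr}$ sums over every metabolic
gene the TR regulates and every reaction carrying that gene. To guard
against scores that arise by chance from the *structure* of a regulon
rather than the actual slopes, each TR is screened against a null in
which every scored reaction receives an nRAP drawn uniformly from the
global $[\min, \max]$ of observed nRAP values (each reaction has a
single observed value, so no per-reaction range exists). With ~1000
draws, $q_i$ is the fraction of randomized TREs falling within
$\pm 10\%$ of the actual $TRE_i$; the TR passes when $q_i < 0.05$. Two
edge cases are handled explicitly: when the observed range has zero
width every draw reproduces the actual score and $q = 1$ (nothing is
significant — the data carry no contrast), and when
$|TRE| < 10^{-9}$ the relative window degenerates to measure zero, so
the TR is marked not significant outright. Draws are consumed in sorted
reaction-id order from a single seed, making $q$ values bit-reproducible.

## The hierarchy: gTRE

TR–TR edges define the hierarchy. Self-loops and all edges internal to a
nontrivial strongly connected component are excluded before leveling:
the net effect of a negative feedback loop is zero and a positive one
diverges, so retaining such edges would hand downstream scores
unrealistically large or infinite values. The member TRs stay as nodes —
only the looping interactions are dropped — because removing whole TRs
would orphan their metabolic regulons. Levels are assigned on the pruned
DAG by longest path from the roots, which guarantees every retained edge
points strictly downward; a curated hierarchy would be reconstructed by
hand, and longest-path layering is the automated rule that keeps the
bottom-up recursion well defined for every edge. Scores then propagate
from level $h$ (bottom) to 1 (top):

$$gTRE_p = TRE_p + \sum nRS_{p(p+1)} \cdot gTRE_{p+1},$$

the sum running over the TRs the regulator directly controls (empty for
TRs regulating no other TR). TRs that failed the randomization filter
contribute $TRE = 0$ but, by default, still *conduct* their children's
scores upward; `strict_significance = TRUE` removes them as nodes
instead. The conduit default was chosen because a non-significant
mid-level TR still physically transmits regulation, and cutting it would
silently disconnect validated lower-level scores; both semantics are
implemented because the choice is genuinely open.

Ranking sorts by gTRE descending — positive candidates for
overexpression, negative for downregulation — with ties broken by |TRE|
then id, so the ordering is total and reproducible.

## Numerical choices

* LP backend: all flux LPs run through a single wrapper around
  `boot::simplex` (feasibility/optimality tolerance $10^{-9}$). The
  wrapper shifts variables to their lower bounds, folds zero-width
  variable boxes into the right-hand side, drops linearly dependent
  stoichiometric rows by QR factorisation, and re-checks the
  steady-state residual of every solution — degenerate columns and
  dependent rows otherwise destabilise simplex pivoting on exactly the
  LPs this pipeline generates (fixed sweep fluxes, fixed exchanges).
* Slopes with $|nRAP| < 10^{-6}$ snap to zero to stabilise downstream
  signs; perfectly linear sweeps agree with the two-point slope.
* Numerically infeasible sweep points are retried with an
  $\varepsilon = 10^{-6}$ bound relaxation, then the reaction is flagged
  and excluded from gene scores rather than silently zeroed.
* Infinite bounds are capped at $10^6$ before solving.

## The synthetic instance, and what passing it shows

`toy_instance()` builds a nine-reaction model — uptake, a three-step
product pathway, a two-step biomass-precursor pathway, a drain diverting
the pathway intermediate, biomass, product exchange — whose nRAP signs
are derivable by hand (+5 along the product path, −5 for drain and
biomass steps under default bounds). The seven-TR TRN plants a
three-level chain, a product-pathway activator, a drain activator, a
repressor, a self-loop and a two-TR feedback cycle, so every exclusion
rule fires in every end-to-end run. Expression intensities are integers
(multiples of 4 in [12, 996]): the non-producer values are drawn from
the seed, while producer values follow fixed planted *relative* changes,
so nRS values — and hence the ground-truth ranking — are identical
across seeds while magnitudes vary. Two of the planted TRs sit
deliberately near the significance boundary ($q \approx 0.05$ for
single-reaction regulons under the toy's symmetric slope range), which
exercises the filter without affecting the planted top/bottom ordering.

What the toy does *not* emulate: realistic transcriptome noise (values
are exact), genome-scale combinatorics (thousands of reactions, hundreds
of TRs), incomplete expression coverage, or curation errors in TRN
signs. Passing the suite therefore demonstrates correctness of the
machinery — solver, scoring, filtering, propagation, ranking — not
predictive performance on real organisms, which depends on model and
data quality. Problem sizes throughout the tests (a 9–11 reaction model,
≤ 12-node random hierarchies, 200–10 000 randomization draws, ten
end-to-end seeds) were chosen as the smallest instances that still
exercise every rule and keep expected values derivable by hand or by
brute-force oracle.

## Known limitations

* The method scores *directions* of TR manipulation, not magnitudes of
  yield change — the layers are coupled through scores, not through an
  integrated kinetic model.
* The alternate-route extension is a heuristic; it can miss routes whose
  exposure requires simultaneous multi-reaction knockouts.
* The loopless correction can understate loopless extremes (above).
* The simplex backend is appropriate for small and mid-size models;
  genome-scale reconstructions with tens of thousands of reactions would
  want an industrial LP solver behind the same `lp_solve()` interface.
* The ±10% randomization window and the 0.05 threshold are operating
  conventions, exposed as `window` and `alpha`, not fitted quantities.
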