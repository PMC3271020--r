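---
title: "Multilevel flux balance analysis of microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel flux balance analysis of microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comfba)
```

## The modeling problem

Flux balance analysis (FBA) predicts the steady-state reaction fluxes of a
single organism by maximizing a biomass objective subject to stoichiometric
mass balance, $S v = 0$, and flux bounds $l \le v \le u$. Microbes, however,
rarely live alone: in a syntrophic co-culture the fermenter can only keep
degrading its substrate if a partner continuously scavenges the reduced
carrier (hydrogen or formate) it must vent, and in a phototrophic mat one
guild's photosynthate feeds the others. A single objective — either each
species for itself, or one aggregate community objective — cannot represent
the tension between those two levels of selection.

`comfba` therefore treats a community as a *multilevel* optimization problem:

* **Inner problems, one per species $k$.** Maximize the species' own biomass
  flux $v^k_{bio}$ subject to its stoichiometry $S_k v^k = 0$, its bounds,
  and its assigned traffic with the community: for every shared metabolite
  $i$, the species' net production $\sum_j S^{sh}_k[i,j]\, v^k_j$ must equal
  $e^k_i - u^k_i$, where $u^k_i, e^k_i \ge 0$ are its uptake and export
  flows (mmol/gDW/h).
* **Outer problem.** Choose all the inter-organism flows to maximize a
  community-level objective (total biomass by default) subject to the pool
  mass balance for every shared metabolite,
  $\sum_k e^k_i + u^c_i = \sum_k u^k_i + e^c_i$, where $u^c_i \le$ medium
  bound is the supply from the environment and $e^c_i \le$ accumulation
  bound is what may pile up, and subject to *every inner problem being at
  its optimum*.

Uptake and export are deliberately separate nonnegative variables rather
than one signed exchange flux: ecological interaction types are encoded by
fixing or coupling individual directions (see below), which a signed
variable cannot express. The redundancy this creates — a species could
simultaneously import and re-export the same metabolite — is removed from
reported solutions by a deterministic tie-break, not by integer variables.

Biomass flux is assumed proportional to biomass abundance, so community
composition data enter simply as flux-ratio constraints on the biomass
reactions.

## Predictive mode and how it is solved

Predictive mode answers: *if every member grows as fast as its allocation
allows, which allocation does the community objective select?* This is an
optimistic bilevel program. Because each inner problem is an LP, a point is
inner-optimal exactly when the inner KKT conditions hold: primal
feasibility, dual feasibility of

$$c_k - S_k^\top \lambda - C_k^\top \nu - A_k^\top \xi + \mu^l - \mu^u = 0,
\qquad \mu^l, \mu^u \ge 0,$$

and complementary slackness $\mu^l_j (v_j - l_j) = 0$,
$\mu^u_j (u_j - v_j) = 0$ on the finite bounds ($\lambda$: internal
balances, $\nu$: the allocation-fixing rows, $\xi$: inner equality
constraints such as measured fluxes or intra-species flux ratios — all
equalities, hence free duals with no complementarity). Substituting the KKT
system for each inner problem turns the bilevel program into a single-level
problem whose only nonconvexity is complementarity, a product of a dual and
a primal slack — the bilinear structure that makes the joint problem
non-convex. Two exact strategies are provided:

* `method = "dual_milp"` (default): each complementarity pair gets an
  indicator binary with big-M rows $\mu \le M z$ and
  $\text{slack} \le \text{cap}\,(1 - z)$, giving a MILP. The slack cap is
  the natural bound range $u_j - l_j$ whenever finite; $M$ (default $10^3$)
  only stands in for genuinely unbounded quantities. After every solve the
  certificates are validated — no dual may sit at $M$ and no artificial cap
  may bind — and on failure $M$ is doubled, at most three times, before a
  classed error is raised. A persistent failure with an unbounded primal
  relaxation is re-reported as unboundedness, which the caps would otherwise
  mask.
* `method = "bilinear"`: the strong-duality route without big-M. Branch and
  bound acts directly on the complementarity disjunctions: at a node, an
  unresolved pair is either forced to $\mu = 0$ or to zero slack ($v_j$
  pinned at its bound). The node relaxation simply drops unresolved
  products, so its LP value is a valid bound; a node whose LP optimum
  happens to satisfy all products is a feasible incumbent. Since
  complementarity plus primal/dual feasibility is equivalent to the
  strong-duality equality, incumbents are certified global optima when the
  tree is exhausted.

Both methods share one deterministic branch-and-bound engine over the
in-package dense two-phase simplex (no LP library is linked; the problems
are desk-scale, tens to low hundreds of variables). Two devices keep the
trees small. First, the root relaxation of the total-biomass objective is
already tight: raising any member's biomass at a fixed allocation never
hurts the total, so the joint single-level LP optimum is bilevel-feasible
and closes the gap immediately; branching only really happens for
non-monotone objectives (a single species, an engineering target flux).
Second, an *allocation repair* heuristic turns any relaxation point into an
incumbent: fix its flows, re-solve every inner LP (optimistically
re-optimized towards the outer objective at the fixed inner optimum), and
keep the point if all community rows still hold.

Optimistic semantics — among alternate inner optima the outer-favourable one
counts — is inherent in this encoding and matches solving the reformulation
to global optimality.

### Determinism and the reported solution

Alternate optima are resolved by a lexicographic tie-break: after the
optimal outer value $Z^*$ is certified, a second solve minimizes total
inter-organism flow $\sum_{k,i}(u^k_i + e^k_i)$ subject to the outer
objective pinned at $Z^*$. This yields reproducible solutions (identical
configurations give byte-identical output files) and eliminates pass-through
cycling. For the same reason, flux-variability ranges of per-species pool
flows are reported *net* (export minus uptake): the gross flow variables
admit unbounded import/re-export cycles that carry no mass.

## Descriptive mode: optimality levels

Observed communities frequently do not sit at the predictive optimum — a mat
cyanobacterium may fix more carbon than its own growth needs and feed the
community. Descriptive mode quantifies this in three stages:

1. compute each member's community-specific maximum $v^{k,max}_{bio}$ — its
   biomass in the predictive solution, i.e. the best it can do *while all
   others also strive to grow maximally* (not its monoculture optimum);
2. solve a single-level problem with all steady-state, bound, pool and
   experimental constraints (measured fluxes in the relevant species' inner
   problems, composition ratios in the outer problem), maximizing the outer
   objective with inner optimality *not* enforced;
3. report the optimality level $c^k = v^k_{bio} / v^{k,max}_{bio}$.

$c^k < 1$ means the member grows sub-optimally at $100\,c^k$ percent of its
community-specific maximum; $c^k = 1$ optimal; $c^k > 1$ super-optimal — a
biomass above the reference maximum, possible only by depleting resources
from other members, as in a competition fixture forced to equal biomass
where the inefficient competitor's reference maximum is zero (reported as
`NaN` with a super-optimality flag, since no finite ratio exists).

Stage 2 relaxes inner optimality to feasibility rather than keeping scaled
inner maximizations. For sub-optimal members both formulations coincide (the
realized biomass is below the conditional optimum either way); for the
mixed case the relaxation is the weaker, more conservative reading, and it
keeps stage 2 a plain LP. The per-species certification gap
$z_k(\text{allocation}) - v^k_{bio}$ is still reported on every solution, so
the user can see exactly which members sit below their
allocation-conditional optimum and by how much.

## Interaction typology

Ecological interaction types are encoded purely by restricting
inter-organism flows of the involved metabolites — directionality fixes
(who may export, who may take up), caps (a commensal recipient's uptake is
bounded by total donor export), couplings (total export equals total uptake
for obligate transfer; a victim's mandatory absorption proportional to the
producer's export in amensalism, with an auto-created drain reaction and a
user-supplied linear coupling coefficient, since no kinetic form is assumed
for inhibition). `apply_interaction()` re-derives all induced bounds, rows
and drains from scratch, making it idempotent, and `custom` rules are
applied literally. These encodings are this package's reading of the
qualitative typology; the linear-coupling amensalism arm in particular is a
modeling choice, not a mechanistic claim.

## The verification oracle

Because the multilevel solver is the scientific core, the package carries
its own independent verification instrument: `grid_oracle()` enumerates
allocations of the pool flows on a regular lattice, solves every inner LP at
each allocation, discards points violating balances, and returns the best
outer objective. The community supply/accumulation slacks are eliminated
through the pool balance (an interval check), terminal by-products with
free accumulation are left out of the grid, and per-flow grid bounds come
from LP presolves that propagate cross-feeding availability for a few
rounds; a flow that remains unbounded is a hard error, as a finite grid
needs finite bounds. The pool balance itself is checked strictly: gridded
flows live on one common lattice, so exactly balanced points are always
representable and the oracle remains a true lower bound of the exact solver
— only coupling constraints with off-lattice coefficients get a tolerance
of one resolution step. The oracle scales to roughly three species and two
shared metabolites; it is a test instrument, not a production solver.

`certify()` closes the loop on any returned solution by independently
re-solving each inner LP at the reported allocation; predictive solutions
must certify with gaps below $10^{-6}$.

## What the fixtures emulate — and what they do not

The deterministic fixtures are desk-scale stand-ins for the classic
community motifs: an obligate syntrophic pair coupled by a carrier that must
not accumulate (interspecies hydrogen transfer), two members competing for
one substrate with different yields, and a three-member commensal chain. All
stoichiometric coefficients are small integers, so every optimum is
hand-checkable: the syntrophic pair's total biomass equals twice the
substrate bound (10 + 10 at the default bound of 10 mmol/gDW/h), the
competition fixture allocates everything to the efficient member. The
seeded random topologies generate 2–3-member cross-feeding chains with
integer coefficients, media of 2–5 mmol/gDW/h, and randomly forbidden or
free by-product accumulation; they always contain at least one cross-fed
metabolite so the bilevel coupling is never trivial, and they are feasible
at zero flux by construction. Three-member chains use unit by-product
yields and smaller media so the oracle's verification grid stays around a
thousand points.

Passing the suite therefore shows the *solver machinery* is exact on
networks whose optima are independently enumerable. It does not show
anything about genome-scale networks: no cofactor coupling, no maintenance
ATP, no reversible internal cycles, no degenerate alternate-optima plateaus
of realistic size, and flux units are uniformly mmol/gDW/h with any unit
conversion left to the caller. Results on published case-study models
additionally depend on obtaining those models and their bounds.

## Numerical choices

* LP kernel: dense full-tableau two-phase simplex, Dantzig pricing with a
  Bland's-rule fallback against cycling; pivot/feasibility tolerance
  $10^{-9}$, phase-1 feasibility acceptance $10^{-7}$.
* Certification: inner duality gaps $\le 10^{-6}$; pool residuals
  $\le 10^{-9}$ in every returned solution.
* Branch and bound: depth-first, most-violated branching (most fractional
  binary / largest complementarity product), deterministic tie-breaks by
  variable index; integrality tolerance $10^{-6}$, complementarity
  acceptance $10^{-7}$.
* The tie-break solve pins the outer objective with an equality row at its
  certified value; if numerical noise ever empties that face, the
  un-tie-broken solution is returned unchanged.
* Ratio targets in `community_fva()` are bisected to $10^{-6}$ on $r$ with
  a feasibility solve per step, after guarding that the denominator cannot
  vanish. Since the certificate-feasible set is a union of polytopes, a
  ratio range is in principle a union of intervals; bisection reports the
  hull, which is exact in the single-interval cases that arise here.
* Degenerate inputs: a single-species community collapses exactly to plain
  FBA; an empty medium gives zero growth; infeasible configurations are
  reported with a deletion-filter subset of constraints whose removal
  restores feasibility; unbounded growth is reported with a ray member.

## Problem sizes used in the tests

The shipped suite verifies the solver against the exhaustive oracle on the
two deterministic fixtures and fifty seeded random communities at grid
resolution 1 (a few hundred to ~1300 inner-LP evaluations per community),
re-certifies every predictive solution, and exercises both solution methods
on every fixture. These sizes were chosen so every check is exhaustive or
closed-form rather than statistical.

## Known limitations

Inner objectives other than biomass maximization (e.g. minimization of
metabolic adjustment), dynamic multi-interval growth with biomass
carry-over, kinetic inhibition, spatial structure, and strain-design outer
objectives are out of scope. SBML support is read-only and limited to the
flux-bounds/objective subset of the fbc package that the reader documents;
the JSON dialect is the canonical format. The oracle requires finite
derivable flow bounds and desk-scale grids.
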