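---
title: "Structural core detection and continuous validation of the hypoxia switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural core detection and continuous validation of the hypoxia switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petristruct)
```

## The model and its assumptions

`petristruct` treats a biochemical network as a place/transition Petri
net: species are places, reaction directions are transitions, and the
integer incidence matrix $C$ (rows indexed by places, columns by
transitions) records the net token change $C_{pt}$ of place $p$ when
transition $t$ fires. Three modelling conventions matter throughout:

* **Reversible reactions are expanded** into two opposite transitions
  (`<id>_f`, `<id>_b`) cross-linked through `reverse_of`. The "forward"
  label is simply the direction in which the reaction is written; no
  analysis result depends on it — classification into trivial and
  non-trivial invariants uses only invariant coverage.
* **Side conditions are read arcs.** A species that gates a reaction
  without being consumed (oxygen here) is stored as a separate `read_set`
  rather than as a pair of opposite arcs. Structurally a read arc
  contributes zero to $C$ (the oxygen row is all-zero); kinetically it
  multiplies the rate. Keeping the two views in one representation avoids
  any ambiguity between them.
* **Arc weights are integers; markings are non-negative reals.** The
  continuous (concentration) reading is the primary one; the token game is
  not implemented.

The packaged case study is the hypoxia response switch: constitutive HIF
production; slow direct degradation; and two oxygen-dependent degradation
branches in which HIF — free or bound to its partner ARNT — is captured by
the prolyl hydroxylase PHD, hydroxylated when oxygen is present, and
finally degraded via VHL. HRE binding hangs off the ARNT complexes but
carries no steady-state flux. Transcriptional regulation downstream of
HRE, FIH-type asparagine hydroxylation and compartmentalization are
outside the model's scope.

## Exact invariant enumeration

A P-invariant is an integer vector $y \ge 0$, $y \ne 0$, with
$y^\top C = 0$; a T-invariant an $x \ge 0$, $x \ne 0$, with $C x = 0$. The
package enumerates the unique set of *minimal* semi-positive invariants
(no support strictly contains another's; entries have gcd 1) by
Fourier–Motzkin (Farkas) elimination on the tableau $[C^\top | I]$ (P) or
$[C | I]$ (T):

1. pick a remaining constraint column, replace the current rows by all
   non-negative combinations of oppositely signed rows that cancel it
   (plus the rows already at zero);
2. divide every new row by its gcd and discard rows whose annotation
   support strictly contains another row's support;
3. after the last constraint, the annotation parts are exactly the
   minimal invariants, reported in canonical support order.

All arithmetic is exact integer arithmetic in doubles (values stay far
below $2^{53}$ after gcd reduction); every returned vector satisfies its
kernel equation exactly, and the test suite asserts this per result.

Two numerical-control choices:

* **Elimination order.** Constraints are eliminated in order of the
  smallest product (#positive rows × #negative rows), which bounds the
  number of rows created in the next step. The result does not depend on
  the order — the minimal generating set is unique — only the intermediate
  sizes do.
* **Row guard.** The number of minimal invariants is exponential in the
  worst case, so the tableau is capped (`max_rows`, default $10^6$) with
  a clear diagnostic instead of an unbounded allocation.

Triviality is structural: an invariant is trivial iff its support is
exactly one expanded reverse pair with weights (1, 1). The hypoxia net has
seven such pairs and three non-trivial invariants — the degradation
pathways P1 (direct), P2 (PHD route) and P3 (ARNT route). One reverse pair
(HIFOH/ARNT association) is special: its dissociation direction also
carries pathway flux. The package keeps the structural count at seven and
reports such pairs in an `io_contributing_pairs` annotation instead of
changing the count; reduction semantics depend only on non-trivial
coverage, so both conventions reduce identically.

### Structural deadlocks and zero initial concentrations

A place set is a structural deadlock (siphon) when every transition
producing into it also consumes from it; once empty it stays empty.
`largest_structural_deadlock()` computes the greatest fixpoint inside a
candidate set. The question asked of the two places not covered by any
P-invariant (HIF and hydroxylated HIF) is: may they start at zero? The
helper `is_in_proper_deadlock()` therefore runs the fixpoint over the
places that start empty (plus the queried place), excluding pure side
conditions: an all-zero-row place such as oxygen is an external input
whose level is part of the experiment, not a species that can be starved.
On the hypoxia net the fixpoint empties, so both places may start at zero;
simulations from either initial HIF concentration (5 or 0) reach the same
steady states, which the suite asserts.

## ADT sets, coarsening and pathways

Over a chosen invariant basis, the signature of a transition is the set of
basis invariants containing it; transitions with equal signatures form the
abstract dependent transition (ADT) classes — they can only function
together. Classes are split into connected components (shared-place
adjacency, read arcs included) before coarsening; each connected class
becomes a macro transition, places used by a single macro become internal,
the rest form the top-level interface. Macro letters are assigned by the
net-order position of each class's first member, which keeps pathway
labels stable across runs.

On the non-trivial basis the hypoxia net yields six classes (sizes 1, 1,
2, 2, 4 and the nine uncovered transitions); the covered five coarsen to
macros A–E with interface {HIF, PHD, HIFOH, O2}. Every non-trivial
invariant then reads as an elementary macro chain — (A,B), (A,C,E),
(A,D,E) — ordered from the macro holding a source transition, with
lexicographic tie-breaks; a branched invariant would be flagged non-linear
and still reported.

The pairwise dependency can also be decided without enumerating
invariants: transitions $t_1, t_2$ are dependent over the full basis iff
neither $\{Cx = 0, x \ge 0, x_{t_1} \ge 1, x_{t_2} = 0\}$ nor its mirror
is feasible. Feasibility is decided exactly: a fraction-free Gaussian
elimination produces an integer basis $N$ of $\ker C$ (with the $t_2$
column removed), and Fourier–Motzkin elimination over the null-space
coordinates decides whether $\{Nz \ge 0, (Nz)_{t_1} \ge 1\}$ has a point.
This route was chosen over a floating-point LP after the available simplex
implementation proved unreliable on cone-shaped feasible regions (and
non-deterministic, because it randomizes pivot tie-breaks); the exact test
is deterministic and shares no code with the invariant enumerator, so the
equivalence of the two routes is a meaningful cross-check, asserted on 200
random nets.

## Continuous interpretation

Reading the net as a continuous Petri net with mass-action kinetics gives
every transition the rate
$v_t = k_t \prod_p m(p)^{f(p,t)}$, the product running over consumed
places and read-arc side conditions, and every dynamic place the equation
$\dot m(p) = \sum_t C_{pt}\, v_t$. Fixed places (oxygen) are held
constant; the model constructor requires their incidence rows to be zero
so that "fixed" never silently deletes flux.

Integration uses a stiff variable-step solver (`deSolve::lsodar`) with
absolute tolerance $10^{-10}$ and relative tolerance $10^{-8}$. Steady
state is detected by a root function on the derivative norm
($\max_p |\dot m(p)| < 10^{-9}$, `dnorm_tol`) rather than a fixed horizon,
so "converged" is an explicit, checkable flag; hitting the horizon
(`t_max`, default $10^6$) without the root reports `converged = FALSE`
with the final norm, never silently. The weighted sums of all five
conservation pools are constant along trajectories to better than
$10^{-6}$, which the suite asserts.

### The degradation threshold

The switch point is defined operationally: the smallest fixed oxygen level
at which the steady-state HIF concentration falls below a threshold,
refined by bisection between the bracketing grid points to $10^{-3}$. The
threshold needs care. With the packaged constants the steady-state HIF
level cannot reach zero exactly — production is constant and the total
removal capacity at saturating oxygen is about $11.4$ per concentration
unit, leaving a floor of $\approx 0.02$ — so a threshold far below that
floor would never be crossed. What "complete degradation" denotes is the
collapse of the hypoxic plateau ($\approx 137$) to order one, and that
collapse is sharp: the critical concentration moves by less than
$\pm 0.02$ for thresholds anywhere in $[0.5, 2.5]$. The default threshold
is 1.0 — two orders of magnitude below the plateau — giving a critical
oxygen concentration of $\approx 0.657$ for the full model; a scan that
never crosses the threshold returns the no-switch sentinel `NA`, which is
precisely the PHD knock-out signature.

### Comparing the core against the full model

The core model (backward reactions and the HRE subsystem removed) is
compared to the full model pointwise along the oxygen scan. Near the
switch the curve is almost vertical, so a tiny horizontal shift (the knee
moves from 0.657 to 0.649 when the backward rates are dropped) produces a
large *relative* difference at the single knee grid point while the curves
are visually identical. The package therefore states curve equivalence as
maximum absolute deviation relative to the curve's dynamic range (the
hypoxic plateau); the core stays within 0.3% of the full model on that
metric, asserted against a 1% bound, and the two switch points agree to
0.008 oxygen units.

## Reconstructing the kinetic parameter set

The parameter table this fixture derives from prints twelve values: five
for single reactions and seven that each apply to a *pair* of reactions.
The pairing is not recoverable from the table layout alone, so the
assignment shipped in `inst/extdata/hypoxia_params.toml` was reconstructed
and is gated by self-checks rather than taken on faith. Two observations
fix it:

* Counting: 5 singles + 7 shared pairs = 19 constants = 19 transitions,
  and the network contains exactly seven *analogous* reaction pairs across
  its two oxygen-dependent branches (PHD binding, PHD release,
  hydroxylation, ARNT binding, ARNT release, HRE binding, HRE release).
  Reading the pairs as forward/backward of single reversible reactions
  instead leaves the system without any switch near the documented
  operating point, for every possible assignment.
* Capacity: at the switch, production (0.2321) balances the
  hydroxylation capacity $k_{\mathrm{hyd}} \cdot [\mathrm{O_2}] \cdot
  \mathrm{PHD}_{tot}$; with $k_{\mathrm{hyd}} = 0.0361$ and
  $\mathrm{PHD}_{tot} = 10$ this predicts a critical oxygen level of
  $0.643$, matching the observed $\approx 0.65$ — and predicts that the
  ARNT route alone (capacity limited by $\mathrm{ARNT}_{tot} = 5$) needs
  about twice the oxygen, which the simulations confirm.

The resulting mapping also reproduces the fast, strong PHD binding
($K \approx 69$ versus $\approx 3.6$ for ARNT) that the biology requires,
the hypoxic plateau $k_1/k_2 = 136.5$, and all knock-out behaviors. The
file is editable; the header lists the self-checks that gate any edit.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `max_rows` | 1e6 | tableau guard for invariant enumeration (worst case exponential) |
| `abs_tol`, `rel_tol` | 1e-10, 1e-8 | stiff-integrator error tolerances |
| `dnorm_tol` | 1e-9 | steady-state criterion on max abs. derivative |
| `t_max` | 1e6 | integration horizon; reaching it flags non-convergence |
| `threshold` | 1.0 | complete-degradation level, dimensionless; two orders below the hypoxic plateau, insensitive over [0.5, 2.5] |
| `refine_tol` | 1e-3 | bisection width for the critical concentration |
| scan grid | 0–1, step 0.01 | oxygen titration protocol of the case study |
| `p_reversible`, `p_read` | 0.3, 0.15 | random-net generator: share of reversible pairs and read arcs, mimicking the case-study mix |

All simulation entry points accept a `seed` argument for interface
uniformity; the mass-action dynamics are deterministic.

## What the random-net generator does and does not emulate

`random_massaction_net()` produces seed-reproducible bipartite nets with
arc weights in {1, 2}, optional mirrored reversible pairs and read arcs,
and uniform rate constants. It exists to drive the exactness checks: the
enumeration against a brute-force kernel search, and the direct dependency
test against signature co-membership, each on 200 instances up to 6×6.
Because the brute force enumerates integer vectors with entries up to 4
while true minimal invariants of weighted nets can have larger entries
(observed up to 30), the comparison is bound-aware in both directions:
in-bound results must match the brute set verbatim, and any brute vector
beyond that must be witnessed as non-minimal by an out-of-bound result's
strictly smaller support. The generator makes no attempt to mimic
biochemical realism — no conservation structure, no kinetic plausibility —
so passing these tests certifies the algorithms' correctness on arbitrary
small structures, not any biological claim.

## Known limitations

* Enumeration and the Fourier–Motzkin feasibility test are exponential in
  the worst case; both carry row guards and fail loudly rather than
  degrade.
* PNML has no read-arc notion: read arcs are written as opposite arc
  pairs, and equal-weight opposite pairs are collapsed back to read arcs
  on import. A user who means a genuine catalytic arc pair gets the same
  incidence matrix either way, but the distinction is not round-tripped.
* "Complete degradation" is threshold-relative (see above); the
  steady-state HIF level has a small positive floor at saturating oxygen.
* Stochastic, timed and hybrid net semantics, reachability-based
  properties and P-invariant-based ODE dimension reduction are out of
  scope; the reduction argument is steady-state reasoning and should not
  be applied to transient questions.
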