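---
title: "Methods: reverse engineering immune biomarker networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse engineering immune biomarker networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicdr)
```

## The inverse problem

The package treats each measured biomarker concentration — 35 plasma
cytokines (pg/mL scale) and 15 PBMC cell phenotypes (percent scale) by
default — as a state variable of a generalized Lotka–Volterra system. The
modeling assumption is that the rate of change of each *target* biomarker
equals the algebraic sum of all biologically admissible causes, each cause
being one relationship in which a *source* biomarker stimulates or
suppresses the target, optionally modulated by a *modulator* biomarker.
Writing each cause as a linear (`a_j x_S`) or bi-linear (`a_j x_M x_S`)
term of a Kolmogorov–Gabor polynomial truncated at second order, the
per-instant system is linear in the unknowns:

$$\frac{dx}{dt} = K\,a,$$

where `K` has one row per biomarker and one column per relationship, and
column `j` carries the state product of relationship `j` in the row of its
target. The truncation at the bi-linear term keeps the column values
well-scaled for the SVD solve and bounds the problem size. With 50
equations and 28,605 unknowns the system is massively underdetermined; the
package returns the minimum-norm least-squares solution, which spreads
activity across redundant relationships — a deliberate modeling choice that
mirrors the redundancy of immune regulation rather than seeking a sparse
explanation.

Because `K`'s columns each have a single nonzero entry, `K`'s rows are
mutually orthogonal, and the exact factorization is known in closed form:
the singular values are the sorted row norms and the left singular vectors
form a signed permutation. The test suite holds the engine to this closed
form at full convergence; it is also why analysis results are driven by the
relative magnitudes of row norms, i.e. by the native concentration scales.

## The Knowledge Model

The rule table is data, not code: each row declares the biomarker classes
admitted in the modulator/source/target roles and an optional same-cell
constraint. The shipped default encodes seven types under three structural
rules: every relationship carries a cell in its source or target role;
bi-linear relationships with more than one cellular component use a single
cell (autocrine signaling; paracrine excluded), *except* that a cell
modulating a source cell with a cytokine target may differ from it; linear
relationships have no modulator. Expanded over the default panel:

| type | modulator | source | target | constraint | count |
|---|---|---|---|---|---|
| cyt_mod_cell_src_cyt_tgt | cytokine | cell | cytokine | — | 18,375 |
| cell_mod_cell_src_cyt_tgt | cell | cell | cytokine | cells may differ | 7,875 |
| cyt_mod_cell_autocrine | cytokine | cell | same cell | source = target | 525 |
| cell_mod_cyt_src_same_cell | cell | cytokine | same cell | modulator = target | 525 |
| linear_cyt_to_cell | — | cytokine | cell | — | 525 |
| linear_cell_to_any | — | cell | any | — | 750 |
| cell_self_unit_mod | same cell or `ext` | cell | same cell | all cell roles same | 30 |

for a total of 28,605 unique relationships.

The `ext` sentinel deserves a note. The model distinguishes a
*non-modulated* (linear) relationship from a relationship modulated by
*non-biomarker* factors — hormones, drugs, anything outside the measured
panel. The latter is represented by the unit-valued `ext` modulator: its
column value equals the source concentration, like a linear term, but it is
a distinct coordinate of the unknown vector with its own occurrence counts.
Only the 15 cell self-relationships carry it in the default rules. Without
this distinction the deduplicated enumeration would top out at 28,590
relationships: no combination of role-domain and equality constraints over
35 cytokines and 15 cells can reach 28,605 otherwise, a counting fact the
design honors by keeping the two sentinels distinct.

Deduplication on the (modulator, source, target) key keeps the first
generating type, and the canonical order (type, then modulator, source,
target in panel order) fixes the column order of every `K`, so right
singular vectors are comparable across instants and participants.

## The analysis grid

Blood draws on the standard schedule fall on days 0–4 and 7–11. Between
each retained pair of consecutive draws, `build_grid()` places
`points_per_interval` (default 6) analysis points strictly inside the
interval at fractions `j/(p+1)`, where concentrations come from the linear
interpolant and rates are the constant interval slope. Endpoints are
excluded because the piecewise-linear slope is undefined at draws. The
default `exclude` weekend policy drops any interval spanning more than
2 days: this removes the Friday-to-Monday gap (3 days) while keeping 2-day
holiday-bridging intervals, and yields the canonical 8 × 6 = 48 analysis
instants. Normalization always uses the participant's actual grid size, so
shorter schedules remain comparable on the 0–100 scale.

Concentrations are used on their native scales; no standardization is
applied (an explicit per-biomarker `rescale_series()` hook exists for
studies that want one). Zero concentrations are permitted — they zero the
affected columns — and negative inputs are rejected at load time.

## The factorization engine

`K` is factored by Golub–Kahan bidiagonalization (Householder reflections,
economy-size factors, wide matrices through their transpose) followed by
implicit-shift QR sweeps on the bidiagonal middle matrix. Three stopping
policies are exposed:

* `full_convergence` — iterate until every superdiagonal entry is below
  `off_diagonal_tol` (relative, default 1e-12); this is a standard SVD.
* `max_sweeps` — a fixed budget of implicit-shift steps (0 permitted).
* `ill_conditioned_guard` (default) — before stepping a diagonal block,
  adjacent diagonal entries closer than `near_equal_ratio` (default 1e-3,
  relative) freeze the block: rotations that would discriminate between
  nearly equal singular values are numerically untrustworthy, so the
  rotation state is left as is.

Whatever the policy, orthogonal transformations are exact to roundoff, so
the accumulated factors with the *current* middle matrix reproduce `K`;
`svd_factorize()` reports this as `middle_error` and the diagonal-only
reconstruction as `recon_error`, and flags `stopped_early` whenever
unconverged superdiagonal mass remains. Early-stopped factors have left
singular vectors that are genuine mixtures of biomarker directions — the
mechanism by which "supporter" activity (an active quad whose LSV tag
differs from its target) arises. Singular values are reported non-negative
and descending; each LSV is sign-fixed so its largest-magnitude component
is positive, with ties broken at the lowest row index, making runs
reproducible bit for bit.

The minimum-norm solve treats singular values below `rank_tol` (default
1e-12 relative) as zero. `K` has full row rank whenever all concentrations
are positive and every biomarker is targeted by at least one relationship,
so effective rank deficiency signals degenerate input; it is recorded in
the solution rather than raised as an error.

## Tagging, thresholds and occurrence counts

At every instant each LSV is name-tagged with a unique biomarker by greedy
assignment on descending `|U|`, ties broken by panel order then LSV index;
near-ties within 5% are logged as ambiguous. A quint (instant, LSV, target,
source, modulator) is active iff

1. `|a_j| >` `zero_rel_tol · max|a|` (default 1e-12) — relationships whose
   unknown is zero represent no causal effect and are removed;
2. `|U[target row, LSV]| ≥ lsv_threshold` (default 0.10 absolute; LSV
   columns are unit vectors, so 0.10 admits a clear dominator and a modest
   number of supporters);
3. `|Vt[LSV, j]| ≥ rsv_threshold ·` row maximum (default 0.05 relative).

The three conjuncts are independent configuration keys (set a threshold to
0 to disable it for sensitivity analysis), and every quad export records
the thresholds used. The recorded value of an active quint is the RSV
component magnitude — the coordinate of the relationship in that LSV's row
— rather than the unknown `a_j` itself, which keeps the score on the
orthonormal scale of the decomposition. Counting the instants at which a
quad is active and scaling by `100/max_count` yields normalized occurrence
counts in [0, 100], multiples of 100/48 on the standard grid.

## Aggregation arithmetic

Quads sum to Triplets (over LSV), Doublets (three pairwise views) and
Singlets (per role), and the grand total is conserved across every level.
When a table carries integer raw counts, higher-level sums go through the
raw counts and normalize once: summing 2-decimal presentation values
accumulates rounding error (a triplet of 2-decimal quads can print 183.32
where the raw-count path gives the exact 183.33), so presentation rounding
happens only at export. Cohort means count absent quads as zero and divide
by the cohort size (an active-only mean is available behind a flag); the
signed difference of two cohort means is antisymmetric by construction and
splits into positive and negative parts for the green/red edges of the
flow diagrams. Flow diagrams keep the top 10 cellular sources and top 15
modulators (plus the `n.a.` node of linear relationships) and scale node
and edge sizes linearly with configurable constants, the same scale for
every diagram of a run.

## The synthetic cohort

The clinical data behind the method is not public, so the generator stands
in for it in every test. Sinusoid mode draws, per participant and
biomarker, a log-normal baseline multiplier, a period uniform on 2–7 days
and a random phase, then emits
`baseline · (1 + 0.3 sin(2πt/period + phase))` plus Gaussian noise of 5% of
baseline on the 10-weekday schedule — positive, oscillating series whose
cytokine and cell scales differ by orders of magnitude, as in real panels.
Defaults are 14 cancer and 27 healthy participants. All randomness flows
from one integer seed through R's Mersenne–Twister, so cohorts are
reproducible bit for bit. What the generator does *not* emulate: cross-
biomarker coupling (sinusoid biomarkers fluctuate independently),
measurement floors/ceilings, and assay-specific noise structure — so green
tests demonstrate the correctness of the machinery, not biological validity
on real cohorts.

gLV mode integrates a user-supplied sparse coefficient vector by explicit
Euler (default step 0.01 days, divergence capped and reported with the
step) and returns the ground truth. Recovery of those coefficients is
deliberately not promised: the minimum-norm solution of a 50 × 28,605
system spreads mass over the null space. The mode exists for
rate-consistency checks — at the simulator's own states, `K a*` equals the
simulator's instantaneous rates — and end-to-end smoke tests.

## Numerical choices and limitations

* Snapshots store `K` as the (target row, column value) map — lossless,
  since each column has a single potentially-nonzero entry — and
  `snapshot_matrix()` materializes the dense matrix on demand; both
  representations feed the engine identically. This keeps a 48-instant
  participant at ~22 MB instead of ~550 MB.
* The fused per-participant loop (`analyze_participant()`) and the chained
  granular operations are verified equal on fixtures; the fused path exists
  purely for speed. A 41-participant cohort (1,968 factorizations of
  50 × 28,605) completes in a few minutes on one CPU.
* Problem sizes in the test suite: property tests run on seeded matrices up
  to 8 × 60 with 100-seed sweeps for the solver oracle; the end-to-end test
  runs the full 41-participant, 48-instant, 28,605-relationship
  configuration once.
* With machine-precision convergence on exactly structured `K`, LSVs are
  signed permutations and only dominator quads fire; supporter activity
  appears under early stopping when singular values cluster. The package
  reports (rather than asserts) the expected dominator/supporter pattern
  via `check_activity_pattern()`, since it is an empirical regularity, not
  a theorem.
* The quality gate (reconstruction ≤ 1e-8 relative, rate residual ≤ 1e-6
  at full convergence) is recorded per instant in the run manifest; the
  rate-residual bound is not asserted for early-stopped instants, where
  discarded superdiagonal mass legitimately leaves a residual.
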