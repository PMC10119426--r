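---
title: "Methods: combined 2D/3D QSAR modelling with qsarflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined 2D/3D QSAR modelling with qsarflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarflow)
```

# The modelling problem

qsarflow models the inhibitory potency (IC50) of small molecules against a
kinase target — the motivating series is a set of 50 VEGFR3 inhibitors — from
their structure, three ways:

1. a **linear model** over a handful of physico-chemical descriptors, found
   by a CODESSA-style heuristic stepwise search;
2. a **non-linear symbolic model** over the same descriptors, evolved by
   gene expression programming (GEP);
3. a **3D field model** (CoMSIA-style) over Gaussian similarity-index fields
   sampled on a lattice around the aligned molecules, fitted by partial
   least squares (PLS).

All three are validated the same way: leave-one-out cross-validation during
model building and an external test set afterwards.

## Activity scale

IC50 values are tabulated in micromolar and transformed once, up front, as

$$\mathrm{activity} = 6 - \log_{10}(\mathrm{IC50}/\mu M),$$

i.e. the negative log of the molar concentration. The transform stabilises
variance and puts sub-micromolar binders above 6. `transform_activity()`
implements it and refuses non-positive input; the inverse is exact to
floating-point precision, which the suite checks.

# Descriptors

Only the descriptors that appear in the reference linear model are
materialised; the remaining several hundred of a full CODESSA catalogue are
out of scope.

* **NN** — the number of nitrogen atoms. A constitutional count; more
  nitrogens usually mean more NO2/NH2-type groups available for hydrogen
  bonding to the target.
* **MPCO(ZPC)** — the minimum partial charge over oxygen atoms, from an
  empirical electronegativity-equalization charge scheme. We use one-shot
  Sanderson equalization: with $S_A$ the atomic Sanderson electronegativity
  and $S_{mol}$ the geometric mean over the molecule,
  $q_A = (S_{mol} - S_A) / (2.08\sqrt{S_A})$. The one-shot formula does not
  conserve charge exactly, so a uniform per-atom shift is applied to make
  the charges sum to the net molecular charge — that conservation is a hard
  invariant of the test suite. Whether the original CODESSA implementation
  adds bond-path corrections beyond one-shot equalization is not documented;
  we deliberately do not guess, and the scheme here is documented as what it
  is.
* **YZS/YZR** — the shadow ratio: the molecule is rotated into its principal
  frame (axes ordered by descending extent, signs fixed so the atom farthest
  from the centroid has non-negative coordinates — a pure determinism
  device), every atom is projected onto the YZ plane as a disc of its van
  der Waals radius, and the area of the disc union is divided by the area of
  the enclosing rectangle. The printed integral formula for this descriptor
  in the source literature is typographically corrupted, so the
  implementation follows the standard reading: projected vdW shadow over
  enclosing rectangle. Whether the rectangle should include the radii is
  equally undocumented; we include them (the ratio then lives in (0, 1]).
  Areas are measured by rasterisation — pixel counting at a default
  resolution of 0.05 Å, which puts a single sphere within well under 1 % of
  $\pi r^2$ and converges under refinement; an analytic disc-union area
  would be exact but harder to verify independently, and the Monte-Carlo
  cross-check in the tests would not distinguish them at test tolerance.
* **MREB** and **MSEC** — quantum-chemical descriptors (maximum C–H bond
  resonance energy; minimum carbon atomic state energy). These require a
  semi-empirical wavefunction that the package does not compute, so they are
  *provided columns*: users supply them per compound. The defining
  contraction $E_R(A,B) = \sum_{\mu\in A}\sum_{\nu\in B} P_{\mu\nu}
  \beta_{\mu\nu}$ is nevertheless implemented (`resonance_energy()`,
  `max_ch_resonance()`) as a standalone operation on user-supplied density
  and resonance-integral matrices, so the arithmetic is testable against a
  brute-force double loop.

`assemble_matrix()` merges computed and provided columns and records
per-column provenance.

# The heuristic linear-model search

`heuristic_search()` reproduces the stepwise procedure: first the best
descriptor *pair* by $R^2$ among all pairs whose absolute Pearson
correlation does not exceed the collinearity cap; then greedy forward
addition of the single descriptor that most improves $R^2$, subject to the
cap against every already-selected descriptor and an optional minimum |t|
for its coefficient, up to the maximum model size. The best model of every
size is recorded, and `choose_model_size()` recommends the smallest size
after which the $R^2$ gain falls below a threshold (default 0.02) — the
diminishing-returns reading of the published size-5 choice.

Conventions worth stating:

* the collinearity cap defaults to 0.8, the value treated as the
  independence criterion in the source analysis;
* $S^2$ is residual variance $RSS/(n-k-1)$. The source reports "$S^2$"
  without defining it; squared standard error of estimate is the other
  reading and equals this one, so nothing hinges on the choice;
* a zero-variance response gets $R^2 = 0$ with a warning (avoiding 0/0);
* ties in $R^2$ during selection break by larger minimum |t|, then column
  order, so the search is fully deterministic;
* $R^2_{cv}$ is leave-one-out, computed through the hat-matrix identity
  $e_{(i)} = e_i/(1-h_{ii})$, which the suite verifies against explicit
  n-refit brute force to 1e-10.

The published five-descriptor equation itself ships as
`hm_published_predict()`, with the printed coefficients, so predictions on
that model are available without refitting anything.

# Gene expression programming

Chromosomes are fixed-length Karva strings: a head of length $h$ that may
hold functions or terminals and a tail of $t = h(n_{max}-1)+1$ terminals
($n_{max} = 2$ here), decoded breadth-first into an expression tree. The
function set is exactly the seven operators of the reference experiment:
`+ - * /` (binary) and `Inv`, `Cos`, `Tan` (unary). Terminals d0–d4 bind to
MREB, NN, YZS/YZR, MPCO(ZPC), MSEC in that order.

**Guarded arithmetic.** `Tan` and the two division-like operators make
overflow inevitable during evolution. Every node output is clamped to
±1e6, and denominators below 1e-12 in magnitude saturate to 1e6. The C++
population evaluator and the R recursive interpreter implement the identical
semantics and are cross-checked to 1e-12 over random trees and an exhaustive
enumeration of small genes.

**Evolution.** Elite roulette selection (the best `elitism` individuals
survive unchanged; the rest of the next generation is fitness-proportional
with replacement), then point mutation, IS/RIS/gene transposition, and
one-point/two-point/gene recombination. Elites bypass the operators, so
best-so-far fitness is monotone — a property test. Fitness defaults to
$1000/(1+RMSE)$ (bounded, standard in GEP tools); squared Pearson
correlation is available. All hyperparameters are unpublished in the source;
defaults follow common GEP practice (population 500, single gene of head 10,
mutation 0.044, recombination 0.3/0.3/0.1, transposition 0.1 each) and are
fully configurable. The recovery experiments in the test suite use 3 genes
of head 7 linked by `+`, a standard multigene setup that suits additive
targets; it was fixed before the acceptance statistics were measured.

**The printed model.** The published symbolic model is printed without
parentheses, and chains like `Cos1/d3/d0` or repeated `TanTan…` admit more
than one grouping; no grouping reproduces a number that could adjudicate.
`parse_model_expression()` therefore implements one explicit convention —
unary functions bind tighter than `*`/`/`, which bind tighter than `+`/`-`,
all left-associative — and `gep_published_model()` ships the reconstruction
under that convention, documented as a convention rather than asserted as
the authors' reading.

# CoMSIA fields and PLS

Molecules are rigidly aligned to a template by least-squares (Kabsch)
superposition over a mapped common substructure (at least three
non-collinear atoms). An axis-aligned lattice covers the union bounding box
plus a margin, and for each molecule five similarity-index fields are
evaluated at every lattice point $q$:

$$A_k(q) = -\sum_i w_{probe,k}\, w_{ik}\, e^{-\alpha r_{iq}^2},$$

with steric weight $w_{i,S} = r_{vdW,i}^3$, electrostatic weight the partial
charge, and hydrophobic/donor/acceptor weights from a small element-keyed
table shipped with the package (deliberately coarse; real CoMSIA
implementations use typed force-field atom types, which would require
connectivity perception that is out of scope). Defaults — attenuation
$\alpha = 0.3\,$Å$^{-2}$, spacing 2 Å, margin 4 Å, probe weights +1 — are
the de-facto literature conventions, stated as such because the source
prints none of them; every one is a parameter.

PLS is univariate NIPALS with X-deflation, mapped back to original columns.
The optimal component number is the argmax of leave-one-out $q^2$ with ties
to the smaller count. SEE is $\sqrt{RSS/(n-ONC-1)}$ and F the usual ratio,
matching the conventions of 3D-QSAR tables. Field contributions are each
field's share of $\sum_j |b_j \cdot sd_j|$; contour masks flag points above
the 80th / below the 20th percentile of $b_j \cdot sd_j$ per field (both
percentiles configurable; a uniform field yields empty masks under the
strict inequalities). Column filtering by minimum standard deviation is off
by default (threshold 0) since the reference filtering energy is
unpublished.

# External validation

$R^2_{ext} = 1 - \sum_{test}(y_i-\hat y_i)^2 / \sum_{test}(y_i-\bar
y_{tr})^2$, referenced to the *training* mean, with pass declared strictly
above 0.5. "Average error" in the source is not defined; the report emits
both MAE and RMSE so either reading is available, and both Pearson r and
$R^2$ for the same reason.

# Synthetic data: what a green test establishes

The generators produce data with exactly the structure each stage assumes:

* `gen_planted_linear()` — a sparse linear signal among nuisance columns
  whose pairwise correlation (default 0.3) comes from a single shared latent
  factor; noise defaults to 10 % of the signal's standard deviation at the
  reference sample size n = 40, p = 100, five true descriptors.
* `gen_symbolic()` — terminals sampled uniformly (default range 0.1–2,
  chosen to keep clear of division/tangent singularities) and a target
  expression over the GEP function set; generation refuses ranges that ever
  hit a guard, so noiseless data re-evaluates exactly.
* `gen_toy_molecules()` — a hard-coded rigid scaffold (no chemistry
  perception, hence hermetic tests) with one substituent atom whose radius
  and charge vary; activities are a fixed linear functional of the true
  steric and electrostatic fields at three lattice points near the
  substituent.

These emulate the *statistical* situation, not real chemistry: descriptor
distributions are Gaussian/uniform rather than heavy-tailed, the toy
molecules are perfectly aligned by construction, and the field ground truth
lives inside the model family. A green recovery test therefore establishes
correctness of the machinery — search, evolution, field algebra, PLS — not
predictive validity on real compounds. Conversely, the reference headline
statistics (HM $R^2$ = 0.82, CoMSIA $q^2$ = 0.503, …) are *not*
reproduction targets anywhere in the package: they depend on an unpublished
632-column descriptor matrix, undisclosed 3D conformers and a commercial
field parameterisation.

# Numerical choices and degenerate inputs

* OLS via QR; rank deficiency is an error, not a silent drop.
* Leverage-1 observations make leave-one-out undefined — an explicit error.
* Shadow rasterisation at 0.05 Å; halving the resolution moves fixture
  areas by < 0.5 % (tested).
* Single-atom molecules get an identity principal frame with a warning;
  near-collinear atom sets warn that the frame is not unique.
* All-zero fitness populations fall back to uniform selection with a
  warning.
* Every stochastic entry point takes a seed and is bit-reproducible under
  it; the pipeline derives per-stage seeds from one global seed.

# Known limitations

* Hydrophobic/D/A atom weights are element-based only.
* The Zefirov-style charge scheme is one-shot, not iterative.
* GEP has no random-numerical-constant domain; models are built from the
  five terminals and parsed constants only.
* The 3D test-set membership of the packaged 50-compound table is unknown
  (`NA`): it was marked by underlining in the original table, which plain
  text does not preserve.
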