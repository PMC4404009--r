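---
title: "Methods: Pareto analysis of coiled-shell morphospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pareto analysis of coiled-shell morphospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretoshell)
```

## The model system

A planispiral shell is described by three dimensionless traits: the whorl
expansion rate $W$ (the factor by which the spiral radius grows per full
revolution), the umbilical ratio $D$ (inner over outer shell radius), and
the aperture shape $S$ (width over height of the opening ellipse).  Every
genus is a point in $(D, S, W)$ space; a genus-level table is the unit of
analysis.

Pareto theory for evolutionary tradeoffs predicts that when several tasks
contribute to fitness, evolved phenotypes fill a low-dimensional polytope
whose vertices — the *archetypes* — are the phenotypes optimal at a single
task.  Two tasks give a line segment, three a triangle, five a
five-vertex polyhedron.  The package provides (i) mechanistic performance
functions for three candidate tasks, (ii) the Pareto front they imply,
(iii) polytope-fitting machinery to recover archetypes from data, (iv) the
randomization statistics that ask whether a polytope is a better
description than chance, and (v) a synthetic generator so that every step
can be validated against known ground truth.

## Shell-economy performance

The economy of shell construction is the internal (cavity) volume gained
per volume of shell material laid down.  Because the shell is
self-similar, both quantities grow in proportion along the spiral, so
their ratio equals the ratio of their per-angle integrands and no
integration along the spiral is needed.  We evaluate both integrands in
the cross-section plane at unit outer radius, where the aperture is an
ellipse with radial semi-axis $a = (1 - D)/2$, axial semi-axis $b = S a$,
and centre $(1 + D)/2$; the previous whorl is the same ellipse scaled by
$1/W$ towards the coiling axis.

Three ingredients define the function:

* **Cavity added per turn.**  The part of the aperture not already
  occupied by the previous whorl.  The two ellipse boundaries cross at
  the radial coordinate $x^\ast = (1 + 1/W)\,D/(1 + D)$ (a closed form),
  and deeper whorls never reach above the immediately previous one within
  the exposed band, so the single-previous-whorl formula equals the full
  multi-whorl union exactly.
* **Wall built per turn.**  The aperture perimeter minus the arc lying
  inside the previous whorl: the shared wall already exists and need not
  be built again.
* **Wall thickness.**  A fixed fraction (default 0.077) of the aperture
  scale $\sqrt{ab}$.  This reference is the one choice that makes the
  ratio *exactly constant* on the whole gyroconic (non-overlapping,
  $W > 1/D$) region at fixed $S$ — open-coiled shells are tubes whose
  local geometry does not change with $D$ or $W$ — which is the
  behaviour the economy landscape must show.

The resulting landscape has the gyroconic plateau as a low baseline
($1/(2 \times 0.077) \approx 6.5$ at $S = 1$), rises along a curved ridge
of moderately overlapping shells where wall sharing beats cavity loss,
and collapses towards zero for strongly involute low-$D$ shells, where
almost the whole new aperture lies inside the previous whorl.  Two
consequences deserve emphasis:

* As $W \to 1^+$ the cavity added per turn vanishes while the outer wall
  still has to be built, so economy tends to zero on that boundary.  The
  package therefore evaluates $W = 1$ as the right-limit $W = 1 + 10^{-6}$.
* The ridge is extremely flat: over a wide stretch of $(D, W)$ the value
  varies by less than one percent, so the *location* of its maximum is
  sensitive to the overlap convention.  The cross-section geometry of
  overlapping whorls admits several defensible conventions (count the
  full aperture as cavity or only the uncovered part; treat the previous
  whorl as an elliptical section or as everything inside its outer
  radius).  We implement the convention above because it is the only one
  we found that is simultaneously physical (no double-counted cavity),
  exactly gyroconic-constant, and near-zero for the depressed involutes;
  the untruncated variant remains available via
  `volume_ratio(..., area_mode = "full")` for comparison.  Users should
  treat the ridge position, not its existence, as model-dependent.

## Growth performance

The growth model penalises a shell for the time it spends at small
diameters.  Assuming shell-material production proportional to body mass,
the penalty is

$$P(D, W) \;=\; \frac{W}{\mathrm{Ratio}(D, W)\,\log W\,(1 + \sqrt{W})},$$

with $\mathrm{Ratio}$ the internal-to-shell volume ratio at `S_eval`
(default 1).  $P$ diverges as $W \to 1$ (the diameter stops growing), so
the performance surface returned is $1/P$, which peaks at evolute,
rapidly expanding shells and vanishes on the $W = 1$ boundary.  The
dependence on $S$ enters only through the volume ratio; the model makes
no claim about an optimal aperture shape for growth, and `S_eval` is
exposed without a recommendation.

## Drag performance

Measured drag coefficients for shell models show drag increasing
monotonically in $D$ and $W$, with the best hydrodynamics at compressed
apertures ($S \to 0$).  The analysis only uses this monotone structure,
so the default surface is a documented analytic stand-in,
$-(\alpha D + \beta (W-1)/(W_{\mathrm{ref}}-1) + \gamma S/S_{\mathrm{ref}})$
with positive weights, whose argmax on any box is the low-$(D,S,W)$
corner.  A measured table (columns `D, S, W, cd`) can be supplied and is
interpolated by inverse-distance weighting, exact at the nodes.

## Pareto front

`front_on_grid()` evaluates the task surfaces on a trait grid and keeps
the non-dominated points (no other point at least as good at every task
and better at one).  Ties are kept, so symmetric degenerate inputs
survive symmetrically.  Fronts are computed on grids rather than by
contour-tangency geometry; the tangency characterisation is used only as
a property check on smooth toy tasks in the test suite.  Grid argmaxes
break ties towards the lexicographically smallest $(D, S, W)$ and are
optionally refined by bounded quasi-Newton iteration.

## Fitting enclosing polytopes

**Minimum-volume simplex** (`fit_simplex()`): the objective is the
simplex volume plus `outside_penalty` (default 200) times the summed
Euclidean distance of points outside; optimisation is Nelder-Mead from an
inflated furthest-point simplex with seeded jittered restarts.  Traits
are standardised to zero mean and unit variance before fitting because
$W$ spans several times the range of $D$; vertices are mapped back.  Two
honest limitations, both visible in the tests: the solver's vertex
precision on exact polytope data is about $10^{-2}$ standard deviations
(a simplex-method polish would sharpen this but has not been needed), and
on noisy data any *enclosing* estimator overshoots acute corners by the
noise scale — with trait noise of 0.02 the recovered apex of a thin
triangle is biased outward by roughly 0.1, and no global penalty weight
can trim corners without cutting into the long edges.

**Principal convex hull / archetypal analysis** (`fit_pcha()`): the $k$
archetypes are constrained to the convex hull of the data inflated by a
relaxation factor $1 + \delta$ about the centroid; data points are
reconstructed as convex combinations of archetypes.  The fit alternates
(i) an accelerated projected-gradient solve for the convex weights and
(ii) backtracked projected-gradient steps on the archetype positions,
with the hull projection computed by pairwise Frank-Wolfe iteration.
Both steps decrease the squared reconstruction error monotonically;
iteration stops when the relative improvement falls below $10^{-8}$.
Seeded restarts guard against local optima.

The relaxation matters for vertex recovery.  With Dirichlet(0.8) vertex
weights — the generator's default, which fills the polytope with mass
towards its boundary — the largest weight among 1000 draws is only about
0.87, so the sampled convex hull sits 0.3-0.7 standard deviations inside
the true vertices, and a $\delta = 0$ fit *cannot* reach them no matter
how good the optimizer: its error is the hull's, not the algorithm's.
Recovery tests therefore use $\delta = 0.15$, which lets archetypes
extrapolate modestly beyond the sampled cloud; the default remains
$\delta = 0$ (archetypes inside the data hull), the conservative choice
for real data.  Recovery accuracy is reported per coordinate in units of
the observed trait range.

`rms_profile()` runs the fit over a range of $k$ with a shared restart
budget; the elbow where extra archetypes stop paying for themselves
indicates the number of tasks.  No automatic selection rule is applied —
the profile is the deliverable.

## Randomization statistics

* **Polygonality** (`polygonality_test()`): the statistic is the t-ratio,
  the area of the data's convex hull over the area of the fitted
  triangle; 1 means the data fill their triangle perfectly.  The null
  randomizes by independently permuting each trait column — this
  preserves the marginal distributions *exactly* (resampling with
  replacement would only do so in expectation) while destroying the
  joint structure.  By default the triangle is refitted for every null
  replicate, the conservative choice; `refit = FALSE` reuses the data's
  triangle.  Failed null fits are excluded and counted.
* **Triangle similarity** (`triangle_similarity()`,
  `similarity_test()`): intersection area over union area by exact
  convex clipping (Sutherland-Hodgman), compared against pairs of
  triangles with i.i.d. uniform vertices on a rectangle.  The ratio is
  invariant to the rectangle's scale and aspect, so the unit square is
  not a modelling choice; the tests verify this.
* **Distance enrichment** (`enrichment_by_distance()`): genera are ranked
  by Euclidean distance to a vertex in standardised trait space, split
  into equal-count bins (counts differ by at most one; ties broken by
  stable index order), and a least-squares line is fitted through the
  bin means.  Significance comes from permuting the covariate over
  genera (two-sided on the slope): the displayed line fit and the test
  then use the same statistic, and no distributional assumption is
  needed.  All permutation p-values are floored at $1/n_{\mathrm{null}}$
  and never reported as zero.

## Westermann-style ternary projection

The ternary map sends each trait to a $[0, 1]$ score ($D$ as-is,
$(W-1)/(W_{\mathrm{ref}}-1)$ with $W_{\mathrm{ref}} = 5$,
$S/S_{\mathrm{ref}}$ with $S_{\mathrm{ref}} = 3.5$) and normalises the
three scores to barycentric coordinates.  The construction is a
documented reconstruction in the spirit of the classical end-member
triangle: its claims here are qualitative (which archetypes map near
corners, where the projection is warped) and any affine-then-normalise
variant meeting those properties would serve.  The map is projective
(doubling all scores changes nothing) and undefined where all three
scores vanish — exactly the low-$D$, low-$S$, low-$W$ region.
`sensitivity_region()` quantifies the warping by mapping a small
ellipsoid (semi-axes a fixed fraction of each coordinate's range) and
summarising the spread of the images; near the low-drag corner the
spread is several-fold larger than anywhere else.

## Synthetic data: what it does and does not emulate

`make_dataset()` draws era-partitioned genus tables (default 113/386/392
genera, matching the three inter-extinction intervals of the motivating
compilations) as Dirichlet-weighted convex combinations of a 5-vertex
reference pyramid plus isotropic Gaussian trait noise (default sd 0.02),
and assigns shell diameters multiplicatively:
$\mathrm{base} \times \prod_v \mathrm{effect}_v^{w_v} \times$ lognormal
noise, so genera near vertices with effect $< 1$ are systematically
small.  Diameters are positive by construction and only the direction of
enrichment is meaningful.  The generator deliberately does **not**
emulate phylogenetic autocorrelation between genera, survivorship
through extinctions, era-specific occupancy shifts, or trait measurement
error correlated with shell size.  Passing parameter-recovery tests
therefore demonstrates that the estimators work on polytope-structured
data under honest noise — not that real fossil compilations satisfy the
model's assumptions.

## Numerical choices

* Cross-section cavity areas use closed-form circular-segment integrals;
  arc lengths use composite Simpson quadrature (2048 subintervals for
  `whorl_section()`, 512 inside grid scans), giving relative errors far
  below $10^{-6}$ on smooth arcs.
* $W = 1$ is always evaluated as $W = 1 + 10^{-6}$.
* Grid argmax ties break towards the lexicographically smallest
  $(D, S, W)$; refinement is L-BFGS-B inside the surface domain and is
  only accepted if it improves on the grid value.
* Degenerate inputs fail loudly: apertures with $D \ge 1$, zero-area
  triangles, collinear data for simplex fits, all-NaN grids.
* Validation problem sizes: vertex recovery at $n = 1000$, rms profiles
  at $n = 400$ with four restarts, randomization nulls at $10^4$
  replicates in the acceptance script and $10^2$-$10^3$ in unit tests.

## Known limitations

* The economy ridge position depends on the overlap convention (above);
  conclusions should rest on the landscape's structure, not on the
  third decimal of its argmax.
* The drag surface is an interface with a monotone default, not a
  hydrodynamic model.
* The growth model assumes production proportional to body mass; known
  sublinear scalings would shift its optimum towards smaller apertures.
* `fit_simplex()` is an enclosing estimator: with noisy data its
  vertices are biased outward at acute corners by the noise scale.
* The Westermann transform's normalisation constants are conventions;
  only corner proximity and warping statements are robust to them.
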