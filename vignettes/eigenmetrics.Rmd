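---
title: "Modal eigenmetrics of bone stiffness: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modal eigenmetrics of bone stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemodal)
```

## The model

`bonemodal` treats a bone as a linear, isotropic, heterogeneous elastic
solid discretized with linear (P1) tetrahedra. Displacements are
continuous piecewise-linear; material parameters are element-constant
(DG0): each tetrahedron carries one ash density, one Young's modulus and
one effective mass density. Two matrices are assembled,

$$\mathrm{K} = \bigcup_e \int_{\Omega_e} \nabla u : C(E_e,\nu) : \nabla\delta u \, d\Omega, \qquad
\mathrm{M} = \bigcup_e \int_{\Omega_e} \rho_e\, u\cdot\delta u \, d\Omega,$$

with one-point quadrature for K (exact for constant-strain tetrahedra) and
the closed-form consistent mass ($\rho V/20$, 2 on the diagonal and 1
off-diagonal per scalar component). The generalized eigenproblem
$\mathrm{K}u_i = \lambda_i \mathrm{M} u_i$ is solved for the smallest
eigenpairs; all eigenvectors are mass-normalized ($u^T\mathrm{M}u = 1$),
which is what makes the modal-superposition receptance below
normalization-independent.

From the eigenpairs the package derives, per specimen:

* the per-node magnitude field $\|u_i\|$ of each mode;
* the compliance-maximum node $k = \arg\max \|u_1\|$ (ties broken toward
  the smallest node index);
* modal stiffnesses $s_i = \lambda_i / (\|u_i\|[k])^2$ (N/mm);
* a truncated static stiffness
  $1/S = \sum_{i \le \hat n} (\|u_i\|[k])^2/\lambda_i$;
* natural frequencies $f_i = \sqrt{\lambda_i}/2\pi$ (Hz).

### Units

All computations run in the consistent mm–N–MPa–tonne–s system:
coordinates in mm, moduli in MPa, densities entered in g/cm³ and converted
once to tonne/mm³ (factor $10^{-9}$) at assembly. Eigenvalues then come
out in rad²/s², stiffnesses in N/mm and frequencies in Hz with no further
conversion.

### Material law

Young's modulus follows the three-branch power law of ash density
(`youngs_modulus()`): $10200\,\rho^{2.01}$ MPa above 0.486 g/cm³, a
constant 2389 MPa on $[0.3, 0.486)$, and $33900\,\rho^{2.2}$ below 0.3.
The printed branch bounds overlap at exactly 0.3; we evaluate branches
top-down so 0.3 takes the constant branch — the two candidate values
differ by about 0.4% there, and the upper junction at 0.486 is continuous
to about 0.2%. No modulus floor is imposed, so a zero ash density yields a
zero modulus, which material validation rejects rather than silently
regularizing. Hydroxyapatite-equivalent densities are first converted with
$\rho_{ash} = 0.877\,\rho_{HA} + 0.08$. The Poisson ratio is a global
constant, default 0.3. CT values, when used, are treated as dimensionless
normalized attenuation and only feed the mass density
($\rho_{eff} = 658\,\mathrm{CT}$ g/cm³ by default); scanner-specific
calibration from CT to $\rho_{HA}$ is deliberately out of scope, and the
tool accepts $\rho_{HA}$ or $\rho_{ash}$ fields directly. When only an ash
density is supplied, the mass density defaults to it — an approximation
appropriate for synthetic fixtures and stated in the export provenance.

## Boundary conditions and rigid modes

`FEMP-I` fixes a named node set (all three DOFs, homogeneous). Constraints
are applied by **DOF elimination**, not by zeroing rows and columns in K
with a unit diagonal: the latter, with M left untouched, plants spurious
$1/M_{ii}$ eigenvalues inside the spectrum of interest. Elimination is
spectrum-equivalent for the constrained subspace, and a back-expansion map
reinserts zeros so every exported vector indexes the full mesh.

`FEMP-II` is completely free. Its six zero-strain motions (three
translations, three rotations) are not computed iteratively: the analytic
rigid vectors are built, M-orthonormalized, verified to be annihilated by
K, and **deflated** from the iteration. A projection criterion (M-norm of
the projection onto the 6-dimensional rigid space > 0.99) classifies
rigid modes scale-freely; an absolute eigenvalue threshold would depend on
units and mesh size. A strain-free mode *outside* that space means the
mesh is a mechanism or disconnected, and the solver refuses to continue.
Because the zero eigenvalue is 6-fold degenerate, individual rigid vectors
mix translations and rotations arbitrarily; the classifier therefore also
reports the exact subspace split (`translation_dim`/`rotation_dim`, 3 + 3
for any connected free body), which is the invariant quantity.

## The eigensolver

No sparse iterative eigensolver for the generalized symmetric problem is
part of the package's dependency set, so `solve_smallest_eigenpairs()`
implements shift-invert **block subspace iteration with Rayleigh–Ritz
extraction**: one sparse Cholesky factorization of $K + \sigma M$
(σ = 0 for constrained systems; a small mass-proportional shift,
$10^{-8}\,\mathrm{tr}K/\mathrm{tr}M$, for free systems), repeated
application of its inverse to an M-orthonormal block of size
$n + \max(8, n/2)$, rigid-space re-projection every iteration, and a
small dense Ritz problem per sweep. The method is simple, handles
degenerate eigenvalues natively (a single-vector Lanczos recurrence finds
multiple copies only through rounding), and is verified rather than
trusted: iteration stops only when every requested pair satisfies
$\|Ku - \lambda Mu\| \le \mathrm{tol}\,\|Ku\|$ (default $10^{-8}$, max 500
sweeps), and non-convergence is an error carrying the residuals. The
random start block is drawn from a caller-isolated RNG stream seeded by
the `seed` argument (default 0), so runs are bit-reproducible and never
perturb the session RNG. On meshes small enough for dense solves the
results match a Cholesky-reduction `eigen()` oracle to relative 1e-8 (in
practice near machine precision); that oracle lives in the test suite,
not in the solver.

Degenerate pairs (symmetric fixtures such as square-section beams) are
returned in ascending-λ order, but individual vectors within a degenerate
cluster are basis-arbitrary; tests and downstream comparisons should use
invariant subspaces or asymmetric fixtures, which is what this package's
suite does.

## Static stiffness: norm form vs directional form

The receptance sum over squared *nodal norms* has a precise static
meaning: with the full spectrum,
$\sum_i (\|u_i\|[k])^2/\lambda_i = \mathrm{tr}\, H_{kk}$, the trace of the
3×3 block of $K^{-1}$ at node k — equivalently the sum of the three
axis-aligned point-load compliances at k. It is **not** the compliance of
any single point load. The package therefore reports two quantities:

* `S` — the norm-form (trace) static stiffness, the primary metric;
* `S_directional` — the same sum with squared projections
  $(u_i(k)\cdot d)^2$ along the mode-1 direction $d$ at k, which with the
  full spectrum exactly equals a point-load solve along $d$
  (`static_solve()`), and is the quantity beam theory's $3EI/L^3$
  describes.

Both identities are asserted at relative 1e-8 in the tests. For a
square-section cantilever the two differ by roughly a factor of two,
because the trace counts both degenerate bending planes.

For FEMP-II there is no direct static counterpart (the unconstrained
static problem is ill-posed); the same sum over deformable modes is still
computed and labeled "free-interface modal stiffness" in every export.

### Truncation and the choice of k

$\hat n = 10$ eigenpairs is the default truncation, and `n_modes = 10`
deformable pairs the default solve — with the block buffer this keeps one
factorization and a modest block, and on the fixtures here the first few
modes dominate the compliance at k. The truncation error is
one-sided (S is overestimated) and non-increasing in $\hat n$. The
location k is taken from mode 1 by default (`k_policy = "first_mode"`):
the smallest static stiffness is expected with the first modal stiffness,
and the superposition needs a single fixed point. A `per_mode` policy
(each $s_i$ at its own argmax) and a `user_node` policy are exposed;
neither is claimed to be canonical. A mode with zero magnitude at k
contributes zero compliance inside the sum (its continuous limit), while
*evaluating a modal stiffness* at such a node is an error pointing the
caller to the per-mode policy.

## Synthetic fixtures and what they do (not) show

The generator builds structured boxes split by the translation-invariant
Kuhn 6-tet template (conforming, deterministic, bit-identical across
runs; all tets positively oriented; total volume exact). Fixtures:

* `box` — 20 mm cube, uniform 0.8 g/cm³, free: exercises the rigid
  spectrum;
* `cantilever` — 100 × 10 × 10 mm, uniform 1.0 g/cm³ (E = 10200 MPa),
  end face fixed: the beam-theory benchmark;
* `two_tet` — 5 nodes: small enough for dense end-to-end oracles;
* `gradient_beam` — ash density ramping linearly 0.3 → 1.2 g/cm³ along
  the axis (element value at the centroid), the realistic
  trabecular-to-cortical range: an asymmetric, heterogeneous case where
  the k-policies genuinely differ.

These fixtures reproduce the *algebraic* structure of bone FE models —
heterogeneous DG0 moduli, fixed-region or free boundaries, well-separated
or degenerate modes — but none of the geometric irregularity, cortical
shell/trabecular contrast, or million-element scale of CT-derived pelvis
meshes (characteristic element size 1 mm). Passing tests validate the
operators, the solver and the metric algebra; they say nothing about
anatomical accuracy, segmentation, registration or cohort statistics,
which are explicitly out of scope (the metric CSV/JSON export is the
interface to such downstream analyses).

## Numerical behavior on the beam benchmark

P1 tetrahedra over-stiffen in bending, so cantilever stiffness converges
to the Euler–Bernoulli limit $3EI/L^3$ **from above and monotonically**
under refinement. Measured on the directional static solve at the tip
center (load along y): relative excess 182% at divisions (10,2,2), 48% at
(20,4,4), 26% at (40,4,4), 6.6% at (80,8,8). An independent scipy
implementation of the identical discretization reproduces these numbers to
machine precision, so they characterize the element, not the code. The
practical reading: with linear tetrahedra, absolute stiffnesses need
roughly 8 elements across a 10 mm section before discretization error
drops below 10% — which is consistent with the ~1 mm element sizes used
for real bones — while *relative* metrics (mode ordering, invariances,
specimen comparisons on a fixed meshing rule) are meaningful much earlier.
The suite asserts the monotone approach, and reports the (40,4,4) error
against a 20% band that this element does not meet at that resolution
(26%); the band is kept as stated rather than widened.

A 5% convergence check on the first five eigenvalues between two mesh
resolutions (`convergence_check()`, `converge_study()`) mirrors the
standard mesh-selection practice for these models.

## Design choices in brief

* 1-based indices internally (native to R); readers/writers translate to
  VTK's 0-based and Gmsh's 1-based on-disk conventions.
* Kuhn 6-tet hexahedron split: fixed diagonals, conforming structured
  meshes, no per-cell reflection bookkeeping.
* Voigt/engineering-strain convention for the 6×6 elasticity matrix, so
  entries are unit-testable against the Lamé closed form.
* Negative-orientation tets repaired on read (assembly assumes positive
  Jacobians); zero-volume tets are a constructor error, while
  `mesh_quality()` reports them without raising for triage.
* Degenerate-input policy: negative densities, ν ≥ 0.5, zero moduli,
  all-DOFs-constrained systems, all-zero norm fields and free-system
  static solves are errors with specific messages, not NaNs.
* Problem sizes in the shipped tests: dense oracles up to ~300 DOFs,
  iterative solves up to ~3000 DOFs, the beam ladder up to divisions
  (40,4,4) — small enough to run everywhere in minutes, large enough to
  expose convergence behavior.

## Known limitations

Linear isotropic elasticity only (no anisotropy, nonlinearity, contact or
soft tissue); homogeneous Dirichlet constraints only; tetrahedral cells
only in both mesh dialects; the mode-1 default for k is a heuristic, not a
proven minimizer of static stiffness; and the free-model "static"
stiffness is a modal quantity without a static experiment behind it.
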