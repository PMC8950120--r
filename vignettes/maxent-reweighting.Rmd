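---
title: "Constrained-entropy reweighting of biased molecular ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained-entropy reweighting of biased molecular ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Enhanced-sampling simulations of protein unfolding deliberately distort the
Boltzmann distribution: a history-dependent bias $V_G(\xi)$, built as a sum
of gaussians in a collective variable (CV) $\xi$, pushes the system out of
its free-energy wells so that folded and unfolded configurations are both
visited. The collection of configurations gathered under the final, fixed
bias is the *metastatistics*: its CV distribution is approximately — never
exactly — flat. The question this package addresses is how to extract
thermodynamic statements from such a deliberately distorted sample without
attempting a full bias cancellation, which demands far more statistics than
a desk-scale (or even cluster-scale) run provides.

## The model

Let $\tilde P_\gamma$ be the metastatistics probability of stored frame
$\gamma$ with CV value $\xi_\gamma$ (frames carry unit multiplicity;
degeneracy is encoded by repetition). Among all distributions $P_\gamma$
with a prescribed CV average $\sum_\gamma P_\gamma \xi_\gamma = s$, the one
closest to the metastatistics in relative entropy maximizes the
cross-entropy $S_c[P,\tilde P] = -\sum_\gamma P_\gamma \ln (P_\gamma/\tilde
P_\gamma)$ and is the exponential tilt

$$P_\gamma = \frac{\tilde P_\gamma e^{-\lambda \xi_\gamma}}{Z_\lambda},
\qquad
Z_\lambda = \sum_\gamma \tilde P_\gamma e^{-\lambda \xi_\gamma},$$

with $\lambda(s)$ fixed by the constraint. At the maximum,
$\bar S_c(s) = \ln Z_\lambda + \lambda s \le 0$, with equality exactly at
the metastatistics mean ($\lambda = 0$); $\bar S_c$ is $-\mathrm{KL}(P \|
\tilde P)$, and the identity $d\bar S_c/ds = \lambda(s)$ holds along the
profile (the package tests verify it numerically to $10^{-3}$). Any
observable $B$ is averaged under the tilt,
$\langle B\rangle_\lambda = \sum_\gamma P_\gamma B_\gamma$, and the
informational free energy of the constrained state is

$$F(s) = \langle H\rangle_{\lambda(s)} - T\,k_B\,\bar S_c(s),$$

shifted so that $F$ vanishes at a chosen reference $s$. $H$ is an
enthalpy-like per-frame observable: either the simulation enthalpy carried
in the metastatistics table, or the MM/PBSA-style mean-field energy
$\bar U = U_\mathrm{intra} + U_\mathrm{solv,np} + U_\mathrm{solv,pol}$
assembled by this package (the intramolecular terms are ingested, never
computed here).

**What $F(s)$ is and is not.** $F(s)$ measures the cost of *imposing an
ensemble average* on the metastatistics. It is not the potential of mean
force of standard metadynamics, $F(s)-F(s_0) = -[V_G(s)-V_G(s_0)]$, which
the package also provides for comparison. The distinction matters: at an
intermediate imposed average the tilted ensemble is a *mixture* of the
low- and high-CV populations, not a localized state. An exact-quadrature
study on a double well (reproduced in the package tests) shows the
consequence: free-energy *differences between well regions* are recovered
essentially exactly as the metastatistics approaches flatness, while the
*barrier top* is structurally invisible to the constrained-mean profile —
the mixture at $s \approx 0$ has nearly the same average energy and a small
entropy cost. Users should read $F(s)$ as a relative-stability measure
between imposed states (the folded/unfolded comparison it was designed
for), never as a transition-state estimate.

## Solving for the tilt

$\lambda(s)$ solves the scalar equation
$\langle\xi\rangle_\lambda = s$, approached as a least-squares problem
$\chi^2 = (\langle\xi\rangle_\lambda - s)^2/\sigma^2$ with $\sigma^2 = 1$
by convention. The solver is Levenberg–Marquardt (`minpack.lm`) with the
analytic derivative $d\langle\xi\rangle_\lambda/d\lambda =
-\mathrm{Var}_\lambda(\xi)$, declared converged when the relative $\chi^2$
change drops below $10^{-4}$. Because $\langle\xi\rangle_\lambda$ is
strictly decreasing in $\lambda$, a bracketed root search is a safe
fallback whenever the LM step stalls; both routes give the same solution.
All tilted sums are accumulated in the log domain with max-shifting, so
$|\lambda\xi|$ up to $\sim 700$ cannot overflow, and $\ln Z_\lambda$ (never
$Z_\lambda$) is stored. Targets outside the open sampled CV range are
rejected as unreachable; a zero tilted variance is reported as a degenerate
ensemble. The sensitivity $\partial s/\partial\lambda =
-\mathrm{Var}_\lambda(\xi)$ also propagates an uncertainty on the imposed
average to one on $\lambda$; the error diverges where the modulated
ensemble collapses onto a single CV value — large $\lambda$ uncertainties
near the middle of the sampled range are expected and physically
meaningful, not a solver failure.

Statistical errors on constrained averages use stride-offset blocking:
block $b$ of 100 is the subsample $b, b+100, b+200, \dots$ (9000 frames at
the default geometry, matching a 900,000-frame trajectory), each block
averaged under the same tilt, and the error reported as the RMS deviation
of block averages about their mean — the across-block spread, with the
spread$/\sqrt{N_\mathrm{blocks}}$ alternative available via an argument.

## Collective variables

The CV is a coordination number over backbone hydrogen-bond pairs,
$S_a = \sum_{ij} (1-x_{ij}^6)/(1-x_{ij}^8)$ with $x_{ij} = |r_i - r_j|/d_0$
— a smooth bond count that is 1 at contact and exactly $6/8$ at $r = d_0$
(the analytic limit of the removable singularity, special-cased within
$|x-1| < 10^{-6}$). The frataxin pair lists are shipped: 18 N/O pairs
across the four-strand β-sheet (`beta_1-4`, the biased CV), 19 pairs for
helix α1 and 8 for α2, all at $d_0 = 3.5$ Å; they address backbone N/O
atoms by author residue numbering, so they are identical for the wild type
and the eight studied point variants. The salt-bridge score SSB enumerates
*all* acidic × basic group pairs (Asp Cγ, Glu Cδ, terminal C × Lys Nζ,
both Arg Nη, terminal N; His excluded) at $d_0 = 4$ Å. Counting both Nη
atoms of arginine is a deliberate reading of "all possible pairs";
per-pair contributions are returned so the sensitivity of SSB to this
choice is directly inspectable. The exponent pair (6, 8) is fixed.

## Bias bookkeeping

Biases are explicit gaussian sums (unit height in kcal/mol and unit width
in CV units by default; the width is the standard-deviation parameter). A
one-sided harmonic wall $k/2\,(\xi-\xi_0)^2$ with $k = 100$ kcal/mol below
$\xi_0 = 1$ guards against complete unfolding. For use as a fixed external
potential the accumulated bias can be smoothed: a quartic is least-squares
fitted to 15 equally spaced samples on $[1.5, 15.5]$ and continued outside
by its tangent lines, giving a $C^1$ form whose linear tails replace the
wall. Multi-walker runs mix biases "altruistically": walker $i$ receives
$(1-\alpha)V_i + \alpha w \bar V$ with $\bar V$ the plain walker mean.
$\alpha = 0$ is the identity and $w = 1$ preserves the summed bias for any
$\alpha$; the schedule steps $\alpha$ through $0, 0.25, 0.5, 0.75$ at
$w = 1$ and finishes bias construction at $\alpha = 1$, $w = 0.5$. This
linear-combination form satisfies those limits but is a declared stand-in
for the published multi-walker scheme, which should be consulted before
any claim of exact fidelity.

## The toy generator

`run_walkers()` exercises every code path above on an analytic 1-D system
where the CV is the coordinate itself: overdamped Euler–Maruyama dynamics,
$x \leftarrow x - U'(x)\,\Delta t/\gamma m + \sqrt{2 k_B T \Delta
t/\gamma m}\,\eta$, with per-walker reproducible noise streams. The study
conditions are fixed: the asymmetric double well $U(x) = 5(x^2-1)^2 + x$
kcal/mol (barrier 6 kcal/mol from the deeper well, well asymmetry 2
kcal/mol — comparable to a small protein's folding barrier), $T = 300$ K,
8 walkers, deposited gaussians of 0.12 kcal/mol height and 0.15 width
(about a third of the well width, standard metadynamics practice), one
deposition per 200 steps, and stage durations
(32000, 8000×4, 32000, 40000) steps mirroring the equilibrate → mix →
fix-and-collect staging, with frames recorded every 10 steps of the final
fixed-bias stage (32,000 frames). The half-length schedule was rejected
during design because the deposited bias demonstrably had not converged
(the $-V_G$ estimate missed the barrier by ~20%); at the adopted length it
agrees with the analytic barrier to 2–4% across seeds.

What the toy does and does not emulate: it reproduces biased multi-walker
dynamics, partial histogram flattening with residual wells, altruistic
mixing, and a per-frame energy observable — the features the reweighting
machinery consumes. It has no molecular structure, no solvent, no
conformational entropy, and its CV is noiseless; passing tests therefore
validate the estimator pipeline, not force-field realism. The
exact-quadrature oracle (`constrained_profile_reference()`) applies the
same constrained-entropy formulas to the continuous biased density and is
the independent reference the sampled pipeline is checked against.

## Solvation terms

SASA uses Shrake–Rupley counting on a deterministic 122-point golden-spiral
covering with a 1.4 Å probe. Hydrogens have zero radius, contribute zero
area and do not occlude (their surface is subsumed by the parent heavy
atom). The point set is fixed in the lab frame, so rigid-motion invariance
holds only to quadrature error — about 1–2% at 122 points on a packed
solute, tightening with more points; tests assert it at that measured
tolerance. Radii and the nonpolar coefficients $\sigma_i$ (positive
hydrophobic, negative hydrophilic) ship as editable element-keyed TSV
tables; because published radii sets differ at the percent level, the SASA
cross-check against an independent implementation is asserted at 2% with
both codes given the same radii.

The polar term solves the linearized Poisson–Boltzmann equation on a
$100^3$ lattice at 0.875 Å spacing (≥ 10 Å solute–boundary clearance
enforced): 7-point stencil, $\varepsilon = 1$ inside the atomic spheres and
80 outside with Debye screening from 0.1 M 1:1 salt, Dirichlet boundary
values from the screened Coulomb sum, Jacobi-preconditioned conjugate
gradients to a $10^{-6}$ relative residual. Two numerical choices carry the
accuracy: the face dielectric is the harmonic mean weighted by the *exact*
inside-fraction of each lattice edge (sphere-chord overlap, combined over
atoms by the maximum), and the Coulomb singularity is split off
analytically so only the smooth reaction field is solved on the lattice —
no matched vacuum solve is needed and the Born-ion benchmark lands within
1% at the working spacing, changing by < 0.5% under grid halving. The
default charge set is a formal-charge table (carboxylate oxygens $-0.5e$,
Lys Nζ $+1e$, Arg Nη $+0.5e$); any force-field charge table can be
substituted. The dielectric cavity is hard spheres without molecular-surface
smoothing, and the solver is strictly linear — both stated limitations.

## Structural observables

Superposition centres both selections (geometric centre by default) and
finds the optimal rotation by SVD with reflection correction. The RMSD is
unweighted by default: backbone heavy atoms have near-equal masses and the
standard tools the reference values come from use the unweighted
convention; a mass-weighted mode is available behind a flag, and on
backbones the two differ well below the comparison tolerances. The
inter-helix angle is the arc-cosine of the dot product of the
Cα(94)→Cα(112) and Cα(184)→Cα(191) unit vectors, reported on [0°, 180°]
(undirected axes). Reweighted histograms apply the modulation weights of a
solved tilt to any observable column; relative SASA divides each group
column by its metastatistics maximum so groups of different sizes become
comparable.

## Degenerate inputs and tie-breaks

Alternate-location conformers resolve to the highest occupancy (ties:
first encountered). Residue ranges are inclusive author numbering
throughout. An empty salt-bridge pair set scores 0 rather than erroring.
Targets at or beyond the sampled CV extremes are unreachable by
construction (the tilt can approach but never attain them). The quartic
smoother requires at least five samples; blocking schemes require
$N_\mathrm{blocks} \le$ stride so blocks never reuse frames.

## Problem sizes

The shipped validation workloads are desk-scale by design: 32,000-frame
toy metastatistics from 8 walkers (≈ 4 s), a 600-frame ensemble for the
$d\bar S_c/ds$ identity on a 651-point grid, 1,000 random ≤ 20-frame
ensembles for enumeration equivalence, the Born ion on the full $100^3$
lattice at two spacings, a 50-residue synthetic helix for SASA
cross-checks, and 900,000-point white noise for the blocking geometry.
Real-application inputs (multi-million-frame tables, full proteins in the
PB grid) use the same code paths; the PB solve on a protein-sized cavity
is the only step that grows beyond seconds.

## Known limitations

The structure-derived reference values for the frataxin fold (coordination
numbers, SASA totals, inter-structure RMSD) require the deposited PDB
entries, which are not redistributable inside the package; the acceptance
suite records this as an explicit failure rather than skipping. The
constrained-mean profile cannot resolve barrier tops (see above). The
altruistic mixing formula is a declared stand-in. PB is linear with a
hard-sphere cavity; SASA rotation invariance is quadrature-limited; and
the mean-field pathway ingests, rather than computes, intramolecular
force-field terms.
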