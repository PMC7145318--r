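---
title: "Methods: models, estimators and design choices in sugartraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in sugartraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`sugartraj` analyses molecular-dynamics trajectories of disaccharide–water
mixtures under orthorhombic periodic boundary conditions. This vignette is
the package's own account of the science it implements: the estimators, the
assumptions behind them, the tunable parameters, what the synthetic
generators do and do not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## Data model and geometry

A `Trajectory` couples a topology (per-atom element, site label, molecule
id/type, mass, charge, Lennard-Jones σ/ε) with frames of Cartesian
coordinates (Å), per-frame box lengths and times (ps). Site labels follow
the standard disaccharide scheme: per hexose ring, carbons C1–C6, hydroxyl
oxygens O1–O4 with hydrogens Ho, a ring-oxygen analogue Oe; one bridging
(glycosidic) oxygen Ob per molecule; waters are Ow with two Hw. Labels
duplicated across the two rings are disambiguated with a ring suffix
(`"O1/2"`). XYZ and PDB files cannot carry charges or LJ parameters, so the
topology travels in a tab-separated sidecar.

All distances use the analytic minimum-image fold
`d − L·floor(d/L + 1/2)`, which places every component in [−L/2, L/2). Only
orthorhombic cells are supported: the NPT cells these analyses target are
rectangular, and triclinic support would complicate every estimator for no
gain here. Molecules are kept whole by construction (generators wrap
molecule centres, not atoms), so intramolecular geometry never needs
unwrapping; analyses that traverse a molecule (dihedrals, alignment) still
rebuild it through minimum-image steps defensively.

Composition arithmetic uses fixed molar masses M_THAL = 342.296 and
M_water = 18.0153 g/mol. With 1500 waters fixed, the integer disaccharide
count for a target mass fraction ω is `round(n_w·M_w·ω / (M_T·(1−ω)))`; the
realized ω is recomputed from integer counts and the residual reported.

## Hydrogen bonds

A bond is a donor–H···acceptor triple with d(O_d···O_a) ≤ 3.5 Å and donor
angle ≤ 60°, both inclusive. The angle is taken at the donor oxygen between
its O–H bond and the O···O vector. The criterion source states only
"donor–acceptor separation and angle"; 60° is only geometrically sensible
for this donor-centred angle (the alternative D–H···A angle convention is
cut near 120–180°), so that convention is adopted, recorded in the criteria
object, and configurable. Ob and Oe are excluded as acceptors by default —
the bridging oxygen is sterically hindered and the production analyses
discard it — and a flag re-enables them. Each donor hydrogen binds at most
one acceptor per frame (nearest acceptor wins); this prevents double
counting in dense systems and can be switched off for oracle comparisons.

The census reports per-class totals (WW, WT = water donor → sugar,
TW = sugar donor → water, TT) averaged over frames, and per-molecule
averages. For the symmetric classes (WW, TT) each bond contributes to both
partners, i.e. per-molecule = 2·total/n; for the mixed classes
per-molecule = total/n_sugar. The factor 2 is stated explicitly because
"bonds per molecule" is otherwise ambiguous; the same convention is applied
to WW and TT for consistency.

## Reactive-flux kinetics

The bond population is intermittent: h(t) = 1 whenever the pair satisfies
the criteria at frame t, regardless of intervening breaks. With averages
over all time origins,

- c(t) = Σ⟨h(0)h(t)⟩ / Σ⟨h(0)⟩ — probability a bond present at 0 is present
  at t;
- n(t) = Σ⟨h(0)(1−h(t))·present(t)⟩ / Σ⟨h(0)⟩ — broken but still within the
  reformation cutoff (default: the bonding distance cutoff, 3.5 Å).

The rate model is the standard two-rate reactive-flux system
k(t) = −dc/dt = k_f·c(t) − k_b·n(t), solved for (k_f, k_b) by least squares
over a window with non-negativity enforced; lifetimes are reciprocals.
The method name in the source carries no equations, so this Luzar–Chandler
form with the intermittent population operator is adopted as the standard
reading of "reactive flux with forward and backward processes" — the one
substantive interpretation this package commits to, hence stated
prominently here. The derivative is a central difference (optional
running-mean smoothing, off by default); the default window
[0.1, 0.5]·t_max skips the short-time transient and the noisy tail. A fit
with k_f = 0 reports an infinite forward lifetime with a warning rather
than failing — mirroring the physically expected non-identifiability of
reformation deep in the glassy regime.

Correlation sums are computed exactly (all origins) via FFT
cross-correlation in column blocks, so 10⁴ pairs × 2000 frames fits
comfortably in memory and seconds of CPU.

## Structure

**RDF.** g(r) histograms all intermolecular minimum-image A–B site
distances, normalized by exact spherical-shell volume, B-site density and
the number of A sites and frames. Intramolecular pairs are always excluded:
the target analyses concern intermolecular structure. Defaults: bin width
0.05 Å, r_max = min(12 Å, L/2). The running integral
N(r) = 4πρ_B ∫₀^r g s² ds uses trapezoidal accumulation on the same bins;
tests require agreement with direct neighbour counting within 1%.

**SDF.** Target-site density in a reference molecule's body frame. The
canonical frame is the first reference molecule in the first frame; each
(frame, molecule) sample is superposed onto it by least-squares rigid-body
(Kabsch) alignment of ≥ 3 non-collinear sites, and target positions (nearest
image to the reference) are binned on a cubic grid. The density integrates
to the mean target count within the grid extent, which the tests assert.

**CDF.** For molecule pairs within r_max (default distance: Ob–Ob, the
bridging-oxygen separation the source itself equates with centre-of-mass
separation), the joint histogram of distance and the acute angle φ ∈ [0°,
90°] between two intramolecular vectors (default: ring carbons C1–C4).
φ is folded to the acute range because ring vectors are
orientation-symmetric; stacking detection needs only the acute angle. For
isotropic orientations the φ-marginal follows sin φ, which the tests check
by Kolmogorov–Smirnov.

**Dihedrals.** Standard signed dihedral of four labelled sites per molecule,
histogrammed over (−180°, 180°] with circular mean and s.d. The default
quadruple around the glycosidic bridge is Oe/1–C1/1–Ob–C1/2. The exact
four atoms used in the source are not stated, so the quadruple is a
parameter; no literature value is used as a test oracle. (An earlier draft
used Oe–C1–Ob–C1 with a 180° glycosidic angle, which is degenerate; the
template therefore uses a bent C1–Ob–C1 bridge of 114°, keeping the default
quadruple well-defined.)

## Clustering and percolation

Molecules are linked when designated sites fall within a cutoff (default
Ob–Ob ≤ 6.0 Å, motivated by the first-peak region of the Ob–Ob RDF in the
5–10 Å range) or, alternatively, when hydrogen-bonded. The criterion is a
documented choice, not a value from the source, which discusses clusters
only via RDFs and snapshots. Components are found by union–find with an
integer image offset propagated per molecule; an edge that closes a cycle
with a non-zero summed image shift marks the cluster as percolating on the
affected axes — the standard detection of aggregates that connect to their
own periodic images ("propagating through neighbouring cells"). Tests
require exact agreement with a 3×3×3 replicated-supercell flood fill.

## Transport

MSD is averaged over molecules and time origins on the centre of mass,
computed **only** from unwrapped coordinates — the Brownian generator emits
them in a dedicated channel, and `compute_msd` refuses wrapped-only input
rather than silently producing bounded nonsense. Lags are log-spaced (≤ 120
by default); origins are strided only when the full average would exceed
~3·10⁸ operations, and sample counts are reported. The diffusive window is
the longest contiguous lag range with local log–log slope |β−1| ≤ 0.1
(5-point smoothed central differences); D is the linear MSD slope there
divided by 6. Ballistic input (β = 2) and glassy, sub-diffusive input yield
an explicit "no diffusive regime" error instead of a spurious D — matching
how non-diffusive state points should be reported. Arrhenius diagnostics
fit ln D vs 1/T; structured residuals and depressed R² are the intended
signature of super-Arrhenius (Vogel–Fulcher-like) behaviour near the glass
transition.

## Glass transition and Couchman–Karasz

Tg is read from the maximum of the density–temperature curve per
composition — an unconventional criterion, but the one the source states
and uses (its protocol simulates each temperature independently to avoid
cooling-rate artifacts). `quadratic_window` fits a parabola to the five
tabulated points bracketing the grid maximum and returns the vertex
(falling back to the grid argmax with a warning if the vertex escapes the
window); a smoothing-spline argmax is provided as a robustness alternative.
Monotone curves raise an explicit "no density maximum" error. The
Couchman–Karasz mixture rule
Tg(ω) = (ω·ΔCp_T·Tg_T + (1−ω)·ΔCp_W·Tg_W)/(ω·ΔCp_T + (1−ω)·ΔCp_W)
is implemented with literature-typical default parameters (Tg 136/388 K,
ΔCp 1.94/0.55 J g⁻¹K⁻¹ for water/trehalose); these are configurable inputs,
never test oracles — the source reports no numeric Tg values, so agreement
is validated structurally (monotonicity, bounds, exact recovery on
synthetic curves), not numerically.

## Energetics

Intermolecular pair energies are Lennard-Jones with Lorentz–Berthelot
mixing plus Coulomb with the CODATA conversion constant
(≈ 1389.35 kJ Å mol⁻¹ e⁻²), summed per molecule-type class (water–water,
water–sugar, sugar–sugar) within a 15 Å default cutoff. Coulomb is
truncated in real space at the same cutoff instead of Ewald-summed: a
per-class decomposition is not well defined for the reciprocal-space Ewald
term, so this deviation from the production engine is deliberate and an
optional shifted potential reduces truncation artifacts. No 1–4 scaling
and no tail corrections are applied; bonded terms are out of scope, so the
reported total is the intermolecular sum only.

## Synthetic generators: the stated world

The generators produce data whose ground truth is known by construction;
they emulate the *statistical signatures* the analyses measure, not the
physics of real mixtures.

- **Pseudo-disaccharide template**: rigid, coarse, with correct site labels
  and multiplicities (12 C, 8 OH + Ho, 2 Oe, 1 Ob), hexagonal rings
  (C–C 1.54 Å, C–O 1.43 Å, O–H 0.96 Å), bent 114° glycosidic bridge,
  configurable inter-ring dihedral. Hydroxyl hydrogens point out of the
  ring plane so radial solvation approaches stay outside the donor cone.
  It is not a chemically accurate conformer and carries illustrative
  charges/LJ values (SPC-like water: q = −0.8476/+0.4238 e,
  σ(Ow) = 3.166 Å, ε(Ow) = 0.650 kJ/mol); these are test fixtures, not
  force-field claims.
- **Hydrated fixture**: exactly `waters_per_site` waters per hydroxyl
  oxygen at the prescribed donor distance, placed by a deterministic greedy
  search over a direction cone that keeps every water ≥ 3.55 Å from all
  other sugar oxygens and outside the site's own donor cone; the
  construction is verified post hoc and fails loudly rather than delivering
  approximate counts. Up to 2 waters per site is always feasible; 3 may
  legitimately fail sterically.
- **Telegraph kinetics**: independent two-state chains sampled on the frame
  grid with per-step switching probabilities 1 − exp(−k·dt), realized
  geometrically as water pairs toggling between a bonded (2.8 Å, 0°) and a
  broken-but-adjacent (3.2 Å, 90°) arrangement. The discretization biases
  recovered rates by O(k·dt) — ≤ ~1% at the default k·dt ≤ 0.02 — well
  inside the 15% recovery tolerance.
- **Brownian dynamics**: Gaussian steps of per-axis variance 2·D·dt; no
  interactions, no hydrodynamics, no caging. A green diffusion test
  establishes estimator correctness, not that real sugar solutions are
  Fickian.
- **Clusters**: chains with controlled link distances; the percolating
  variant spaces one chain across the full box length so its ends meet
  through the boundary.
- **Density curves**: ρ(T) = ρ0(ω) − c·(T − Tg)² + noise with
  ρ0 = 1.0 + 0.58ω g/cm³ and c = 5·10⁻⁶ g cm⁻³ K⁻² by default — magnitudes
  chosen once to resemble the measured curves (maxima shifting with
  composition, ~0.1 g/cm³ variation across the 100–400 K grid) — with the
  production temperature grid (100, 150, 180, 200, 230, 270, 310, 340,
  370, 400 K) as default.

What a green suite establishes: the estimators recover known truth at
stated tolerances and agree with independent brute-force oracles. What it
does not establish: anything about real trehalose–water physics — those
claims require real trajectories, which this package analyses but does not
produce.

## Numerical choices and degenerate inputs

- Distance/angle cutoffs are inclusive; boundary behaviour is tested.
- The minimum-image fold uses `floor(x/L + 1/2)`, giving the half-open
  interval [−L/2, L/2) deterministically at the boundary.
- RDF shell normalization uses exact shell volumes (4π/3)(r₊³−r₋³) rather
  than the 4πr²Δr approximation; the difference matters only for wide bins.
- Reactive-flux fits clamp negative rates to zero and refit rather than
  reporting unphysical values; singular designs raise errors.
- Tg parabola fits enforce negative curvature; off-window vertices fall
  back to the grid argmax with a warning.
- Empty selections, monotone curves, never-bonded pairs, wrapped-only MSD
  input, packing failures and missing force-field parameters all raise
  targeted errors naming the offending entity.

## Known limitations

- Orthorhombic boxes only; no triclinic cells, velocities or forces.
- Coulomb truncation (not Ewald) in the energy decomposition, as discussed.
- The MSD origin average strides origins on very long inputs (reported in
  the output) rather than using an FFT decomposition.
- Percolation is detected from the adjacency graph of one frame; no
  tracking of cluster identity across frames.
- The CLI covers the analysis surface with sensible defaults but not every
  function argument; the R API is the complete interface.
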