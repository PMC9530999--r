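---
title: "Methods: dye-dimer geometry, excitonic coupling and contacts on DNA Holliday junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dye-dimer geometry, excitonic coupling and contacts on DNA Holliday junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjdimer)
```

## Scope and model

`hjdimer` analyses multi-frame coordinate data of a DNA four-arm
(Holliday) junction carrying two covalently tethered cyanine dyes. It
does not run molecular dynamics; it consumes trajectories (multi-model
PDB or a plain text frames format) and reduces them to the quantities
that characterise the dimer: the orientation factor $\kappa_{m,n}$, the
centre distance $R_{m,n}$, the excitonic hopping parameter $J_{m,n}$,
dye--DNA contact maps, presentation statistics, and junction arm
angles.

The geometric model of a dye is deliberately minimal: the transition
dipole of a cyanine runs along the polymethine long axis, so each dye
is represented per frame by the segment between the centroids of two
end-atom selections, $r_i$ (head) and $s_i$ (tail). From these,
$l_i = |r_i - s_i|$, $\hat\mu_i = (r_i - s_i)/l_i$ and the centre
$(r_i + s_i)/2$. The dipole magnitude $\mu_i$ is an input (Debye),
treated as constant over the trajectory: bending or stretching of the
dye would modulate the true transition dipole slightly, and no
correction for this is attempted. When a dye definition omits the end
selections, the two indolenine-ring nitrogens are used (the residue
must then contain exactly two nitrogen atoms); any explicit atom
selection overrides this.

All lengths are nanometres inside the package (PDB Ångströms are
divided by 10 at the file boundary), times are picoseconds, couplings
meV. Coordinates are assumed whole-molecule and unwrapped across
periodic boundaries; the package performs no periodicity handling, and
distance-based quantities are meaningless on wrapped input.

## Orientation factor and classification

$$\kappa_{m,n} = \hat\mu_m\cdot\hat\mu_n -
3(\hat R_{m,n}\cdot\hat\mu_m)(\hat R_{m,n}\cdot\hat\mu_n)$$

with $\hat R_{m,n}$ the unit vector between dipole centres. The signed
value is stored -- the sign carries head/tail information -- and
$|\kappa|$ is taken at presentation time. $|\kappa| \in [0, 2]$, with 2
attained only for collinear dipoles; $|\kappa| \le 1$ is read as
predominantly stacked (H-like), $|\kappa| > 1$ as predominantly
end-to-end (J-like). Classification combines this with a distance
criterion: centre distances at or below `dimer_r_max` (default 1.5 nm)
count as a closely spaced dimer, larger ones as separated. The
boundary $|\kappa| = 1$ classifies as H-like (closed on the stacked
side); this is an arbitrary but fixed convention recorded in the
output metadata.

## Extended-dipole coupling

Each transition dipole is replaced by two opposite point charges
$\pm q_i$, $q_i = \mu_i / l_i$, at the dye ends ($+q$ at $r_i$, $-q$ at
$s_i$). The coupling is the Coulomb energy of the four inter-dye charge
pairs, screened by the squared refractive index of the aqueous medium:

$$J_{m,n} = J_0\left(\frac{1}{|r_m - r_n|} + \frac{1}{|s_m - s_n|}
  - \frac{1}{|r_m - s_n|} - \frac{1}{|s_m - r_n|}\right),
\qquad J_0 = \frac{\mu_m \mu_n}{4\pi\epsilon_0 n^2 l_m l_n}.$$

`prefactor_J0()` reports $J_0$ in meV·nm so that the bracket, taken
with distances in nm, yields meV directly. Internal arithmetic is SI
(CODATA 2018 constants; 1 D = 3.33564095198152×10⁻³⁰ C·m) with a single
conversion at the end. The default refractive index is 1.33, water at
optical frequencies; only this $n^2$ screening is applied -- no
local-field factors. Under this charge convention a parallel stacked
pair has $J > 0$ and a collinear head-to-tail pair $J < 0$; summaries
report $|J|$, the per-frame tables keep the sign.

`point_dipole_J()` implements the Kasha closed form
$\kappa\,\mu_m\mu_n / (4\pi\epsilon_0 n^2 R^3)$. It is not used in the
pipeline; it exists as an independent limiting-case oracle. The test
suite verifies that the extended-dipole value agrees with a literal
four-charge Coulomb sum to ~10⁻¹⁴ relative on 1000 random
well-conditioned geometries, converges to the point-dipole form within
0.1% at $R = 100\,l$ monotonically along a ray, and is damped relative
to the point-dipole value at contact-scale separations for stacked
geometry -- the physically expected behaviour of distributed charges.

A note on conditioning: the four-term bracket cancels almost exactly
for far, weakly coupled geometries with $\kappa \approx 0$, where any
fixed *relative* tolerance is dominated by floating-point rounding of
the cancelled terms. Oracle-equivalence checks therefore reject
geometries whose bracket magnitude falls below 2% of its largest term;
the physics of such geometries ($J \approx 0$) is covered separately by
closed-form zero cases.

## Contact maps

Residue groups follow the junction's standard partition: the six
central bases (residue numbers 11--16, configurable) of each of the
four strands, plus one group per dye -- 26 groups for a 4 × 26-residue
junction with two dyes. A dye residue falling inside the window is
excluded from the base groups. Two groups are in contact in a frame
when the shortest distance between their representative points is
within the cutoff (default 1.2 nm, the short-range interaction cutoff
of the simulations such maps describe); "within" is implemented as ≤,
an inclusive boundary -- boundary cases are measure-zero for real
coordinates and are pinned in the tests. Bases contribute their centre
of mass (all atoms, standard atomic weights; a heavy-atom-only option
exists); dyes contribute the whole-residue centre of mass plus both
dipole-end centroids, capturing their anisotropic shape. Map entries
are fractions of retained frames; the diagonal is 1 by definition.
Multi-trial pooling is a frame-count-weighted average. Every output map
is validated for symmetry, unit diagonal and [0, 1] bounds.

## Presentation statistics

Heatmaps are normalized 2-D histograms of pooled observations. Default
bin widths -- R in [0, 5] nm at 0.05 nm, $|\kappa|$ in [0, 2] at 0.05,
$|J|$ in [0, 200] meV at 2.5 meV -- were chosen once to resolve the
peak scales of closely spaced cyanine dimers (a few tenths of a nm,
tens to ~150 meV). Trials are pooled before normalization, so pooling
is exactly order-independent.

Trial summaries report, per quantity, the pooled mean, the pooled
*population* standard deviation (ddof = 0), the per-trial means, and
the sample standard deviation across trial means. Both spreads are
emitted because a "mean ± SD over trials" table is ambiguous between
the two; the pooled SD is the default headline number.

## Junction arm angles

The construction here is an explicit package convention, validated on
constructed geometries with known angles rather than against any
external definition. An arm is two equal-length, pairing-ordered
residue spans; base-pair centroids are midpoints of paired residue
centres of mass, and an arm axis is the first principal direction
(SVD) of at least four ordered centroids, oriented away from the
junction centre (or from first to last centroid when no centre is
given). A stacked duplex axis is the principal direction of the pooled
centroids of its two arms, oriented from the first arm toward the
second. The inter-duplex angle (IDA) is the angle between the two
duplex axes in [0, 180]°. The twist is the angle between the
projections of the two axes onto the plane perpendicular to the
inter-duplex anchor-to-anchor vector, folded into [0, 90]° so that
coplanar duplexes give exactly 0 regardless of axis orientation.
Degenerate inputs -- coincident anchors, an axis parallel to the
inter-duplex vector, collinearity-insufficient point sets -- raise
geometry errors rather than returning branch-unstable values.

## Synthetic generator: what it emulates, and what it does not

The generator provides the study conditions for every test. Rigid-rod
dimer ensembles place two rods (default length 1.4 nm, the Cy5 scale)
with a per-frame centre separation drawn from Normal(`r_mean`, `r_sd`)
along the mode's canonical axis -- perpendicular to the rods for the
stacked modes, longitudinal for the end-to-end mode -- and perturb each
rod by independent rotations about two axes orthogonal to its director,
angles ~ Normal(0, 10°) by default. Mode defaults emulate the
characteristic separations of the four observed configurations:
H dimer 0.5 ± 0.04 nm, J dimer 1.4 nm, separated-H 2.5 ± 0.3 nm,
effectively-monomer 4.2 ± 0.5 nm (the monomer mode draws the second
rod's orientation uniformly). The small-angle rotation model was chosen
because it is analytically tractable: centres are unaffected, so the
drawn separation is recovered exactly in expectation, and the noiseless
limits are exact ($\kappa = 1$ stacked, $\kappa = -2$ head-to-tail).

The mock junction is four 26-residue pseudo-strands (one carbon
pseudo-atom per base, 0.34 nm rise) laid out as two straight duplexes
crossing at a configurable angle (default 60°), with the arm pairing
switched between the Iso I and Iso II conformers and the second duplex
displaced 0.8 nm out of plane. Pseudo-dyes (two end atoms plus a centre
atom, uniform masses so centres of mass are exact) are placed per
isomer/attachment: transverse dyes 0.5 nm apart (Iso I) or 4 nm apart
on opposite sides (Iso II); adjacent dyes end-to-end at 1.4 nm (Iso I)
or separated-stacked at 2.2 nm (Iso II). Frames are static replicates
unless seeded jitter is requested.

None of this is physical DNA mechanics: no solvent, ions, tether
torsions, base stacking or junction breathing. Passing tests therefore
demonstrate that the *analysis machinery* is correct -- formulas,
bookkeeping, classification, determinism -- not that any MD force field
or sampling protocol is adequate. Real trajectories additionally
carry slow conformational transitions and dye--DNA intercalation that
the generator does not emulate.

## Protocol defaults and numerical choices

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| orientation stride | 100 | ps | standard sampling for $\kappa$, R series |
| contact stride | 500 | ps | contacts vary more slowly |
| burn-in | 100 000 | ps | discard equilibration (100 ns of a 1 μs run) |
| contact cutoff | 1.2 | nm | matches the short-range interaction cutoff |
| centre window | 11--16 | residue | six central bases per 26-residue strand |
| $\mu_{Cy5}$, $\mu_{Cy5.5}$ | 15.35, 15.57 | D | TD-DFT literature values, supplied as inputs |
| refractive index | 1.33 | -- | water at optical frequencies |
| $\kappa$ boundary | 1.0 | -- | stacked/end-to-end divide |
| dimer $R_{max}$ | 1.5 | nm | closely spaced vs separated |

With these defaults a 1 μs trajectory written every 10 ps yields
exactly 9001 orientation observations and 1801 contact frames per
trial after burn-in -- an invariant the suite pins. Strides must be
integer multiples of the frame spacing (checked to 10⁻⁹ relative);
frame times are compared with a 10⁻⁶ ps tolerance. Degenerate
geometry (coincident dipole ends, centres, or inter-dye end points)
raises errors instead of producing infinities.

Test and acceptance problem sizes -- 3 × 3000-frame ensembles for
parameter recovery, 1000-frame ensembles for the coupling trend,
100-frame 26-group mocks for contact oracles, 1000 random geometries
for oracle equivalence -- were chosen as the smallest sizes at which
the sampling-theory tolerances (3 standard errors) are meaningfully
tight.

## Reproducibility

Generators are deterministic given (spec, seed). Pipeline outputs are
written with fixed numeric formats and embed the MD5 hash of the run
configuration plus the thresholds used, so identical config + seed
gives byte-identical TSV/JSON files; the suite checks this end to end
through the CLI dispatcher.

## Known limitations

- $\mu_i$ is constant per dye; no vibronic or conformational
  modulation of the transition dipole.
- Only the $n^2$ Coulomb screening of the extended-dipole form; no
  transition-charge (TrEsp) or ab initio couplings, and no vibronic
  Hamiltonian diagonalization.
- Contact criterion uses representative points, not atom-level minimum
  distances; no hydrogen-bond or stacking classification, no contact
  lifetimes.
- The junction angle construction is a pinned convention; absolute
  angle values from other conventions may differ by several degrees
  even for identical coordinates.
- No periodic-boundary handling; inputs must be unwrapped.
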