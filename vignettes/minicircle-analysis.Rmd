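---
title: "Analysing supercoiled DNA minicircles: topology, defects, triplex energetics and AFM morphometrics"
author: "minicircler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing supercoiled DNA minicircles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicircler)
```

## The scientific problem

Closed-circular DNA (a minicircle) is topologically constrained: the number
of times its two strands wind around each other, the linking number Lk, is
fixed until a strand is cut. Torsional stress is imposed by changing Lk away
from the relaxed value Lk0 = n_bp / h, with h ~ 10.5 bp/turn for B-DNA. The
linking difference dLk = Lk - Lk0 (or the superhelical density sigma =
dLk/Lk0) partitions between untwisting of the double helix (twist, Tw) and
coiling of the helical axis in space (writhe, Wr), with Tw + Wr = Lk
(White-Fuller). Enough negative stress disrupts the B-form locally: sharply
bent *kinks* and melted *denaturation bubbles* appear, act as flexible
hinges, absorb torsion and thereby change the global shape of the circle.
These local disruptions in turn modulate how ligands engage the double
helix; the package's worked example is a triplex-forming oligonucleotide
(TFO), a pyrimidine third strand that reads a purine tract in the major
groove through Hoogsteen hydrogen bonds.

`minicircler` implements this analysis chain as a reusable pipeline and, in
place of trajectory or microscope data, generates every input synthetically
with known ground truth: closed curves of prescribed writhe, ribbons of
prescribed Lk, pseudo-atomic minicircles with planted defects and third
strands, and simulated AFM topographs.

## Topology on discrete curves

Curves are ordered point sets (`closed_curve`). Writhe is evaluated as the
Gauss double integral discretized over segment pairs using the exact
pairwise-segment solid angle (the tetrahedral formula), not midpoint
quadrature. The distinction matters: with the exact solid angle, the
discrete Calugareanu-White-Fuller identity holds to machine precision at
any resolution, so a parallel-transport framing of any closed polygon has
an exactly integer linking number. `make_ribbon` exploits this: it builds
the (twist-free) parallel-transport frame, spreads the closure holonomy
uniformly over all steps - the holonomy otherwise sits entirely in the
closing step, where adding an integer winding could push a single rotation
past the principal branch of the angle - and then adds an integer number of
uniform turns to hit the requested Lk. The returned ribbon satisfies
Tw + Wr = Lk to 1e-3 or better (the residual is the writhe discretization,
not the framing).

Twist is measured against a parallel-transported reference, so axis bending
contributes nothing; its sign convention is fixed by requiring consistency
with the Gauss-integral writhe sign. Adjacent and identical segment pairs
are skipped in the writhe sum (singular integrand, standard practice).

Bending is quantified by the directional correlation of tangent vectors
separated by 16 points (about one and a half helical turns): this is long
enough to integrate the bend produced by one defect and short enough not to
mix neighbouring features. On an n-point circle every angle equals
360 * 16 / n degrees, which anchors the statistic analytically (16.99
degrees at n = 339). Peaks above 35 degrees become bend features; features
at or above 75 degrees - the empirical boundary between what canonical
B-DNA can sustain and what requires broken base pairing or stacking - are
classified as defects in `angle_only` mode, while `interactions` mode
classifies by whether the feature span overlaps a span of broken canonical
interactions, whatever the angle. The profile position of a 16-bp statistic
leads the physical bend by half a window, so reported feature positions are
shifted by `separation/2`, placing them at the bend itself.

Global shape: the best-fitting plane comes from the principal axes of the
centred contour; planarity is the mean out-of-plane distance as a
percentage of the longest in-plane axis (the percentage needs a length
normalization, and the longest axis is this package's documented choice);
the aspect ratio is the in-plane extent perpendicular to the longest axis
divided by the longest axis, using extreme points rather than a rotated
bounding box, for both contours and AFM grains. An open circle has aspect
ratio 1; compact writhed forms fall well below it.

## Synthetic minicircles and planted defects

`build_minicircle_model` lays a coarse-grained duplex - three pseudo-atoms
per nucleotide: phosphate (charge -1 e), sugar centroid, base centroid with
a small per-base partial charge - on a closed axis with a rise of 0.34
nm/bp. The relaxed helical repeat is 10.5 bp/turn and defines Lk0 =
n_bp/10.5 throughout the package (one consistent convention for all sigma
arithmetic); the imposed dLk modifies the per-bp twist uniformly.

Planted defects realize the three canonical disruption types as geometric
signatures that the package's own detectors (and any detector using the
same cutoffs) can find:

* **bubble** (>= 2 bp): both base centroids displaced 0.8 nm along the
  base-pair long axis - beyond the hydrogen-bond cutoff and beyond the
  8 Angstrom flipped-base threshold;
* **type I kink** (1 bp): one base displaced 4.5 Angstrom laterally -
  pairing broken, that strand's stacking broken, centroid still inside the
  flipped threshold;
* **type II kink** (2 bp): the two strands pulled 1.5 Angstrom apart along
  the pair axis - hydrogen bonds broken while every base stays within
  stacking distance of its 5' neighbour.

Kinks additionally bend the axis (110 and 100 degrees by default). A rigid
hinge rotation of everything downstream would break ring closure, so the
bend is instead realized by `inject_kink`: the closed curve is rebuilt from
its turning-angle profile with the corner turning concentrated at the kink,
segment lengths kept uniform (preserving the helical rise, which the
stacking detector depends on), and closure restored by modulating the
background curvature with two Fourier harmonics solved by Gauss-Newton
iteration. The axis bend is spread over a few bp so that per-step bending
stays below what the stacking criterion tolerates immediately next to the
defect. Rare crowded multi-kink configurations admit no such closed ring;
since the hinge is cosmetic for defect detection (the displacement
signatures carry the signal), those defects fall back to an unbent axis.

Detection mirrors construction only through public, physical criteria:
hydrogen bonds by a 3.5 Angstrom / 140 degree distance-angle cutoff
(hydrogens are implicit; the angle is taken at the donor heavy atom against
its sugar antecedent), stacking by a geometric proxy (base-centroid
separation <= 4.5 Angstrom and normal alignment >= 0.7 - deterministic and
testable where an energetic criterion would need a forcefield), flipped
bases by centroid displacement > 8 Angstrom from the local axis. Typing is
rule-based: maximal flipped runs of >= 2 are bubbles; two consecutive
unpaired-but-not-flipped pairs with 5' stacking intact are a type II kink;
an isolated unpaired pair with a broken stack is a type I kink; an isolated
unpaired pair with both stacks intact is sub-threshold and yields nothing.

The helical-axis contour is the per-bp circular-window average (11 bp,
uniform or cosine-tapered weights) of Watson-Crick base-pair midpoints,
with flipped pairs excluded and the window renormalized. A full
twist-weighted axis definition exists in the literature; the fixed-width
moving average used here is simpler, and its adequacy is bounded by tested
invariants (rigid-motion equivariance at 1e-9, arc length within 5% of
n_bp x 0.34 nm, flat bend profiles on ideal circles).

## Triplex energetics

The binding decomposition works on a bound/unbound model pair that is
identical outside the third strand. Each third-strand base has a 9-base
neighbourhood - the three bases of its own plane plus the planes directly
above and below (the "9 bases" composition is an assumption made
configurable in code). `in_plane` sums its interactions within the plane
(the Hoogsteen and Watson-Crick proxies), `adjacent` those to the
neighbouring planes (stacking/bifurcated/backbone proxies); their sum is
the binding energy, which discards the unbound third strand's self-energy
by construction.

Non-bonded terms use kcal/mol, Angstrom and elementary charges with Coulomb
constant 332.06, a relative dielectric of 78.5 and an optional Debye length
of 9.6 Angstrom (about 100 mM ionic strength, matching the optimal
triplex-binding salt conditions). A Poisson-Boltzmann or Generalized-Born
treatment is deliberately out of scope: the screened-Coulomb model is
transparent, exactly testable against an all-pairs oracle, and the
referencing conventions (`reference_delta` to the relaxed topoisomer or to
a linear fragment) cancel most of the absolute-scale error. Only signs,
orderings and identities are asserted about these energies - the package
makes no claim to reproduce any published energy distribution. Exclusions
are pairs within one residue or between adjacent residues of a strand, the
1-2/1-3 analogue at pseudo-atom resolution.

Two qualitative behaviours are built in and tested: compacting a circle at
fixed contour length raises the magnitude of its electrostatic self-energy
(the penalty that grows with writhe-induced compaction), and displacing the
third strand out of the groove weakens |e_bind| monotonically.

## Simulated AFM topographs and the image pipeline

`render_afm_image` rasterizes projected contours as tubes of height 1.5 nm
(the height DNA measures in liquid AFM), convolves with a Gaussian tip
kernel, and adds per-scan-line offsets, a first-order background tilt and
pixel noise. Metadata records the seed and every planted parameter plus
per-molecule ground truth (centroid, aspect ratio, contour length), so any
recovery statistic can be recomputed without re-reading the image.

The processing chain mirrors standard AFM grain analysis: (1) *flatten* -
per-row median subtraction, first-order levelling and zero-mean; medians,
not means, so molecules do not bias the background, and the two median
corrections are iterated to a joint fixed point, making flattening
idempotent to numerical precision; (2) *smooth* - Gaussian sigma = 1.5
pixels truncated at 3.5 pixels (the sigma-vs-support reading of that
combination is ambiguous; both are configurable); (3) *mask* at mean + 1
standard deviation, one-sided above the mean since DNA is raised off the
surface; (4) label connected components at 8-connectivity; (5) *filter
grains* in a fixed order - border-touching grains out, grains under 200
nm^2 out, then the median area computed once and grains outside 50-150% of
it out; (6) per-grain morphometrics with extreme-point axes; (7) 80-nm
crops; (8) *tracing* - half-maximum mask, morphological thinning
(implemented in-package), spur pruning, path ordering, a short moving
average to remove the staircase length bias of 8-connected paths, endpoint
extension along the mask to undo skeleton tip retreat on open molecules,
and greedy maximal straight-segment fits (RMS deviation < 1 pixel) of at
least 5 nm, about one and a half DNA turns - the same resolution as the
16-bp tangent separation used for contours. Angles between consecutive
segments are directional changes in degrees. `locate_protrusion` finds the
maximal contiguous run of path heights above the baseline median by a
threshold, wrapping across the index origin on closed traces, which is how
a bound triplex shows up on a traced molecule.

One synthetic-data caveat surfaced by the suite is worth keeping: a
molecule laid parallel to the fast-scan axis occupies most of one scan
line, and row alignment then subtracts it into the background - the
simulated fixtures are laid diagonally for exactly the reason real AFM
practice avoids that orientation.

What the simulations do *not* emulate: tip-sample convolution beyond a
Gaussian kernel (no tip shape or deconvolution), molecule-surface
deformation, overlapping or touching molecules, and real population
heterogeneity. Passing recovery tests therefore demonstrates correctness
of the pipeline's measurement logic, not performance on arbitrary real
scans.

## Numerical choices and degenerate inputs

* arccos arguments are clamped to [-1, 1]; angles are degrees everywhere.
* Repeated contour points raise a degenerate-geometry error naming the
  0-based index; colinear point sets are rejected by the shape metrics.
* Bend-feature runs separated by less than half the tangent separation are
  merged (one physical bend per feature); tied profile maxima resolve to
  the middle of the plateau.
* All circular coordinates are 0-based with half-open spans, indices modulo
  n; lengths are nm except pseudo-atomic coordinates (Angstrom, PDB
  convention), with conversion confined to the I/O layer.
* Random number use is confined to seeded scopes that save and restore the
  caller's RNG state; every generator is bit-reproducible from its seed.
* Float TIFF storage rescales heights to [0, 1] with the offset and scale
  in the JSON sidecar (the installed TIFF writer clamps values outside
  that range), so TIFF round trips are exact at single precision; the
  whitespace text-grid format round-trips at full double precision.

## Problem sizes used by the test suite

The suite exercises 339-bp circles for all worked examples; property suites
use 50 random ribbons (200-500 points) for the twist-writhe partition, 10
solenoids at 678 points against a 4x-density quadrature oracle for writhe,
30 seeded defect configurations for round-trip recovery, and 20 simulated
256-pixel scans with 5-15 molecules each for grain recovery. These sizes
give stable statistics for every tested property while keeping the suite
quick to run.

## A worked example

```{r example, eval = FALSE}
## a -2 topoisomer with a planted 3-bp bubble and a bound third strand
m <- build_minicircle_model(339, delta_lk = -2,
                            defects = list(list(span = c(170, 3),
                                                kind = "bubble")),
                            with_tfo = TRUE, tbs = c(60, 16), seed = 1)
rep <- run_pipeline(pipeline_config(models = list(m),
                                    run_energetics = TRUE))
r <- rep$models[[1]]
r$defects          # one bubble record at bp 170-172
r$topology$sigma   # -0.062: sigma = dLk / (339/10.5)
r$writhe           # axis writhe of this conformer
r$energy$e_bind    # third-strand interaction energy, kcal/mol
```

## Known limitations

* The defect typing is purely rule-based; no visual-inspection step, no
  free energies of denaturation, no sequence-dependent melting.
* The energetics is a relative, screened-Coulomb model: absolute binding
  free energies, entropy and solvation surface terms are out of scope.
* The tracer refuses branched skeletons (self-crossing projections) rather
  than resolving crossings.
* Sequence-dependent elasticity and any molecular dynamics are out of
  scope; the generators produce geometric, not thermodynamic, ensembles.
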