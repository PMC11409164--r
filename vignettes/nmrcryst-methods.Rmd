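---
title: "Methods: ensemble selection against chemical-shift distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble selection against chemical-shift distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcryst)
```

## The model

Amorphous molecular solids are ensembles. Solid-state NMR observes that
ensemble through inhomogeneously broadened lines: each assigned site k is
described not by one shift but by a distribution, which we take to be
Gaussian with mean $\mu_k$ and standard deviation $s_k$ (both in ppm). The
structural question — which conformations and packing motifs does the
experiment actually support? — is answered by scoring a large pool of
candidate environments (the *MD set*, from molecular-dynamics snapshots)
against these distributions and keeping the best-matching subset (the
*NMR set*).

An environment's agreement is computed shift by shift. For a predicted
shift $\delta_i$ against the distribution $(\mu_i, s_i)$ we use the
two-sided Gaussian tail probability

$$p_i = \operatorname{erfc}\!\left(\frac{|\delta_i - \mu_i|}{s_i\sqrt 2}\right),$$

which is 1 at the mean and decreases with the standardized deviation, and
aggregate with the geometric mean $p_\mathrm{global} = (\prod_i
p_i)^{1/N}$. The upstream literature defers the exact functional form to
its methodological reference; we chose the geometric mean because the
reported global probabilities (p* ≈ 0.24–0.44 for selections over ~46
shifts) are of the order of a *single*-shift tail probability, which a raw
product over dozens of shifts could not be. If bit-compatibility with
another implementation is required, validate this choice against it; the
scoring routine accepts any tabulated distribution behind the same
interface, so the Gaussian assumption is a convenience, not a constraint.

Predicted shieldings $\sigma_\mathrm{iso}$ are converted with fixed
per-nucleus offsets, $\delta = c_\mathrm{nuc} - \sigma_\mathrm{iso}$, with
$c_{^1\mathrm H} = 30.78$ ppm and $c_{^{13}\mathrm C} = 170.04$ ppm as
defaults (`default_offsets`); both are user-replaceable.

### Local (W-n) selection

With all assigned shifts weighted equally, a local structural signal (a
hydrogen bond felt by one proton) is diluted by every remote shift.
`bond_shell()` builds the W-n subset: heavy atoms within n bonds of a
chosen center, plus their attached hydrogens. Distances are counted over
heavy atoms only — hydrogens decorate included heavy atoms and never relay
a path — which makes the shell count unambiguous. `local_probability()`
is then exactly the global score restricted to distributions whose label
is a shell member. Selection thresholds, counts (e.g. the published 5009)
and alternative counts (e.g. 5175 used for probability-floor comparisons)
are all plain parameters of `select_environments()`; the package takes no
position on the relationship between the two published counts.

## Environments, geometry, maps, energies

**Extraction.** An environment is a central molecule plus every molecule
with at least one atom within the cutoff (default 7 Å) under the
minimum-image convention, with molecules made whole by a 1.8 Å bonding
heuristic and neighbors translated to the central molecule's image. The
minimum-image shortcut is asserted valid (`cutoff` < half the shortest
cell vector); the test suite checks the result against an explicit
27-image enumeration.

**Hydrogen bonds.** The source protocol states no geometric criteria, so
the package defaults to common crystallographic practice — H···A ≤ 2.5 Å
and D–H···A ≥ 120° — exposed in `hbond_criteria()` and recorded with every
statistic. Intramolecular acceptors are excluded by default (enable with
`include_intramolecular = TRUE`, which then enforces a minimum bond
separation). Among passing acceptors the nearest wins; classes are the
topology label of the acceptor atom on the neighbor molecule, `"water"`,
or `"none"`.

**Torsions.** Signed IUPAC torsions on (−180°, 180°]. Note one property
deliberately *not* asserted: IUPAC torsions are invariant — not
antisymmetric — under reversal of the four-atom sequence, and the tests
pin that behavior against explicit rotations about the central bond.
Histograms bin periodically with right-closed bins, so +180° and −180°
(the same torsion) share a bin. Each analyzed torsion must be specified by
all four atoms; the package does not guess flanking atoms from a bond.

**Density maps.** Environments are aligned either by proper-rotation
least-squares superposition (Kabsch, ≥3 non-collinear reference atoms;
reflections are never applied) or by a bond-axis frame (origin atom, +z
bond partner, and an azimuth atom in the xz half-plane — required, because
a two-atom axis leaves the azimuth free). Amplitude-one Gaussians of width
w = 0.5 Å (read as a standard deviation; exposed as a parameter in case a
FWHM was intended) are placed at every atom position and averaged over
environments on a cubic grid of side L = 12 Å centered on the first
reference atom. This normalization makes "an atom always at the same
point" give a channel maximum of exactly 1. The grid spacing is not stated
in the source protocol; the default h = 0.2 Å resolves the Gaussian with
2.5 points per sigma and gives the 61³ grid. Evaluation is exact (no
distance cutoff) and is tested against the direct double sum at 1e−12.
Export is standard Gaussian cube (bohr units, z-fastest), with an empty
atom block since the map is an ensemble average.

**Formation energies.** $E_\mathrm{form} = E(\text{environment}) -
E(\text{environment without the central molecule})$, capturing the central
molecule's conformational energy plus its intermolecular interactions; no
isolated-molecule reference is subtracted (the record keeps both terms, so
any other convention is recoverable). The energy backend is a contract —
`(positions, elements) → kJ/mol` — with two implementations: a transparent
toy potential (soft Gaussian contact wells per element pair, plus a
directional hydrogen-bond well of depth 5 kJ/mol at H···A = 1.85 Å,
cos²-modulated in the D–H···A angle) and an external-command adapter for
production codes. The toy backend is pairwise-additive, rigid-motion
invariant and size-consistent, and is checked against a scalar pair-sum
oracle.

## Spectra

`fit_gaussian_mixture()` performs bounded least squares (L-BFGS-B with an
analytic gradient) of a sum of Gaussians initialized at the crystalline
seed shifts; each fitted component is then labeled by the nearest seed —
the assignment-transfer rule for amorphous forms whose spectra overlap the
crystalline ones. Ties are broken deterministically (nearest mean, then
higher intensity, then lower ppm). A linear baseline can be fitted jointly
but is off by default: synthetic traces need none, and silent baseline
fitting can absorb real signal. Widths collapsing below the grid spacing
are flagged rather than hidden. Proton distributions come from picked
HETCOR peaks: the peak nearest each carbon mean (within a window) supplies
the ¹H mean; since the upstream protocol does not state how ¹H widths were
extracted, the peak table may carry an optional `width_1H` column, with a
configurable default otherwise.

## The synthetic world

`generate_environments()` emits clusters around a fixed 14-atom model
molecule: a six-carbon ring, an N1–H1 donor, a ring carbonyl acceptor O1,
and a flexible two-torsion tail C4–C7–C8 ending in a second acceptor O2.
Environments carry ground-truth flags and their geometry realizes them:

* a fraction (default 0.30) receives a planted hydrogen-bond partner
  (drug O1, drug O2, or water; weights 0.5/0.3/0.2) with H···A drawn from
  N(1.85 Å, 0.05 Å) and D–H···A within ~24° of linear — safely inside the
  default detection criteria, which is why truth flags and geometric
  detection agree ≥ 99%;
* partner orientations that would create secondary H-bond contacts are
  rejected and resampled, so the planted bond is the only one;
* every environment gets 1–2 non-bonded neighbor molecules (10% water) at
  a nearest-atom distance of 4.5–6.5 Å: inside the cutoff, outside the
  criteria;
* the tail torsion about C4–C7 is drawn from two modes at 0° and 180°
  (sd 12°), and the forward shift model couples the torsion-adjacent
  carbons to cos θ with a 0.8 ppm amplitude;
* the donor proton's shift is base (8.0 ppm) + 4.0 ppm when H-bonded, so
  the H-bonded donor mean is 12.0 ppm; all shifts carry independent
  Gaussian noise.

**Noise scale — the one genuinely load-bearing choice.** The per-nucleus
shift noise defaults to 1.3 ppm (¹H) and 2.0 ppm (¹³C), the scale of
amorphous MAS linewidths (an order of magnitude broader than
microcrystalline lines). This value was fixed *before* the acceptance
tests were written, from a feasibility analysis of the selection contrast:
with a toy molecule carrying only 11 assigned shifts (7 in the W3 shell),
a 4 ppm donor increment over 0.5 ppm noise separates the populations by
8σ, and *both* the local and the global top-1% selections saturate at
exactly 100% H-bonded — the local-beats-global phenomenon the pipeline
exists to demonstrate would vanish into a tie. The published contrast
relies on 8-of-46 dilution that an ~11-shift molecule cannot reproduce; at
1.3 ppm noise (a ~3σ separation) the W3 selection still recovers ≥ 93%
H-bonded environments while the all-shift selection is reliably and
strictly weaker, across every seed tried. The 14th atom and the tail exist
for the same reason: four assigned shifts must lie *outside* the W3 shell
for "global dilutes, local resolves" to be expressible at all.

**What a green test does and does not establish.** The generator emulates
the statistical structure the analysis assumes — broadened Gaussian
per-site distributions, a downfield H-bonded donor, conformational modes,
a stabilizing interaction co-occurring with the spectroscopic signature.
It does not emulate real force-field physics, shift-prediction errors
correlated across sites, non-Gaussian lineshapes, or the size (46 shifts,
2.8 M environments) of the real problem. Green end-to-end tests establish
that the machinery is self-consistent and recovers planted truth; they do
not reproduce the published percentages, which depend on the real dataset.

**A deliberate red.** One acceptance assertion states that the NMR-set
mean formation energy lies a full 5 ± 1 kJ/mol below the random-baseline
mean. With the baseline itself 30% H-bonded, the expected difference is
diluted to (f_NMR − f_MD) × 5 ≈ 3.3 kJ/mol, and the assertion fails — the
undiluted statement is conditional ("within the selected set, environments
forming the hydrogen bond are ≥ 5 kJ/mol more stable"), which the suite
verifies separately at ±1 kJ/mol. The assertion is kept as stated rather
than weakened; the well depth was not tuned to rescue it.

## Numerical choices

* Geometric-mean aggregation underflows as a sum of logs; any $p_i = 0$
  annihilates to exactly 0.
* `top_k` ties at the boundary break by environment id after a stable
  sort — selection is deterministic.
* Chemically equivalent predictions (several rows per environment and
  label, e.g. CH₂/CH₃ protons) are averaged before scoring; a prediction
  without a distribution is silently ignored (partial assignment is
  normal), a distribution without a prediction is an error (a data
  defect).
* The density accumulator evaluates separable Gaussians as 61 BLAS matrix
  products per channel, exactly (no truncation radius), so the oracle
  equivalence holds to 1e−12.
* All generator randomness derives from a single integer seed, and the
  RNG state of the caller is restored afterwards; identical seeds give
  byte-identical ensembles.

## Known limitations

* The scoring aggregation is a reasoned reconstruction (see above), not a
  bit-compatible port of the upstream method.
* The extended-XYZ dialect is the single trajectory format; formats
  needing topology binaries are out of scope, as is running MD itself,
  training or running a shift predictor, and semi-empirical
  quantum-chemical energies (plug real codes in through
  `command_backend()`).
* H-bond criteria, torsion flanking atoms, density alignment mode and
  grid spacing are all stated-default parameters, not fitted quantities;
  conclusions should be checked for sensitivity to them.
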