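---
title: "Flexible fitting of coarse-grained structures to AFM images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible fitting of coarse-grained structures to AFM images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High-speed atomic force microscopy (HS-AFM) films biomolecules at work, but a
height image alone does not say which internal (e.g. chemical or
conformational) state the molecule is in. afmflex implements the
flexible-fitting route to that question: deform a coarse-grained structural
model under a physical potential plus an image-agreement bias, do this for
each candidate conformational state, and compare how well the fitted
ensembles explain the image — region by region. The worked system is a
two-head-bound motor on a filament whose leading lever arm can be "up" or
"down"; the method decides which state a frame represents.

## The energy model

The total potential is

$$V_\mathrm{total} = V_\mathrm{protein} + V_\mathrm{stage} + V_\mathrm{AFM}
  \;(+\, V_\mathrm{restraint}),$$

with one bead per residue and all lengths in nm.

**Structure-based protein potential.** `build_topology()` derives every term
from a single reference conformation, which thereby becomes the global
minimum — the defining property of a Go-type model, and the only property the
fitting method relies on. Full sequence-dependent coarse-grained force fields
put state preference into their contact energies the same way; we use the
classic reduced form: harmonic bonds $k_b(d-d_0)^2$ and angles
$k_a(\theta-\theta_0)^2$ on consecutive beads of a chain, Gaussian
native-contact wells $-\varepsilon\exp(-(d-d_0)^2/2w^2)$ for reference pairs
within a cutoff (at least 3 residues apart or on different chains), and a
soft-core excluded volume $\varepsilon_{ev}[(s/d)^{12}-2(s/d)^6+1]$ for
$d < s = r_i + r_j$, continued linearly below $0.7\,s$ so that conformations
evaluated far from their topology's reference (as happens when the reference
is switched between states) feel finite forces.

**Stage wall.** A per-bead 12-6 potential in $z$ only,
$\varepsilon[(\sigma/z)^{12} - 2(\sigma/z)^6]$, minimum $-\varepsilon$ at
$z=\sigma$ (default: each bead's radius), models the mica stage at $z=0$;
below $0.7\sigma$ it too is continued linearly.

**AFM bias.** $V_\mathrm{AFM} = k\,(1 - \mathrm{c.s.}(H^\mathrm{sim};
H^\mathrm{ref}))$, where the cosine similarity over the masked pixels is

$$\mathrm{c.s.} = \frac{\sum_p H_p^\mathrm{sim} H_p^\mathrm{ref}}
 {\sqrt{\sum_p (H_p^\mathrm{sim})^2}\sqrt{\sum_p (H_p^\mathrm{ref})^2}}.$$

$H^\mathrm{sim}$ is the smoothed pseudo-AFM image of the instantaneous
configuration, so $V_\mathrm{AFM}$ is differentiable in the coordinates and
its analytic negative gradient enters the dynamics.

## Pseudo-AFM images

Two renderers share one contract. The *collision* method is hard geometry: a
spherical tip of radius $R$ descends on each pixel's vertical line and stops
at the first sphere-sphere contact, $H_p = \max_i\, z_i - R +
\sqrt{(R+r_i)^2 - d_i^2}$, floored at 0. The *smoothed* method is the
differentiable surrogate used inside the dynamics:

$$H_p = \gamma \log\Bigl[1 + \sum_i \exp\Bigl(\frac{z_i + r_i}{\gamma}
 - \frac{(x_i-x_p)^2}{2\sigma_x^2} - \frac{(y_i-y_p)^2}{2\sigma_y^2}\Bigr)\Bigr],$$

a log-sum-exp soft maximum with Gaussian lateral weighting. It is everywhere
non-negative (the $+1$ is the stage floor), infinitely differentiable, and
sharpens to the tallest bead top $z_i+r_i$ over the pixel as
$\gamma,\sigma \to 0$. Any smooth soft-maximum with these limits is a
conformant renderer; this is the package's canonical one. Two numerical
points deserve note. First, the evaluation is a stable log-sum-exp (per-pixel
max subtracted), since $(z+r)/\gamma$ reaches $\sim 10^2$ at the default
$\gamma = 0.1$ nm. Second, the lateral support is truncated per bead where a
term's exponent falls 20 below the stage baseline
($d_\mathrm{cut} = \sigma\sqrt{2((z+r)/\gamma + 20)}$), which bounds the
truncation error below $10^{-6}$ nm; a naive fixed few-$\sigma$ window is
*not* adequate here, because the lateral attenuation in a log-sum-exp is
subtractive, not multiplicative.

The lateral widths $\sigma_x=\sigma_y=0.5$ nm correspond to imaging with a
tip of roughly 2.6 nm radius, which is why the collision renderer's default
tip radius is 2.6 nm.

## Image preprocessing

The stage surface in a measured frame is tilted by a fraction of a degree.
`fit_stage_plane()` estimates $z = ax + by + c$ over an empty margin region
by linear least squares (pixel-center coordinates in nm, so the slopes are
dimensionless); `level_image()` subtracts the plane per pixel — at sub-degree
tilts, subtraction and frame rotation differ negligibly and subtraction
preserves the grid. `crop_region()` then cuts the fitting region, keeping
absolute pixel-center coordinates so structures keep living in the frame's
coordinate system. All user-facing pixel indices are 1-based inclusive, the
field's counting convention; the conversion to 0-based happens once at the
compute-core boundary.

## Dynamics

`run_langevin()` integrates underdamped Langevin dynamics with the BAOAB
splitting, uniform bead masses and a deterministic per-replica random stream
(a counter-derived seed per `(master seed, replica)` pair, so replicas are
independent and each is exactly reproducible). Defaults: $T=300$ K,
$dt = 0.3$ reduced time units, friction $0.25$ per time unit, $k_B =
0.0019872$ energy/K so that energies read as kcal/mol-scale numbers.

The package defines its own reduced time unit. The bead mass is the one
place where that choice bites: with $\sim$20 contact wells per bead the
stiffest modes satisfy $\omega\,dt < 1$ only for masses of order tens of
reduced units, and the kinetic-temperature accuracy of BAOAB improves
quadratically as $\omega\,dt$ falls. With the default mass (40 reduced units)
the equipartition temperature of the toy complex is reproduced within a few
percent at $dt = 0.3$, and the configurational statistics (e.g. the
stationary bond-length variance $k_BT/2k_b$) are accurate to the percent
level. Only relative convergence of the fitting matters, so the absolute
time scale is not interpreted.

A run records, every `record_interval` steps, the step index, cosine
similarity, each energy component, kinetic energy and the snapshot. A
non-finite energy aborts the run with the offending snapshot attached to the
condition; campaigns drop aborted replicas and flag them.

## The synthetic study system

Because no frame of the original measurement is deposited, the package ships
a generator that emulates the measurement end to end; every test runs
against it. The geometry is deliberately *geometric*, not biological — the
inference method depends on the shape difference between states, not on any
particular protein:

* **Filament**: a two-strand helical rod of large beads (radius 3.2 nm,
  rise 2.75 nm, twist 30°/bead) lying along the frame, the brightest and
  state-independent feature, as an actin filament is.
* **Heads**: icosahedral bead shells docked onto two binding sites, pressed
  against the filament band so they read as lumps on it.
* **Necks/levers**: thin bead rods (radius 0.6 nm, optically faint — real
  motor necks are barely above the noise floor). Both necks of the *down-up*
  state meet at a dimerization junction, where the up lever is latched by
  native contacts; in the *down-down* state the leading lever is swung
  $\sim$140° forward about a hinge at the head and lies along the filament,
  latched there by neck-filament contacts of its own topology.

That latch design is load-bearing. A lever whose orientation is held only by
hinge stiffness cannot be protected from the bias: harmonic angles at
feasible stiffness store only a few $k_BT$ against a concerted rotation, and
a quasi-spherical head shell can rotate against the filament almost freely
(its contact distances are nearly rotation-invariant). Encoding each state as
a *specific interface* — as real myosin does with converter packing and
lever-lever dimerization — makes the cross-state conversion cost several
hundred energy units, far beyond what the bias can pay at its default
strength.

The image corruption model adds what a measured frame has: a stage plane
with sub-degree tilt (defaults echo a measured plane, $a = 0.00348$,
$b=-0.00003$, $c = 7.215$ nm), i.i.d. Gaussian pixel noise of SD 0.53 nm
(the level measured on a real stage margin), and optional exponential
"parachuting" streaks trailing scan-direction off molecule edges. What the
generator does **not** emulate: scan-line asynchrony, drift, tip-shape
irregularity, streptavidin obstacle particles (available but off by
default), and real molecules' conformational heterogeneity. Tests passing on
this generator therefore validate the machinery and the inference logic, not
performance on any particular real dataset.

## Choice of the bias strength

The paper-style protocol fixes $\sigma_x,\sigma_y,\gamma$, $T$ and $dt$, but
not $k$. The two failure modes bracket it: too weak, and the structure never
aligns against thermal noise; too strong, and the bias silently converts one
lever-arm state into the other, destroying the very signal the inference
needs (we observed exactly this in development: at $k \gtrsim$ the
state-switching cost divided by the inter-state similarity difference, the
"wrong" state's lever bends to match the image). The default $k = 300$ sits
well inside the window: rigid misalignment costs $\sim 0.1$ in similarity,
so the alignment drive is $\sim 30$ energy units, while bending the lever
against its latch costs several hundred.

## State inference

For each candidate state, the latter half of every replica's records is
pooled (per replica, then concatenated) and the cosine similarity is
re-scored on the region of interest — the neck region, chosen to exclude the
filament, whose pixels dominate the full-region similarity and carry no
state information. `similarity_distribution()` estimates the density with a
Gaussian KDE (Silverman bandwidth, 512-point grid over the sample range);
the mode is the grid argmax. `compare_states()` returns the state with the
larger mode only if (a) the mode difference exceeds a declared resolution
and (b) the same state also has the larger median (a rank-based guard; no
distributional test is implied). Otherwise: `"indeterminate"`.

The default resolution is `max(2 * grid spacing, bandwidth / 2,
2 * between-replica SE of the per-replica modes)`. The last term matters:
MD similarity series are strongly autocorrelated, so bandwidth-based floors
understate the sampling uncertainty of a pooled mode; the spread of
per-replica modes is the honest replicate-level uncertainty. For the
synthetic twin study the analysis scripts additionally pass an explicit
*effect-size* threshold of 0.01: mode differences below 0.01 are of the same
order as campaign-to-campaign plateau variability and are treated as "the
distributions overlap", which is precisely the behaviour expected on the
full fitting region, where both states' fits agree with the image almost
equally and only the neck region separates them.

## Degenerate inputs and tie-breaks

All-zero images on a mask raise `"similarity undefined"` rather than scoring
0 — in practice this means a misconfigured mask or a structure that left the
grid, and in dynamics it aborts the replica. All-equal similarity samples
produce a spike distribution whose mode is the value. Angle forces skip the
force (not the energy) within $10^{-8}$ of $\sin\theta = 0$. Beads below the
stage or inside the excluded-volume core see linearly continued potentials,
so forces stay finite everywhere.

## Problem sizes

The shipped studies are scaled so a complete run fits on a laptop core: the
toy complex has 106 beads; saturation campaigns run 3 replicas of $2\times
10^5$ steps; the state-recovery experiment runs 10 campaign repetitions of
both states at 3 replicas $\times\ 4\times10^4$ steps. At production scale
one would use the full protocol the defaults encode (10 replicas,
$3\times10^6$ steps, recording every $10^4$ steps, so the latter half pooled
over replicas is 1,500 snapshots).

## Known limitations

* The structure-based substitute has no sequence-dependent energetics,
  electrostatics or solvent; state preference enters only through the
  reference geometry.
* Leveling by per-pixel subtraction is exact only for small tilts (fine
  below 1°).
* The collision renderer supports spherical tips only; tip-shape inference
  is out of scope.
* One frame at a time: no multi-frame fitting, no frame segmentation, no
  scan-asynchrony correction.
* The toy generator's parachuting streaks are a minimal model (exponential
  tails at molecule edges) with free parameters, not calibrated to data.
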