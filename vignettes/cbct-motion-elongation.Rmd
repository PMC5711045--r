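---
title: "Modeling and simulating mobile-target elongation in cone-beam CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and simulating mobile-target elongation in cone-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctmotion)
```

## The physical picture

A CBCT scan from an on-board kV imager takes 30–60 s with the couch
stationary. A lung lesion moving with respiration (period ≈ 4 s) along the
superior–inferior (SI, z) axis therefore traverses its full excursion many
times during one scan. Filtered backprojection has no notion of time: the
projections it combines saw the object at different positions, and in the
long-scan limit the reconstruction converges to the *time-averaged* object.
A target of stationary SI length $L_0$ then appears elongated.

Two closed forms cover the motion patterns simulated here:

* **Constant speed** $V_P$ for an in-view time $T$:
  $L = L_0 + V_P T$.
* **Sinusoidal motion** $Z(t) = Z_0 + A\sin(\omega t + \varphi)$, speed
  $V_P(t) = \omega A \cos(\omega t + \varphi)$: every voxel sweeps
  $(-A, A)$, so the maximal apparent length is $L_{\max} = L_0 + 2A$,
  independent of frequency and phase. With ROM $= 2A$ (peak-to-peak range
  of motion), measured length vs ROM is a line of slope 1 and intercept
  $L_0$.

The instantaneous form
$L(t) = L_0 + [\omega A \cos(\omega t + \varphi)]\,t$ obtained by
substituting the sinusoidal speed into the constant-speed law is exposed as
`length_instantaneous()` exactly as written, for inspection and plotting
only: it is unbounded in $t$ and can drop below $L_0$, so every quantitative
comparison in the package anchors on $L_0 + 2A$ (cyclic) or $L_0 + V_P T$
(constant speed). Equivalently, the time fraction a sinusoidally moving
point spends at displacement $u$ is the arcsine density

$$p(u) = \frac{1}{\pi\sqrt{A^2 - u^2}}, \qquad u \in (-A, A),$$

whose support is exactly $[-A, A]$; convolving the static phantom along z
with $p$ (the *occupancy blur*, `occupancy_blur()`) is the analytic
long-scan limit of the reconstruction and dilates every target's support by
$[-A, A]$ — the geometric content of $L_{\max} = L_0 + 2A$.

## The digital phantom

`default_phantom_config()` builds a 96³ voxel volume at 2 mm isotropic
spacing (the 2 mm voxel matches the reconstructed slice thickness being
emulated): a water-equivalent slab block (|x|, |y| ≤ 80 mm,
μ = 0.020 mm⁻¹) containing a lung-equivalent foam slab (|y| ≤ 30 mm,
μ = 0.005 mm⁻¹), with three water-equivalent cuboid targets of
50 × 30 mm cross-section and stationary SI lengths $L_0$ = 10, 20, 40 mm.
Attenuations are nominal 60–120 kVp values chosen to give strong
target/foam contrast; they are configurable and nothing downstream depends
on their absolute scale.

Design choices worth stating:

* **Which cuboid dimension lies along z.** The three targets are described
  with their distinguishing dimension (1, 2, 4 cm) assigned to z and the
  5 cm and 3 cm dimensions to x and y. This assignment gives three distinct
  intercepts in the length-vs-ROM plot; it is configurable via
  `target_spec()` because the physical phantom being emulated admits other
  mountings.
* **Placement.** Small at (45, 0, +50) mm (superior right), medium at
  (45, 0, −50) mm (inferior right), large at (10, 0, 0) mm (medial right).
  The targets are placed off the rotation axis so both fan geometries image
  them fully, and the SI positions are chosen so that, at the largest
  studied ROM of 40 mm, (a) each blurred support stays inside the axially
  well-reconstructed region (cone-beam coverage degrades over the last few
  slices), and (b) the measurement windows of the two targets sharing an
  (x, y) column never overlap.
* **Voxelization.** Centre sampling with half-open `[lo, hi)` intervals:
  deterministic, bit-reproducible, and exact for boundaries on voxel-centre
  planes; worst-case extent error is one voxel, halving when the grid is
  refined. An optional `supersample` factor averages sub-voxel samples when
  smoother boundaries are wanted.

## Acquisition and reconstruction

The projector computes cone-beam line integrals by ray marching with
trilinear interpolation at half-voxel steps, for a generic on-board-imager
geometry (SAD 1000 mm, SDD 1500 mm, 384 mm square flat panel). Motion is
applied per projection as a rigid z-shift of the sampling grid — exact for
rigid 1D motion, with no resampling loss. Two protocols mirror the two
clinical modes: half-fan (detector displaced laterally 143 mm, 360° in
60 s, thorax-style technique) and full-fan (centred detector, 200° short
scan in 30 s, head-style technique). kVp and mAs are carried as metadata
only; there is no spectral, scatter or detector physics. Poisson noise is
available (`add_noise()`) but off by default — the elongation analysis is
geometric.

Reconstruction is standard Feldkamp filtered backprojection: cosine
weighting, redundancy weighting, row-wise ramp filtering, voxel-driven
distance-weighted backprojection. Redundancy weights are Parker weights for
the short scan and a smooth displaced-detector transition
$w(u) + w(-u) = 1$ over the detector-overlap region for half-fan; a plain
full circle uses ½. No motion correction of any kind is applied anywhere:
the artifact under study must be preserved.

Numerical choices:

* **Ramp filter.** Band-limited Ram-Lak kernel applied by zero-padded FFT
  convolution. The reconstruction default adds a Hann apodization — the
  usual clinical choice — because it suppresses view-aliasing streaks and
  edge ringing that otherwise perturb low-threshold length measurements at
  desk-scale projection counts; `"ramlak"` remains available for maximum
  in-plane sharpness. Both windows leave the z-resolution untouched (the
  filter acts along the fan direction only), so measured SI lengths are not
  blurred by this choice.
* **Desk-scale presets.** `default_protocol(..., desk_scale = TRUE)` halves
  the projection counts (180 half-fan, 100 full-fan) and coarsens the panel
  to 96 × 96 at 4 mm pitch (same physical size). The experiment drivers and
  the acceptance script use these presets; a static full-fan pipeline at
  desk scale recovers all three stationary lengths to about 0.1 mm, so the
  reduction does not limit the conclusions. Problem sizes throughout:
  96³ voxel grids, ≤ 200 projections per scan.
* **Angles/timestamps** are uniform with inclusive endpoints; backprojection
  uses trapezoidal end-weighting so the duplicated 0°/360° half-fan view is
  not double-counted.

## Measuring apparent length

`measure_length()` emulates a coronal-view distance measurement with
adjusted window/level: the z-profile through a target's static (x, y)
centre (averaged over a 3 × 3 in-plane neighbourhood), a background from
the far-tail median, the plateau from the profile maximum, and the length
between the outermost sub-voxel crossings of
background + fraction × (plateau − background). Degenerate inputs are
flagged rather than guessed: contrast below a floor reports an absent
length with a `low_contrast` flag, and crossings at the window edge set a
`clipped` flag.

The threshold fraction deserves care, and is the one place where a naive
FWHM convention fails:

* For a **stationary** target under a symmetric point-spread blur, the
  half-maximum crossings sit at the true edges: fraction 0.5 is unbiased,
  and the static pipeline recovers $L_0$ to ~0.1 mm.
* For a **motion-blurred** target the elongated support is what the model
  predicts, and the half-max crossing of a symmetric *edge* blur sits at
  the centre of the edge-spread — i.e. near the *stationary* edge. For
  $A \le L_0/2$ the arcsine-blurred profile at half maximum returns
  $L_0$, not $L_0 + 2A$. Elongation measurements therefore use a low
  fraction: 0.05 on the surrogate path (analytic profiles, no noise) and
  0.1 on FDK reconstructions (slightly higher to sit above residual
  streak fluctuations). With the arcsine density's mass piling at $\pm A$,
  the 0.05-crossing of the continuous profile lies within ~0.5 mm of the
  true support for every studied combination of $L_0$ and $A$.
  `sweep_thresholds()` documents the sensitivity explicitly.

One discretization subtlety: with 2 mm sampling, a steep edge spans a
single inter-sample gap and linear crossing interpolation can overshoot by
up to one voxel per edge. The surrogate path avoids this entirely: because
the blurred profile of a piecewise-constant voxel field has the closed form
$\sum_j v_j [F(z - z_j + s/2) - F(z - z_j - s/2)]$ ($F$ the arcsine CDF,
$s$ the spacing), `occupancy_blur(..., z_refine = 8)` samples the *exact*
convolution on an 8× refined z-grid, and crossings are then accurate to a
fraction of a voxel. FDK reconstructions carry genuine 2 mm resolution, so
no such refinement is possible (or meaningful) there.

## The experiments

`run_rom_sweep()` reproduces the core study: ROM ∈
{0, 5, 10, 15, 20, 25, 30, 40} mm at 0.25 Hz, with the motion phase drawn
per ROM from a seeded uniform distribution on $[0, 2\pi)$ — deliberately
uncontrolled, as in practice — and shared between the two scan modes so
that the half-fan/full-fan comparison sees the same motion. The frequency
default is 0.25 Hz (15 cycles/min, period 4 s). Against $L_0 + \mathrm{ROM}$:

* the surrogate sweep agrees to well under one slice thickness
  (max |deviation| ≈ 0.8 mm over all 24 rows), with per-target regression
  slopes 0.98–1.00;
* the FDK sweep carries the expected low-threshold biases of a few mm at
  the largest amplitudes, but the biases are common to both scan modes:
  half-fan and full-fan lengths agree within 2 mm at every ROM, and at
  fixed $A$ = 15 mm the measured lengths vary by less than 2 mm across
  $f \in \{0.2, 0.25, 0.33\}$ Hz and $\varphi \in \{0, \pi/2, \pi\}$ —
  the frequency/phase independence the model asserts.

`run_speed_curve()` evaluates the constant-speed law on a speed grid
(three parallel lines of slope $T$ and intercepts $L_0$) and can validate
one point by simulation. The validation scan images the measured target
*alone*: constant-speed motion never revisits a position, so each transient
position is reconstructed from a sub-arc only, and the other targets would
cast limited-angle ghosts across the measured profile. This is a real
feature of non-cyclic motion in CBCT, not a simulator artifact; isolating
the target keeps the check about the length law. A 0.5 mm/s, 30 s full-fan
simulation measures 54.4 mm against the predicted
$40 + 0.5 \times 30 = 55$ mm.

## What the synthetic data do and do not show

The generator emulates a rigid mobile phantom: homogeneous cuboid targets,
strictly 1D SI motion, perfectly periodic breathing, a monoenergetic
scatter-free projector. Passing tests therefore demonstrate the geometric
elongation law and its mode/frequency/phase invariances under those
conditions. They do not speak to deformable or multi-dimensional tumor
motion, irregular breathing, CT-number fidelity of moving voxels (the
time-average dilutes attenuation — visible as the reduced plateau of small
targets at large ROM — and no claim is made about those values), scatter
or beam hardening, or moving-couch (helical/axial) CT, to which the model
does not apply. Within the field of view, targets must stay imaged;
`forward_project()` warns when the moving support leaves the axial cone
(at ROM 40 mm the slab corners clip, which is recorded in provenance and
does not affect the targets).
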