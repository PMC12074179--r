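---
title: "Designing biplanar nulling coils on printed circuit boards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing biplanar nulling coils on printed circuit boards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Optically pumped magnetometers (OPMs) only operate in a near-zero magnetic
field, so OPM-MEG systems surround the subject with "fingerprint" coils
printed on two large parallel planes that cancel the remnant field inside a
target sphere between them.  This vignette explains the model behind
`opmnull`, the choices that were genuinely open, and what the bundled tests
do and do not demonstrate.

## The design model

A coil confined to a surface is described by a *stream function* `s`: a
scalar on the surface whose iso-contours are the current flow lines and
whose surface-rotated gradient is the current density,
K = grad(s) x n.  Equivalently the surface is a magnetic dipole sheet of
density `s n`, which is the representation used for the scalar potential.
On the triangulated coil planes `s` is piecewise linear with one value per
vertex (zero on the plane boundary, so no current leaves the board), and
the magnetic field is linear in those values, `b = A s`.

The design problem is the regularized quadratic program

    s_hat = argmin_s  1/2 s' R s + lambda || b_target - A s ||^2

where `R` is the resistance matrix (the finite-element stiffness matrix
scaled by the sheet resistance rho/t, so `s' R s` is the ohmic power at
unit drive) and `A` the field coupling matrix.  Minimizing dissipation
keeps the winding short and smooth; `lambda` trades that against target
fidelity.

Three implementation details matter:

* **Field kernel.**  The field of the piecewise-linear stream function is
  computed by giving every mesh triangle a closed boundary line current
  equal to its mean vertex value and summing exact segment Biot-Savart
  fields; shared edges largely cancel, leaving the discrete rotated
  gradient.  This converges to the analytic sheet field as the mesh is
  refined and is verified against circular- and square-loop closed forms
  (2% on the test fixtures, limited by the staircase representation of a
  circle on a square grid, not by the kernel).
* **Named-component misfit.**  The least-squares term runs over the
  coil's *named* field component only.  For gradient coils this is forced
  by physics: a coil with dBz/dz = G must produce transverse components
  (div B = 0 gives dBx/dx + dBy/dy = -G), so insisting on zero
  off-components makes the problem unattainable and drives `lambda`
  toward a wild interpolating solution.  For uniform coils the transverse
  components vanish by symmetry anyway; using one definition everywhere
  keeps the residual comparable across coil kinds.
* **Choosing lambda.**  `lambda` is not a user-facing dial: the solver
  factorizes `R` once, takes the SVD of `A R^{-1/2}`, and root-finds the
  (monotone) relative residual to a **2% target on the named component**.
  The selected `lambda` is reported in the design report.  2% is tight
  enough that the achieved field is visually uniform over the target
  sphere and loose enough that the winding stays manufacturable; the
  resulting designs reproduce the published efficiencies of the reference
  system to a few percent for five of the six coils (the dBz/dz coil runs
  about 13% hot; no `lambda` reproduces both its published conductor
  length and its efficiency simultaneously, so its operating point
  evidently involves a condition the published description does not pin
  down).

## Discretization into turns

`discretize()` extracts N iso-contour levels placed by the midpoint rule
over the *signed symmetric range* [-max|s|, +max|s|] of the joint
two-plane stream function; a level outside one plane's local range simply
produces no loop there.  Each level carries the same current increment
2 max|s| / N, so driving the discrete coil with that increment reproduces
the continuous field (verified to < 5% at N = 30 and < 1% at N = 200).
The symmetric range is what makes turn counts come out right across coil
kinds: a uniform-field pair (same-sign stream function on both planes)
puts half the levels on each side of zero, a gradient pair (opposite
signs) the same, and for the x/y coils with two-signed lobes per plane
both conventions coincide.  With per-plane ranges instead, the z-coils
come out with twice the published conductor length and twice the
published efficiency, which is how the convention was identified.

Loops are oriented along the physical current direction (higher stream
function to the left of travel); polarity +1 means anticlockwise viewed
from +z.  Efficiency is the named field component at the target center
per mA (uniform coils) or the fitted slope of the component along the
7-point axial probe line from -15 cm to 15 cm (gradient coils); a
"sweep" mode emulates the bench protocol (current ramps of 0-60 mA and
0-24 mA with a line fit) and coincides with the direct evaluation because
the kernel is exactly linear.

## The shielded room

Mu-metal is modeled as an infinite-permeability surface: its interior
face is an equipotential of the magnetic scalar potential, enforced by an
equivalent stream function `s_shield` on the shield mesh satisfying

    C_U^coil s_coil = - C_U^shield s_shield,

after which the total field is `B = C_B^coil s_coil + C_B^shield
s_shield`.  Because every shield panel is flat, the panel's own dipole
sheet contributes exactly `s/2` at its own surface (the in-plane
principal value vanishes), giving a well-conditioned diagonal self-term;
cross-panel terms use the regular quadrature kernel, and the solve is a
truncated pseudo-inverse with relative singular-value cutoff 1e-8 (the
operator on an open mesh can be rank-deficient).  The construction
reproduces the method of images for a current loop over an infinite
plane to better than 0.1% at the test resolutions, and a symmetric
shield box raises the z-coil efficiency just as the published room
measurements do.

Discrete coils drive the shield through their exact loop potentials
(Van Oosterom-Strackee solid angles), so shielded efficiencies use the
same definition as free-space ones.  Plane shields extend 1.5x the coil
size beyond the footprint (3x in total), and panel meshes are coarser
than the coil mesh; both were convergence-checked once (43 vs 63
vertices per edge and 2.1 vs 3.0 m half-extent change the floor scenario
below by < 1%).

The one externally anchored scenario is a floor 10 cm below the lower
edge of the y-coil.  Solving it gives a 0.31 nT/mA efficiency reduction,
confirmed independently by the method of images.  The published
reduction attributed to the floor is 0.1 nT/mA, but the same source
shows the full room *raising* the z-coil efficiency, i.e. walls and
ceiling partly compensate the floor; since the room dimensions are not
published, the floor-only scenario is reported as computed rather than
tuned toward the quoted net value.

## From loops to a two-layer board

The discretized loops are disjoint; `connect_loops()` turns them into one
conducting path from terminal to terminal, deterministically:

* Loops are grouped into *nests* (chains of mutually nested rings).  A
  cut ray runs from the innermost ring's centroid outward; every ring is
  opened where it crosses a corridor around the ray, and short bridges
  join consecutive rings into a spiral entered at the outermost ring.
* The return from the innermost ring travels on the back layer,
  retracing every front bridge with a geometrically identical,
  oppositely-traversed copy and hopping each ring's gap with a short
  stub.  The stub current exactly replaces the arc removed from the
  ring, so layout-versus-ideal-loop field perturbations at the target
  center are 0.01-0.3% of the coil field at 1 mA - and removing the
  return copies degrades that by two orders of magnitude, which is the
  cancellation test.
* Ring sub-groups that the ray misses (corner lobes of the z-coil,
  nested side-lobes of the x/y coils) hang off a tail inside the
  innermost ring as back-layer *spurs*: a tight out-and-back pair of
  adjacent back traces that crosses rings in projection only.
* Nest entries and the feed are joined by jumpers routed with a
  breadth-first search on a 3 mm obstacle raster of the board (falling
  back to a bare-centerline raster through pinched channels, and to the
  back layer when an entry is pocketed behind another nest's rings).
  The whole forward jumper chain is retraced on the back layer, ending
  at a back-side terminal pad directly under the front one, so the feed
  is a canceling two-layer pair.
* `split_board()` severs the layout along the coil's symmetry axis
  (vertical for the x/z coils, horizontal for the y coils) into two
  manufacturable halves, terminating severed traces with matched solder
  pads.  The x/y coils come out with exactly two pad pairs; the z-coils'
  rings straddle the axis and need one pair per severed trace.  Jumpers
  are routed cut-aware so they cross the axis exactly once when they
  must and never otherwise.

Two honest limitations.  First, `board_crossings()` still reports a
handful of same-layer crossing pairs per plane on the richest reference
layouts (none on clean concentric topologies): these are ring-shoulder
clips near pocketed entries, exactly the places where the original
interactive workflow relied on a human to nudge a trace, and they are
reported for manual review rather than silently accepted.  Second, the
x/y coils' connected-path overhead is 16-20% of the loop length versus
about 8% for the published boards: at this operating point those coils
have six nests per plane rather than two, so the jumper chain is longer.
The z-coils land at 2-8%, matching the published scale.  Clearance below
the 5 mm trace width in pinched channels is left to the fabrication
review; design-rule checking beyond crossing/connectivity is out of
scope.

## Background-field nulling

With the coils mounted, the sensor readings obey `b = M I`: driving each
coil alone at a known current and subtracting an all-coils-off baseline
gives the columns of `M` (nT/mA), and the nulling currents solve
`I = M^{-1} b` (least squares when there are more sensors than coils,
which is the intended configuration).  The condition number of `M` is
reported and a configurable threshold (default 100) warns rather than
fails.  A flip-and-average utility separates sensor bias from field.

`simulate_nulling_session()` exercises the whole procedure against the
actual discretized coils: helmet-like sensors on a hemisphere with
jittered radial axes observe a background (uniform vector, optional
uniform gradient tensor, optional linear drift), the coupling matrix is
estimated from simulated activations, and the compensation currents are
frozen at time zero.  A 21 nT uniform background along a random
direction drops below 5% of its initial value (under 2 nT) with the
three uniform coils - the simulated analogue of the helmet measurement
the system is built for.  What this does *not* show: performance against
spatially complex backgrounds, sensor calibration errors, cross-axis
projection effects, or closed-loop drift tracking; the drift scenario
only demonstrates that frozen currents degrade monotonically.

## Numerical choices and defaults

* Mesh: 33 vertices per plane edge (2048 triangles per plane).  Refining
  to 41 changes the designed efficiencies by < 0.5%; target sampling
  (128 Fibonacci points on the sphere surface, plus the center for
  uniform coils) is similarly converged against 256.
* mu0 = 4 pi x 1e-7 exactly; copper resistivity 1.72e-8 Ohm m; copper
  thickness by the PCB nominal 35 um/oz (the density-based value,
  34.06 um/oz, is available but the nominal convention is what
  reproduces the published 70 um and all twelve published
  length-resistance pairs to +-0.05 Ohm).
* Field evaluation refuses points within 1 mm of a source surface
  (singular-evaluation error) rather than regularizing the kernel.
* Contour extraction uses the grid contourer on each plane's vertex
  lattice; levels never sit at an extremum (midpoint rule) or at zero
  (even N), and a contour touching the boundary is an error since the
  stream function vanishes there.
* Routing raster: 3 mm cells, 3 mm obstacle inflation (one trace width
  of center-to-center clearance), deterministic neighbor order, fixed
  tie-breaks; identical inputs give byte-identical layouts and exports.
* Randomness only enters optional fixtures (volume sampling of the
  target sphere, sensor jitter, simulated noise); every such function
  takes a seed and restores the caller's RNG state.

## What the tests show

The suite checks the kernels against closed forms (loop fields, solid
angles, thin-annulus resistance, far-field decay, divergence- and
curl-freeness), the optimizer against its normal equations and monotone
residual, discretization against the continuous field, the shield
against the method of images and its defining equipotential condition,
the layouts against connectivity/polarity/cancellation invariants plus
Gerber and JSON round trips, and the nulling algebra against exact and
noisy synthetic recoveries.  End-to-end blocks rebuild the reference
coils at full resolution and compare efficiencies, lengths and
resistances with the published system table.  All of it runs on
synthetic inputs; none of it certifies a physical board beyond the
geometry it encodes.
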