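# opmnull

Design pipeline for **biplanar background-field nulling coils** printed on
two-layer circuit boards, as used with optically pumped magnetometers
(OPM-MEG).  OPMs only operate in a near-zero magnetic field; a set of six
"fingerprint" coils etched on two large parallel PCBs flanking the subject
cancels the remnant uniform field components (Bx, By, Bz) and the
z-gradients (dBx/dz, dBy/dz, dBz/dz) inside a spherical target region,
while leaving the subject accessible.

The package covers the whole chain from physics to manufacturing files:

* **Stream-function optimization.**  A coil confined to a surface is a
  scalar stream function *s* (its iso-contours are the current lines).
  The design solves the regularized quadratic program

  ```
  s_hat = argmin_s  1/2 s' R s  +  lambda * || b_target - A s ||^2
  ```

  where `R` is the resistance matrix (ohmic power quadratic form) and `A`
  the Biot–Savart coupling matrix from per-vertex stream values to the
  field at target points.  `lambda` is chosen automatically so the
  relative misfit of the coil's named field component is 2%.
* **Discretization** into N = 30 contour levels over the signed symmetric
  stream-function range, giving the closed current loops of the coil, and
  efficiency evaluation in the field's units (nT/mA for uniform coils,
  nT/m/mA for gradient coils, from the fitted slope over a −15…15 cm
  axial probe line).
* **Shielded-room modelling**: mu-metal as an infinite-permeability
  equipotential surface, solved with scalar-potential coupling matrices
  (`B = C_B^coil s_coil + C_B^shield s_shield` with
  `C_U^coil s_coil = −C_U^shield s_shield`), verified against the method
  of images.
* **PCB layout**: deterministic connection of the disjoint loops into a
  single two-layer conducting path (spiral bridges, canceling back-layer
  returns, back-layer spurs for nested lobes, grid-routed jumpers), a
  symmetry-axis board split with paired solder pads, and exports to
  Gerber RS-274X, Excellon drill, SVG and a schema-versioned layout JSON.
* **Field nulling**: estimating the sensor-by-coil coupling matrix from
  per-coil activations (`b = M I`), solving `I = M^{-1} b` (least squares
  for more sensors than coils), and a full simulated nulling session
  against the designed coils.

## Worked example

Design the uniform Bz coil at the reference geometry (1.4 m square planes
separated by 1.4 m, 50 cm target sphere, N = 30, 5 mm traces, 2 oz
copper), then turn it into boards:

```r
library(opmnull)

d <- design_coil("Bz")
d
#> Biplanar Bz nulling-coil design
#>   planes: 1.4 x 1.4 m at z = +/- 0.7 m; target sphere r = 0.25 m
#>   lambda = 1.339e+11, relative residual = 2%
#>   N = 30 contour levels -> 64 loops; efficiency 6.18 nT/mA

summary(d)
#> Bz coil: 64 loops (36 CCW / 28 CW), 30 contour levels
#>   lambda 1.339e+11, residual 2%
#>   loop length 165.4 m, loop resistance 8.13 Ohm
#>   efficiency 6.18 nT/mA

boards <- connect_loops(d$coil, kind = "Bz")
boards$plane_pos
#> Board layout (plane z = +0.7 m): 78 front / 78 back traces, 19 vias
#>   conducting length 89.18 m, trace width 5 mm

halves <- split_board(boards$plane_pos, cut_plan("Bz"))
halves$n_pad_pairs
#> [1] 114
write_gerber(halves$a, "gerber/", name = "Bz-pos-left")
```

Reading the numbers: the optimizer meets a 2% field misfit on the target
sphere with λ ≈ 1.3e11; the 30 contour levels yield 64 loops (the
counter-rotating outer rings flatten the field across the large target
sphere); the discrete coil produces 6.18 nT at the sphere center per mA
of drive current, with 165 m of winding ≈ 8.1 Ω at 5 mm / 2 oz copper —
all close to the published reference system (6.4 nT/mA, 164.5 m, 8.1 Ω).
The z-coil's rings straddle the vertical cut axis, so its two board
halves need many solder joints (114 pad pairs); the Bx/By coils come out
with exactly two.

`plot(d)` draws the stream-function contours and the discrete loops;
`predict(d, points, current)` evaluates the coil field anywhere;
`residuals(d)` returns the target misfit.  For the shielded room:

```r
floor <- shield_panel(center = c(0, -0.8, 0), normal = c(0, 1, 0),
                      half_extent = 2.1, resolution = 43)
sys <- shield_system(d$mesh, floor)
shielded_efficiency(d$coil, sys, "Bz")
```

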