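---
title: "The analytic spherical bidomain model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The analytic spherical bidomain model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherebidomain)
```

## The physical problem

A sphere of excitable tissue of radius $a$ sits in an infinite, uniform
conducting bath containing a point current source at $\mathbf p_+$ and a
point sink at $\mathbf p_-$, both strictly outside the tissue, carrying
$\pm I_0$. This is the idealized geometry of an in-vitro MREIT scan of a
ganglion in artificial sea water with injection electrodes at the chamber
wall. The tissue is an isotropic *bidomain*: intracellular and interstitial
continua of resistivities $\rho_i$ and $\rho_o$ co-occupy the volume and
are coupled through a passive membrane of resistance-times-area $R_m$ and
surface-to-volume ratio $\beta$. The model is quasistatic (no capacitive or
inductive time dependence, $\mathbf E = -\nabla\phi$), the membrane is a
pure resistor (no active channels, no capacitance), and all conductivities
are isotropic and real.

Writing $I_m$ for the volumetric transmembrane current, the coupled
equations $\nabla^2\phi_i = I_m\rho_i$, $\nabla^2\phi_o = -I_m\rho_o$,
$I_m = (\phi_i-\phi_o)\,\beta/R_m$ decouple under the change of variables

$$V_m = \phi_i - \phi_o, \qquad
  \psi = \tfrac{\rho_o}{\rho_i+\rho_o}\phi_i +
         \tfrac{\rho_i}{\rho_i+\rho_o}\phi_o,$$

into a scalar Helmholtz equation $\nabla^2 V_m = V_m/\lambda^2$ with length
constant $\lambda = \sqrt{\rho_m/(\rho_i+\rho_o)}$, $\rho_m = R_m/\beta$,
and a Laplace equation $\nabla^2\psi = 0$. In the bath, the potential is
the sum of the two free monopole fields $\pm I_0\rho_e/(4\pi R_\pm)$ and a
harmonic secondary field $\phi_{\mathrm{bath}}$ that decays at infinity.
With this sign convention the current balance at any interior point reads
$\nabla\cdot\mathbf J_i = -V_m/\rho_m$, which the test suite verifies by
finite differences.

## Series solutions and the harmonic layer

Separation of variables in spherical coordinates gives

$$V_m = \sum_{\mu=0}^{\mu_{\max}}\sum_{\nu=-\mu}^{\mu}
        a_{\mu\nu}\, i_\mu(r/\lambda)\, Y_\mu^\nu(\theta,\varphi),\qquad
  \psi = \sum b_{\mu\nu} r^\mu Y_\mu^\nu,\qquad
  \phi_{\mathrm{bath}} = \sum c_{\mu\nu} r^{-\mu-1} Y_\mu^\nu,$$

where $i_\mu$ is the modified spherical Bessel function of the first kind
(the second kind is singular at the origin and never needed) and
$Y_\mu^\nu$ are orthonormal complex spherical harmonics **with the
Condon–Shortley phase**, so that
$Y_\mu^{-\nu} = (-1)^\nu\overline{Y_\mu^\nu}$. Normalized associated
Legendre functions are generated by the standard stable three-term
recurrence along degree (sectoral seed carrying the phase), which is
accurate far beyond the truncations used here; $i_\mu$ is evaluated through
`besselI` at half-integer order with a series fallback
$x^\mu/(2\mu+1)!!$ below $x = 10^{-8}$.

The free electrode potentials are expanded, when a truncation-consistent
representation is required, through the interior/exterior expansion of
$1/|\mathbf r - \mathbf r'|$ with radial factors
$\min(r,r_\pm)^\mu/\max(r,r_\pm)^{\mu+1}$; by the addition theorem the sums
collapse to Legendre polynomials of the source-to-field angles, which is
how the package evaluates them.

## Interface conditions and coefficients

At $r=a$ three conditions hold: continuity of potential
($\phi_e = \phi_o$), continuity of normal current density
($\rho_e^{-1}\partial_r\phi_e = \rho_o^{-1}\partial_r\phi_o$), and zero
intracellular normal current ($\partial_r\phi_i = 0$). Because the
harmonics are orthogonal, the conditions decouple by mode: for each
$(\mu,\nu)$ they are a $3\times3$ linear system in
$(a_{\mu\nu}, b_{\mu\nu}, c_{\mu\nu})$ driven by the source-expansion
coefficient of that mode. The package solves this system exactly rather
than using a hand-derived closed form: during development the closed-form
route was found fragile (it is easy for a transcription of the eliminated
solution to violate one of the three conditions while still looking
plausible), whereas the direct solve satisfies all three conditions to
machine precision by construction and is equally fast
($\mu_{\max}+1$ tiny solves). Two conditioning choices matter:

* unknowns are scaled to their boundary values ($a_{\mu\nu}$ is solved as
  $a_{\mu\nu} i_\mu(a/\lambda)$, $b_{\mu\nu}$ as $b_{\mu\nu}a^\mu$,
  $c_{\mu\nu}$ as $c_{\mu\nu}a^{-\mu-1}$), which keeps the system $O(1)$
  even when $i_\mu(a/\lambda)$ underflows toward $10^{-80}$ at degree 40;
* stored coefficients keep these scalings, and the radial evaluators use
  the matching scaled families $i_\mu(r/\lambda)$, $(r/a)^\mu$,
  $(a/r)^{\mu+1}$, so no large powers of dimensional radii ever appear.

The auxiliary combinations `aux_p` (electrode geometry) and `aux_q`
(material denominator) of the closed-form route are retained as exported
helpers; a vanishing `aux_q` flags a singular configuration.

Conjugate symmetry ($X_{\mu,-\nu} = (-1)^\nu\overline{X_{\mu\nu}}$ for real
sources) is enforced structurally: only $\nu\ge 0$ is stored and real
fields are assembled as the $\nu=0$ term plus twice the real part of the
$\nu>0$ terms, halving the work and making the imaginary residue exactly
zero rather than merely small.

## Gradients, currents, and the polar axis

Current densities are defined as $\mathbf J = -\rho^{-1}\nabla\phi$ applied
to the series, with term-wise analytic derivatives:
$\partial_r i_\mu(r/\lambda) = (\mu/r)i_\mu + i_{\mu+1}/\lambda$, power-law
radial derivatives, $\partial_\varphi Y = i\nu Y$, and the polar identity
$\partial_\theta Y_\mu^\nu = \nu\cot\theta\,Y_\mu^\nu +
\sqrt{(\mu-\nu)(\mu+\nu+1)}\,e^{-i\varphi}Y_\mu^{\nu+1}$ (the coupling
factor is implemented as the square-root product, which is finite at
$\nu=\mu$ where the equivalent gamma-function ratio has a pole). The free
monopole contribution to the bath current uses the exact Cartesian monopole
gradient rotated into the spherical frame, so production evaluations never
depend on series convergence near the electrodes; the harmonic-series form
of the electrode field and its gradient are retained for
truncation-consistent checks and as a cross-check of the expansion.

On the polar axis ($\sin\theta = 0$) the $\cot/\csc$ factors are removed by
their exact limits: only $\nu=\pm1$ terms survive, with
$d\bar P_{\mu 1}/d\theta \to -\sqrt{(2\mu+1)\mu(\mu+1)/16\pi}$ at the north
pole; under $\theta\to\pi-\theta$ the $\theta$-derivative picks up parity
$(-1)^\mu$ and the $\csc$ term $(-1)^{\mu+1}$. These limits are implemented
explicitly (no epsilon offsets) and tested against near-axis evaluations.
At $r=0$ only degree-1 terms contribute to gradients and the exact limits
$i_1(r/\lambda)/r \to 1/3\lambda$, $(r/a)/r \to 1/a$ are used.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `rho_i`, `rho_o`, `rho_e` | 0.19, 0.29, 0.29 | Ω·m | intracellular, interstitial, bath resistivities (biologically realistic; bath = artificial sea water) |
| `R_m` | 0.15 | Ω·m² | membrane resistance × area |
| `beta` | 2×10⁴ | 1/m | membrane surface per tissue volume |
| `a` | 2 | mm | tissue radius ($\lambda \approx 3.95$ mm, same order as $a$) |
| `I0` | 1 | mA | injected current |
| `p_plus`, `p_minus` | (5 mm, π/2, 0), (5 mm, π/2, −π/2) | | electrode positions |
| `mu_max` | 10 | | series truncation |
| `exclusion_radius` | 0.05 a | m | no-evaluation zone around electrodes |

A note on orientation: the reference electrode pair is placed in the
coordinate plane $z=0$ (source on $+x$, sink on $-y$), matching the
Cartesian layout of the standard resistivity-ratio figures, so "the plane
containing source, sink, and sphere center" is literally $z=0$ and the
mirror symmetry of the problem makes $J_z$ vanish there. The axisymmetric
scenario instead puts the electrodes on the $z$ axis ($\theta=0$ and
$\theta=\pi$), making azimuthal independence a literal $\varphi$-invariance
that the tests sweep directly. The two layouts are rigid rotations of one
another; all physics is orientation-free. Membrane-constant convention:
$R_m$ is specified as resistance × unit area (Ω·m²) together with $\beta$,
giving $\rho_m = R_m/\beta = 7.5\times10^{-6}$ Ω·m³ and
$\lambda\approx3.95$ mm, the reading consistent with a length constant of
the same order as the tissue radius.

`mu_max = 10` is the default because the reference-configuration potentials
stabilize to five decimal places in volts there: the coefficient magnitudes
decay like $(a/r_\pm)^\mu = 0.4^\mu$, and the convergence study
(`convergence_study()`) shows the maximum change between $\mu_{\max}=10$
and 14 over the 50-point probe set is below $10^{-7}$ V. Doubling the
electrode distance visibly accelerates the decay, as the geometric factor
predicts.

## Truncation-consistent validation

One subtlety governs the interface residual report. The truncated solution
satisfies the interface conditions **mode-by-mode exactly**, but the
closed-form monopole potentials contain all degrees: comparing a truncated
$\phi_o$ against a closed-form $\phi_e$ at $r=a$ leaves the $\mu>\mu_{\max}$
remainder of the electrode field, about $(a/r_\pm)^{\mu_{\max}+1}\sim
4\times10^{-5}$ relative at the default truncation — truncation remainder,
not solution error. The residual report therefore evaluates the electrode
field in its series representation at the same truncation, where the
machine-precision satisfaction of the boundary conditions is visible
(residuals $\sim10^{-16}$). Conversely, the line-profile and tangency
checks use the closed form at $\mu_{\max}=40$, where the remainder is below
$10^{-15}$ and the closed form is the better-converged representation.

PDE residuals use a second-order central 7-point finite-difference
Laplacian at the fixed probe set (30 interior, 10 boundary-shell, 10
near-bath points on a golden-angle spiral; shipped as
`extdata/probe_points_synthetic.csv` and regenerated by `probe_points()`).
The Helmholtz residual of $V_m$ is normalized by $\max|V_m|/\lambda^2$ and
the Laplace residuals by $\max|f|/a^2$; all three shrink by the expected
factor ~4 when the step halves over $h \in \{a/50, a/100, a/200\}$. The
probe strata keep a 5 percent margin from the interface so that every
stencil stays inside its domain for all steps up to $a/20$, and the same
point set is used at every $h$ (comparable maxima).

## Biot–Savart computation

The current density is sampled on a regular Cartesian grid (default
128×128×13 over a 3 mm cube centered on the sphere, hence anisotropic
voxels): the bath current $\mathbf J_e$ outside the sphere and the total
tissue current $\mathbf J_i + \mathbf J_o$ inside (both domains occupy the
same volume, and the sum — which equals the monodomain current
$-(\rho_i^{-1}+\rho_o^{-1})\nabla\psi$ — is the physically flowing,
divergence-free field). Nodes within half a grid cell of $r=a$, where the
field definition switches and tangential components jump, are masked to
zero (one-cell shell); nodes exactly on $r=a$ otherwise count as bath.

$B_z$ is the difference of two convolutions of $J_x, J_y$ with the kernel
components $G_{x,y} = x,y/(x^2+y^2+z^2)^{3/2}$, evaluated by FFT with these
discretization choices:

* the volume element becomes multiplication by the voxel volume;
* the singular self-voxel of the kernel is set to zero — the kernel is odd,
  so its principal value over the central voxel vanishes;
* each dimension is zero-padded to twice its size ($\ge 2N-1$) before
  transforming, making the circular convolution equal to the linear one;
  the result is cropped back to the sampling window.

With identical discretization on both sides, the FFT path reproduces the
direct Riemann-sum quadrature to rounding error; the 1 percent acceptance
margin is therefore extremely conservative. Only current inside the sampled
cube contributes — the bath current beyond the 3 mm window is deliberately
not integrated, matching the scope of the sampled-volume computation, and
this truncation is the main systematic difference from the infinite-domain
field. $B_x$ and $B_y$ go through the same machinery, which enables the
solenoidality check ($\nabla\cdot\mathbf B = 0$, verified against the
direct sum with small-step finite differences at off-grid points).

## Degenerate inputs, tie-breaks, tolerances

* Electrodes at or inside the tissue radius are rejected at construction.
* Coincident source and sink cancel exactly: all coefficients, fields and
  grids are identically zero (tested).
* Evaluations within `exclusion_radius` (default 5 percent of $a$) of an
  electrode raise an error naming the offending point; the Gauss-law flux
  diagnostic deliberately bypasses the guard because the monopole part of
  its integrand is closed-form.
* The interface-system determinant cannot vanish for physical (positive)
  parameters; `aux_q` and a conditioning guard still check.
* `mu_max` beyond ~100 would underflow $i_\mu(a/\lambda)$ for the reference
  geometry and is refused with a clear message; the practical range is
  $\le 40$.

## What the scenario layer emulates — and what it does not

The built-in scenarios fix the interstitium-to-bath resistivity ratio
($\rho_e/\rho_o \in \{1, 0.1, 10\}$) with all other reference parameters,
and the axisymmetric limit moves the source directly above the tissue.
These reproduce the qualitative regimes of interest: an electrically
invisible sphere at ratio 1, current drawn into a low-resistivity
interstitium, and current shunted around a high-resistivity one. The model
is exact for its assumptions, but those assumptions exclude: anisotropic
conductivity, frequency-dependent (complex) impedivity, membrane
capacitance and active (Hodgkin–Huxley) dynamics, multilayer geometries,
and any tissue shape other than a sphere. Passing validation here
demonstrates correctness of the analytic solution and its numerics, not
fidelity of the bidomain idealization to any particular real tissue.

Problem sizes in the shipped tests and the acceptance script (64×128
boundary grids, 64×64 plane samplings, 32×32×13 Biot–Savart grids, 50
probe points) were chosen as comfortable working sizes for an exact
reference solution; every routine accepts larger grids and truncations if
finer sampling is wanted.
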