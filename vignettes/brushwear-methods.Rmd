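---
title: "Methods: a discrete-element model of toothbrushing abrasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete-element model of toothbrushing abrasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Non-carious cervical lesions (NCCLs) are saucer-shaped losses of tooth
substance near the gum line, and mechanical abrasion by toothbrushing is one
of their suspected drivers. Observing how dozens of flexible bristle tufts
load a tooth surface — dozens of simultaneous, intermittent contacts — is
impractical experimentally and awkward for mesh-based solid mechanics, which
handles large bristle bending well but multi-body contact poorly. brushwear
takes the discrete-element route: every tuft is a short chain of bonded
spheres that bends like a beam, every contact is a nonlinear spring-dashpot,
and abrasion is bookkept with Archard's wear law wherever a bristle slides
over enamel.

The simulator has four layers:

1. **Fiber model.** One tuft (a bundle of ~40 filaments treated as a single
   aggregate beam of diameter 1.8 mm and length 10.8 mm) is a worm-like
   chain of 8 particles with stretching, bending, and optional torsion
   energies,
   \[
   H_S = \tfrac12 k_s \sum_i (l_i - l_0)^2,\qquad
   H_B = k_{bend} \sum_j w_j\,(1 - \hat t_j\cdot\hat t_{j+1}),\qquad
   H_T = \tfrac12 k_T \sum_i (\gamma_i - \gamma_0)^2,
   \]
   with forces the exact analytic gradients. Stiffnesses come from the
   standard lattice-beam discretisation of a rod of modulus $E$ and shear
   modulus $G$: $k_s = EA/l_0$, $k_{bend} = EI/l_0$, $k_T = GJ/l_0$.
2. **Contact mechanics.** Hertz–Mindlin: normal force
   $F_n = \frac43 E^\ast \sqrt{R^\ast}\,\delta_n^{3/2} -
   2\sqrt{5/6}\,|\beta|\sqrt{S_n m^\ast}\,v_n$ with
   $S_n = 2E^\ast\sqrt{R^\ast\delta_n}$, tangential spring-dashpot with
   stiffness $S_t = 8G^\ast\sqrt{R^\ast\delta_n}$ capped by Coulomb friction
   $\mu|F_n|$.
3. **Assembly and kinematics.** 42 tufts on a 3 × 14 grid over a
   27.5 × 10.2 mm head; a tooth model of two coplanar enamel plates joined
   by a rectangular interproximal groove; a horizontal scrub stroke —
   forward half the two-stroke length $L$, instantaneous reversal, back —
   with the head height fixed so the undeformed tips would overlap the
   tooth plane by the brushing depth $d_z$.
4. **Wear.** Archard's law $Q = KWL/H$; in incremental form each sliding
   contact deposits $(K/H)\,F_n\,\delta_t$ into the wear-map cell under the
   contact point, with $\delta_t = |v_t|\,\mathrm{d}t$ the per-step slip.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| brushing speed $V$ | 0.10 (0.05–0.15) | m/s | stroke kinematics |
| brushing depth $d_z$ | $r$ = 0.9 mm ($r$, $r/2$, $r/4$) | m | proxy for brushing force |
| stroke length $L$ | 56 | mm | two-stroke scrub cycle; tooth span $L/2$ |
| acrylic $E$, $\nu$, $\rho$, $H$ | 3.4 GPa, 0.3, 1185 kg/m³, 0.22 GPa | — | tuft-beam material |
| enamel $E$, $\nu$, $\rho$, $H$ | 60 GPa, 0.3, 3000 kg/m³, 0.92 GPa | — | tooth material |
| friction $\mu$ | 0.18 | — | all material pairs |
| restitution $e$ | 0.3 | — | not a tabulated material property; see below |
| Archard $K$ | 1 | — | wear reported per unit $K$; see below |
| wear cell | 0.5 | mm | map resolution |
| time step | $0.1\,\Delta t_{crit}$ | s | $\Delta t_{crit} = 2\sqrt{m/k_{max}}$ |
| background damping | 10 | s⁻¹ | settles released bristles between events |

Two constants the material tables do not provide are deliberately exposed
rather than guessed as ground truth. The **coefficient of restitution** only
sets the contact damping ratio $\beta = \ln e/\sqrt{\ln^2 e + \pi^2}$; the
default $e = 0.3$ heavily damps the high-frequency ringing of tip impacts.
Quasi-static force levels and total wear are insensitive to it (the damping
term vanishes at low approach speeds); rebound heights of individual tip
impacts are not. The **Archard constant** $K$ for acrylic on enamel is not
tabulated; all outputs are linear in $K$, so wear is reported "per unit K"
and every comparative statement (depth vs speed ordering, spatial
distribution, symmetry) is $K$-independent.

## Numerical design choices

**Clamped-end bending.** With a uniform joint stiffness $EI/l_0$, a
tip-loaded chain of 6 free segments is systematically ~26% too compliant
(the discrete lever sum gives $91/72$ of the continuum deflection). The
clamp fixes the tangent of the first bond, so the curvature at the wall is
carried by only half a segment; the consistent discretisation doubles the
stiffness of the root joint ($w_j = 2$ there, 1 elsewhere). With this, the
chain reproduces $FL^3/3EI$ to 1.4% at small loads and the
large-deflection elastica to 1.8% at a 30 N tip load — comfortably inside
the 3.3%/5% validation gates.

**Damping sign convention.** $\beta$ is stored signed ($\beta \le 0$ for
$e < 1$, 0 at $e = 1$) and its magnitude is applied against the relative
normal/tangential velocity, so dissipation always opposes relative motion.

**No tensile contact.** The total normal force is clamped at zero: there is
no cohesion in the model. A side effect is that dissipation is truncated
near separation, so the effective restitution of a binary impact exceeds
the nominal $e$: +0.2% at $e=0.9$, +2.6% at 0.7, +9.9% at 0.5, +18% at 0.4.
The recovery property is therefore only claimed for $e \ge 0.5$; this is a
known behaviour of this damping form combined with a no-tension clamp.

**Coulomb cap with spring truncation.** When the tangential trial force
exceeds $\mu|F_n|$, the force is scaled onto the cone and the accumulated
slip vector is rescaled so the spring alone carries the capped force. The
slip history is rotated into the current tangent plane each step and reset
when a contact breaks.

**Facet attribution.** The tooth is a set of one-sided rectangles. Face
(interior-projection) contacts use the signed plane distance, so a centre
that has crossed the plane is still expelled through the front face.
Edge/corner contacts use the closest boundary point. A particle's edge
contacts are suppressed whenever it has any face contact, and coincident
closest points across facets (shared edges) are deduplicated — this
prevents double-counting at the groove lips, exactly where wear
concentrates. Concave corners (wall–floor) keep both face contacts.

**Integrator.** Semi-implicit (symplectic) Euler. With velocity-dependent
damping and friction it is simpler and more robust than velocity Verlet,
and at $\Delta t = 0.1\,\Delta t_{crit}$ an elastic frictionless collision
conserves kinetic energy to well under 1% (verified in the tests). The
engine is deterministic: no randomness anywhere, fixed iteration order,
bit-identical repeated runs.

**Press-in initialisation.** Prescribing the stroke-time tip overlap
$\delta_n = d_z$ as an *initial condition* would store of order 1 J of
Hertz elastic energy per tuft at $t=0$ and eject tips at hundreds of m/s.
The head therefore starts with the tips grazing the tooth plane, presses in
at 0.05 m/s to depth $d_z$, holds 20 ms to settle, and only then strokes —
as a real brush is placed before it is moved. Wear and force measurement
begin at stroke start; during the stroke the head height is fixed, as the
depth definition requires.

**Degenerate inputs** are rejected with diagnostics: zero-area facets,
coincident sphere centres (contact normal undefined), zero-length bonds,
non-physical material constants, and blown-up integrations abort naming the
offending particle and step.

## What the geometry emulates — and does not

The tooth model is deliberately schematic: two flat labial surfaces and one
rectangular interproximal groove (width 2.4 mm — slightly wider than the
tuft beam so tips can enter — depth 3 mm, both configurable). The measured
span equals half the stroke so the head centre crosses the groove at stroke
fractions 1/5 and 4/5, where per-tuft force snapshots are taken. A
wear-excluded auxiliary plate (36 mm) extends the right side so the stroke
reversal happens on supported ground, and a wear-excluded support extends
the left of the measured region so bristles are supported at stroke start;
neither enters any wear statistic. The plate height defaults to 16.5 mm so
that the map spans an odd number of 0.5 mm cells and the mirror plane of
the (symmetric) assembly is a cell centre — otherwise wear from the centre
tuft row falls on a cell boundary and spuriously breaks the top–bottom
symmetry score. The tuft grid (3 × 14), groove cross-section, and support
lengths are geometry choices where only counts and overall dimensions are
fixed by the design; all are configurable.

Real teeth are curved, real tufts are 40 separate filaments with rounded
tips, and real brushing involves toothpaste slurry; none of that is
modelled. Torsion is implemented but off by default — bending dominates the
scrub stroke and is the validated mode; a configuration flag enables it.
Gravity is off by default (bristle weight is orders of magnitude below
contact forces and the brushing orientation is unspecified).

## Force magnitudes: a known limitation

The aggregate-beam idealisation has a real consequence. Validating the
chain against the elastica anchors its flexural rigidity at
$EI = 1.75\times10^{-3}$ N m² (a 30 N tip load deflects the 9.3 mm free
length by about 40%). A beam that stiff, pressed 0.9 mm into a rigid plane,
pushes back with hundreds of newtons per tuft (its Euler buckling load
alone is ~50 N): the simulated per-tuft tooth forces are of order
$10^2$ N. A real tuft is 40 independent filaments of ~0.05 mm diameter
whose collective buckling load is a few millinewtons — which is why real
brushing forces are a few newtons for a whole brush. A single 1.8 mm
acrylic beam cannot be simultaneously calibrated to the elastica bench at
30 N loads *and* produce millinewton-scale tip forces; the two regimes
differ by the filament-vs-beam moment of inertia, a factor of ~4×10⁴.

The package keeps the documented aggregate-beam calibration (it is what the
validation bench pins down) and treats *relative* outputs as the meaningful
ones: wear ordering across depths and speeds, the ~10× max-to-mean force
concentration at the groove crossings, and the spatial structure and
symmetry of the wear map. Absolute forces and absolute wear volumes should
not be read as clinical predictions. One further consequence: because the
plates are scraped continuously at these high per-tuft forces, the
plate-interior wear density exceeds the groove-band density in our runs —
groove facets still collect a substantial share (roughly 15–30%) of total wear,
but the per-area concentration in the groove band that a gentle force
regime produces does not survive the stiff-beam regime.

## Problem sizes used by the tests

The acceptance tests run the full 336-particle assembly: one complete
56 mm cycle at $V = 0.1$ m/s, $d_z = r$ (≈3.5 × 10⁶ steps) for the force
criteria, and the two comparison slices (three depths at $V = 0.1$; three
speeds at $d_z = r$) as half-stroke (28 mm) variants — the wear orderings
are already fully expressed there and each condition stays under a minute
of integration per simulated second. Unit tests use two-sphere impacts,
single chains, and a two-tuft quarter-stroke configuration. The cantilever
bench relaxes an 8-particle chain per load and sweeps 0–30 N in seconds.

## Known limitations

- Absolute force and wear magnitudes reflect the aggregate-beam stiffness
  (see above); use relative comparisons.
- Restitution is only faithfully recovered for $e \ge 0.5$.
- Rolling of tips is not modelled: tangential slip is translational, and
  particle spin is integrated only for the (optional) twist bookkeeping.
- The tooth geometry never changes: wear is accounted, not removed.
- Only the horizontal scrub stroke is implemented; no tilt, roll, or
  circular strokes.
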