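---
title: "Simulating multi-voxel PRESS and semi-LASER spectroscopy of hyperpolarized 13C substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-voxel PRESS and semi-LASER spectroscopy of hyperpolarized 13C substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpmrsim)
```

## The problem

Dissolution dynamic nuclear polarization boosts the ^13^C signal of injected
substrates (pyruvate, the Z-OMPD pH sensor) by four orders of magnitude, but
the polarization is a *non-renewable* pool: every RF pulse consumes part of
it irreversibly and T~1~ relaxation removes the rest within tens of seconds.
Localized spectroscopy sequences built for thermally polarized protons —
PRESS (90°–180°–180°) and semi-LASER (90° followed by two pairs of adiabatic
full-passage refocusing pulses) — therefore behave differently when several
voxels are acquired back to back: any voxel whose excitation or refocusing
slab cuts through a voxel acquired later has already saturated or inverted
part of that voxel's magnetization. `hpmrsim` simulates this whole chain at
desk scale: the pulses, their Bloch-simulated slice profiles, the voxel/slab
geometry, the sequence timing arithmetic, the spatial magnetization ledger,
the competing 2D FID-CSI acquisition with its point-spread-function
bleeding, and the spectral quantification (time-domain Lorentzian fitting,
SNR, multi-compartment chemical-shift pH).

## RF pulses

Two families are generated:

* **HSn adiabatic full passage** (`make_hs_pulse()`): envelope
  $A(\tau)=\operatorname{sech}(\beta|\tau|^n)$ on $\tau\in[-1,1]$ with an
  antisymmetric frequency sweep. Defaults follow the hardware settings the
  simulator models: 3.4 ms, $\beta = 5.3$ (a ~1% edge truncation since
  $\operatorname{sech}(5.3)\approx 0.01$), $n = 1$, 3.2 kHz bandwidth. For
  $n=1$ the sweep is the $\tanh$ companion scaled so the swept range equals
  the nominal bandwidth; for $n>1$ no closed form ties the sweep to the
  inversion band, so the sweep shape (the normalized integral of $A^2$) is
  rescaled by a two-iteration calibration against the package's own Bloch
  engine until the simulated inversion-band width matches the request. The
  `beta`/`n` parameterization is exposed directly so alternative
  interpretations of vendor "RF constants" can be injected.
* **Windowed-sinc selective excitation** (`make_excitation_pulse()`): a
  Hamming-windowed sinc with time–bandwidth product `2 * sharpness`
  (`sharpness` = zero-crossing pairs per side, default 3). This is a
  behavioral stand-in for vendor Shinnar–Le Roux designs: what downstream
  modules need is a band-limited pulse whose simulated profile width matches
  the nominal bandwidth within 10% and whose on-resonance flip is exact,
  both of which hold (the flip via the area theorem, since rotations about
  a fixed axis commute).

Default sample counts are odd (513/257) so the waveform midpoint is sampled:
the peak is then exactly 1 and the HS envelope minimum exactly
$\operatorname{sech}(\beta)$.

## Bloch engine

`propagate()` implements the standard hard-pulse (piecewise-constant
rotation) approximation, vectorized over isochromats, relaxation-free —
justified because the 13C metabolite T~1~, T~2~ are orders of magnitude
longer than a 1–3.4 ms pulse. The test suite cross-checks it against an
independent dense-step matrix-exponential integrator to 10^-4^.
`slice_profile()` plays a pulse under its slice gradient
$G = \mathrm{BW}/(\gamma\,\Delta z)$; `inversion_vs_b1()` reproduces the
inversion-recovery-versus-power experiment used to find the adiabatic
threshold. Two qualitative facts the simulator reproduces and the tests pin
down: the AFP inversion plateaus near $M_z = -1$ over at least a twofold B~1~
range while an equal-bandwidth amplitude-modulated 180° does not, and the
AFP slice edge (10%→90% transition) is sharper than the 180°'s at equal
nominal scaling. Measured B~1~ thresholds on real coils fold in coil
efficiency and are not asserted; only the $\gamma$-scaling trend is.

## Voxel planning and CSDE

Voxels are axis-aligned boxes realized as the intersection of one excitation
slab and two refocusing slabs (`slabs_of()`; default roles: excitation along
z, refocusing along x and y, configurable per plan). `overlap_report()`
returns, for every voxel, the fraction of its volume inside each *earlier*
voxel's slabs — the saturated/inverted fraction — computed analytically from
the box geometry (the ledger below rasterizes instead, as an independent
route). `csde()` is the chemical-shift displacement arithmetic
$100\cdot\Delta f/\mathrm{BW}$: for the 900 Hz pyruvate–lactate separation
at 7 T it gives 17% of the slice thickness for a 5.4 kHz excitation pulse
and 26% / 28% for 3.4 / 3.2 kHz refocusing pulses. (Source literature quotes
both 11% and 17% for the excitation case in different places; the formula
gives 16.7%, and this package reports the formula.)

## Sequence timing, crushers, scan-time arithmetic

`solve_slaser_timing()` minimizes TE subject to the semi-LASER echo
condition $\tau_1+\tau_3+\tau_5=\tau_2+\tau_4$ and per-interval lower bounds
from pulses, crushers and gradients. With odd-side and even-side bound sums
$L$ and $R$, the minimum of $\sum\tau$ is $2\max(L,R)$, achieved by topping
up the last interval of the deficient side — a closed form the tests verify
against a brute-force 0.01 ms grid search. PRESS minimal TE is treated as an
input because its gradient ramp composition is hardware-specific.

The crusher scheme around the four AFPs is stored as the published table of
relative areas (Gx: 0,0,0,1,1; Gy: −1,0,0,0,1; Gz: 0,−1,1,0,0; one common
amplitude, 40% of a 590 mT/m system = 236 mT/m, 0.5 ms). The property worth
asserting is that no spurious coherence pathway refocuses. A coherence that
is transverse from crusher event *i* to crusher event *j* and refocused by
the intervening pulses accumulates the *alternating-sign* cumulative area
$\sum_{k=i}^{j}(-1)^{k-i}\mathbf{a}_k$ (the coherence order flips at each
refocusing pulse); `crusher_pathway_areas()` enumerates these ten vectors,
which are all nonzero and pairwise distinct for the stored table. The naive
same-sign sums are *not* all distinct (events 2–3 cancel exactly on every
axis), which is why the alternating-sign reading is the one implemented: it
is the physically meaningful dephasing for pathways the crushers exist to
suppress. The placement of the five events relative to the four AFPs is kept
as an ordered list without asserting which pulse each brackets.

`scan_time()` and `spectral_resolution()` reproduce the published
acquisition arithmetic: 12×8 × 230 ms = 22.1 s and 13×11 × 90 ms = 12.9 s
for single-slice CSI, ≈39 s for three slices, 7 voxels × 1 s TR = 7 s for
multi-voxel MRS; and 1.1 / 5.9 Hz per point for the 30 ppm/1024-point and
40 ppm/256-point acquisitions. The Hz-per-point convention treats
"acquisition points" as complex points with a zero-fill factor of 2 before
the transform — the single convention that reproduces all printed values —
and the 13C frequency at 7 T defaults to 74.96 MHz ($\gamma$ = 10.708
MHz/T).

## The hyperpolarized magnetization ledger

`magnetization_grid()` rasterizes a bounding box (0.5 mm isotropic by
default) and tracks M~z~ only. Three events act on it:

* excitation: $M_z \leftarrow M_z\cos(\theta\,p(r))$ with $p(r)$ the
  normalized flip response (ideal boxcar or an interpolated Bloch profile);
* refocusing: $M_z \leftarrow -(2q(r)-1)M_z$ inside the slab, with
  inversion efficiency $q=1$ perfect and $q=0.5$ full saturation. Transverse
  magnetization created outside the voxel is assumed fully crushed and lost,
  matching the strong-crusher design. For semi-LASER the per-axis AFP *pair*
  is folded into one event with net efficiency `q_afp`;
* relaxation: $M_z \leftarrow M_z e^{-\Delta t/T_1}$, with no thermal
  recovery term (negligible against the hyperpolarized scale).

Defaults `q_afp = 0.97` and `q_slr = 0.80` are free parameters chosen to
reproduce the *direction* of the PRESS-versus-semi-LASER comparison
(adiabatic refocusing preserves more magnetization under slab overlap); they
are not measurements, and the ledger targets orderings, not the published
multiplicative factors, which entangle unmodeled physiology (perfusion,
inflow) and true pulse profiles. The remaining-magnetization probe reports
total $|M_z|$ over its initial value: residually inverted regions still hold
usable polarization, and magnitude is the quantity that is monotone in the
refocusing efficiency, which is what makes the semi-LASER ≥ PRESS
comparison well-posed for arbitrary plans. `effective_t1()` fits a
mono-exponential to a signal-versus-time record; under repeated excitation
at flip $\theta$ every TR the closed form
$1/T_{1,\mathrm{eff}} = 1/T_1 - \ln(\cos\theta)/\mathrm{TR}$ holds exactly
in the simulator and the fit recovers it within 2% under the dynamic
acquisition settings (35°, TR 2 s).

## 2D FID-CSI point-spread function

`centric_order()` implements centric–centric encoding: the k-space center is
acquired first, each vertical column is traversed in an up–down alternating
center-out pattern, and columns are visited left–right center-out. The
up-first tie-break is configurable because the source schematic does not
disambiguate it; the PSF asymmetry conclusion is insensitive to it. Because
a whole column is acquired before moving on, horizontally adjacent k-space
points differ by ~N~y~ acquisition indices while vertical neighbors differ
by ~2, so the acquisition weights
$w_j = \sin\theta\,\cos^{j-1}\theta\,e^{-(j-1)\mathrm{TR}/T_1}$
(RF consumption × T~1~ decay, verified against step-by-step simulation to
10^-12^) vary much more along rows. The PSF (inverse DFT of the weight map,
unit peak) consequently bleeds predominantly left–right: sidelobe energy
outside the nominal one-voxel main lobe is larger along the row direction
than the column direction, and convolving a square test object
(`convolve_object()`, circular convolution scaled so uniform weights are the
identity) shows the same asymmetry in image space. k-space center for even
sizes is index N/2.

## Spectral synthesis, fitting and SNR

`synth_fid()` builds
$s(t)=\sum_p A_p e^{i(2\pi f_p t+\phi_p)}e^{-\pi w_p t}$ + complex white
Gaussian noise; $w_p$ is the Lorentzian full width at half maximum (the
`exp(-pi w t)` convention), and every stochastic path is seeded.
`fit_fid()` minimizes the time-domain complex residual sum of squares with
Levenberg–Marquardt under bounds ($A, w \ge 0$), one constant complex
baseline term per fit, initialized by magnitude-spectrum peak picking on a
mildly matched-filtered (3 Hz broadened) spectrum plus a linear solve for
amplitudes and phases. If the converged fit leaves a tall coherent peak in
its residual spectrum (max/median above 5, against ~3.3 for white Rayleigh
residuals), alternate candidate sets from the next-strongest maxima are
fitted and the lowest residual wins — the multi-start that makes moderate-SNR
fits robust to noise maxima. Noiseless in-model data are recovered to
10^-6^ relative with residuals below 10^-10^ of the signal energy.

Spectra use a zero-fill factor of 2 and halve the first time-domain point
(trapezoid convention): a one-sided decay otherwise spreads a flat complex
offset across the whole spectrum. Even so, magnitude spectra keep
*dispersive* tails that fall off only as $1/\Delta f$, which is why
background regions belong at the spectrum edges — the same practice the SNR
definition (fitted peak height ÷ background-region magnitude standard
deviation, `snr()`) assumes. `apparent_background_snr()` implements the
sanity check that a peak-free background region of pure complex noise reads
mean/sd $=\sqrt{\pi/2}/\sqrt{2-\pi/2}\approx 1.91\approx 2$ (Rayleigh
statistics). Fits of records synthesized without noise flag their SNR as
overflow rather than reporting a meaningless ratio against numerical
background texture.

## Chemical-shift pH

The Z-OMPD sensor's C5–C1 shift difference titrates with pH:
$\mathrm{pH} = pK_a + \log_{10}\frac{\delta-\delta_\mathrm{acid}}
{\delta_\mathrm{base}-\delta}$, exact at the midpoint and strictly monotone
between the limits (`delta_to_ph()` / `ph_to_delta()`). The shipped
calibration constants (pK~a~ 7.0, limits 18.0 / 21.0 ppm) are **synthetic
placeholders**: the true titration constants live in the sensor's primary
calibration literature and are not baked in; every test here uses the
synthetic calibration, so correctness of the mapping and the fitting is
independent of the placeholder values. C1 serves as the pH-insensitive
frequency anchor (configurable), so the estimate is invariant to global
frequency shifts.

`multi_compartment_fit()` jointly fits one C1 peak plus *n* C5 components
(compartment count is a user input), picks C5 candidates inside the
calibration window from the matched-filtered spectrum, and adds a rescue
pass: a compartment that converged to zero amplitude is re-seeded from the
residual of the converged fit, and the refit is kept only when it lowers the
residual sum of squares by more than 1% — real compartments buy several
percent, noise bumps do not. Compartments closer than a quarter linewidth,
collapsed to below 1% amplitude, or landing outside the calibration window
are merged with a degeneracy warning (identical-pH compartments are
unidentifiable by construction). Uncertainties propagate from the local
curvature of the fit through the titration derivative.

The synthetic kidney phantom (`synth_kidney_ph_fid()`) emulates the
three-compartment regime: cortex/medulla/pelvis-like truths 7.32 / 7.06 /
6.58, amplitude fractions 0.5 / 0.3 / 0.2, and a per-peak SNR of about 16
anchored to the *dominant* C5 component — the convention under which split
C5 resonances are quoted per detected peak, and the regime in which the
smallest compartment (SNR ≈ 6) is still a resolvable component. Under those
conditions all three pH values are recovered within ±0.05 for every seed in
a 100-seed sweep.

## What the synthetic generators do and do not emulate

The generators produce ideal Lorentzian lines with white complex noise,
perfectly linear receive, no B~0~ inhomogeneity (no shim-induced broadening),
no B~1~ maps, no motion, no metabolic exchange during acquisition, and no
perfusion/inflow. Passing tests therefore demonstrate the correctness of
the sequence physics, bookkeeping and estimators on in-model data — not
robustness to lineshape distortion or physiological confounds in vivo.
In-vivo published SNR and pH numbers are used only as generator truths and
direction checks, never asserted as simulation outputs.

## Numerical choices and problem sizes

* Bloch integration step = waveform sample spacing (≤ 20 µs); profiles use
  ≥ 201 isochromats; doubling sample counts moves profile widths by < 1%.
* Ledger rasterization 0.5 mm isotropic; analysis examples use bounding
  boxes of a few centimeters (tens of thousands of cells), which keeps every
  simulation in the test suite in the seconds range.
* Monte-Carlo sizes: 200 replicates for frequency-precision checks, 100
  seeds for the Rayleigh background and pH-recovery sweeps.
* Optimizer tolerances 10^-14^ (ftol/ptol), 500 iterations; ties between
  multi-start candidates break by lowest residual.
* Degenerate inputs error early with typed conditions
  (`hpmrsim_invalid_parameter`, `hpmrsim_fit_failure`) naming the offending
  field; config files are schema-validated with field paths.

## Known limitations

The PRESS refocusing efficiency and the AFP pair efficiency are scalar
knobs, not derived from B~1~ maps; crushers are idealized as complete
transverse destruction; the ledger ignores inflow, so in-vivo effective-T~1~
values (which entangle perfusion) are reproduced in ordering only; the
semi-LASER timing solver works on user-supplied interval bounds rather than
a full gradient-event compiler; and the FID container is a JSON text format
holding full double precision, chosen for portability and inspectability
over binary containers.
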