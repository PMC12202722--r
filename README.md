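# hpmrsim

Simulation and quantification toolkit for **multi-voxel localized MR
spectroscopy of hyperpolarized ^13^C substrates** — for sequence developers
and preclinical spectroscopists who want to budget a non-renewable
hyperpolarized magnetization pool across a multi-voxel PRESS or semi-LASER
acquisition before burning a dissolution on it.

Hyperpolarized magnetization cannot be recovered once an RF pulse has
consumed it. When several voxels are acquired consecutively, every
excitation or refocusing slab that cuts through a not-yet-acquired voxel
saturates (or residually inverts) part of its signal. `hpmrsim` models that
chain end to end:

* **RF pulses** — HSn adiabatic full passage
  (A(τ) = sech(β·|τ|ⁿ), tanh/integral frequency sweep; defaults 3.4 ms,
  β = 5.3, n = 1, 3.2 kHz) and Hamming-windowed-sinc selective excitation
  (time–bandwidth = 2·sharpness), `make_hs_pulse()` /
  `make_excitation_pulse()`.
* **Bloch engine** — vectorized hard-pulse isochromat propagation,
  slice profiles, inversion-versus-B1 curves, adiabatic thresholds
  (`propagate()`, `slice_profile()`, `inversion_vs_b1()`).
* **Voxel planning** — slab bookkeeping, acquisition-order overlap reports,
  chemical-shift displacement: CSDE% = 100·Δf/BW (17% excitation, 26/28%
  refocusing for the 900 Hz pyruvate–lactate split at 7 T), `slabs_of()`,
  `overlap_report()`, `csde()`.
* **Sequence arithmetic** — minimal-TE semi-LASER timing under the echo
  condition τ₁+τ₃+τ₅ = τ₂+τ₄, crusher scheme and coherence-pathway check,
  scan-time and Hz-per-point conventions (`solve_slaser_timing()`,
  `scan_time()`, `spectral_resolution()`, `crusher_scheme()`).
* **Magnetization ledger** — a 3D Mz grid advanced shot by shot:
  Mz ← Mz·cos(θ·p(r)) per excitation, Mz ← −(2q−1)·Mz per refocusing event,
  exp(−Δt/T₁) between shots; per-shot signal records, the
  remaining-magnetization probe and effective-T₁ fits with the closed form
  1/T₁,eff = 1/T₁ − ln(cos θ)/TR (`simulate_acquisition()`,
  `effective_t1()`).
* **2D FID-CSI** — centric–centric encoding order, k-space weights
  w_j = sin θ·cos^(j−1) θ·e^(−(j−1)TR/T₁), point-spread function and
  signal-bleeding maps (`centric_order()`, `kspace_weights()`, `psf()`,
  `convolve_object()`).
* **Spectral fitting** — seeded Lorentzian FID synthesis, time-domain
  least-squares fitting with residual-guided multi-start, SNR = fitted
  height / background-region magnitude SD, line broadening
  (`synth_fid()`, `fit_fid()`, `snr()`, `line_broaden()`).
* **pH quantification** — Henderson–Hasselbalch mapping of the Z-OMPD C5–C1
  shift difference, pH = pKa + log₁₀((δ−δ_acid)/(δ_base−δ)), with joint
  multi-compartment fitting of split C5 resonances
  (`ph_calibration()`, `delta_to_ph()`, `multi_compartment_fit()`).

## Worked example: two overlapping kidney voxels

Two voxels cover the left and right kidney. They are disjoint along the
excitation axis but share both refocusing-slab extents — the configuration
in which PRESS loses the second voxel while semi-LASER keeps it.

```r
library(hpmrsim)

plan <- voxel_plan(c("Kidney L", "Kidney R"),
                   rbind(c(-5, 0, 0), c(5, 0, 0)), c(5.5, 4.5, 9.7))
roles <- c(exc = "x", ref1 = "y", ref2 = "z")
overlap_report(plan, roles)
#>      later  earlier role fraction
#> 1 Kidney R Kidney L ref1        1
#> 2 Kidney R Kidney L ref2        1

g <- function() magnetization_grid(c(-12, 12), c(-6, 6), c(-9, 9),
                                   resolution_mm = 0.5, t1_s = 30)
sl <- simulate_acquisition(plan, g(), flip_deg = 90, tr_ms = 1000,
                           refocusing = "afp", roles = roles)
pr <- simulate_acquisition(plan, g(), flip_deg = 90, tr_ms = 1000,
                           refocusing = "slr", roles = roles)
round(sl$record$signal, 3)  # semi-LASER: 1.000 0.855
round(pr$record$signal, 3)  # PRESS:      1.000 0.348
sprintf("remaining: semi-LASER %.3f vs PRESS %.3f", sl$remaining, pr$remaining)
#> "remaining: semi-LASER 0.416 vs PRESS 0.221"
```

The second voxel keeps 86% of its signal under adiabatic refocusing
(inversion efficiency 0.97 per refocusing event) but only 35% under
imperfect amplitude-modulated refocusing (0.80), and the final non-selective
probe finds roughly twice the polarization left after semi-LASER — the
overlap mechanism, reproduced in the ledger.

Three-compartment pH from a synthetic kidney phantom (generator truths
7.32 / 7.06 / 6.58, fractions 0.5 / 0.3 / 0.2, dominant-peak SNR ≈ 16):

```r
res <- multi_compartment_fit(synth_kidney_ph_fid(seed = 1), 3, ph_calibration())
res
#> <ph_result> C1 reference at 160.003 ppm, 3 compartment(s)
#>  compartment   ppm delta_ppm fraction    ph    ph_se in_validity_window
#>            1 180.0     20.02   0.4727 7.316 0.003755               TRUE
#>            2 179.6     19.59   0.3114 7.051 0.005315               TRUE
#>            3 178.8     18.81   0.2159 6.569 0.008231               TRUE
```

Each recovered pH sits within ±0.05 of its generator truth. The shipped
calibration constants are labeled synthetic placeholders — substitute
measured titration constants for real quantification.

A thin command-line front end over the same functions is installed at
`inst/cli/hpmrsim.R` (`Rscript $(Rscript -e 'cat(system.file("cli","hpmrsim.R",package="hpmrsim"))') plan-check plan=myplan.csv`, plus
`simulate-profile`, `timing-solve`, `scan-time`, `simulate-acq`, `csi-psf`,
`synth`, `fit`, `snr`, `ph-fit`, `make-fixtures`, `csi-bleed-demo`).

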