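---
title: "Holographic energy-flow reconstruction: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic energy-flow reconstruction: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A planar electrode array records the potential map `P(x, y, t)` generated
by distributed electrical sources in the tissue beneath it. `neholo`
treats one temporal-frequency component of that map as a hologram and
back-propagates it through a homogenised tissue model.

The chain, per frequency ω:

1. **Complex permittivity** `ε̂ = ε + iσ/ω` folds conduction losses into
   the permittivity; the **characteristic wavenumber** is
   `k = ω√(μ ε̂)` (principal square root, so `Re k ≥ 0`, and `Im k > 0`
   for a conductive medium). Internally, lengths are mm, spatial
   frequencies rad/mm, ω rad/s, σ S/m; ε and μ are stored as relative
   values and scaled by the vacuum constants inside the wavenumber.
   At delta-band frequencies `|k| ~ 10⁻⁶ rad/mm`, while the array's
   spatial-frequency lattice spans several rad/mm: essentially every
   spatial mode is **evanescent** (near-field), decaying as `e^(−k_r z)`
   with depth. Those modes carry all sub-pitch spatial detail.
2. **Normal wavenumber**: `k_z = √(k² − k_r²)` where `k_r² ≤ |k|²`,
   otherwise `k_z = −i√(k_r² − k²)`. With lossy (complex) `k` the printed
   lossless comparison is ambiguous; comparing against `|k|²` reduces to
   it continuously as σ → 0 and keeps the forward propagator
   `G_z = e^(−i k_z z)` non-amplifying. This resolves an inconsistency in
   the source formula table, whose far-field condition is printed with a
   minus sign (`k_x² − k_y² ≤ k²`) that conflicts with the radial
   `k_r² = k_x² + k_y²` used by the filter; it is treated as a typo.
3. **Electric field** at the electrodes is the in-plane gradient
   `E = ∇P` (central differences, one-sided at the edges; the sign
   convention is `+∇P` — all outputs are in arbitrary units, so the
   physical minus is immaterial). The plane-normal component is set to 0:
   a single-plane map has no normal derivative. This closure is also what
   makes the magnetic-field estimate non-trivial — a full 3-D gradient
   would satisfy `K × (−iK P̂) ≡ 0` identically, whereas the truncated
   field yields a usable orthogonal partner.
4. **Back-projection**: `E_z = F⁻¹(F(E) · G_z⁻¹ · K_filter)`. The
   *inverse* propagator is applied here. A decay-only back-projection was
   considered and rejected: under it the reconstruction contrast is
   maximal at `z = 0` and decreases monotonically with depth, so no
   reconstruction plane can be "in focus" and the two-sided defocusing
   behaviour (moving `z` away from the source depth in either direction
   degrades the image) cannot exist. Undoing the evanescent decay is
   exactly what refocuses buried structure; the price is exponential
   amplification of high-`k_r` noise, which the filter bounds — the
   filter is therefore mandatory whenever `z > 0` in this mode. The
   forward simulator keeps the decaying direction.
5. **Magnetic-field estimate** `H_z = F⁻¹(K × F(E_z))`,
   `K = (k_x, k_y, k_z)` per lattice node.
6. **Poynting field** `S_z = E_z × H_z`, deliberately *without*
   conjugation, so that the complex product can later be split: the real
   part is read as propagating energy flow, the imaginary part as
   resonant (standing-wave) energy exchange (`split_complex_flow()`).
   The physics-standard `E × conj(H)` is available via
   `poynting(conjugate = TRUE)`.
7. **Energy source density** `ESD = ∂S_x/∂x + ∂S_y/∂y`: in-plane terms
   only. The method is not tomographic — a single reconstruction plane has
   no normal derivative — and a reconstruction plane behaves as a local
   depth average rather than a sharp focal slice.
8. **Dissipation** `D = σ|E_z|²` (summed over components). The literal
   unconjugated form `σ(E·E)` is complex for complex fields; the
   magnitude-squared convention is the only one that makes the map real
   and non-negative for arbitrary inputs, matching how dissipation maps
   are displayed. This is a documented divergence from the literal
   printed formula.

## Transform conventions and padding

The spatial transform uses the kernel `e^(+i k·x)` forward and
`e^(−i k·x)` in synthesis (R's `fft(·, inverse = TRUE)` and `fft(·)/N`
respectively); with the time kernel `e^(−iωt)` this makes `e^(−i k_z z)`
the decaying direction on the near-field branch. Implementers porting to
another FFT library must map its sign convention onto this explicitly.

Propagation zero-pads each axis ×2 by default (leakage control), after
removing the frame mean; the mean is carried through the DC channel
(multiplied by the DC propagator and filter gain) and the cropped residual
is re-centred. This keeps `z = 0` with an all-pass filter an exact
identity and guarantees the decaying propagator never increases the L2
norm of a frame.

## Virtual electrodes (Papoulis–Gerchberg)

`pg_interpolate()` alternates between enforcing the recorded samples on
the fine-grid sublattice and projecting onto the band `k_r ≤` band limit
(default: the raw grid's Nyquist `π/pitch` — the information ceiling of
the array; nothing above it can be genuinely recovered). Stopping: relative
L2 change < 1e-8 or 500 iterations, whichever first; hitting the cap sets
a `converged = FALSE` attribute rather than raising. The recorded samples
are re-imposed after the last iteration, so real electrodes always carry
their measured values exactly. Complex frames are interpolated in one pass
(the algorithm is linear, so per-part interpolation would be identical).

The FFT-periodic interpolant extends `factor − 1` nodes beyond the last
electrode row/column; those nodes are wraparound extrapolation across the
periodic seam, not virtual electrodes *between* real ones, and they carry
seam artifacts that leak into energy maps. They are therefore cropped by
default (`crop_margin = TRUE`): a 10 × 10 array upsampled ×3 yields a
28 × 28 fine grid, i.e. two virtual electrodes between each real pair.
The downsampling experiment (below) is the one consumer that keeps the
margin, because it must restore the full even-sized original grid.

## Source maps and localisation

For stationary rhythms the pipeline runs on the complex phasor of the
band of interest (`band_phasor()`, default: strongest FFT bin in
0.5–2 Hz). Two structural facts shape how sources are read off the maps:

- The in-plane Poynting flow of a radially symmetric source vanishes at
  the source centre (it is quadratic in a field that is zero there by
  symmetry), so the ESD of a compact source is an **annulus**, not a
  blob — nodewise maxima sit on the ring. `locate_esd_sources()` therefore
  clusters the above-half-max region by proximity and reports
  intensity-weighted centroids, which for an annulus coincide with the
  source centre.
- Distinct oscillators at the same frequency interfere in any quadratic
  map. `cycle_energy_map()` evaluates the instantaneous fields at 12
  phases of the cycle and averages |ESD|; cross terms between generators
  with different phases largely cancel over the cycle (this mirrors
  averaging energy maps over many recorded periods).

`peak_background_contrast()` and `esd_blob_width()` quantify focusing:
contrast is the weakest per-source neighbourhood peak over the background
rms; width is the intensity²-weighted RMS radius of the above-half-max
region, which tracks the annulus radius and is robust where a naive
half-max-area FWHM is dominated by background noise.

## Defaults and the parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `z` | 0.1 | mm | useful range for a 0.4 mm array is roughly 0.065–0.265 mm; pick by the contrast/defocus procedure |
| `kc` | 1.5 × π/pitch | rad/mm | half-gain point beyond the measured band: measured content passes at gain > 0.9, roll-off confined to the extrapolated band |
| `alpha` | 0.2 | — | transition width ≈ α·kc; small enough to suppress amplified noise, large enough to avoid ringing |
| `pad_factor` | 2 | — | leakage control; diminishing returns beyond 2 |
| `upsample_factor` | 3 | — | two virtual electrodes between each real pair; benefits beyond ×3 were not explored |
| `omega` | 2π·1.5 | rad/s | delta-band carrier; the propagator is evaluated at one representative frequency (stationarity assumption); per-frame reconstruction over a time stack is available by mapping over frames |
| σ, ε, μ | 0.3 S/m, 10⁵, 1 | SI | **placeholders** on the scale reported for cortical grey matter — configure per experiment; they are not measured ground truth |
| `anisotropy_ratio` | 1 | — | across/along-layer conductivity ratio, folded in as a scalar rescaling of σ in the wavenumber and dissipation; full tensor propagation is out of scope |

The k-space product assumes a laterally homogeneous plane, so wavenumbers
use the spatial *mean* of the layer properties; the per-node σ map enters
only the dissipation formula. How a layered property map could be encoded
exactly in a single k-space filter is an open question of the method
itself.

## The forward simulator

`simulate_recording()` rasterises disc/point/rectangle sources at their
depths, projects each one to the electrode plane with the *decaying*
angular-spectrum propagator (all-pass), expands along the source
waveforms, and adds seeded white Gaussian noise per electrode and sample.
The two-disc fixture places discs of radius 0.3 and 0.6 mm at depths 0.1
and 0.2 mm (or both at 0.15 mm with `same_depth = TRUE`, the
configuration with a single well-defined true depth), centres (1.2, 1.2)
and (2.8, 2.8) mm — node-aligned and inside the well-sampled interior —
in temporal quadrature, emulating independent generators; noise sd is 10 %
of the peak projected amplitude.

What the simulator deliberately does **not** emulate: it shares the
angular-spectrum propagator with the reconstruction (a self-consistent
inverse-crime setup — acceptable because validation rests on closed-form
single-mode oracles plus method-internal consistency, not physical
fidelity); sources are pure sinusoids, noise is white, media are
dispersion-free and the volume between planes is source-free. Passing
tests therefore demonstrate internal correctness and resolution behaviour,
not performance on real tissue.

## Wavelet semblance and the downsampling experiment

`semblance()` computes analytic Morlet CWTs (centre frequency ω₀ = 6,
scales log-spaced over 0.5–2 Hz by default) and returns
`cos(arg(W_x · conj(W_y)))` per time and scale — a phase-only statistic,
invariant to positive rescaling. Cone-of-influence nodes (edge distance
< √2·scale) are excluded from summaries.

`superresolution_experiment()` downsamples a full-grid recording 2-fold,
restores it by (A) PG interpolation alone and (B) the same interpolation
followed by holographic back-projection, and scores each branch per
electrode by mean semblance against the original recording. Branch B's
comparison series is the back-propagated **potential** by default.
Spatial-gradient components (`ex`, `ey`) are offered but score ~0.45
lower: the gradient reverses sign across each source, so at half the
electrodes the series is in anti-phase with the recorded voltage and the
statistic measures sign geography, not reconstruction quality. All
per-frame steps are linear, so both branches are materialised as matrices
(`pg_matrix()` plus a propagation operator) and applied to the whole frame
stack at once — identical to per-frame processing, at a fraction of the
cost.

Two structural facts about this protocol deserve emphasis. Branch A
reproduces the original recording *exactly* (noise included) at every
retained electrode, by PG's enforcement pass. And branch B is a fixed
linear transform of branch A, so it can only reweight the same
information. On the package's synthetic fixtures the measured outcome of
the experiment — reported by `scripts/acceptance.R` as
`superres_neh_win_runs` and `superres_pooled_wilcoxon_p` — reflects these
facts; the experiment, and the paired Wilcoxon signed-rank summary
(`paired_compare()`, two-sided, with a paired-t alternative), are provided
as the instrument for making the same comparison on real recordings,
where the balance between the branches is an empirical question.

## Numerical choices

- Round-trip transform error is < 1e-10 unpadded; the single-mode
  propagator oracle holds to < 1e-9 relative (measured ~1e-14).
- PG recovery of strictly band-limited fields under regular ×2/×3
  decimation converges geometrically (error contraction ≈ 1 − 1/m² per
  iteration); 500 iterations is far beyond what the 1e-6 recovery target
  needs.
- Cycle averaging resamples each marked cycle to 8 phase points by linear
  interpolation before averaging; markers come from negative-going zero
  crossings of the band-passed (Butterworth order 3, zero-phase) grid
  mean, or are supplied explicitly.
- Test problem sizes: 10–16 node grids, 2–20 s simulated recordings at
  50–200 Hz, 20-run experiment batches — sized so the whole suite runs in
  a few minutes on one CPU.

## Known limitations

- Single-plane, non-tomographic: no volumetric reconstruction, no normal
  ESD term.
- Regular complete grids only; no missing-electrode handling.
- One frequency per run in the propagator; strongly non-stationary data
  violate the phasor assumption.
- Tissue properties are user-supplied scalars per layer band (no
  dispersion, scalar anisotropy only).
- Absolute magnitudes of all reconstructed quantities are arbitrary.
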