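# neholo — near-field electromagnetic holography for microelectrode arrays

`neholo` estimates electromagnetic field structure *inside* neural tissue
from planar microelectrode-array voltage recordings. A regular grid of
electrodes (e.g. a 10 × 10 array at 0.4 mm pitch resting on a cortical
slice) samples the interference pattern of the many electrical generators
below it. Treating the array as a hologram, the package back-propagates
that pattern through a homogenised tissue model in the spatial-frequency
(k-space) domain and reports, at a chosen reconstruction depth `z`:

- the electric field estimate `E_z`,
- an orthogonal magnetic-field estimate `H_z`,
- the complex Poynting energy-flow field `S_z`,
- the **energy source density** (ESD, the electromagnetic analogue of
  current source density) and the **energy dissipation** map.

It is aimed at electrophysiologists analysing slow, quasi-stationary
population rhythms (delta-band activity and similar) who want maps of
where energy is generated, where it flows, and where it is lost — without
pairwise statistical connectivity modelling.

## The method

For a potential map `P` on the grid, with tissue conductivity σ, relative
permittivity ε and permeability μ at angular frequency ω:

```
ε̂  = ε + iσ/ω                                complex permittivity
k   = ω √(μ ε̂)                               characteristic wavenumber
k_z = √(k² − k_x² − k_y²)        k_x² + k_y² ≤ |k|²   (far-field)
    = −i √(k_x² + k_y² − k²)     otherwise            (near-field)
G_z = e^(−i k_z z)                            plane-to-plane propagator
K_filter(k_r) = 1 − 0.5 e^((k_r/k_c − 1)/α)   k_r ≤ k_c
              = 0.5 e^((1 − k_r/k_c)/α)       k_r > k_c

E   = ∇P                                      field at the electrodes
E_z = F⁻¹( F(E) · G_z⁻¹ · K_filter )          back-projection (refocusing)
H_z = F⁻¹( K × F(E_z) ),  K = (k_x, k_y, k_z)
S_z = E_z × H_z          ESD = ∇·S_z          D = σ|E_z|²
```

At physiological frequencies nearly every spatial mode is evanescent
(near-field): it decays exponentially with depth but carries the
sub-electrode-pitch detail. Back-projection inverts that decay, and the
k-space filter (`kc`, `alpha`) decides how much of the amplified
evanescent band enters the estimate — the focus-versus-noise trade-off.
Papoulis–Gerchberg band-limited interpolation inserts virtual electrodes
between the real ones (×3 per axis by default) before reconstruction.
All reconstructed magnitudes are in arbitrary units: the array sits inside
a distributed source, so localisation is meaningful, absolute field
strengths are not.

The package also contains a quasi-static forward simulator (oscillating
disc/point sources at known depths, seeded noise) used as ground truth,
and wavelet phase-semblance utilities for comparing reconstructed and
recorded time series.

## Worked example

Two discs of differing radius (0.3 and 0.6 mm) oscillate at 1.5 Hz,
0.15 mm below a 10 × 10 array; their projected potentials are recorded for
20 s with 10 % white noise, and the energy source density is reconstructed
at the true depth:

```r
library(neholo)

rec   <- fixture_fig1b_like(same_depth = TRUE)   # seeded synthetic recording
P     <- band_phasor(rec, freq = 1.5)            # complex 1.5 Hz phasor map
recon <- neh_reconstruct(P, rec$medium, z = 0.15)
esd   <- cycle_energy_map(recon)                 # cycle-averaged |ESD|
locate_esd_sources(esd)
#>          x        y     peak n_nodes
#> 2 2.774070 2.731666 2.573298      16
#> 1 1.223401 1.220525 2.473775       8
```

The two clusters sit at (1.22, 1.22) and (2.77, 2.73) mm — within a
thirtieth of a millimetre and 0.08 mm of the true centres (1.2, 1.2) and
(2.8, 2.8), i.e. well inside one fine-grid pixel (0.133 mm), even though
the raw electrode pitch is 0.4 mm. Region-averaged flow vectors
(magnitude and angle of the in-plane Poynting mean) summarise directional
interactions between named areas:

```r
region_vectors(recon$Sz, list(deep        = list(x = c(1, 14),  y = c(1, 28)),
                              superficial = list(x = c(15, 28), y = c(1, 28))))
#>        region    mean_x    mean_y magnitude  angle
#> 1        deep -0.000254  0.000376  0.000454  2.166
#> 2 superficial  0.001081 -0.000188  0.001098 -0.173
```

Reconstructing 0.15 mm away from the true depth lowers the
source-to-background contrast on both sides — the defocusing behaviour
that is used to pick `z` and the filter parameters in practice.

A thin command-line front end is installed at
`system.file("cli", "neholo.R", package = "neholo")` with `simulate`,
`reconstruct` and `validate` subcommands operating on CSV-directory
recordings with a YAML sidecar.

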