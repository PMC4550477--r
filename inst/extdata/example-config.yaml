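# Example analysis configuration: 10 x 10 array at 0.4 mm pitch over two
# cortical layer bands. Tissue property values are placeholders on the
# scale reported for grey matter; set them from your own measurements.
grid: {nx: 10, ny: 10, pitch_mm: 0.4}
layers:
  - {x_from_mm: -0.2, x_to_mm: 1.8, sigma_S_per_m: 0.25, eps_rel: 1.0e5, mu_rel: 1.0}
  - {x_from_mm: 1.8, x_to_mm: 3.8, sigma_S_per_m: 0.35, eps_rel: 1.0e5, mu_rel: 1.0}
anisotropy_ratio: 1.0
reconstruction: {z_mm: 0.1, alpha: 0.2, pad_factor: 2, upsample_factor: 3}
superresolution: {factor: 3, band_limit_frac: 1.0, max_iter: 500, tol: 1.0e-8}
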