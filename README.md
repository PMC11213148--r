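# qldenoise

Automatic denoising of single-channel images by quantum-localization
filtering in a signal-adapted eigenbasis.

Photon-limited images — nuclear-medicine projections, low-dose CT, any
count-starved acquisition — carry Poisson noise that obscures structure.
qldenoise treats such an image as a disordered quantum system: the pixel
intensities define the potential of a discrete Schrödinger operator

```
H = diag(x) + c·L,      c = ħ²/2m,
```

with `L` the 5-point grid Laplacian (zero padding) and the Planck constant
estimated a priori from the image itself, `ħ = Σᵢ (xᵢ/max x)² / (N/2)`.
The orthonormal eigenmodes of `H` form an adaptive basis, and each mode is
scored by its participation ratio

```
Pₙ = (Σᵢ e²ᵢₙ)² / Σᵢ e⁴ᵢₙ,      pₙ = Pₙ / N_pixels ∈ (0, 1],
```

the effective number of pixels it occupies — the same diagnostic that
separates localized from extended vibrational modes in amorphous solids.
Delocalized mid-spectrum modes behave like diffusons and carry the
background noise; the image structure lives in the comparatively localized
modes at the spectral edges. A Lorentzian fitted to the distribution of
`pₙ` yields a participation threshold `p* = λ₀ − Γ` and, from it, low/high
eigenvalue bands of retained modes. The image is rebuilt from those bands
alone — typically ~20% of the modes — with no tuning parameter anywhere in
the pipeline.

The package provides the full pipeline (`denoise()`), the individual stages
(`estimate_planck()`, `build_hamiltonian()`, `decompose()`,
`participation_ratio()`, `pr_histogram()`, `fit_lorentzian()`,
`select_modes()`, `reconstruct_subspace()`), a piecewise-constant phantom
generator and Poisson noise calibrated to a target SNR (`make_phantom()`,
`add_poisson_noise()`), PSNR/SSIM quality metrics, benchmarking harnesses
(`benchmark_sweep()`, `alpha_sweep()`), broom-style `tidy()`/`glance()`
methods, ggplot2 `autoplot()` methods, and a command-line interface
(`inst/cli/qldenoise`).

## Worked example

```r
library(qldenoise)

clean <- make_phantom(phantom_spec(seed = 1))        # 64x64 count phantom
noisy <- add_poisson_noise(clean, target_snr_db = 15, seed = 1)
noisy$spec$achieved_snr_db
#> [1] 14.89412

result <- denoise(noisy$noisy, reference = clean)
result
#> Quantum-localization denoising of a 64 x 64 image
#>   hbar = 2.135522
#>   p* = 0.2569944 ; kept 773 of 4096 modes (compression 0.8113 )
#>   vs reference: PSNR 31.51 dB, SSIM 0.9116
```

Reading the output: the Planck constant 2.14 was estimated from the noisy
image (no user input); the Lorentzian fit to the participation-ratio
histogram put the delocalized peak at λ₀ ≈ 0.27 with HWHM Γ ≈ 0.017, so
modes smoother than p\* ≈ 0.26 — 81% of the spectrum, the noise-carrying
mid-band — were discarded. The 773 retained spectral-edge modes reconstruct
the image at PSNR 31.5 dB / SSIM 0.91 against the clean reference, within a
few hundredths of the noisy input's own fidelity at a fifth of the modes.
Denoising a clean phantom the same way is nearly lossless (SSIM ≈ 0.998):
the discarded band carries essentially no image content.

Diagnostics chain naturally:

```r
glance(result)                      # one-row tibble of fit + selection
tidy(result)                        # per-mode table with keep flags
autoplot(result$spectrum, selection = result$selection)
autoplot(result$histogram, fit = result$fit)
```

The same pipeline from a shell:

```sh
inst/cli/qldenoise phantom --size 64 --seed 1 --out clean.csv
inst/cli/qldenoise noise   --in clean.csv --snr 15 --seed 1 --out noisy.csv
inst/cli/qldenoise denoise --in noisy.csv --reference clean.csv \
    --out denoised.csv --summary run.txt
```

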