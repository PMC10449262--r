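# octoprops

Joint depth-resolved estimation of the optical attenuation coefficient
μ(z) and the backscattering fraction R(z) from OCT A-scan intensity,
for researchers doing quantitative tissue characterization and
attenuation-compensated OCT imaging.

OCT intensity confounds three depth profiles.  Within the
single-scattering model the irradiance decays as
`L(z) = L(0) exp(-2 ∫₀ᶻ μ(u) du)` and the detected linear intensity is

    I(z) = 2 β R(z) μ(z) L(z),

so the classical depth-resolved estimator
`μ₀(z) = I(z) / (2 ∫_z^∞ I(u) du)` — exact for constant R — is biased
wherever the backscattering fraction steps between layers.  The pair
(μ₀, constant mean backscatter) reproduces any intensity profile
exactly, so the joint inversion is non-unique until structure is
imposed.  `octoprops` resolves it with a constrained stationary
iteration: each loop re-segments the backscattering profile by
thresholding its derivative ("fuzzy processing": small variations are
averaged away, large changes retained as breakpoints), re-fits each
segment's attenuation from its log-slope and its backscattering
fraction by amplitude matching against the remaining irradiance, and
refreshes the depth-resolved μ by applying the baseline estimator to
I/R.  Constraints on R's range and spread, a clamp on μ/μ₀, a loop cap
and a relative-change tolerance guard the loop.  From the recovered
profiles, `I_D(z) = 2 R(z) μ(z) βL(0)` re-renders the image free of
accumulated attenuation loss.

The package also provides everything needed to validate the estimator
without external data: a closed-form single-scattering A-line simulator
for layered phantoms, a Monte Carlo photon-transport engine (weighted
packets, Henyey–Greenstein scattering, Fresnel boundaries, Russian
roulette, coherence-gated A-line synthesis) with a bundled 13-layer
retinal scene, axial-PSF calibration by exhaustive search, noise-floor
fitting with exponential tail extrapolation, and phase-function
utilities (backscattering fraction over the collection cone, anisotropy
as the mean scattering cosine).

## Worked example

The bundled four-layer digital phantom has per-layer backscattering
fractions 0.005 / 0.007 / 0.006 / 0.004 (0.5 mm top layers, surface at
0.125 mm, 1 µm axial pitch) and attenuation 1 / 2 / 3 / 1.5 mm⁻¹:

```r
library(octoprops)
ph    <- phantom_two()
aline <- simulate_aline(ph)              # noise-free A-line, analytic tail
state <- solve_aline(aline, ph$beta_L0)  # constrained joint iteration
state
#> <iteration_state> k = 10 (max_loops), 16 segment(s), R_tilde = 0.005684

round(layer_means(state$R,  ph, aline$grid, max_depth = 2.5), 5)
#> 0.00499 0.00697 0.00600 0.00406
round(layer_means(state$mu, ph, aline$grid, max_depth = 2.5), 3)
#> 1.001 2.004 3.000 1.500
```

The per-layer means of the recovered backscattering fraction land
within ~1% of the generating values, and the attenuation within ~0.2% —
while the uncorrected baseline `vermeer_mu(aline)` is off by up to 20%
in the upper layers.  `compensate()` then turns the recovered profiles
into a depth-independent plateau per layer, and `run_pipeline()` chains
averaging, PSF correction, floor extrapolation, the solver and
compensation over whole B-scans.  A Monte Carlo end-to-end check runs
with:

```r
sc  <- retina_scene()                        # 13-layer model
sim <- simulate_mc_bscan(sc, 1e5, 20, seed = 1)
```

A thin command-line wrapper for shell use ships in
`inst/cli/octoprops` (subcommands `simulate`, `solve`, `mc`,
`compensate`).

## Documentation

The methods vignette
(`vignettes/joint-attenuation-backscatter.Rmd`) covers the model and
its assumptions, the degeneracy of the naive fixed-point scheme and how
the segmentation prior resolves it, every tunable parameter with units
and defaults, the variance-reduction design of the Monte Carlo
detector, numerical conventions, and known limitations.
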