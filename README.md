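# cestkit

Chemical exchange saturation transfer (CEST) MRI experiments, fully in
silico. The package covers the three stages of a CEST experiment —
**preparation** (building and serializing pre-saturation pulse trains),
**simulation** (multi-pool Bloch–McConnell integration of the saturation
block), and **evaluation** (Z-spectra, MTR asymmetry, WASABI B0/B1 field
fits, parametric maps) — plus a synthetic five-tube digital phantom so that
every analysis can be run end to end without scanner data.

It is aimed at CEST methods developers who want to prototype saturation
protocols, test evaluation pipelines, or generate controlled training /
validation data before going anywhere near a scanner.

## The model

Each voxel is a set of exchanging proton pools: water (fraction
$f_w = 1$), $N$ dilute CEST pools with fractions $f_i$, relaxation times
$T_{1i}, T_{2i}$, exchange rates $k_i$ and chemical shifts $\delta_i$
(ppm), and optionally a semisolid magnetization transfer (MT) pool tracked
by its longitudinal component only. During a constant RF segment with
amplitude $\omega_1 = \gamma B_1$ and offset $\Delta\omega$, the
magnetization obeys the Bloch–McConnell equations

$$\frac{d\mathbf{M}}{dt} = A\,\mathbf{M} + C,$$

where $A$ couples relaxation, rotating-frame precession at
$(\delta_i + \Delta B_0)\,\omega_0 \cdot 10^{-6} - \Delta\omega$, RF nutation, and
exchange with detailed balance ($k_{w \to i} = k_i f_i$); the MT pool is
saturated at the rate $R_{\mathrm{rf,mt}} = \pi \omega_1^2 g(\Delta\omega)$
with a Lorentzian absorption lineshape $g$. Shaped pulses are approximated
piecewise-constant and each segment is advanced *exactly* by the matrix
exponential of the affine augmentation of $(A, C)$ (scaling-and-squaring
Padé). A Z-spectrum is the crushed water longitudinal signal normalized to
the unsaturated scan, $Z(\Delta\omega) = S_\mathrm{sat}(\Delta\omega)/S_0$,
and the asymmetry curve is
$\mathrm{MTR_{asym}}(\Delta\omega) = Z(-\Delta\omega) - Z(+\Delta\omega)$.

WASABI field mapping fits the off-resonant Rabi model

$$Z(\Delta\omega) = \left| c - d\,\frac{\omega_1^2}{\omega_\mathrm{eff}^2}
\sin^2\!\left(\frac{\omega_\mathrm{eff}\,t_p}{2}\right) \right|,
\qquad \omega_\mathrm{eff}^2 = \omega_1^2 + (\Delta\omega - \delta)^2,$$

returning the absolute $B_1$ and the water-frequency shift
$\delta = \Delta B_0$ per voxel.

## Worked example

```r
library(cestkit)

seq <- buildAPTw3T()          # 36 sinc-Gauss pulses, B1rms 2 uT
timingSummary(seq@train)
#> TimingSummary: t_sat 1.975 s, duty cycle 90.91%

env <- larginineEnvironment(20)   # 20 mM L-arginine, k = 350 Hz, +3 ppm
z <- simulateZspectrum(seq, env)
z
#> ZSpectrum: 33 offsets [-4, 4] ppm, Z range [0.05945, 0.9824]

asym <- mtrAsym(z)
max(values(asym))                             # 0.0449
offsets(asym)[which.max(values(asym))]        # 2.5
```

The Z-spectrum dips to 0.059 at 0 ppm (direct water saturation) and the
asymmetry curve rises to about 4.5% on a broad peak produced by the
guanidinium pool: exchange broadening and spillover at 2 µT place the
curve's maximum slightly below the 3 ppm pool resonance (see the methods
vignette for the analysis).

Field mapping with WASABI, simulating a voxel with a 0.1 ppm B0 shift and
5% low B1:

```r
envShifted <- larginineEnvironment(20)
envShifted@db0 <- 0.1
envShifted@relB1 <- 0.95
wasabiFit(simulateZspectrum(buildWASABI(), envShifted))
#> WasabiFit: B1 3.513 uT, dB0 0.1 ppm, c 0.996, d 1.98, RMS residual 0.00343
```

The fit recovers 3.513 µT against the ground truth 3.7 × 0.95 = 3.515 µT
and the 0.1 ppm shift essentially exactly. Comparing a sequence across
environments:

```r
wm <- loadEnvironment(system.file("extdata", "wm_3t_synthetic_bmsim.yaml",
                                  package = "cestkit"))
compareEnvironments(buildAPTw3T(),
                    list(larginine_20mM = larginineEnvironment(20),
                         white_matter = wm))
#>      environment argmax_ppm    max_asym
#> 1 larginine_20mM        2.5 0.044879797
#> 2   white_matter        2.0 0.003345839
```

The five-tube phantom pipeline (`makeDigitalPhantom()`,
`simulateStack()`, `parametricMap()`) turns these pieces into voxelwise
MTRasym, B0 and B1 maps; `runPipeline()` drives the whole chain from one
yaml config, and `inst/scripts/cestkit` exposes it on the command line.

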