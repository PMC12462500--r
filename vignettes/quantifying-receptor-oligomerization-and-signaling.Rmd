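---
title: "Quantifying receptor oligomerization, mobility and signaling with receptorQuant"
author: "receptorQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor oligomerization, mobility and signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptorQuant)
```

# Scope and models

receptorQuant implements the quantitative core of a single-cell and
plate-reader workflow for studying how an accessory protein (such as MRAP2)
reshapes the oligomeric state, mobility, trafficking and pharmacology of a
G-protein-coupled receptor (such as the melanocortin-4 receptor, MC4R). The
package contains five analysis engines and one synthetic-data engine; this
vignette states the model behind each, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do not
demonstrate about real data.

## Molecular brightness and oligomerization fingerprints

For photon-counting detectors, pixel counts are Poisson draws around the
local emitter intensity, so shot noise contributes a variance equal to the
mean. Pooling ROI pixels, the molecular brightness is

$$\varepsilon = \frac{\mathrm{Var}(k)}{\langle k \rangle} - 1
\quad\text{(counts entity}^{-1}\text{ dwell}^{-1}\text{)},$$

and the number of particles per beam area is $\langle k\rangle /
\varepsilon$. Brightness scales with stoichiometry: a dimer carrying two
protomers of brightness $\varepsilon_1$ fingerprints at $2\varepsilon_1$. A
mixture of species with particle fractions $f_i$ and stoichiometries $s_i$
(equal per-protomer brightness) appears at

$$\frac{\varepsilon_\mathrm{app}}{\varepsilon_1}
= \frac{\sum_i f_i s_i^2}{\sum_i f_i s_i},$$

because brighter entities weight the variance by their own photon
contribution (`mixtureApparentBrightness()`). A 7:6 dimer:monomer particle
mixture gives $34/20 = 1.7$, the fingerprint of a receptor population
averaging on an approximately dimeric condition; ratios are always reported
against a monomeric reference construct measured under identical settings
(`brightnessRatio()`).

Two estimators are provided. The default is the moment estimator above: it
is assumption-light, unbiased on single populations, and fast. The second,
`histogramBrightness()`, is a spatial-intensity-distribution (SpIDA-style)
fit of the full pixel histogram: particle numbers per beam area are Poisson,
emission is weighted by the 2D Gaussian beam profile on the pixel lattice,
detection is Poisson, and the resulting compound distribution is evaluated
through its characteristic function and fitted by multinomial maximum
likelihood. The moment method is the default because it has an unambiguous,
testable expectation for a single population while the histogram fit depends
on the assumed PSF; the two agree within 10% on single-population
simulations, which is itself a tested invariant.

**Brightness convention.** The per-protomer brightness parameter of the
generator is defined in the same shot-noise-referenced scale the moment
estimator reports: for a 2D Gaussian beam the shape factor
$\gamma = \int w^2 / \int w = 1/2$ is folded into the brightness, i.e. an
emitter of brightness $\varepsilon$ has peak emission $2\varepsilon$ counts
per dwell. This is the usual practice in number-and-brightness work and
makes generator truth and estimate directly comparable; monomer-referenced
ratios are independent of the convention.

ROI handling follows the practice of avoiding regions of uneven
fluorescence: polygons use the center-in rule, at least 50 pixels are
required, and ROIs whose 8×8-pixel block means vary by more than 20% CV are
rejected (`maxBlockCV`, tunable). Brightness is emitted per ROI; per-cell
aggregation, when wanted, is a plain mean of the per-ROI estimates — the
acquisition practice behind such data images several ROIs per cell and
reports per-cell means, so both levels are accessible.

## Line-scan STICS and two-color cross-correlation

A kymograph records a repeatedly scanned confocal line: 256 pixels of 50 nm
at 1800 Hz in the reference acquisition (all configurable). After segment
exclusion and detrending, the spatiotemporal correlation

$$G(\xi, \tau) = \frac{\langle \delta I_a(x, t)\,
\delta I_b(x + \xi, t + \tau)\rangle}{\langle I_a\rangle\langle
I_b\rangle}$$

is computed by FFT over both axes and binned logarithmically in $\tau$
(geometric edges, 16 bins/decade by default, equal weight per integer lag
within a bin, first bin one line period). Binning averages the normalized
correlation; normalizing first keeps blocks with different mean intensities
commensurable when their surfaces are averaged. The surface decays
temporally and broadens spatially — free 2D diffusion through a Gaussian
beam of $1/e^2$ waist $\omega_0$ gives

$$G(\xi, \tau) = G_0\left(1 + \tau/\tau_d\right)^{-1}
\exp\!\left(-\frac{\xi^2}{\omega_0^2 + 4 D \tau}\right),
\qquad \tau_d = \frac{\omega_0^2}{4D},$$

which `fitDiffusion()` fits with $\omega_0$ fixed at a calibrated value
(default 250 nm; fitting it is available behind `fitWaist = TRUE` but is
poorly constrained by typical data). The functional form is the standard
Gaussian-beam 2D-diffusion autocorrelation; its exactness on analytic
surfaces and its recovery of generator ground truth (bias below 10%, CV
below 20% at 100,000 lines over a 0.02–0.2 µm²/s decade) are both tested.

Numerical choices: the $\xi = \tau = 0$ shot-noise spike is excluded from
all fits — temporal bins start at one line period, which removes it, a
standard fluctuation-spectroscopy practice. Detrending follows the
count-addition scheme: lines are grouped into bins (typically 10,000), and
unit counts are added at uniformly random locations of each bin until its
mean matches the maximum bin mean to within one count per bin. Addition
(never subtraction) preserves the integer Poisson character; added counts
are white and therefore correlate only at zero lag, which the fits exclude.
Excluded line/pixel segments split the kymograph into contiguous blocks that
are processed independently and averaged with line-count weights.

Co-diffusion of a two-color pair is summarized by the amplitude ratio at
zero spatial lag and the first temporal bin,

$$q = \frac{G_{AB}(0, \tau_1)}{\min\big(G_{AA}(0, \tau_1),
G_{BB}(0, \tau_1)\big)},$$

which is near 0 for independent channels and near 1 for full co-labeling,
and is monotone in the co-labeled fraction. The underlying data only
supports a qualitative co-diffusion statement; the ratio definition is this
package's choice of a standard FCCS-style summary, and only its anchors and
monotonicity are treated as meaningful.

## Concentration-response fitting and assay normalizations

All plate-reader assays (Epac FRET, ebBRET, Epac-Venus FRET, NanoBiT,
IP-One, NFAT-reporter) share one engine: the three-parameter Hill model

$$y = \mathrm{bottom} + \frac{\mathrm{span}}{1 +
10^{\log_{10}\mathrm{EC}_{50} - \log_{10}[L]}},$$

fit by unweighted least squares with the Hill slope fixed at 1 (a
fixed-slope variant is exposed but never default). Replicates enter jointly
rather than as means, preserving the error structure. Concentrations are
handled in log10 molar; zero-dose (basal) wells are excluded by default
because the downstream normalizations explicitly exclude changes in basal —
they can be mapped to a configurable concentration floor for fitting, and to
a plotting floor only for display. Initialization uses the extreme
concentration means (bottom/span) and the geometric mean concentration
(EC50). Standard errors come from the Jacobian; non-convergence and flat
data return flagged objects, never silent numbers, and an EC50 outside the
tested range is flagged `extrapolated`. `span` is kept signed — a
decreasing raw BRET or FRET curve is physically meaningful — with a
`decreasing` flag, so the normalization equations below can be applied
literally; reoriented (positive-span) presentation is then a display choice.

Derived quantities follow the printed assay arithmetic:

* $\mathrm{pEC}_{50} = -\log_{10}(\mathrm{EC}_{50}\,[\mathrm{M}])$.
* Epac FRET time courses are mapped affinely per well to 0% at baseline and
  100% at the forskolin/IBMX ceiling.
* BRET is acceptor counts over donor counts; the agonist-induced change in
  BRET is $(\mathrm{BRET}_\mathrm{cond} -
  \mathrm{bottom}_\mathrm{cond})/\mathrm{span}_\mathrm{mock} \times 100$.
* $E_\mathrm{max} = \mathrm{span}_\mathrm{cond}/\mathrm{span}_\mathrm{mock}
  \times 100$ — a span ratio, so basal differences never enter. The
  equations commute: fitting normalized data reproduces the raw-fit span
  ratio, a tested invariant.
* Epac-Venus FRET is $485/(485 + 535)$ channel light, baseline-corrected by
  subtracting the fitted bottom asymptote of the same experiment.
* NanoBiT responses divide each reading by the mean of at least three
  stable pre-stimulation reads (absorbing expression and gain differences),
  then integrate the normalized post-stimulation trace by the trapezoid
  rule.

Normalization is applied per individual experiment before any pooling, with
a pooled (global-fit) mode available; per-experiment is the default because
the upstream assay protocols normalize each experiment to its own controls.

## Trafficking and kinetics

Endosome counting uses Laplacian-of-Gaussian blob detection at a scale
matched to the expected spot size, a robust threshold (median +
`thresholdMads` × MAD of the response image, making counts invariant under
detector gain) and greedy non-maximum suppression at a 2σ separation. The
default threshold of 4.5 MADs was calibrated once against the generator's
design operating point: it produces no false positives on blank textured
frames while keeping essentially full sensitivity at the design SNR of 3.
Detection runs per frame within an optional cell mask; cell segmentation
itself is outside the package's scope, so masks come from the fixture
generator or simple thresholding. Pre/post-stimulation comparisons are
reported as paired per-cell counts. Absolute counts from real micrographs
depend on unpublished analysis settings, so only relative (pre/post,
±accessory protein) comparisons should be interpreted; accuracy is
established against synthetic ground truth (precision and recall at least
0.95 at SNR ≥ 3 with spots separated by ≥ 4σ).

Membrane recruitment and loss kinetics use
$y(t) = \mathrm{baseline} + A\,(1 - e^{-k_\mathrm{on}(t - t_\mathrm{stim})})$
with a default 25-frame baseline at 4 s/frame (the reference TIRF
acquisition). Flat traces are flagged `rate_indeterminate` rather than
fitted; a doubling of the generating rate is recovered as a fitted-rate
ratio of 2 within 5%, mirroring the kind of accessory-protein effect the
workflow is designed to resolve.

## Saturation radioligand binding

Ligand concentrations are decay-corrected,
$L = L_0 \cdot 2^{-t/T_{1/2}}$ with $T_{1/2} = 59.39$ d for ¹²⁵I
(configurable). Total and nonspecific wells are fitted globally —
$\mathrm{total}(L) = B_\mathrm{max} L/(K_d + L) + \mathrm{NS}\,L + bg$,
$\mathrm{nonspecific}(L) = \mathrm{NS}\,L + bg$, NS and $bg$ shared — the
behavior of the named one-site total-and-nonspecific procedure, rather than
pre-subtracting nonspecific counts. Free ligand is approximated by added
ligand (no depletion correction). $B_\mathrm{max}$ is reported normalized
to a mock condition, a ratio that is independent of background and detector
gain under the shared-parameter model, which is why the ratio — not raw
$B_\mathrm{max}$ — is the exposed comparison.

# The synthetic-data engine

Every analysis consumes data the package can generate with embedded ground
truth, so all recovery claims are testable offline.

* `simulateConfocalStack()` / `simulateKymograph()`: emitters are placed by
  a 2D spatial Poisson process in a periodic box padded by three beam
  waists (avoiding edge bias), take Brownian steps of per-axis variance
  $2D\Delta t$, and are imaged through a 2D Gaussian beam with pure Poisson
  detection (photon-counting detectors; no analog gain or read noise).
  Line scans sample a fixed row once per line period — at 0.56 ms the
  intra-line motion is far below the beam transit time — and emitters live
  in a ±3-waist band around the line. In two-color mode a configurable
  fraction of channel-A particles carries the channel-B label at identical
  coordinates; the rest of channel B is independent at matched density.
* `simulateDoseResponse()`, `simulateRecruitmentTrace()`,
  `simulateSaturationBinding()`: the exact parametric models above plus
  Gaussian (additive or multiplicative) noise.
* `simulateEndosomeFrames()`: Gaussian spots of configurable SNR (peak in
  background shot-noise SDs) on a textured background, with a guaranteed
  4σ pairwise separation.

Defaults mirror the reference acquisitions: 512×512 px frames and 256 px
lines at 50 nm pixels, 1800 Hz line rate, three-parameter dose-response
tables of 8 concentrations × 3 replicates. Where the source protocols do
not state a value, a realistic one was chosen once and kept: beam waist
250 nm (a placeholder typical of visible-light confocal optics, not a
measured value), particle density 10 µm⁻², per-protomer brightness
0.5 counts/dwell, D = 0.1 µm²/s. Test problem sizes (e.g. 200-frame
512×512 stacks for the oligomer fingerprint, 100,000-line kymographs for
diffusion recovery, 200 simulated tables for fit calibration) are the
package's reproducibility choices.

What the generator deliberately omits — and what passing tests therefore do
not show about real data: vesicular transport and membrane topography,
photobleaching kinetics (only its exclusion/detrend handling is tested),
FRET photophysics, analog detector artifacts, cell-to-cell expression
heterogeneity, and real cell segmentation. Recovery on synthetic data
validates the estimators' arithmetic and statistical behavior, not the
biology of any particular micrograph.

# Worked example

```{r example}
# oligomer fingerprint of a 7:6 dimer:monomer mixture, end to end
mix <- simulateConfocalStack(membraneSimConfig(
    fieldSizePx = c(256L, 256L), nFrames = 40L,
    species = data.frame(stoichiometry = c(2L, 1L), fraction = c(7, 6) / 13,
                         brightness = 0.5),
    particleDensityUm2 = 10, seed = 1))
ref <- simulateConfocalStack(membraneSimConfig(
    fieldSizePx = c(256L, 256L), nFrames = 40L,
    species = data.frame(stoichiometry = 1L, fraction = 1,
                         brightness = 0.5),
    particleDensityUm2 = 10, seed = 2))
roi <- roiRectangle(8, 8, 247, 247)
brightnessRatio(momentBrightness(mix, roi), momentBrightness(ref, roi))
# analytic expectation
mixtureApparentBrightness(c(7, 6) / 13, c(2L, 1L))
```

```{r example-dr}
# potency shift between two conditions
mock <- fitHill3(simulateDoseResponse(doseResponseSimConfig(
    log10EC50Molar = log10(4.5e-9), noiseSd = 2, condition = "mock",
    seed = 3)))
plus <- fitHill3(simulateDoseResponse(doseResponseSimConfig(
    log10EC50Molar = log10(1.3e-9), noiseSd = 2, condition = "plus",
    seed = 4)))
c(mock = pEC50(mock), plus = pEC50(plus))
```

# Known limitations

* The histogram (SpIDA-style) estimator fits a single population; two-state
  fits and bleaching corrections are out of scope.
* The diffusion model assumes free 2D diffusion; flow, anomalous diffusion
  and raster (frame-mode) STICS are not implemented.
* The co-diffusion metric is an amplitude ratio at the first temporal bin;
  it is monotone in, but not an unbiased estimator of, the bound fraction
  under unequal channel densities.
* Hill fits assume a unit slope by design; genuinely cooperative data
  require the fixed-slope variant and an externally chosen slope.
* Binding fits assume no ligand depletion and a linear nonspecific
  component.
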