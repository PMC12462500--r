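# receptorQuant

Quantitative analysis of membrane-receptor oligomerization, mobility,
trafficking and pharmacology from fluorescence data — built for workflows
that ask how an accessory protein (e.g. MRAP2) reshapes the behavior of a
G-protein-coupled receptor (e.g. the melanocortin-4 receptor).

The package bundles five analysis engines behind Bioconductor-style S4
containers, plus a synthetic-data engine that generates every input with
embedded ground truth:

| Engine | Core quantity |
|---|---|
| Molecular brightness (moment + SpIDA-style histogram) | ε = Var(k)/⟨k⟩ − 1; oligomer fingerprint ε/ε₁ = Σfᵢsᵢ²/Σfᵢsᵢ vs a monomeric reference |
| Line-scan STICS / FCCS | G(ξ,τ) = G₀(1+τ/τ_d)⁻¹ exp(−ξ²/(ω₀²+4Dτ)), τ_d = ω₀²/4D; cross-correlation fraction q = G_AB/min(G_AA,G_BB) |
| Dose-response | y = bottom + span/(1+10^(log₁₀EC₅₀−log₁₀[L])); pEC₅₀, Emax = span_cond/span_mock × 100, BRET/FRET/NanoBiT normalizations |
| Trafficking | LoG endosome counts; y(t) = baseline + A(1−e^(−k_on t′)) recruitment kinetics |
| Binding | total(L) = B_max·L/(K_d+L) + NS·L + bg fitted globally with nonspecific wells; ¹²⁵I decay correction |

## Worked example

Simulate a 7:6 dimer:monomer receptor population and a monomeric reference,
then recover the oligomerization fingerprint:

```r
library(receptorQuant)

mix <- simulateConfocalStack(membraneSimConfig(
    fieldSizePx = c(256L, 256L), nFrames = 40L,
    species = data.frame(stoichiometry = c(2L, 1L),
                         fraction = c(7, 6) / 13, brightness = 0.5),
    particleDensityUm2 = 10, seed = 1))
ref <- simulateConfocalStack(membraneSimConfig(
    fieldSizePx = c(256L, 256L), nFrames = 40L,
    species = data.frame(stoichiometry = 1L, fraction = 1,
                         brightness = 0.5),
    particleDensityUm2 = 10, seed = 2))
roi <- roiRectangle(8, 8, 247, 247)

momentBrightness(mix, roi)
#> BrightnessEstimate (moment): epsilon = 0.8305 counts/entity/dwell over 2284840 pixels
#>   number density 1.807 per beam area

brightnessRatio(momentBrightness(mix, roi), momentBrightness(ref, roi))
#> [1] 1.663933
mixtureApparentBrightness(c(7, 6) / 13, c(2L, 1L))
#> [1] 1.7
```

The measured ratio (1.66 at this small demonstration size; 1.70 ± 0.01 at
the full 512×512 × 200-frame scale the acceptance script runs) matches the
analytic mixture fingerprint: a
population with a 7:6 dimer:monomer particle ratio appears 1.7× brighter
than a monomer — the signature of a receptor averaging on an approximately
dimeric state. A dose-response shift reads out the pharmacology side:

```r
mock <- fitHill3(simulateDoseResponse(doseResponseSimConfig(
    log10EC50Molar = log10(4.5e-9), noiseSd = 2, condition = "mock", seed = 3)))
plus <- fitHill3(simulateDoseResponse(doseResponseSimConfig(
    log10EC50Molar = log10(1.3e-9), noiseSd = 2, condition = "plus", seed = 4)))
c(mock = pEC50(mock), plus = pEC50(plus))
#>     mock     plus
#> 8.352916 8.881091
```

pEC₅₀ rises from ~8.35 (EC₅₀ ≈ 4.4 nM) to ~8.88 (EC₅₀ ≈ 1.3 nM): a
leftward potency shift of the kind an accessory protein produces.

A thin command-line wrapper over the same functions is included
(`inst/scripts/pipeline.R`) with subcommands `simulate`, `fit-dr`,
`brightness`, `stics`, `endosomes`, `recruitment`, `binding`; see
`?runPipeline`.

The methods vignette
(`vignettes/quantifying-receptor-oligomerization-and-signaling.Rmd`)
documents the models, parameter defaults, numerical choices and the limits
of what synthetic-data validation shows.

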