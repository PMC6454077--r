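# ctmpi — temporal sampling bias in dynamic CT myocardial perfusion

Dynamic CT myocardial perfusion imaging estimates myocardial blood flow
(MBF, mL/g/min) with the maximum-upslope model

```
MBF = MaxSlope(TAC) / PeakEnhancement(AIF) * 60 / rho
```

where the tissue attenuation curve (TAC) and arterial input function (AIF)
are sampled by the scanner's acquisition scheme. Clinical ECG-triggered
"shuttle" protocols image the analyzed slab only once every 2–3 s, so the
derivative in the numerator and the maximum in the denominator are taken
over a handful of samples of a fast-evolving bolus — and the resulting MBF
is systematically biased low. `ctmpi` is a simulation laboratory for this
effect, aimed at perfusion-imaging researchers: it generates ground-truth
contrast kinetics of an ex-vivo perfused heart (gamma-variate AIF,
one-compartment tissue model with extraction fraction `E` and transfer
constant `K1 = E*F`), samples them with three acquisition schemes —
shuttle (slab revisit every 4th beat), non-shuttle (every beat), continuous
(16 frames/s) — and quantifies the bias of the maximum-upslope estimator and
of Patlak `K1` with the extraction correction `F = K1/E`, across three
phantom hearts, FFR-graded stenosis levels (0.9 … 0.5 and total occlusion in
the circumflex territory) and the AHA 16-segment model. A synthetic 4D
short-axis image phantom (NIfTI) exercises the pipeline end-to-end at the
image level.

Real measurements enter through the same door as simulated ones: any
two-column `time_s,value_hu` CSV (and optional 4D stack + label map) can be
fed to the estimator stage.

## Worked example

```r
library(ctmpi)

aif <- generateAif(aifParameters())    # 60 s scan, injection at 5 s
aif
#> ContrastCurve with 6001 samples over [0, 60] s
#>   values: 40.0 .. 290.0 HU; injection at 5 s

## one segment with true flow F = 2 mL/g/min and extraction E = 0.6
tac <- tissueCurve(aif, tissueKinetics(flowF = 2, extractionE = 0.6))
mbfUpslope(tac, aif)
#> MbfEstimate (UPSLOPE): 0.9567 mL/g/min  [max slope 4.186 HU/s, AIF peak 250 HU]
```

Even with perfect (dense, noise-free) sampling the upslope estimate is
0.96, not 2: the method measures at best `K1 = E*F = 1.2`, further reduced
by washout. The Patlak route recovers `K1` and, with the extraction
correction, the flow:

```r
pk <- patlakK1(tac, aif, fitWindow = "early")
pk
#> MbfEstimate (PATLAK): 1.18 mL/g/min  [K1 1.18 mL/g/min]
flowFromK1(mbfValue(pk), 0.6)
#> [1] 1.966281
```

The full factorial study (3 hearts x 5 analyzed FFR grades x 3 scan modes x
16 segments x 10 replicates, heart rate 107–115 bpm, 10 HU image noise)
shows the temporal-sampling bias directly — the sparser the sampling, the
lower the median MBF over the 1650 analyzed non-ischemic rows per mode,
against a pooled true MBF of 1.90 mL/g/min:

```r
rows <- runExperiment(defaultConfig(), seed = 1)
summarizeMeasurements(rows[rows$method == "UPSLOPE", ], "mode")
#>          mode    n    median        q1        q3 true_flow underestimation_pct
#> 1  CONTINUOUS 1650 1.2363406 1.0784312 1.4016090  1.898736            34.88612
#> 2 NON_SHUTTLE 1650 0.9148701 0.7680074 1.0544036  1.898736            51.81689
#> 3     SHUTTLE 1650 0.7312659 0.6141643 0.8520686  1.898736            61.48670

flowMbfCorrelation(rows)    # estimated MBF tracks the pump input flow
#>          mode         r    n
#> 1  CONTINUOUS 0.6256243 1650
#> 2 NON_SHUTTLE 0.6864891 1650
#> 3     SHUTTLE 0.5589252 1650
```

`modeContrast(rows, "SHUTTLE", "CONTINUOUS")` runs the paired Wilcoxon
signed-rank comparison between two modes. A command-line front end over the
same functions lives in `inst/cli/ctmpi` (`simulate`, `estimate`, `run`,
`summarize`, `phantom` subcommands). The methods vignette
(`vignettes/temporal-sampling-bias.Rmd`) documents the models, defaults and
design decisions.

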