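# lakephoto

Many north-temperate lakes are *browning*: dissolved organic carbon
(DOC) and water colour have been rising for decades as watersheds
recover from acid deposition and hydroclimate shifts. Browner water
absorbs more sunlight, and photoexcited dissolved organic matter (DOM)
transfers that energy to dissolved O₂, producing singlet oxygen (¹O₂) —
a reactive intermediate that degrades micropollutants, pathogens and
DOM itself. `lakephoto` is an R package for scientists who want to
quantify that chain end to end: classify browning from long-term
monitoring records, diagnose which regional drivers DOC co-oscillates
with, derive apparent ¹O₂ quantum yields from probe photolysis
kinetics, model depth-averaged steady-state ¹O₂ concentrations, and
screen contaminants against lake flushing.

At its core is the depth-averaged steady-state model

$$
[{}^1\mathrm{O}_2]_{ss}^{\mathrm{euph}}
 = \frac{\Phi_{app}}{k_d^{\Delta}} \, CF
   \sum_{\lambda=290}^{550}
   \frac{Z_{\lambda}}{z_{\mathrm{euph}}}
   \bigl(1-e^{-K_{d,\lambda} z_{\mathrm{euph}}}\bigr)
   (1-f_{\mathrm{backscatter}})\, f_{\mathrm{abs,CDOM}}
$$

with DOC-driven optical sub-models for the euphotic depth
$z_{\mathrm{euph}}$ and the diffuse attenuation coefficient
$K_{d,\lambda}$, and the apparent quantum yield
$\Phi_{app} = k_{obs}\,k_d^{\Delta}/(k_{rxn,FFA}\,R_a)$ derived from
furfuryl-alcohol probe decays with *p*-nitroanisole/pyridine
actinometry. Around it sit the seasonal Mann–Kendall test with Sen's
slopes and k-means browning classification (clusters A/B/C =
mild/moderate/intense), Morlet wavelet coherence with band aggregation
(3–6, 12–24, 36–72 months), phase classification and surrogate
significance, and `log10(t_half / tau)` contaminant screening. A seeded
synthetic-data module generates every input the pipeline consumes, so
the whole chain is testable without any downloads.

## Worked example

From a probe decay to a contaminant fate screen:

```r
library(lakephoto)
library(dplyr)

field <- light_field()                       # daily-average light field
spec  <- gen_spectrum(a440 = 2.2, s_slope = 0.017)
ra    <- rate_light_absorption(spec, field)  # in-vial absorption, M/s

trace <- gen_kinetics(phi_true = 0.022, ra = ra, noise_cv = 0.02, seed = 42)
k     <- fit_first_order(trace)
qy    <- apparent_quantum_yield(k$k_obs, ra, phi_srnom = 0.0214)
qy
#>   phi_app one_o2_ss_exp         ra phi_ratio_srnom
#> 1  0.0219      7.33e-13 0.00000925            1.02

ss <- steady_state_1o2(qy, field, lake_optical_model(doc = 4.8))
ss
#>   c_euphotic c_near_surface c_epilimnion      ra_vol z_euphotic_cm   doc
#> 1   2.96e-14       4.96e-13           NA 0.000000374          564.   4.8

screen_compounds(gen_compounds(106, seed = 1), ss$c_euphotic,
                 tau_years = 0.8) %>% count(fate_class)
#>   fate_class               n
#> 1 comparable              28
#> 2 faster_than_flushing    71
#> 3 slower                   7
```

The quantum yield recovered from the noisy trace (0.0219) sits within
1 % of the planted 0.022 and at 1.02× the parallel Suwannee River NOM
reference; the depth-averaged euphotic-zone concentration is about 6 %
of the near-surface value (light attenuation costs roughly an order of
magnitude); and at this lake's ¹O₂ level and a 0.8-year residence time,
¹O₂-mediated loss outpaces or keeps up with flushing for 99 of 106
screened compounds.

`run_pipeline(run_config(seed = 1))` chains every stage on a fully
synthetic 37-lake set and returns (optionally writes as CSV) the lake,
trend, cluster, coherence, photochemistry and screening tables plus a
seeded run manifest.

## Documentation

The methods vignette
(`vignettes/singlet-oxygen-browning.Rmd`) documents the models, the
phase and unit conventions, every tunable constant with its default,
what the synthetic generators do and do not emulate, and known
limitations.
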