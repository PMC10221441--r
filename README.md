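# asdphase

Thermodynamic prediction of drug-load-dependent **loss of release (LoR)**
for amorphous solid dispersions (ASDs) dissolving in water.

An ASD holds a poorly soluble drug (API) molecularly dispersed in a glassy
polymer. Above a formulation-specific drug load, release collapses: the
hydrating surface either crystallizes (LoR **Type I**, congruent loss of
API and polymer) or demixes into a glassy API-rich phase that passivates
the interface while the polymer escapes (LoR **Type II**, incongruent
release). `asdphase` predicts which — and at what drug load — from pure
thermodynamics:

* **PC-SAFT** equation of state (hard-chain + dispersion + association
  contributions to the residual Helmholtz energy,
  $a^{res}=a^{hc}+a^{disp}+a^{assoc}$) for activity coefficients in
  API/polymer/water mixtures, with temperature-dependent binary
  interactions $k_{ij}(T)=k_{ij,m}T+k_{ij,b}$ and Wolbach–Sandler cross
  association;
* **solid–liquid equilibrium** for the API solubility line,
  $\ln(x_i\gamma_i) = -\tfrac{\Delta h^{SL}}{RT}(1-\tfrac{T}{T^{SL}})
  -\tfrac{\Delta c_p^{SL}}{R}(\ln\tfrac{T^{SL}}{T}-\tfrac{T^{SL}}{T}+1)$;
* **liquid–liquid equilibrium** (isoactivity) for the binodal, tie lines
  and spinodal of the miscibility gap;
* **Gordon–Taylor / Simha–Boyer** glass-transition modeling and the
  *escape glass transition* (eGT) locus where the hydrating surface's
  $T_g$ equals the medium temperature;
* a **hydration-pathway classifier** that orders the locus crossings along
  the straight dilution path of each drug load and assigns the LoR type.

Packaged parameters (`"dohrn2023"`) cover the published
naproxen/PVPVA64/water and venetoclax/PVPVA64/water systems.

## Worked example

```r
library(asdphase)

params <- loadParameters("dohrn2023")
sysn   <- ternarySystem(params, "naproxen")

# solubility of crystalline naproxen in dry PVPVA64 at 37 C
sp <- sleSolubility(sysn, T = 310.15, P = 1e5, solvent_ratio = Inf)
round(sp$w[1] * 100, 1)
#> [1] 23.1

# where does the 20 wt%-drug-load hydration path cross each locus?
cr <- findCrossings(sysn, T = 310.15, P = 1e5, drug_load = 0.20,
                    loci = c("egt", "solubility"))
cr[, c("locus", "w_water", "Tg_C")]
#>        locus    w_water     Tg_C
#> 1 solubility 0.06513408 42.26874
#> 2        egt 0.07582308 37.00000

classifyLor(cr, crystallization_propensity = "fast")
#> <lor_classification> Type I
#>    eGT at 7.6 wt% water; solubility crossing at 6.5 wt%; no binodal
#>    crossing; crystallization propensity fast
#>   expected: congruent loss (API+polymer)
```

The solubility line is crossed at 6.5 wt% water, *before* the surface
escapes its glass at 7.6 wt% — so this fast-crystallizing API is predicted
to crystallize inside the gel layer and shut down release (Type I). The
threshold drug load for this onset:

```r
lorThresholdDl(sysn, 310.15, 1e5, crystallization_propensity = "fast") * 100
#> [1] 18.48379   # wt% drug load, bisected to 0.1 wt%
```

For the slow-crystallizing venetoclax system the binodal decides instead:

```r
sysv <- ternarySystem(params, "venetoclax")
bc <- binodalCrossing(sysv, 310.15, 1e5, drug_load = 0.025)
round(bc$w_water * 100, 1)          # water at the binodal: 6.5 wt%
round(bc$w_conjugate * 100, 1)      # conjugate phase: 99.8 wt% venetoclax
#> [1] 99.8  0.0  0.2
```

With eGT at ~11.4 wt% water, the 2.5 wt%-DL path demixes well before the
glass releases: LoR Type II, polymer-only release.

`hydrationReport()` assembles the full per-drug-load table (dry, eGT,
solubility, binodal rows with compositions and Tg), `ternaryDiagram()`
computes whole-diagram loci with CSV/JSON export, and
`inst/scripts/asdphase.R` wraps the same functions for shell use.

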