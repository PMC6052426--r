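# vtecea

A Markov cohort cost-effectiveness model of **edoxaban versus warfarin for
the treatment and secondary prevention of venous thromboembolism (VTE)**,
from a UK NHS perspective.

Anticoagulation after a deep vein thrombosis (DVT) or pulmonary embolism
(PE) trades off recurrence prevention against bleeding risk and treatment
burden. Warfarin is nearly free but needs INR monitoring and causes more
bleeds; the factor-Xa inhibitor edoxaban costs more per day, needs no
monitoring, and showed fewer bleeds in the Hokusai-VTE trial. `vtecea` is
for health economists and HTA analysts who want that comparison as a
tested, scriptable pipeline rather than a spreadsheet: a monthly-cycle
cohort model over a lifetime horizon with eight exclusive health states
(on treatment after the index VTE, off treatment, recurrent VTE, on
treatment after recurrence, CRNMB, non-ICH major bleed, ICH, death), three
concomitant long-term states (severe post-thrombotic syndrome, CTEPH,
post-ICH disability), time-stratified treatment-effect odds ratios, and
discounted QALY/cost accounting.

The comparative statistics are the incremental QALYs ΔE and costs ΔC
(edoxaban − warfarin), the ICER ΔC/ΔE with dominance classification, and
the net monetary benefit

```
NMB = ΔE · λ − ΔC ,   λ = willingness-to-pay (£20,000/QALY by default).
```

Around the base case the package provides scenario analyses
(non-significant ORs set to 1; 1-year and 5-year horizons), index-event
subgroups (DVT only, PE ± DVT, PE only, PE + DVT), one-way deterministic
sensitivity analysis with tornado plots, and a probabilistic sensitivity
analysis (beta / log-normal / gamma distributions, CE plane, CEAC). A
synthetic Gompertz–Makeham life table stands in for national mortality
tables so everything runs without downloads; `read_life_table()` accepts
an official `age,sex,qx` CSV.

The methods vignette (`vignettes/model-methods.Rmd`) documents the model
structure, every pathway convention, the cost and utility schedules, and
known limitations.

## Worked example

```r
library(vtecea)

params <- load_parameters(base_case_path())   # packaged base-case inputs
res <- run_ce_analysis(params)
res
#> <vte_ce_result> edoxaban vs. warfarin
#>   incremental QALYs 0.0209, incremental costs £-59.1
#>   dominant; NMB at £20,000/QALY: £478
```

Edoxaban is *dominant*: it yields more QALYs (+0.021 discounted over the
cohort's lifetime, driven by fewer intracranial haemorrhages and the
monitoring disutility of warfarin) at lower total cost (−£59 per patient:
the higher drug cost is outweighed by removing INR monitoring, ≈ £312
discounted in the warfarin arm). The per-arm ledger mirrors the usual
results-table layout:

```r
result_table(res)[c(8, 9, 10, 11, 17), ]
#>                       quantity  edoxaban  warfarin
#>        Life years (discounted)   16.0015   15.9842
#>             QALYs (discounted)   12.1320   12.1110
#>  Treatment costs excl. INR (£)  356.2940   86.1676
#>             INR monitoring (£)    0.0000  311.7613
#>                Total costs (£) 7771.7774 7830.8777
```

Everything chains with the pipe and has `tidy()` / `glance()` /
`autoplot()` methods:

```r
run_experiments(params)                          # base + scenarios + subgroups
one_way_dsa(params) |> autoplot()                # tornado diagram
run_psa(params, n = 2000, seed = 1) |> autoplot()  # CE plane
run_psa(params, n = 2000, seed = 1) |> ceac() |> autoplot()
```

A thin command-line launcher is installed at `inst/scripts/vtecea`
(`fixture`, `run`, `dsa`, `psa`, `report` subcommands).

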