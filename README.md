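# apaptox

A whole-body physiologically based pharmacokinetic (PBPK) model of
acetaminophen (APAP) disposition and hepatotoxicity in an average 70 kg
adult, for pharmacologists and toxicologists who want to simulate how dosing
patterns and lifestyle factors — chronic APAP use, binge drinking,
fasting/malnutrition — change the risk of drug-induced liver injury.

## The model

Fourteen well-stirred compartments (twelve perfused tissues plus arterial
and venous blood) are connected by blood flow, each obeying a
perfusion-limited mass balance

    V dC/dt = Q (C_in − C/(Kp·BP)) − R_out

with the lung in series at cardiac output and an explicit portal topology
(gut and spleen drain into the liver; the hepatic artery carries
Q_liver − Q_gut − Q_spleen = 390 mL/min). The kidney removes a fixed
fraction E = 0.02 of the arterial concentration entering it; the liver runs
three saturable Michaelis–Menten pathways — glucuronidation, sulfation, and
CYP-mediated oxidation to the reactive metabolite NAPQI. NAPQI never leaves
the liver: it is detoxified by bimolecular conjugation with glutathione
(GSH), whose pool regenerates in proportion to its deficit from normal,

    d[GSH]/dt   = m(t)·k_gen·([GSH]_N − [GSH]) − k_II·[NAPQI]·[GSH]
    d[NAPQI]/dt = v_ox/V_liver − k_II·[NAPQI]·[GSH],

and liver injury is flagged when [GSH] falls below 30% of normal. The
normal concentration [GSH]_N is fixed by a calibration anchor: a single
15 g oral dose depletes the pool by 70% at its minimum (calibrated value
5.070 mmol/L). Lifestyle scenarios act as continuous piecewise-linear
multipliers on pathway capacities and on GSH regeneration. The stiff
coupled system is integrated with `deSolve` (lsoda), with bolus doses as
event discontinuities.

See `vignettes/apap-pbpk-model.Rmd` for the full account of the science,
parameters and numerical choices.

## A worked example

A chronic APAP user (2 g every 6 hours for 5 days) who has just come off a
binge: CYP2E1 starts 2.14-fold induced and decays back over 5 days, the GSH
pool starts halved and its regeneration recovers over 24 h, while chronic
intake ramps glucuronidation up and sulfation down over 3 days.

```r
library(apaptox)
sim <- simulate_apap(apap_regimen(2, 360, 20, "oral"),
                     combined_chronic_alcohol(2), t_end = 7200)
assess_toxicity(sim)
#> Minimum liver GSH: 23.4% of normal at t = 498 min
#> TOXIC: crosses the 30% threshold at t = 387 min (0.27 days)
route_fractions(sim)
#> Route fractions of absorbed dose: glucuronide 0.587, sulfate 0.064,
#>   oxidized 0.294, renal 0.050, residual 0.004
```

The supra-therapeutic regimen crosses the injury threshold about six and a
half hours after drinking stops — inside the most dangerous 12–18 h window —
whereas the same simulation at the therapeutic 1 g dose stays non-toxic
(minimum 42.8% of normal). The route fractions show where the absorbed dose
went: most was conjugated to the harmless glucuronide, the alcohol-induced
oxidation pathway consumed a large GSH-demanding share, and a small residual
was still in the body at the end of the run.

The same experiments are available as named fixtures
(`run_config(generate_fixture("combined"))`) and from the shell:

```sh
inst/cli/apap-pbpk simulate --dose-g 2 --n-doses 20 \
    --scenario chronic+alcohol --t-end 7200 \
    --out-csv run.csv --out-json run.json
inst/cli/apap-pbpk metrics --in-csv run.csv
```

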