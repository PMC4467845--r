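# seadose

Radiological dose and heavy-metal intake assessment from seafood
consumption.

Marine fish are a dominant protein source for coastal populations, and
they bioaccumulate both naturally occurring radionuclides (the ²²⁶Ra and
²³²Th decay chains, and ⁴⁰K) and trace metals from their environment.
`seadose` implements the complete measurement-to-risk chain used in
dietary surveillance of such foodstuff:

* **Gamma-spectrometry quantification.** ²²⁶Ra and ²³²Th are quantified
  through their short-lived progeny under secular equilibrium. For a net
  peak area *N* of a line with emission intensity *P*γ and chain branch
  *b*, counted for live time *t* on a sample of dry mass *m* with
  full-energy-peak efficiency *ε(E)*,

  *A* = *N* / (*t* · *ε(E)* · *P*γ · *b* · *m*)  [Bq/kg dry weight].

  The efficiency curve is a least-squares polynomial of ln *ε* in ln *E*;
  per-line activities are combined per parent chain by inverse-variance
  weighting; relative uncertainties (counting statistics, efficiency ~4%,
  mass ~1.5%, intensity ~1%) add in quadrature; detection capability is
  screened with the Currie 95% minimum detectable activity,
  MDA = (2.71 + 4.65·√*B*) / (*t·ε·P*γ*·m*).

* **Ingestion dose and risk.** With per-capita annual fish consumption
  *A*if (kg/y, derived from landings × consumed fraction / population),
  ingestion dose coefficient *D*cf (Sv/Bq) and mortality risk coefficient
  *R*c (Bq⁻¹) over a lifespan *A*ls:

  *D*int = *A*s · *A*if / 365  [Bq/day],
  *D*eff = *A*s · *A*if · *D*cf  [converted to µSv/y],
  *D*eff,total = Σ chains *D*eff,
  LCR = *D*int · 365 · *A*ls · *R*c.

* **Heavy-metal screening.** Estimated daily intake per kg body weight,
  EDI = *C*metal · *W* / *m*bw (µg/kg bw/day, with *W* the daily fish
  ration in grams), computed from location-mean concentrations with
  non-detects excluded, and screened against a tolerable-daily-intake
  (TDI) registry.

* **Group statistics.** One-way ANOVA from explicit sums of squares and
  Tukey HSD (Tukey–Kramer for unbalanced groups) across sampling
  locations.

* **Synthetic surveys.** A seeded generator reproduces the survey design
  (3 locations × 3 fish + 3 water replicates, Poisson gamma peaks for
  every primary line, metal tables with censoring) so the whole pipeline
  is testable end to end without any external data.

The package ships, under `inst/extdata/`, the activity and trace-element
tables of a survey of Indian mackerel (*Rastrelliger kanagurta*) and
seawater from three coastal locations along the Straits of Malacca
(Bagan Lalang, Port Klang, Pantai Remis), used throughout as the worked
case study. All reference constants (decay data, dose and risk
coefficients, TDI values, consumption parameters) are built in and
overridable through a YAML config.

## Worked example

```r
library(seadose)

bundle <- load_reference_tables()        # built-in defaults
act    <- malacca_activity()             # bundled activity survey

dr    <- dose_risk_table(act, bundle)    # per-sample intake/dose/risk
means <- aggregate_rows(dr, "location")  # location + overall means
overall <- means[means$location == "overall", ]

round(overall$daily_intake_K40_Bq_per_day, 2)
#> [1] 45.29
round(overall$total_dose_uSv_per_y, 1)
#> [1] 226.8

edi <- edi_table(malacca_metals(), bundle)
subset(edi, element == "As",
       select = c(location, edi_ug_per_kg_bw_day, ratio, flag))
#>        location edi_ug_per_kg_bw_day     ratio      flag
#> 12   Port Klang            1.3900095 0.6495372 below_tdi
#> 31 Pantai Remis            0.9896095 0.4624344 below_tdi
#> 49 Bagan Lalang            0.6034786 0.2819993 below_tdi
```

The overall mean daily ⁴⁰K intake from fish is 45.29 Bq/day and the mean
total committed effective dose is ~227 µSv/y — below the ~290 µSv/y
worldwide-average ingestion dose — while every screened metal's
estimated daily intake sits below its tolerable daily intake (arsenic is
the closest, at about 65% of its TDI in Port Klang fish).

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (synthetic survey), `02_activity_from_peaks.R`
(peak areas → activities), `03_dose_risk.R`, `04_metals_edi.R`,
`05_location_stats.R`; each writes its tables under `results/`.

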