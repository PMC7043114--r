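# p2i — deterministic portfolio-to-impact modelling of vaccine pipelines

`p2i` estimates what it would cost to move a portfolio of vaccine candidates
from their current development phase through phase III, and how many product
launches to expect along the way. It is aimed at product development
partnerships, funders and R&D policy analysts who need risk-adjusted,
calendar-year funding forecasts for a pipeline rather than per-trial
budgets. The package ships the 18-candidate portfolio of the European
Vaccine Initiative (EVI) — vaccines for malaria, placental malaria,
leishmaniasis, shigellosis/ETEC, Nipah and Zika — together with the
published per-archetype assumptions, and reproduces the published analysis
of that portfolio end to end.

## The model

Each candidate *i* is classified into an archetype *a* (simple, complex or
unprecedented vaccine) carrying, for each phase *p* ∈ {preclinical, I, II,
III}, a cost *C(a,p)* (US$ millions), a duration *L(a,p)* (years) and a
probability of success *s(a,p)*. A candidate sits at the start of its
current phase *e(i)* on January 1 of the start year and traverses the
remaining phases back to back in continuous time. The model is fully
deterministic:

- **Launch probability**: λᵢ = ∏ₚ₌ₑ₍ᵢ₎..III s(aᵢ,p); "launch" means
  completing phase III. Expected launches are sums of λᵢ.
- **Entry probability**: πᵢ(p) = ∏ₑ₍ᵢ₎≤q<p s(aᵢ,q), the chance the candidate
  ever reaches phase *p*.
- **Risk-adjusted cost**: πᵢ(p)·C(aᵢ,p), accrued uniformly over the phase's
  duration; a calendar year's cost is the rate-weighted overlap of the year
  with each phase interval, truncated at the horizon's end.
- **Launch dating**: the calendar year containing the end of the phase III
  interval (an instant landing exactly on a year boundary counts in the
  earlier year).

Scenario runs replace individual parameter cells (e.g. phase I success for
unprecedented vaccines 0.50 → 0.70); sensitivity analysis multiplies all
success probabilities and/or all costs by a factor such as 0.9 or 1.1.

## Worked example

```r
library(p2i)
res <- aggregate_portfolio(evi_portfolio())
res
#> Portfolio model result (2019-2031)
#>   total cost within horizon: 470.76 US$ millions
#>   expected launches:         0.69
#>   by disease:
#>     malaria                 165.75  0.098
#>     placental malaria        75.12  0.05
#>     Zika                     74.05  0.22
#>     Nipah                    74.05  0.22
#>     shigellosis, ETEC        33.98  0.07
#>     leishmaniasis            47.81  0.024
```

Moving all 18 candidates through the pipeline costs about US$ 471 million
risk-adjusted over 2019–2031 and yields 0.69 expected launches (a value of
1 would mean one launch is certain). The per-disease launch numbers are
closed-form products of the archetype success probabilities — e.g. the
Nipah candidate, a simple vaccine in phase I, launches with probability
0.68 × 0.46 × 0.71 ≈ 0.22. The annual view (`res$annual`) shows the first
launch mass (0.44, the two simple vaccines) arriving in 2025.

The scripted analyses build on the same calls:

```sh
Rscript analysis/01_baseline_run.R        # per-disease and annual tables
Rscript analysis/02_modified_assumptions.R# EVI-internal phase I evidence
Rscript analysis/03_sensitivity.R         # +/-10% one-way and two-way grids
Rscript analysis/04_synthetic_portfolios.R# behaviour across random mixes
```

Each writes its tables under `results/`.

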