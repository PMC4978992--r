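# waxwane

Fossil clades tend to wax and wane: they originate in a small area, spread
and diversify, then decline to extinction. `waxwane` is an R package for
testing one proposed engine of that decline — the steady evolutionary
accumulation of specialised, small-ranged, mutually sympatric species —
directly from fossil occurrence records (Paleobiology Database download
style: species, clade, paleocoordinates, age interval).

The package is aimed at paleobiologists and macroevolution researchers. From
an occurrence table it:

* filters open nomenclature, rare species and stratigraphically
  discontinuous taxa, and picks a clade-specific equal-length time binning
  (every bin must hold ≥ 3 species with ≥ 3 occurrences);
* estimates per-species, per-bin range sizes as minimum-convex-polygon (MCP)
  areas on equal-area projections (Lambert azimuthal / Mollweide / Albers),
  and the clade's union range with an exact convex-polygon union;
* builds the three range curves (total, clade, average) and the **degree of
  sympatry** `s = total / clade range` (1 = disjoint ranges, k = k identical
  ranges);
* compares linear, sigmoid and generalized-logistic growth of the cumulative
  total range by AICc;
* locates trend **shift points** on the net-diversification, cumulative
  total-range, and sympatry curves (piecewise-linear fits, BIC-selected break
  count) and tests their temporal coincidence by a 9,999-draw randomisation;
* tests post-shift directionality: the area test (gap between cumulative
  curves per unit time, post/pre, as a percentage), the average-range slope
  test, a one-sided Mann-Whitney test for net-rate decline, and exact
  binomial summaries across clades;
* infers per-lineage origination/extinction times under a Poisson
  preservation model by MCMC, derives 1-Myr speciation/extinction/net-rate
  timelines, and fits the covariate birth-death model
  `λ(t) = λ₀ exp(γ_λ s_t)`, `μ(t) = μ₀ exp(γ_μ s_t)` linking rates to
  sympatry, flagging correlations whose 95% credible intervals exclude 0;
* simulates whole fossil clades (spatially explicit birth-death with
  heritable range shrinking and sympatry feedback, Poisson preservation) for
  end-to-end calibration.

## Worked example

```r
library(waxwane)

# a synthetic clade with late-phase specialisation, then the full pipeline
case <- end_to_end_case("late-phase-specialisation", seed = 3)
cfg <- run_config(case$occurrences, out_dir = "out", coords = "planar",
                  seed = 7, n_rand = 999)
st <- run_pipeline(cfg)

head(as.data.frame(st$curves)[, c(1:5, 7, 9)], 3)
#>   bin bin_mid_ma richness total_km2 clade_km2 cum_total_km2 sympatry_ratio
#> 1   1   79.99854        2  46965.62  46965.62      46965.62       1.000000
#> 2   2   74.99854        6 491744.66 374936.70     538710.28       1.311540
#> 3   3   69.99854        6 561287.81 494063.15    1099998.09       1.136065

st$trends$best_model
#> [1] "generalized_logistic"

st$shifts$triples
#>   age_net_div age_cum_total age_sympatry mean_age mean_pairwise_distance p_dist
#> 1        28.5      54.99854     49.99854 44.49902               17.66569  0.473

st$covariate$summary
#>      parameter       mean      ci_low   ci_high significant
#> 1      lambda0 0.24951649  0.18356971 0.3179524          NA
#> 2          mu0 0.23341358  0.16906722 0.3089733          NA
#> 3 gamma_lambda 0.04377943 -0.22491086 0.2862018       FALSE
#> 4     gamma_mu 0.22941274  0.01623016 0.4870336        TRUE
```

Reading the output: the curve table gives, per bin, the standing richness
(species with a valid range estimate), the summed species ranges
(`total_km2`), the union range (`clade_km2`), and the running total;
`sympatry_ratio = total/clade`. The cumulative total-range curve is best fit
by a saturating (generalized-logistic) growth model, not a linear one. The
shift triple pairs one shift age per curve with the randomisation p-value
(`p_dist`) that their spread is tighter than chance — here a single,
non-significant triple. The covariate table reports posterior means and 95%
credible intervals for the baseline rates and the sympatry correlations;
`significant` marks intervals excluding zero — here extinction rises
significantly with sympatry (`gamma_mu > 0`), as this scenario builds in.
Every stage also writes a tidy CSV under `out/` together with a
`manifest.json` of checksums, seeds and configuration, and reruns are
byte-identical.

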