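# pandaniche

Ecological niche evaluation of giant panda habitat under labor-force
aging.

Villages around the Sichuan giant panda nature reserves disturb panda
habitat through two livelihood activities: cultivating land at the forest
edge and cutting fuelwood from shrubland. As young laborers migrate out,
the remaining agricultural labor force is aging, and aging households
extract less. `pandaniche` is for conservation ecologists and
socio-ecological modellers who want to quantify that mechanism: it links
a micro-level household resource-utilization decision model to a
macro-level ecological niche evaluation of the villages as habitat
evaluation units, and compares outcomes between old-age-dominated (OAG,
primary laborer ≥ 55 years) and young-adult-dominated (YAG) resource
use.

Because the underlying 538-household questionnaire is unpublished, the
package ships a first-class synthetic survey generator calibrated to the
survey's printed descriptive statistics (truncated-normal and ordinal
variables moment-matched *after* truncation), so the whole analysis is
reproducible from code.

## The model in brief

**Household decisions.** Beliefs update by exponential smoothing,
`Belief' = λP + (1−λ)Belief`. The importance of utilization pattern
`k ∈ {cropland, fuelwood}` is the revenue-weighted share
`UA_k·I_k / Σ_k UA_k·I_k`. The final decision modulates that share by
four factors with normalized salience weights `w_x = a_x/Σa_x`:
`final_k = (Σ_x w_x m_x)·importance_k`, where stronger ecological value
identity, social pressure and environmental constraints suppress
utilization (`m = 1 − score`) and weaker labor literacy does too
(`m = score`). Decisions aggregate to village × age-group intensities.

**Niche evaluation.** Villages × age groups are scored on a 4-dimension,
14-index system (utilization strength, support, constraints, panda
habitat), each index with a *state* (2013 value) and *potential*
(2013–2018 increment) layer combined as `R = S + A·P/T`. Indexes are
weighted by coefficients of variation `V_j = δ_j/|x̄_j|`,
`W_j = V_j/ΣV_j`. The relative niche width of dimension `d` is the
weighted resource share `N_d(i) = Σ_{k∈d} (W_k/w_d)·R_ik/Σ_i R_ik`, the
comprehensive width `M_i = Σ_d N_d(i)·w_d`; widths sum to 1 across
units. Overlap between neighboring villages is the Pianka cosine index
`O_jk = Σ P_ij P_ik / √(Σ P_ij² Σ P_ik²)`, and the OAG/YAG overlap
ratio classifies each pair as a positive (ratio < 1) or negative
(ratio > 1) difference.

See `vignettes/niche-evaluation.Rmd` for the full account, including the
design choices (direction handling, min–max rescaling, degenerate
columns) and what the synthetic data do and do not emulate.

## Worked example

```r
library(pandaniche)

cfg <- scenario_config(seed = 1, aging_effect = 0.3)  # 538 households,
res <- run_all(cfg, out_dir = "run1")                 # 35 villages, 9 reserves
res$comparison
```

```
Old-age vs young-adult group comparison
  communities compared:        35
  OAG comprehensive width higher: 26 (YAG higher: 9)
  neighboring pairs:           26
  overlap differences: 17 positive, 9 negative, 0 undefined
  median OAG/YAG overlap ratio: 0.9792
```

With a 30% mean reduction of resource-use quantities in aging
households, the old-age group's comprehensive niche width exceeds the
young-adult group's in 26 of 35 villages — aging weakens habitat
pressure, raising the habitat-level niche — and the median OAG/YAG
overlap ratio of 0.979 < 1 says aging also relaxes the ecological
competition between neighboring villages. `run1/` receives every
intermediate table (households, decisions, index matrix, weights,
widths, overlaps) plus a manifest with file checksums; re-running with
the same seed reproduces the tables byte-identically.

The top evaluation units for the same run:

```r
w <- res$niche$widths
head(w[order(-w$M), c("community_id", "age_group", "N_X1", "M")], 4)
```

```
   community_id age_group   N_X1      M
11          C06       OAG 0.0189 0.0311
12          C06       YAG 0.0111 0.0307
15          C08       OAG 0.0157 0.0307
9           C05       OAG 0.0165 0.0304
```

Note how the OAG row of each village carries the larger
utilization-strength width `N_X1`.

A thin command-line wrapper with `simulate` / `decide` / `evaluate` /
`run-all` subcommands is installed at `inst/cli/panda_niche.R`.

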