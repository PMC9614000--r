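# halosucc

Community-phylogenetic and plot-ecological analysis of plant succession
on newly emerged saline coastal land.

When a saline water body retreats, the freed land forms a chronosequence:
sites of different ages stand in for successive stages of primary
succession under salt stress. `halosucc` implements the statistical
toolkit for comparing the floras of two such sites — an "early" and a
"late" stage — in terms of the evolutionary relationships and the
ecological traits of the species that persist, disappear, or newly
arrive, and for relating plot-scale vegetation pattern to
microtopography and soil salinity.

## What it computes

**Phylogenetic structure of species turnover.** Species missing from a
dated backbone phylogeny are grafted as basal polytomies within their
genus (or family, when no congener is present); an ultrametric backbone
stays ultrametric and existing patristic distances are untouched. For a
species set *S* on the tree, the mean pairwise distance is

MPD(S) = (2 / n(n−1)) Σ_{i<j} d(s_i, s_j),

with d the patristic distance in millions of years. The observed MPD of
the lost or acquired species is compared with a null distribution of MPD
over uniform random subsets of equal size drawn from a declared species
pool; the left tail p = (#{null ≤ obs} + 1)/(n_perm + 1) measures
phylogenetic clustering.

**Taxonomic distinctness.** The TDI of a community is the mean pairwise
rank-step distance through the genus–family–order hierarchy (congeners
1, confamilials 2, same order 3, different orders 4), so it lies in
[1, 4]; a set of confamilial species in distinct genera scores exactly
2.0.

**Enrichment of loss and gain.** Whether losses concentrate in a family,
whether all gains falling in one family is surprising, and whether an
order is overrepresented among a site's families are exact
hypergeometric tail tests. For gains: with N early-site species of which
K belong to the family, the chance that all n = 4 acquisitions fall
in-family is C(K, 4)/C(N, 4) — for K = 6 of N = 31 this is 4.77 × 10⁻⁴.

**Plot statistics.** Species prevalence (occupancy) by site ×
microtopography stratum; Fisher exact tests of microhigh/microlow
preference with Bonferroni correction; Mann–Whitney comparisons of bare
ground and of electrical conductivity (EC, dS/m); a Spearman screen of
bare ground against EC across the seven auger depth layers; Fisher
tests of desert/halophyte/meadow trait enrichment among persistent vs
lost species; a right-sided Fisher test of nurse-plant association
(e.g. with big tamarisk bushes); and a one-sided Mann–Whitney test of
whether retained species were more prevalent than lost ones (random
extinction would make loss probability track abundance).

**Synthetic data.** A seeded generator produces Yule trees with nested
monophyletic taxonomies, paired succession floras with tunable gain
clustering γ, and plot/soil surveys with per-species microtopography
preferences and EC-coupled bare ground — so every stage of the pipeline
is testable with no field data. A deterministic stand-in bundle
(`caspian_standin()`) mirrors the published summaries of a two-site
Caspian coast study and drives the worked example below.

## Worked example

```r
library(halosucc)
bundle <- caspian_standin()
report <- run_full_analysis(
  taxa = bundle$taxa, plots = bundle$plots, soil = bundle$soil,
  backbone = bundle$backbone$tree,
  backbone_taxonomy = bundle$backbone$taxonomy,
  regional_families = bundle$regional_families,
  n_perm = 10000, seed = 42)
print(report)
```

```
Succession analysis report
  flora: 31 early / 24 late / 20 shared / 11 lost / 4 acquired
  MPD p-left: lost = 0.0033 | acquired = 0.004 
  gain test p = 0.000477 | min family-loss p = 0.0983 
  order overrepresentation p = 0.000424 
  EC screen best layer: 30-50 r = 0.305 
```

The flora summary says the late site kept 20 of the early site's 31
species, lost 11 and gained 4. The gain test p = 0.000477 is the exact
chance that all four acquisitions land in a six-species family when
drawn without replacement from the 31 early species — strong clade
clustering of the newcomers. No family lost more species than chance
predicts (all loss p ≥ 0.098). The Caryophyllales are heavily
overrepresented among the site's families relative to the 42-family
regional pool (p = 0.000424). Bare ground correlates best with the EC of
the 30–50 cm soil layer (Spearman r = 0.305), the layer most root
systems occupy.

```r
report$tdi
#>        group n_species      tdi
#> 1      early        31 3.739785
#> 2       late        24 3.800725
#> 3     shared        20 3.884211
#> 4 only_early        11 3.036364
#> 5  only_late         4 2.000000
```

The four late-only species score TDI = 2.0 — four genera of a single
family — while both full site floras sit near the cross-order maximum
of 4, i.e. overall taxonomic diversity barely changed while its
composition turned over. `write_report(report, "out/")` emits the full
JSON report (schema in `inst/schema/`) plus per-table CSVs.

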