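# injurynet

Bipartite network analysis of serious sports-injury registries.

Injury-surveillance registries record rare, serious injuries as
categorical case reports — player group, injury type, cause of play,
collision site. With only dozens of cases, the informative object is the
cross-tabulation's *structure*: which player groups cluster with which
injuries and causes. `injurynet` turns such registries into bipartite
graphs (group nodes vs category nodes, an edge per observed combination)
and finds their communities by divisive edge-betweenness clustering
(Girvan–Newman), cutting the removal dendrogram at maximum
Newman–Girvan modularity

    Q = sum_c [ L_c / m − (D_c / 2m)² ]

(L_c: edge weight inside community c; D_c: its degree sum; m: total edge
weight), and scores each community's cohesion S — the ratio of its
internal to external ordered-pair connection density — to extract the
central subgroup. Node coordinates come from a seeded, bit-reproducible
Fruchterman–Reingold layout.

The package ships, as plain-text fixtures, the printed tables of a
14-year (2004–2018) Japanese youth-rugby registry of 48 high-school head
injuries and 54 spinal-cord injuries, plus a synthetic registry generator
with planted group-by-category associations and planted-block bipartite
graphs, so the entire pipeline is testable end to end without downloads.
It is aimed at sports-epidemiology and injury-surveillance analysts who
want reproducible, scriptable community analyses of small categorical
registries.

## Worked example

The registry's acute-subdural-hematoma (ASH) cases by cause play and
player group (`16E1` = 16-year-olds in their first year of rugby, `16EM`
= 16-year-olds with many years of experience, ...):

```r
library(injurynet)

tab <- group_table_variant(fixture_table("table2_ash_causes"), "separate")
g   <- from_crosstab(tab, weight_mode = "binary")
g
#> <bipartite_graph> 7 + 6 nodes (cause_site x group), 15 edges

bp <- best_partition(g)          # Girvan-Newman + max-Q cut
round(bp$Q, 4)
#> [1] 0.3711
bp$membership
#> OTHG  THG  THB    C    R    S    O 16E1 17E2 18E3 16EM 17EM 18EM
#>    1    2    2    2    3    1    4    2    4    1    2    1    3
```

The maximum-modularity cut (Q = 0.3711, matching the published value of
0.37 for this figure) puts both 16-year-old groups (`16E1`, `16EM`) in
one community with the own-tackle causes (`THG` tackle-and-head-to-
ground, `THB` tackle-and-head-to-body, `C` other collisions) — the young
tackle cluster this registry is known for — while oppose-tackle-to-ground
(`OTHG`) groups with saving and the experienced 17-year-olds.
Community 3 is `{R, 18EM}`, an isolated ruck pair, which is why the
central-subgroup report flags its cohesion as infinite
(`central_subgroup(g, bp)$infinite_s`) rather than pretending it is a
dense core.

Descriptive proportions recompute the registry's headline figures from
the fixtures (counts, unrounded fractions, half-up percents):

```r
published_descriptives()
#>                   quantity count total  fraction percent
#> 1       inexperienced_head    35    48 0.7291667      73
#> 2      inexperienced_spine    43    54 0.7962963      80
#> 3        inexperienced_ash    22    28 0.7857143      79
#> 4 tackle_share_head_causes    40    48 0.8333333      83
#> 5   high_school_head_share    48   117 0.4102564      41
#> 6  high_school_start_share 14225 24918 0.5708725      57
```

`run_pipeline(analysis_presets()$fig3_ash_causes, out_dir = "out")` runs
the whole chain (table → graph → clustering → subgroup → layout) and
writes deterministic JSON/TSV/GraphML/CSV artifacts; reruns are
byte-identical. A thin command-line front-end lives at
`inst/scripts/inet.R` (`run`, `fixtures`, `synth`).

Note the source tables are not perfectly self-consistent (three printed
margins disagree with their cells); `table_consistency()` lists the
discrepancies and `proportion_summary(..., margins = "printed")`
reproduces the published arithmetic where it relies on the printed
totals. See the vignette (`vignettes/injury-networks.Rmd`) for the
method, the construction variants, and these caveats in detail.

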