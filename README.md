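# lbcc

Ranking essential proteins in protein–protein interaction (PPI) networks.

Essential proteins — those whose single deletion is lethal — are prime drug
targets and the backbone of minimal-genome reasoning, but knockout screens
are slow. In curated interactomes, essential proteins sit in unusually
dense neighbourhoods, lie on many shortest paths, and congregate in
annotated protein complexes. `lbcc` turns those regularities into a
ranking score,

```
LBCC(v) = a·log Den1(v) + b·log Den2(v) + c·log IDC(v) + d·log BC(v)
```

where `Den1(v)` and `Den2(v)` are the edge densities of the subgraphs
induced by `v`'s closed neighbourhood and its closed radius-2 ball, `BC`
is unnormalized betweenness centrality, and `IDC(v)` sums `v`'s PPI degree
restricted to each complex containing it (floor 0.001 for proteins outside
every complex; the same floor guards every logarithm). Default weights are
`(a, b, c, d) = (1, 4, 3, 1)`.

The package also provides the six standard baseline centralities (DC, BC,
SC, EC, LAC, NC) plus the local clustering coefficient, readers for
plain-text edge lists / essential-protein lists / complex collections, a
seeded synthetic benchmark generator, and the full evaluation protocol for
gene-ranking methods: top-k true-essential counts, the six confusion
statistics at a top-20% cutoff, precision–recall and jackknife curves, and
pairwise method-difference analysis. See the vignette
(`vignettes/lbcc-methods.Rmd`) for the model and all numerical
conventions.

## Worked example

Score a synthetic 100-protein benchmark (5 planted modules of 12 proteins
on a 40-node sparse background, with complexes planted inside modules) and
evaluate the ranking against the planted essential labels:

```r
library(lbcc)

fix <- generate_fixture(fixture_spec(seed = 7L))
ranking <- rank_proteins(lbcc_score(fix$network, fix$complexes))
head(ranking, 5)
#>   protein    score
#> 1  M02P06 3.677433
#> 2  M03P08 3.468048
#> 3  M02P04 2.872273
#> 4  M03P01 2.796241
#> 5  M03P05 2.702770

res <- evaluate_ranking(ranking, fix$essentials, ks = c(10, 20, 40))
res$top_k
#> 10 20 40
#>  5  9 18
res$confusion
#> confusion counts (cutoff k = 20):
#>   TP=9  FP=11  TN=57  FN=23
round(res$statistics, 3)
#>    SN    SP   PPV   NPV     F   ACC
#> 0.281 0.838 0.450 0.713 0.346 0.660
```

The top of the ranking is dominated by module proteins (`M..P..` names):
9 of the top 20 are true essentials versus the 32% base rate, and the
confusion statistics summarize the top-20% cutoff (`k = 20` of 100
proteins). Every score is deterministic given the network, and rankings
break ties by protein identifier, so repeated runs are byte-identical.

The same pipeline runs from the shell:

```sh
inst/cli/lbcc synth --seed 7 --out-prefix fix
inst/cli/lbcc score --network fix_edges.txt --measure DC,BC,LBCC \
    --complexes fix_complexes.txt --out scores.tsv
inst/cli/lbcc evaluate --scores scores.tsv --measure LBCC \
    --essentials fix_essentials.txt --top-ks 10,20,40 --out report.tsv
```

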