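---
title: "Scoring essential proteins with LBCC: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring essential proteins with LBCC: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbcc)
```

## The problem

An essential protein is one whose single deletion is lethal or causes
infertility. Knockout screens that establish essentiality directly are slow
and expensive, so a long line of work ranks proteins computationally from
the topology of a protein–protein interaction (PPI) network: essential
proteins tend to have many partners, to lie on many shortest paths, to sit
in densely interconnected neighbourhoods, and — crucially — to congregate in
annotated protein complexes. `lbcc` implements a score that combines all
four signals, plus the standard baselines and the evaluation protocol used
to compare such rankers.

## The score

For an undirected simple graph $G(V, E)$ with proteins as nodes, write
$N_v$ for the neighbours of $v$ and $G[S]$ for the subgraph induced by a
node set $S$.

**Local densities.** Let $H_1 = G[N_v \cup \{v\}]$ be the closed
neighbourhood of $v$ and $H_2$ the subgraph induced by $v$ together with
every node at distance 1 or 2 from $v$ (the closed ball of radius 2,
built here by breadth-first expansion). Both densities are ordinary edge
densities,

$$Den_r(v) = \frac{2\,|E(H_r)|}{|V(H_r)|\,(|V(H_r)|-1)}, \qquad r = 1, 2,$$

so $Den_1$ measures how clique-like a protein's immediate neighbourhood is
(a leaf scores 1, since its closed neighbourhood is a single edge) and
$Den_2$ how dense its wider two-step environment is. $Den_1$ is a
reparametrisation of the local clustering coefficient $LCC$: for
$\deg(v) \ge 2$,

$$Den_1(v) = \frac{(|N_v| - 1)\,LCC(v) + 2}{|N_v| + 1},$$

an identity the test suite checks to $10^{-12}$. Isolated nodes take
density 0: the formula is 0/0 there, and a protein with no interactions
should never rank as essential on density grounds.

**Global position.** $BC(v)$ is betweenness centrality: the sum over
unordered pairs $\{s, t\}$, $s \ne t \ne v$, of the fraction of shortest
$s$–$t$ paths through $v$ — unnormalized, endpoints excluded, computed by
Brandes' algorithm. Pairs in other components contribute nothing. Published
tables built with other tools occasionally count ordered pairs (exactly
twice every value); `betweenness_centrality(net, ordered_pairs = TRUE)`
exposes that convention so table-level comparisons can diagnose a factor-2
offset.

**Complex membership.** With a collection of protein complexes (annotated
sets of proteins), the in-degree centrality of complex is

$$IDC(v) = \sum_{i \,\in\, ComplexSet(v)} \text{IN-Degree}(v)_i,$$

the sum over complexes containing $v$ of $v$'s PPI degree restricted to
that complex's members. Complex members absent from the network contribute
nothing. A protein outside every complex takes the floor value 0.001.

**The combination.** Because the four ingredients live on wildly different
scales (densities in $[0,1]$, BC in the tens of thousands), they are
combined on the log scale:

$$LBCC(v) = a \log Den_1(v) + b \log Den_2(v) + c \log IDC(v) + d \log BC(v)$$

with default weights $(a, b, c, d) = (1, 4, 3, 1)$, each restricted to
$[0, 10]$. No automated weight fitting is provided; users can sweep weights
through `lbcc_weights()` or the CLI.

## Numerical conventions

Several choices the formula alone does not settle; each is explicit and
configurable:

* **Zero flooring.** The 0.001 floor is defined for proteins outside all
  complexes, but $\log 0$ also threatens three other places: $BC = 0$
  (any leaf or isolated node), densities of isolated nodes, and a protein
  that is *in* complexes but has no in-complex interaction. We apply the
  same 0.001 floor to every factor before taking logs — the one floor value
  the method defines — so every LBCC score is finite. The computed-zero IDC
  case is floored inside `idc()` itself.
* **Log base.** Natural log by default. The ranking is provably invariant
  to the base (changing base multiplies every term by the same positive
  constant); only absolute score values change. The base is exposed in
  `lbcc_weights()` for bit-compatibility experiments, and the invariance is
  property-tested.
* **Ties.** `rank_proteins()` breaks score ties by ascending protein
  identifier in C-locale byte order, making every downstream count
  reproducible across platforms and runs.
* **NC.** The edge-clustering-coefficient formulation is used:
  $NC(v) = \sum_{u \in N_v} z(u,v) / \min(\deg u - 1, \deg v - 1)$ with
  $z$ the number of common neighbours and $0/0 \to 0$. This is the standard
  definition in the essential-gene literature for "network centrality";
  on triangle-free graphs it is identically zero.
* **LCC at degree $\le 1$.** The defining formula divides by
  $|N_v|(|N_v|-1)$; such nodes score 0 by convention.
* **EC.** The principal eigenvector of the adjacency matrix, entrywise
  non-negative, L2-normalized; a dense symmetric eigensolve up to 3000
  nodes and power iteration (tolerance $10^{-12}$, max 10000 iterations)
  beyond. An edgeless network is rejected — its principal eigenvector is
  degenerate.
* **SC.** Evaluated from the eigendecomposition as
  $\sum_j u_j(v)^2 e^{\lambda_j}$. PPI-scale spectral radii are far below
  the overflow threshold of `exp()`, so no log-sum-exp rearrangement is
  needed.

## Evaluation protocol

Rankings are evaluated exactly the way the essential-protein literature
does: the number of true essentials among the top $k$ (default
$k = 100, \dots, 600$); the confusion counts when the top 20% of the
ranking is called essential and the rest nonessential, with the six derived
statistics SN, SP, PPV, NPV, F and ACC; full precision–recall and jackknife
(cumulative-true-positive) curves as tables; and pairwise top-$k$ set
differences between methods. Two conventions to note: the top-20% cutoff is
$\lfloor 0.2\,|V| \rfloor$ — rounding is not standardized across papers, so
the integer cutoff actually used is carried in every report — and proteins
without essentiality annotation count as nonessential, the binary framing
admitting no third class. The break-even point is reported as the recall at
the largest rank where precision still covers recall.

## The synthetic benchmark

`generate_fixture()` draws a planted-partition network: `n_modules` dense
modules (within-module edge probability `p_in = 0.9`) over a sparse
background (`p_out = 0.02` between modules), plus `n_background` extra
proteins wired at 0.03 so the graph contains leaves and betweenness-zero
nodes — the degenerate inputs that exercise the flooring path. Essential
labels fall on half the module proteins and 5% of background proteins
(roughly a 30% essential fraction overall, comparable to curated yeast
networks), and complexes are sampled as subsets of single modules. All
sampling comes from one seeded stream in a fixed order (edges over node
pairs in lexicographic order, then labels, then complexes), so a seed
pins the fixture byte-for-byte.

This emulates the two premises the score is built on — essential proteins
cluster densely and gather in complexes — and nothing else. In particular
it does not mimic yeast degree distributions, false-positive interaction
noise, or the correlation structure of real complex annotations, so
passing the recovery benchmark shows the pipeline ranks planted structure
correctly, not that it will reach any particular precision on real
interactomes. The standard recovery check (mean $Den_1$ of module proteins
exceeding the background mean in at least 95 of 100 seeded replicates, and
planted complex members rising above the IDC floor) runs on 100-protein
fixtures, a size chosen so the whole battery completes in seconds.

```{r recovery-example}
fix <- generate_fixture(fixture_spec(seed = 7L))
summary(den1(fix$network)[fix$membership != "background"])
summary(den1(fix$network)[fix$membership == "background"])
```

## Reproducing published benchmarks

`reproduce_benchmarks()` (CLI: `lbcc reproduce`) runs the full chain —
load, score all eleven measures, rank, evaluate — on any dataset supplied
as the three standard files. The curated yeast datasets this method was
originally benchmarked on (YMIPS, YMBD, YHQ, YDIP, with ~1000 essential
proteins and a 745-complex collection) are not redistributed with the
package; once exported to plain text they run through the same entry
point, and `tests/testthat/test-acceptance.R` encodes the published
reference values it checks when those files are present under `data-raw/`.

## Known limitations

* IDC depends entirely on the quality and coverage of the complex
  collection; with an empty collection LBCC degenerates to a
  density/betweenness combination in which every protein shares the same
  floored IDC term.
* Exact betweenness is $O(|V|\,|E|)$; networks far beyond the $10^4$-node
  scale would need approximate algorithms, which are deliberately out of
  scope.
* The default weights are the published operating point for curated yeast
  networks; nothing guarantees they transfer to other organisms or to
  noisy high-throughput networks, and no fitting procedure is shipped.
* Weighted or directed interaction networks are not supported; edges are
  presence/absence.
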