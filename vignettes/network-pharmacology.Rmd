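---
title: "Network pharmacology of multi-herb formulas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology of multi-herb formulas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis problem

Multi-herb formulas act through many chemical ingredients hitting many
protein targets at once, so no single-gene assay explains their effect on a
disease. Network pharmacology tackles this by combining five ingredients of
evidence: (1) a disease expression signature, (2) an ADME-filtered catalogue
of the formula's chemical constituents, (3) compound-to-target annotations,
(4) a protein-protein interactome, and (5) functional gene-set annotations.
`netpharm` implements this workflow end to end for a paired
case/control expression design, with the Gegen Qinlian decoction (GQD) /
colorectal cancer system as its reference use case: four herbs (Gegen,
Huangqin, Huanglian, Gancao), a tumour/matched-normal microarray design
with 17 pairs, and TCMSP-style oral-bioavailability (OB) and drug-likeness
(DL) annotations.

## Stage by stage

### Disease-specific genes

For gene $g$ with per-pair differences $d_i = \mathrm{case}_i -
\mathrm{control}_i$ on the log2 scale,

$$\widehat{\mathrm{log_2FC}}_g = \bar d, \qquad
  t_g = \frac{\bar d}{s_d/\sqrt{n}},$$

with a two-sided p from Student's $t$ on $n-1$ df. Raw p-values are
adjusted by Benjamini–Hochberg step-up, and a gene is called
disease-specific when $|\mathrm{log_2FC}| \ge 1$ (inclusive) **and**
adjusted $p < 0.05$ (strict). The asymmetric tie handling is deliberate: it
matches how the thresholds are conventionally printed.

Microarray practice usually moderates the variance (limma). The default
here is the plain paired test, which is fully specified and exactly
testable; `moderation = "eb"` enables a documented approximation that
shrinks each gene variance toward the study-wide mean with a fixed prior
$d_0$ (default 4):

$$\tilde s^2 = \frac{d_0 \bar{s}^2 + (n-1) s^2}{d_0 + n - 1},
  \qquad \mathrm{df} = d_0 + n - 1.$$

Unlike limma, $d_0$ and the prior variance are not estimated from the data;
the vignette's advice is to treat the moderated mode as a robustness check,
not a reimplementation of limma. Rows with missing values are dropped (with
a reported count) rather than imputed: paired statistics need complete
pairs. Two degenerate cases have fixed policies: zero-variance,
zero-mean differences give $t=0,\ p=1$; zero-variance nonzero-mean
differences get the smallest positive double as p, with a warning, so they
rank first rather than produce `NaN`.

### Ingredient screening

Compounds are retained when $\mathrm{OB} \ge 30\%$ and $\mathrm{DL} \ge
0.18$, the conventional TCMSP screening thresholds, both inclusive.
Deduplication across herbs is keyed on the molecule ID alone (names vary in
capitalization between sources); the merged record keeps the first OB/DL
seen (conflicts are warned about, not resolved) and a sorted,
semicolon-joined `source_herbs` field.

### Target intersection and the pharmacological network

Compound-target pairs survive only if the target is disease-specific;
ingredients that lose all their targets are pruned ("effective" BCIs). The
remaining pairs form an undirected, unweighted bipartite network —
no affinity information exists at this stage, so edges are not weighted.
Exports (SIF, GraphML) prefix node IDs with `mol:` / `gene:` to prevent
collisions between molecule IDs and gene symbols.

### PPI core extraction

The target genes seed a PPI network built from a supplied interactome. How
reference tools expand seeds is not standardized, so the rule is explicit
and configurable: the default (`"direct"`) takes the seeds plus their
direct interactors and every interactome edge with both endpoints inside
that set (including interactor–interactor edges); `"seeds-only"` induces on
the seeds alone.

The core is extracted in two stages at fraction $f = 0.30$: keep the top
$f$ of nodes by degree centrality (DC) computed on the full graph, then
recompute betweenness centrality (BC) **on the induced subnetwork** and
keep its top $f$. "Top 30%" is read as $k = \lceil f n \rceil$ by rank,
with every node tied at the cut retained — published node counts from
plug-in pipelines do not land exactly on 30% (e.g. 130/446 = 29.1%), so a
rank-with-ties rule is documented rather than a rounding rule guessed to
match. With continuous scores the kept count equals the ceiling exactly;
with heavily tied degree distributions the subnetwork can be substantially
larger, and the tie mass is visible in the recorded cut thresholds.

BC is unnormalized shortest-path betweenness for undirected unweighted
graphs (endpoints excluded, each unordered pair counted once), the CytoNCA
convention; normalization is a flag. It is computed by Brandes'
dependency-accumulation algorithm, and the test suite verifies exact
agreement with a naive all-pairs BFS path-counting oracle (and with
igraph) on hundreds of random graphs. Disconnected subnetworks are
handled per component. Crucial genes are simply the seeds that survive
into the core.

### Enrichment

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$. Design choices that
change results and are therefore explicit:

* **Universe**: all genes annotated in the collection (the
  clusterProfiler default), overridable to all measured genes.
* **BH scope**: within each category (BP/CC/MF/pathway) separately by
  default — matching how GO results are conventionally reported per
  ontology — with a pooled mode by flag.
* **Zero-overlap sets are not tested** and do not count toward $m$ in the
  BH correction; this matches common ORA practice and is stated because it
  changes adjusted p-values.
* No set-size filter by default; `min_set_size` / `max_set_size` exist.

Both `gene_ratio` (overlap over in-universe query size) and
`gene_ratio_raw` (over the raw query size) are emitted, since figure
conventions differ on the denominator.

## The synthetic-data generator

Every input can be simulated from one `synth_config()`, whose single
integer seed drives deterministic per-artifact substreams — the same config
yields byte-identical files. The defaults are the study conditions the
package is designed around, chosen once:

* **Expression**: 17 case/control pairs; 2000 genes; 5% truly
  differential with a fixed $\pm 2.0$ log2 shift (signs alternating, so
  up/down counts are balanced); per-sample noise SD 0.5; a per-pair random
  intercept (SD 1.0) that makes the design genuinely paired. Under these
  conditions the default DEG filter attains sensitivity $\ge 0.95$ with
  false-discovery proportion $\le 0.05$, and with no spiked effects the raw
  type-I rate calibrates at 5% — both verified by simulation in the test
  suite.
* **Compounds**: herbs Gegen/Huangqin/Huanglian/Gancao with
  18/143/48/280 catalogued compounds (489 total); 30% per herb constructed
  to pass the OB/DL screen from a two-component distribution (pass: OB
  uniform on [30, 100], DL on [0.18, 1]; fail: below both thresholds), so
  pass counts are exact by construction (146); six bioactive molecule IDs
  duplicated across herbs, so deduplication yields exactly 140.
* **Target map**: a 240-gene pool containing 20 truly differential genes;
  one hub target wired to 90% of compounds (a single dominant target is the
  signature structure of these networks); each compound draws $1 +
  \mathrm{Pois}(0.6)$ further targets; every pool gene is guaranteed at
  least one compound so the mapped-gene count is exact.
* **Interactome**: preferential attachment over 500 nodes with 3 edges per
  new node — a path over the first 3 nodes then weighted attachment —
  giving exactly $(m-1) + (n-m)m$ edges, a connected simple graph, and a
  heavy-tailed degree distribution. Two seed genes are placed on the
  oldest (highest-degree) nodes so that, as in real analyses, a couple of
  seeds dominate the filtration cascade; the rest are placed on late,
  low-degree nodes. Nothing is claimed about the generative process of
  real interactomes; this is a stand-in with the right qualitative
  topology.
* **Gene sets**: 200 random decoy sets (sizes uniform on [10, 50]) across
  the four categories, plus planted sets built around the disease-specific
  pool genes: six pathway sets, one small CC set and a few BP/MF sets, so
  the enrichment stage has known signal to find.

What the generator does **not** emulate: probe-level microarray effects and
probe-to-gene collapse, RMA normalization, real ADME predictors,
correlation between genes, annotation redundancy along the GO DAG, or the
literature-derived degree correlations of curated interactomes. Passing
tests therefore demonstrate the correctness and calibration of the
*procedure*, not the biological validity of any particular real-data
result.

## Numerical choices and problem sizes

Thresholds default to the field conventions (OB 30 / DL 0.18;
$|\mathrm{log_2FC}| \ge 1$, adjusted $p < 0.05$; filtration fraction 0.30;
enrichment $\alpha = 0.05$). Oracle comparisons in the tests use absolute
tolerances of $10^{-10}$–$10^{-12}$; BH and hypergeometric values are
checked against enumeration oracles exactly. The simulation studies in the
test suite and acceptance script use 1000-gene studies over 50 seeds
(operating characteristics) and 100 seeds (null calibration), and random
graphs up to 120 nodes (200 graphs at $\le 30$ nodes for the exact
betweenness battery) — sizes chosen so the whole suite runs in well under a
minute per file while keeping Monte-Carlo error far from the asserted
margins.

## Known limitations

* The moderated test is a fixed-prior approximation, not limma; analyses
  that hinge on moderation details should use limma directly and feed the
  resulting table to `deg_filter()`.
* Multiple probes per gene are out of scope; the pipeline operates on a
  gene-level matrix and inherits whatever collapse rule produced it.
* Database-derived counts (how many compounds a herb has, how many targets
  intersect a signature, interactome size) depend entirely on the versions
  of TCMSP-like catalogues, interactome sources and annotation releases;
  the synthetic defaults mirror one published configuration structurally,
  and no attempt is made to reproduce database contents.
* The seed-expansion rule of plug-in PPI builders is not documented by
  those tools; both plausible rules are implemented and the choice is
  recorded in the run manifest.
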