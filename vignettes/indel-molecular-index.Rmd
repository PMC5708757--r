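---
title: "Methods: the InDel molecular index and panel diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the InDel molecular index and panel diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelindex)
```

`indelindex` implements the full downstream analysis of a codominant InDel
marker survey of rice germplasm: scoring band profiles against an indica and
a japonica reference cultivar, classifying accessions by their InDel
molecular index, quantifying marker informativeness, partitioning molecular
variance between proposed populations, and exploring panel structure by
clustering and ordination. This vignette records the models, the tunable
parameters and the numerical decisions behind each stage.

## Genotype model and scoring

InDel markers amplify length alleles that segregate codominantly on a gel.
Every sample x locus cell is one of:

* `II` — both alleles match the indica reference cultivar's band,
* `JJ` — both match the japonica reference cultivar's band,
* `IJ` — one band of each reference (heterozygote),
* `NN` — no amplification (null allele, typically a primer-site mutation),
* `IX`, `JX`, `XX` — calls involving a scored band that matches *neither*
  reference (the marker panel bundled with the package contains one
  triallelic locus, R3M37, whose 240 bp band is such an `X` allele).

`score_bands()` maps observed band sizes to these codes by nearest-match
within `tolerance_bp`. The default tolerance is 0 because the bundled
marker catalogue records capillary-verified sizes; gel-estimated inputs
should pass a small positive tolerance (about 2 bp). More than two distinct
matched bands at one locus is treated as a scoring error to be reviewed,
not silently truncated. One marker (R1M37) is dominant — a single band
present in the japonica reference and absent in the indica reference — and
band absence is scored as homozygous for the band-lacking reference rather
than as missing, since the marker is genuinely polymorphic between the two
references.

The published marker catalogue does not state, for most markers, *which* of
the two bands is the indica-reference allele. The bundled
`markers_table1.tsv` fixture fixes the direction where it is documented
(R2M37: indica 211 / japonica 151; R3M37: indica 194 / japonica 282; R1M37:
167 bp band carried by the japonica reference) and otherwise adopts the
convention *indica = first-listed band*. This assignment is synthetic and
is flagged as such in the fixture header; every statistic in the package
depends only on a consistent assignment, but per-marker directions for real
data should come from the user's own reference lanes.

## The InDel molecular index and classification

For one accession scored at $N_\mathrm{eff}$ non-null loci,

$$F_i = \frac{2\,n_{II} + n_{IJ} + n_{IX}}{2\,N_\mathrm{eff}}, \qquad
  F_j = \frac{2\,n_{JJ} + n_{IJ} + n_{JX}}{2\,N_\mathrm{eff}}.$$

Two decisions here were genuinely open:

* **Null loci** are excluded from the denominator ($N_\mathrm{eff}$ rather
  than the panel's locus count): a null call contributes no scorable
  allele, and keeping it in the denominator would bias both frequencies
  toward zero for samples with failed amplifications.
* **X alleles** count in the denominator but in neither numerator, so they
  dilute $F_i$ and $F_j$ symmetrically; the per-sample `n_x` column lets
  users rerun with triallelic loci excluded if they prefer
  $F_i + F_j = 1$ exactly.

Classification uses seven contiguous half-open intervals on $F_j$:

| class | $F_j$ interval |
|---|---|
| typical indica | [0, 0.105) |
| indica | [0.105, 0.255) |
| close to indica | [0.255, 0.395) |
| intermediate | [0.395, 0.605) |
| close to japonica | [0.605, 0.745) |
| japonica | [0.745, 0.895) |
| typical japonica | [0.895, 1] |

The published bands are two-decimal roundings with gaps (e.g. 0.25–0.26);
closing each gap at its midpoint makes the map total and single-valued on
$[0,1]$ while agreeing with the printed bands everywhere they apply. The
$F_i$ bands are complements of the $F_j$ bands, so classification is keyed
on $F_j$ alone. `proposed_populations()` implements the grouping used for
the variance partition: intermediate and the japonica-side classes form
population 2, the indica-side classes population 1.

## Marker informativeness

Per marker, with gene-count allele frequencies $p_i$ (homozygote = 2
copies, heterozygote = 1 of each, nulls excluded):

* $\mathrm{PIC} = 1 - \sum_i p_i^2$ (at most $1 - 1/k$ for $k$ alleles);
* band informativeness $I_b = 1 - 2\,|0.5 - p|$ where $p$ is the
  proportion of genotypes *containing* the band, and resolving power
  $R_p = \sum_b I_b$;
* $\mathrm{EMR} = \mathrm{NPA} \times \mathrm{PPA}$ and
  $\mathrm{MI} = \mathrm{PIC} \times \mathrm{EMR}$;
* bands present in strictly fewer than 5% of samples are flagged rare.

Two subtleties. First, $p$ for $I_b$ is the genotype-containing proportion,
not the allele frequency: a marker heterozygous in every sample has both
bands in every genotype, hence $I_b = 0$ for both bands — consistent with
the bundled catalogue, which records $R_p = 0.02$ for exactly such a
marker. Second, PPA ("proportion of polymorphic amplicons") is printed as
1 for biallelic and 2 for the triallelic marker in the source catalogue; a
proportion exceeding 1 is not derivable from any stated formula, so
`marker_report()` uses the printed PPA when present and only computes
PPA = NPA / (total bands) under `recompute_ppa = TRUE`, labelling the
column's provenance either way. Printed PIC values are echoed next to the
recomputed ones and discrepancies are flagged rather than reconciled — the
catalogue's PIC of 0.98 for a biallelic marker cannot arise from
$1-\sum p^2$ and is reported as discrepant, not reproduced.

## Molecular variance and Phi-PT

`amova()` partitions squared pairwise distances on the binary band matrix
(the `band_matrix()` expansion assigns one 0/1 column per catalogued band;
null calls mask their marker's columns and masked cells are excluded
pairwise). The squared Euclidean band distance — the count of mismatching
mutually observed band columns — mirrors the standard binary Phi-PT
workflow for dominant/binary data. With $P$ populations of sizes $n_p$,
$N = \sum n_p$:

$$SS_\mathrm{tot} = \tfrac1N \sum_{i<j} d^2_{ij}, \quad
  SS_\mathrm{w} = \sum_p \tfrac1{n_p} \sum_{i<j \in p} d^2_{ij}, \quad
  SS_\mathrm{a} = SS_\mathrm{tot} - SS_\mathrm{w},$$

with $df_\mathrm{a} = P-1$, $df_\mathrm{w} = N-P$,
$n_0 = (N - \sum n_p^2 / N)/(P-1)$,
$V_a = \max\{0, (MS_\mathrm{a} - MS_\mathrm{w})/n_0\}$,
$V_w = MS_\mathrm{w}$ and $\Phi_{PT} = V_a / (V_a + V_w)$. Negative
among-population components are truncated to zero (the usual convention;
it keeps $\Phi_{PT}$ in $[0,1]$).

Significance uses random reassignment of samples to populations preserving
sizes, with the add-one estimator $(1 + \#\{\text{as extreme}\})/(1 +
n_\mathrm{perm})$, so a test with 10,000 permutations reports at best
$P < 1/10001$ rather than 0. One numerical decision matters here: the
permutations are ranked by the among-population sum of squares — a
monotone, untruncated surrogate for $\Phi_{PT}$ — because ranking the
truncated $\Phi_{PT}$ itself piles a large fraction of null permutations
onto the $\Phi_{PT}=0$ atom and makes null P-values conservative instead
of uniform. Uniformity of null P-values is asserted in the test suite by a
Kolmogorov–Smirnov check across 200 replicate label shufflings.

Per-population diversity uses the same gene-count frequencies per locus:
$N_a$ (alleles observed), $N_e = 1/\sum p^2$, $I = -\sum p \ln p$,
$H_e = 1-\sum p^2$ and $uH_e = \frac{2n}{2n-1} H_e$, summarised across loci
as mean ± (sd across loci)/$\sqrt{L}$.

## Clustering and ordination

Jaccard similarity is computed in-package because per-cell masking (null
calls) requires pairwise-complete band columns, which off-the-shelf binary
distances do not support; on mask-free data it is verified against
`vegan::vegdist` in the tests. UPGMA is delegated to
`stats::hclust(method = "average")`; merge heights are reported as
distance/2 (the ultrametric convention), so the cophenetic distance of a
leaf pair equals the average-linkage distance at which their clusters
merged, and the Newick export (via `ape`) has patristic distances equal to
the cophenetic distances. Tie-breaking among equal merge candidates
follows `hclust`; ties have measure zero for the fractional Jaccard
distances this tree is built on. `cut_clusters()` cuts at a similarity
level (default 0.30) to reproduce the two-major-group partition workflow.

PCA operates on the covariance (centred, unscaled) of the band columns,
with masked cells mean-imputed per column under a warning; percent
variance per axis is eigenvalue over trace and sums to 100 over all axes.
Geographic PCoA is classical metric MDS on Euclidean distances of z-scored
latitude/longitude/altitude; since the input distances are Euclidean the
double-centred solution reproduces them exactly, and only positive
eigenvalues carry configuration.

## The synthetic panel generator

No raw genotype matrix is deposited with the source study, so the
generator stands in for it in every end-to-end test. It emulates:

* a **selfing species**: genotypes are near-homozygous with an explicit
  per-call heterozygosity rate (default 0.03, putting per-sample
  heterozygous fractions in the observed 0–17% range) rather than
  Hardy–Weinberg draws, which would be wrong for rice landraces;
* **two latent subpopulations** with contrasting japonica-allele spectra:
  each population draws per-locus $q \sim \mathrm{Beta}(\alpha,\beta)$,
  and each sample x locus call is IJ with probability `het_rate`, else JJ
  with probability $q$;
* **sparse nulls** (default 0.005 per call, matching a handful of null
  calls per 192 x 42 panel) and **one triallelic locus** where alleles are
  substituted by the third band at rate 0.02;
* **regional collection geography**: one centre per population with
  jitter, japonica-leaning populations at higher altitude.

The study-scale preset (`paper_scale_preset()`) produces 192 samples x 42
loci: 160 indica-like samples with $q \sim \mathrm{Beta}(2, 8)$ (mean
$F_j \approx 0.2$, spread over the indica and close-to-indica classes), 30
japonica-leaning samples with $q \sim \mathrm{Beta}(6, 4)$ (intermediate
to close-to-japonica), and two reference-like extremes (all-II, all-JJ).
These defaults were fixed once from the published panel description
(sample and locus counts, class composition dominated ~85:15 by the indica
side, null and heterozygosity levels) and are deliberately not tuned to
reproduce the study's headline statistics — with the raw matrix
undeposited, quantities like its $\Phi_{PT} = 0.642$ or PC1 = 34% are not
recoverable, and the synthetic panel's analogues are properties of the
generator, not estimates of the study's.

Truth is recorded at two levels: the Beta draws per population x locus,
and each sample's *realised* japonica-allele proportion computed from the
emitted calls before the null/X overlays. With overlay rates set to zero
the recovered $\hat F_j$ equals the realised truth exactly — an identity,
not an approximation — which the tests assert. What passing these tests
does **not** show: robustness to genotyping error, to linkage between
loci, to admixed pedigrees, or to ascertainment of the marker panel; none
of these are modelled.

## Problem sizes and runtime choices

The test suite and the acceptance script favour small, seeded instances:
oracle checks run brute-force double loops at up to 8 samples (where exact
agreement to 1e-9 is asserted against the grouped formulas), UPGMA oracles
at 6 leaves, permutation calibration on a 60-sample panel with 200
replicate shufflings of 199 permutations each, and the divergent-panel
significance check with the full 10,000 permutations. The study-scale runs
(192 x 42, 10,000 permutations) complete in seconds thanks to the
matrix-product formulation of the band distances and the
subset-sum permutation update.

## Known limitations

* The reference-band direction convention in the bundled catalogue is
  synthetic for most markers (see above).
* Phi-PT is computed for the two-level design only; hierarchical
  (region/population/individual) partitions are out of scope, as is
  model-based admixture inference, for which established external tools
  exist.
* The classification intervals assume the published two-decimal bands;
  users with a different reference pair should revisit them.
* `het_proportion()` reports one decimal place by design (to match the
  field's reporting convention); use `n_het / n_scored` from
  `classify_panel()` output when full precision matters.
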