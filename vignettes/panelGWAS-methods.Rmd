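---
title: "Mixed-model association mapping in structured inbred panels: models and methods"
author: "panelGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model association mapping in structured inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelGWAS)
```

# The problem

Diversity panels of inbred crop varieties — rice landrace collections are
the motivating case — are powerful material for genome-wide association
studies: lines are immortal, near-completely homozygous, and can be
phenotyped repeatedly across environments. They are also deeply
structured: a handful of anciently diverged subpopulations (in rice:
*aus*, *indica*, *tropical japonica*, *temperate japonica*, *aromatic*,
nested in the *INDICA*/*JAPONICA* varietal groups) differ strongly in
allele frequencies, so naive marker–trait tests are massively confounded.
panelGWAS implements the full analysis stack for such panels: genotype
handling and filtering, population-genetic summaries, a kinship linear
mixed model with SNP-covariate conditioning and an epistatic interaction
scan, variance decomposition, formulaic peak calling, extended-haplotype
analysis, functional SNP annotation, and broad-sense heritability — plus
a synthetic-panel generator so every stage is testable end to end without
access to any particular data deposit.

# The mixed model

All association scans are built on one model. For $n$ lines with
phenotype $y$ (per-line means over replicates, the scale on which these
panels are analysed),

$$ y = X\beta + u + \varepsilon,\qquad
   u \sim N(0, \sigma^2_g K),\qquad
   \varepsilon \sim N(0, \sigma^2_e I), $$

where $X$ collects the intercept, optional principal-component covariates
and optional SNP covariates, and $K$ is a kinship matrix. Genotypes are
coded additively, AA $=-1$, AB $=0$, BB $=+1$, so a marker effect
$\beta_m$ is the expected trait change per B allele and $2\beta_m$
separates the homozygote classes (dominance is constrained to zero —
essentially harmless in a panel with sub-1% heterozygosity).

`fitNullLMM()` estimates $(\sigma^2_g, \sigma^2_e)$ once on the null
design by REML, profiling the variance ratio
$\delta = \sigma^2_e/\sigma^2_g$ on the eigendecomposition of $SKS$
($S$ the projection off $X$). The profiled restricted likelihood is
evaluated on a dense grid of $\log\delta$ (100 points on $[-10, 10]$ by
default) and refined around every grid local maximum with a
derivative-free optimiser; the grid guards against the multimodality of
the REML surface at small $n$. Each marker is then tested by generalized
least squares under the frozen covariance
$\hat\sigma^2_g K + \hat\sigma^2_e I$ — the EMMAX approximation. An exact
per-marker refit is available (`glsTest(..., refit = TRUE)`) and is used
in the test suite as a cross-check, never as the scan path.

Two implementation details matter:

* **Missing genotypes are dropped, not imputed, per test.** A marker's
  missing lines are removed exactly via a block-downdate of $V^{-1}$
  (no per-marker refactorisation), so tests remain unbiased under
  marker-specific missingness. Complete markers go through a fully
  vectorised rotated-space regression; markers with missing calls go
  through the downdate path, implemented in compiled code with the plain
  R version retained as the reference implementation and oracle.
* **Kinship.** The default estimator is pairwise identity-by-state,
  $K_{ij} = \mathrm{mean}\,(2 - |x_i - x_j|)/2$ over pairwise-complete
  markers; a centred cross-product estimator is selectable
  (`computeKinship(method = "centered")`). Which estimator a given EMMAX
  analysis used is rarely reported; IBS is the documented default of that
  tool and is ours.

## Variance decomposition

For every test the package reports three shares of phenotypic variance:

* `pve_marker` — the additive share of the tested term,
  $\widehat{\beta}_m^2 \mathrm{Var}(x_m)/\mathrm{Var}(y)$, i.e. the term
  variance underlying its $t$ test;
* `pve_model` — the total model share,
  $1 - \mathrm{Var}(e)/\mathrm{Var}(y)$ with $e$ the conditional
  residuals including the kinship BLUP;
* `pve_random` — the kinship share, obtained from a baseline fit in which
  every marker fixed term is replaced by a random genotype vector of
  identical degrees of freedom (`nDummy` draws, one by default,
  seed-controlled), so that `pve_model - pve_random` attributes the
  jointly explained fixed genetic share when several SNP covariates are
  present; per-term shares are additionally attributed by
  leave-one-term-out differencing (`pveDecomposition()`).

A subtlety worth stating: when the kinship matrix is estimated from all
markers it contains the causal markers too, so the dummy baseline
absorbs most of a QTL's variance into the random term. The
model-minus-baseline difference is therefore *not* a useful per-marker
effect size — the additive term share is — and the package reports both
quantities under separate names rather than conflating them.

## Scans

`runScan()` wires the pieces together: marker filters evaluated on the
scan lines (folded MAF strictly $> 0.05$, minor-allele count $\ge 3$,
missing rate $\le 30\%$; for whole-panel scans the marker set can be the
union of per-subpopulation MAF-passing markers via `subpopGroups`),
kinship from the filtered panel, three PC covariates for whole-panel
scans and none within subpopulations, optional SNP covariates, and a
Benjamini–Hochberg significance flag at a 10% FDR computed per scan.
`interactionScan()` adds, for each scan marker, the double-homozygote
interaction regressor of `encodeInteraction()` ($-1$ for AA/AA, $+1$ for
BB/BB, 0 otherwise including any heterozygote) alongside both main
effects, reporting the interaction term.

Conditioning on a known large-effect marker (`snpCovariates`) removes its
peak and exposes secondary loci — the mechanism by which
subpopulation-restricted alleles hiding under a major QTL become
detectable.

A structural fact about the interaction coding deserves emphasis: on
purely homozygous genotypes, $I(x_1, x_2) = (x_1 + x_2)/2$ exactly, so
the interaction term is perfectly collinear with the two main effects.
In a near-homozygous panel the term is identifiable only through the
cells that break this identity — heterozygous calls (set to 0 by the
coding while the mains average to $\pm 1/2$), or fractionally imputed
genotypes in analyses that mean-impute missing calls. This package drops
missing lines rather than imputing, so heterozygotes are the identifying
cells: `plantPureEpistasis()` refuses het-free pairs as unidentifiable,
and the scan flags such markers as singular rather than reporting an
arbitrary coefficient split.

# Peaks

`callPeaks()` applies a formulaic rule: a region qualifies when one SNP
passes $P < 10^{-5}$ and at least two additional SNPs pass $P < 10^{-4}$
within 100 kb on either side. Overlapping qualified windows on a
chromosome merge into one peak (that is how zoomed-in regions are counted
as single entities); the reported MS-SNP is the smallest-$P$ marker, ties
broken by smaller position. `overlapCandidates()` attaches candidate
genes whose interval, extended by a 24 kb flank, touches a significant
SNP of the peak; all coordinates are 1-based closed intervals.

# Population-genetic summaries

* **PCA** (`computePCA()`) uses only markers complete in all included
  lines, centres each marker, and eigendecomposes the line-by-line
  Pearson correlation matrix. Marker centring matters: without it the
  leading eigenvector is the all-positive shared-ancestry mode and no
  component can separate balanced groups.
* **Site-frequency spectra** (`sfs1d()`, `sfs2d()`): folded (no outgroup)
  frequencies binned into 100 equal intervals on $[0, 0.5]$, with
  left-closed bins so cumulative counts agree across refinements. The 2D
  spectrum fixes the minor allele panel-wide and tracks its frequency per
  group, where it may exceed 0.5 or reach fixation.
* **LD decay** (`ldDecay()`): markers with $>1/3$ missing data or fewer
  than three minor-allele carriers are discarded; 4,000-SNP windows move
  non-overlapping along each chromosome (non-overlap avoids
  double-counting pairs; the step is configurable); all within-window
  pairs are scored with $r^2$ (squared genotype correlation over
  pairwise-complete lines) and $|D'|$ (Lewontin-normalised, treating
  homozygous inbred lines as haplotypes and dropping heterozygotes from
  the haplotype counts — no phasing needed at $<1\%$ het rate); distances
  pool into 500 equal-width bins over the observed range.
* **Private/shared SNPs** (`privateSharedSnps()`): per-subpopulation
  polymorphic, MAF-classified and private counts, plus the common set
  segregating in every subpopulation. These are computed on unfiltered
  genotypes — a panel-wide MAF filter would strip exactly the
  subpopulation-private variants the table is about.

# Haplotype analysis

For a region of interest (the *GS3*-flank analysis is the template),
`filterRegionSnps()` applies three marker-local filters in order: folded
MAF $> 0.05$, missing rate $< 3\%$, and a two-sided Fisher exact test on
the 2x2 allele-count table between two named groups (e.g. *INDICA* vs
*JAPONICA*) at $P < 10^{-6}$ (chi-square selectable; Fisher is exact and
assumption-free at these counts). `buildExtendedHaplotypes()` then groups
lines by greedy frequency-seeded agglomeration: the most frequent exact
allele string (missing wildcarded, ties broken lexicographically) seeds a
group, lines within a mismatch budget (default 2; heterozygous cells
count 1/2) of the per-site majority consensus are absorbed, and the
consensus is recomputed to a fixed point. Groups below the minimum size
fall into a rare-recombinant residual pool. No published grouping
algorithm exists for this display, so the agglomeration is this package's
own construction with every tolerance exposed as an argument; the
procedure is deterministic and invariant to line order.
`haplotypePhenotypeSummary()` and `compareHaplotypeGroups()` give the
per-group quartile summaries and Welch contrasts used to read such maps.

# Annotation

`readGeneModels()` parses GFF3 gene models and derives per-transcript
exons, CDS, UTRs, introns (exon gaps) and the putative promoter region —
the 2 kb immediately upstream of the TSS, strand-aware, closed interval
`[TSS-2000, TSS-1]`. `classifySnps()` unions categories over all
overlapping models (a SNP can be exonic in one gene and promoter-proximal
for its neighbour) and assigns the primary category by the priority
exonic > intronic > UTR (5'/3') > PPR > intergenic. The exonic category
is taken from CDS intervals when CDS features exist: UTRs are subsets of
exon intervals in GFF3, so raw exons would otherwise shadow every UTR
under the priority rule. `codingEffect()` translates reference and
mutated codons (standard genetic code; codons supplied in coding
orientation) into synonymous / non-synonymous / stop-gain / stop-loss
calls.

# Heritability

From a balanced replicated multi-environment trial, `estimateComponents()`
takes the two-way ANOVA mean squares and the method-of-moments
estimators $\hat\sigma^2 = MS_E$,
$\hat\sigma^2_{g\times e} = (MS_{G\times E} - MS_E)/r$,
$\hat\sigma^2_g = (MS_G - MS_{G\times E})/(re)$, clamping negative
estimates to zero with a flag, and the entry-mean broad-sense
heritability

$$ H^2 = \frac{\sigma^2_g}
   {\sigma^2_g + \sigma^2_{g\times e}/e + \sigma^2/(re)}. $$

This denominator is the standard entry-mean form consistent with the
symbols involved ($r$ replicates, $e$ environments); alternative
denominators circulate in the literature, so the components are returned
alongside $H^2$ and the formula is exposed directly as
`broadSenseH2()`. With a single environment the G-by-E term is
inseparable and a single-environment variant is returned with a warning.

# The synthetic panel

`simulateGenotypes()` draws, per marker, an ancestral alternate-allele
frequency $p \sim U(0.05, 0.95)$ and per-subpopulation frequencies from
the Balding–Nichols model $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ —
chosen as the standard generative model for diverged allele frequencies,
not as a claim about any particular panel's history. Lines are inbred
draws (homozygous at each marker), flipped to heterozygous at a residual
rate of 0.5% (purified landrace collections retain a trace of residual
heterozygosity) and masked at an overall missing rate of 6.5% (the call
rate of a high-density array); missingness is concentrated in a subset
of markers, with half the markers fully called, as on real arrays —
uniform random missingness would leave almost no marker complete in all
lines and starve the complete-marker PCA. Admixed lines (15% of the
panel by default) mix two subpopulation frequency vectors with a random
ancestry weight, and every line carries its true ancestry fractions, so
the 70%-ancestry classifier (`assignGroup()`) can reproduce the
subpopulation / admixed-*INDICA* / admixed-*JAPONICA* /
admixed-*INDICA-JAPONICA* classes. Defaults: five subpopulations,
Fst 0.3 each, twelve 30 Mb chromosomes.

What the generator deliberately does **not** model: linkage
disequilibrium between markers (draws are independent given the
frequencies — no recombination maps or coalescent history), selection,
and genotyping error beyond missingness. Because the peak rule needs
local LD to be meaningful, `induceLocalLD()` rewrites the markers within
a window around a planted QTL as noisy copies of the focal marker
(per-call flip probability 5%), emulating a tight haplotype block. Tests
passing on these panels therefore validate the statistical machinery
under known truth; they do not certify behaviour under real LD
structure, ascertainment bias, or genotyping artefacts.

`simulatePhenotypes()` builds genetic values from additive QTLs
($\sum a x$), an optional marginal-free epistatic pair, and a polygenic
background $N(0, \sigma^2_{bg} K)$, then adds environment main effects,
G-by-E deviates and replicate error for an $r \times e$ trial. Missing
QTL genotypes contribute through the line's subpopulation mean genotype
(logged). `plantPureEpistasis()` regresses the raw interaction
contribution $w\,I(x_1, x_2)$ on both single-marker codes and subtracts
the fitted parts, so the pair has ~zero marginal effects by construction
— the configuration in which a real two-locus interaction hides from
single-marker scans.

One practical note on planting effects: under strong kinship the
cross-line variance of the polygenic term is much smaller than
$\sigma^2_{bg}$ (correlated lines), so effect sizes targeting a variance
share are computed against the *realized* base-phenotype variance
(`effectForTargetPve()`, or the two-stage construction used in the tests
and the acceptance script), not against nominal components.

# Validation design and problem sizes

The test suite checks every computational path against an independent
oracle: dense explicit-inverse GLS and OLS for the mixed model, a dense
REML likelihood for the variance components, characteristic-polynomial
roots for PCA eigenvalues, two-pass correlation and the Lewontin bound
for LD, enumeration oracles for allele tallies, private-SNP accounting
and the regional filter, a full 576-substitution translation table for
coding effects, and hand-applied rules for peaks and the BH threshold.

End-to-end properties run on simulated study conditions: null
calibration and structure confounding on 20 panels of 500 lines x 10k
markers (Fst 0.1–0.3); QTL recovery, effect and variance-share
calibration on 20 panels of 800 lines x 20k markers; covariate
conditioning and epistasis detection on the 500-line panels. These sizes
keep the whole suite in the tens of minutes on a single core while
leaving each criterion statistically sharp.

Two statistical facts shaped the tests themselves. First, interaction
P values within a single scan share the covariate SNP and the phenotype
realisation; they are exchangeable but dependent given $y$, so whole-scan
uniformity tests reject even though each test is exactly calibrated —
calibration is therefore assessed across independent phenotype draws.
Second, near-degenerate bin-count bounds (uniform SFS) are asserted at
sizes where the multinomial concentration actually guarantees them.

# Limitations

* The EMMAX approximation freezes variance components at the null fit;
  for markers of very large effect the exact per-marker refit gives
  slightly different (more conservative) P values.
* The generator's independent-marker design means genome-wide scans on
  synthetic panels have no background LD; resolution statements on real
  panels depend on LD structure the simulation does not model.
* The extended-haplotype agglomeration is a display-driven heuristic; its
  mismatch budget trades group purity against fragmentation and should
  be read as a description of the data, not an inference procedure.
* Broad-sense heritability assumes a balanced trial; unbalanced designs
  are rejected rather than silently approximated (cell-mean imputation
  can be applied upstream).
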