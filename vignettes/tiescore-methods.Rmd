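---
title: "Cross-loci network ranking: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-loci network ranking: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiescore)
```

## The analysis in one paragraph

`tiescore` asks how two genetic loci jointly regulate a clinical trait in
an F2 intercross. It maps the trait to its QTLs, maps every expression
trait, keeps genes whose eQTL peaks co-localize with the two trait loci,
removes genes that co-localize without being causally coupled to the trait,
projects the survivors onto a protein–protein interactome keeping only
interactions *across* the two locus groups, and ranks each gene by the
Trait–Interaction–Expression (TIE) score: a summary of how strongly the
inferred intensity of its physical interactions co-varies with the trait
across the panel. The premise is that a gene mediating the integration of
two genetic perturbations should sit at a junction of the cross-locus
network and its interaction intensity should track the phenotype.

## QTL and eQTL mapping

Scans use single-marker regression: at each marker the trait is regressed
on genotype as a three-level factor (codes 0 = one homozygote, 1 =
heterozygote, 2 = the other homozygote) over the mice complete for that
marker, and `LOD = (n/2) log10(RSS_null/RSS_full)`. We chose marker
regression over HMM-based interval mapping deliberately: the marker set is
dense (the default synthetic map carries ~2,000 markers, about 1.4 per cM),
and every downstream stage consumes only peak markers and support
intervals, so the extra machinery of pseudomarker imputation would buy
essentially nothing here. The known cost is a small LOD underestimate
between widely spaced markers and at markers with missing genotypes (which
we drop per marker rather than impute). LOD is invariant under affine
transformations of the trait.

Genome-wide significance comes from permutations: the trait is shuffled
across mice, the genome rescanned, and the threshold is the empirical
`1 - alpha` quantile of per-permutation maximum LODs (default `alpha` 0.05,
1,000 permutations; below 100 the quantile is flagged as unstable). QTL
intervals are 1.5-LOD support intervals — the outermost markers within 1.5
LOD of the peak. The interval rule is a declared convention, not an attempt
to reproduce any particular published interval; published analyses rarely
state theirs.

eQTL peaks are recorded per gene *and per chromosome* (a gene may link to
both trait loci), kept when the peak LOD reaches the clinical trait's
genome-wide threshold, and classified **cis** when the peak sits on the
gene's own chromosome within 10 Mb of the gene (boundary inclusive) —
the field's conventional window — and **trans** otherwise. Overlap with a
trait interval is inclusive at both cM bounds. The per-locus count FDR
permutes mouse labels of the whole expression matrix jointly, which
preserves gene–gene correlation while severing all linkage; this is a
declared choice where the convention varies.

## The causality filter

Co-localization is not coupling: because the trait sits in a physiological
feedback loop, a gene linked to a trait locus can be **causal**
(L → G → T), **reactive** (L → T → G), or **independent** (L → G and
L → T with no mediation). Each topology is fitted as a Gaussian graphical
model by maximum likelihood — the locus always as a three-level factor —
and scored by BIC; the smallest BIC wins, and only causal or reactive
genes pass into network construction. Three details matter:

* the independent model carries an explicit residual-correlation
  parameter, so pleiotropy with correlated noise is not mistaken for
  mediation;
* BIC ties (margin < 1e-9) resolve to "independent", the conservative
  label;
* the likelihood/BIC formulation is itself a design choice: it is fully
  specified, deterministic, affine-invariant, and symmetric (swapping the
  roles of gene and trait exchanges causal and reactive labels), which the
  test suite exploits.

On synthetic triplets at n = 250 with locus effect 1 and mediation 0.7 the
classifier recovers each generating topology in ≥ 97% of replicates, and
its accuracy grows with sample size (checked at n = 100/500).

## Cross-group network and the TIE score

Genes surviving the filter for locus 1 and locus 2 are intersected with
the interactome; an edge qualifies iff its endpoints lie in different
groups, with genes linked to *both* loci belonging to both groups (so an
edge between two such genes qualifies). The cross-group frequency reported
alongside is `100 · edges / (|group1| · |group2|)` — the denominator
deliberately counts both-linked genes in both groups, matching the
published counting convention for these networks even though it
double-counts shared-gene pairs; fidelity beats elegance here.

Expression enters the score min–max normalized per gene across the panel,
which absorbs any positive affine transformation of the raw scale (the
log-ratio units therefore never matter). For an edge (i, j) and mouse m the
**Interaction Potential** is the product Ẽ<sub>i,m</sub>·Ẽ<sub>j,m</sub>.
The product is our declared surrogate for the exact published functional
form (which we could not recover from the source text): it is the simplest
form proportional to the relative abundance of both partners, consistent
with mass-action association kinetics, and it vanishes when either partner
is at its panel minimum. `ip_form = "min"` and `"geomean"` are provided as
alternatives; conclusions on the synthetic architecture do not change.
The modelling assumptions are explicit and strong: transcript abundance
proxies protein abundance, and binding affinities and post-translational
states are constant across the panel.

**TIPC** is the Pearson correlation between an edge's IP profile and the
trait over pairwise-complete mice (minimum 3; degenerate profiles score 0
rather than being dropped, so degrees stay stable). A gene's **TIE score**
is the mean of |TIPC| over its cross-network edges, set to exactly 0 below
5 interactions — small neighborhoods make the mean unstable, and the hard
zero matches the published rule. The absolute value is essential: strong
*negative* regulators are exactly the candidates of interest. The mean
(rather than the sum) keeps TIE within [0, 1] and lets a low-degree gene
with uniformly strong edges outrank a promiscuous one — the published
rankings show precisely that non-monotonicity in degree. An exponent on
|TIPC| is configurable (default 1). Significance: every gene's expression
row is permuted across mice independently, all TIE scores recomputed, and
`p = (1 + #{TIE_perm ≥ TIE_obs}) / (n_perm + 1)` per gene (default 1,000
permutations; unscored genes get p = 1). Per-gene nulls are the default;
pooling nulls across genes of equal degree would be the natural variant
but is not what the permutation scheme above produces.

## The synthetic study and what it does (and does not) show

The generator emulates the study design the package targets: 250 F2 mice
(single sex), 19 autosomes of mouse-like cM lengths carrying ~2,000 evenly
spaced markers (~2 Mb/cM), meiosis simulated as a Markov chain with
Haldane's map function (no interference; Kosambi would be a one-line
swap), trait loci on chromosomes 2 (70 cM) and 19 (30 cM). Expression and
trait are standardized, so effects are in correlation units:

* a hub gene driven by both loci (effects `sqrt(0.10)/0.6` ≈ 0.53 and
  `sqrt(0.08)/0.6` ≈ 0.47, BTBR alleles increasing expression) that drives
  the trait with `gamma_hub = -0.6`;
* no direct locus→trait effects by default (`beta1 = beta2 = 0`): the two
  trait QTLs are wholly hub-mediated and explain ~10% and ~8% of trait
  variance, and conditioning the scan on hub expression abolishes both —
  the mediation signature the conditional scan is designed to detect;
* cis genes at their own markers and trans genes responding to locus 1,
  locus 2 or both (standardized eQTL effect 0.5), placed away from the two
  QTL chromosomes so their linkage is genuinely trans; reactive genes
  driven by the realized trait (effect 0.5); pure-noise genes; 311 genes
  in all;
* a planted PPI: the hub wired to 10 genes per locus group plus 400
  background edges sampled uniformly over non-hub pairs.

Everything is a pure function of the configuration and its seed, and a
truth record (roles, hub id, realized sequential variance fractions)
accompanies each panel. Under these defaults the hub is recovered at rank
1 with the minimum attainable permutation p in ≥ 90% of seeded replicates
(100% in the runs shipped with the package), at a problem size —
20 replicates, 200 TIE permutations, 200 threshold permutations — chosen
so the full validation battery completes in about a minute.

What passing these tests does *not* show: the generator has linear,
homoscedastic, Gaussian effects, a single planted hub, no epistasis or
dominance-only architecture, no sex effects, no X chromosome, no
cross-tissue coupling, and background PPI edges wired uniformly rather
than with the heavy-tailed degree distribution of real interactomes. Real
expression data bring correlated noise, batch structure and mixed cell
populations that none of this emulates; the synthetic results validate the
*machinery* (formulas, calibration, recovery under the assumed model), not
the biological reliability of any particular ranking.

## Numerical choices and degenerate inputs

* Scans floor `RSS_full` at `1e-12 · RSS_null` (capping LOD at `6n`
  rather than returning Inf on perfect fits) and return 0 for monomorphic
  markers and zero-variance trait subsets; markers with fewer than 10
  complete mice are dropped with a warning.
* Threshold quantiles use the type-1 (inverse-ECDF) definition, so
  `alpha = 1` returns the minimum permuted maximum exactly.
* Correlations everywhere use pairwise-complete observations with a
  minimum of 3; constant vectors yield 0 (flagged) in TIPC contexts and NA
  in reporting contexts.
* Constant expression rows are excluded from normalization (flagged, their
  edges scoring TIPC 0) and skipped in eQTL scans with a warning.
* The residual correlation in the independent causality model is clamped
  to ±(1 − 1e-12) before the log-likelihood.
* Ranking ties break by degree (descending), then gene id — deterministic
  output for identical inputs.
* Missing genotypes: per-marker complete case. Missing expression or trait
  values: pairwise complete within each correlation. Neither is imputed;
  with the ~20% per-marker missingness cap the complete-case loss is
  modest, and imputation would entangle the permutation nulls.

## Reproducibility

Every stochastic stage takes a seed; pipeline runs derive per-stage
streams from one master seed, and rerunning a configuration is
byte-identical. `scripts/acceptance.R --seed S --out f.json` regenerates
the full validation battery — count-arithmetic checks, hub recovery,
conditional-scan mediation, classifier accuracy, family-wise error and
permutation-p calibration, and brute-force oracle agreement for the scan,
TIPC and TIE paths — from nothing but the installed package and the seed.
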