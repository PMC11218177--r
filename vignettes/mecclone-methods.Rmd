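---
title: "Clonal origin analysis of multifocal tumor pairs: models and methods"
author: "mecclone authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal origin analysis of multifocal tumor pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecclone)
```

## The scientific question

When a patient presents with two spatially separate tumor foci in the
upper gastrointestinal tract, the pair may have arisen in two ways:

* **multicentric origin (MC)** — two independent clones, each the product
  of its own transformation event. Their somatic variant sets are
  essentially disjoint;
* **metastatic origin (ME)** — one clone seeded the other, so both foci
  inherit a large *trunk* of shared somatic variants on top of private
  *branch* variants.

The distinction matters clinically (staging, therapy selection, and
whether the lesions can be treated as one cancer), and it is decidable
from paired-focus sequencing: in published multifocal esophageal/cardiac
cohorts the shared somatic fraction is 0--2.7% for independent pairs and
58--67.6% for metastatic pairs, with nothing in between. `mecclone`
implements the complete analysis around that signal, together with a
synthetic cohort generator that reproduces those study conditions so
every stage runs, end to end, without access to protected patient data.

## Sharing classification with read-level rescue

Variant callers under-call near the detection limit, so comparing two
foci by their call sets alone overstates heterogeneity. The classifier
therefore revisits the read evidence of the partner focus at every called
site:

1. **rescue (shared)** — a single high-confidence read carrying the
   alternative allele in the partner sample makes the site shared;
2. **LOH guard (excluded)** — a would-be-unique site lying inside a
   partner loss-of-heterozygosity segment is excluded: one cannot
   distinguish a truly private variant from one deleted together with its
   allele;
3. **unique** — the partner shows only reference bases.

Rule 1 takes precedence over rule 2 (observed alternative reads beat the
possibility of loss). Sites additionally require a total depth of at
least 10 reads in both the calling tumor and the matched normal
(inclusive), and high-quality alternative support in the calling focus.
"High quality" is not standardized; we use `alt_depth >= 3` and a PASS
filter status, configurable via `hq_min_alt`. Variants lacking that
support are tallied with the coverage failures so the five category
counts always partition the union of analyzed sites.

The shared fraction is Jaccard-style: shared over the union of shared and
(both-sided) unique variants, restricted to nonsynonymous exonic/splicing
SNVs and indels. LOH-excluded and gate-failed sites leave both numerator
and denominator. The channel fractions for copy-number genes (direction
must agree: gain/gain or loss/loss) and structural variants (same type,
both breakpoints within 10 bp, translocations orientation-agnostic) use
the same union denominator.

## Origin calling and the exact rank-sum test

With per-patient shared fractions in hand, origin calling is a threshold
decision. The reported bands leave a 55-point gap; we place the default
threshold at 0.10, comfortably inside it, and call a patient MC when the
fraction is strictly below threshold. A fraction exactly at the threshold
is called ME, because declaring two foci independent cancers is the
stronger clinical claim.

Group comparisons (MC vs ME on each channel) use a Wilcoxon rank-sum test
computed by full enumeration: all `choose(n1 + n2, n1)` assignments of
the pooled mid-ranks, two-sided p-value `min(1, 2 * min(P(W <= w),
P(W >= w)))`. At desk scale (10 patients) the exact null is cheap and has
none of the approximation error of the normal form. For reference, a
complete 6-vs-4 separation gives exactly `2/210 ≈ 0.0095`; normal
approximations with continuity correction report about 0.02 for the same
configuration, which explains why published analyses of identical designs
can print larger p-values. Above a pooled size of 20 the implementation
falls back to the tie-corrected normal approximation and says so in its
`method` field.

## Germline filter cascade

Germline susceptibility screening keeps variants that are (i) adequately
covered (depth ≥ 10), (ii) rare — maximum population allele frequency
across dbSNP/1000 Genomes/ExAC at most 0.001, with a *rescue* for
variants recorded in COSMIC, whose cancer recurrence outweighs their
population frequency; (iii) protein-affecting — exonic or splicing and
not synonymous ("noncoding" is read as everything outside those two
region classes, so UTR and ncRNA variants drop here); and (iv) outside
genomic repeat regions. Missing allele frequencies count as 0 (novel);
missing depth is its own drop category. Rules (ii)--(iv) commute — the
retained set is order-independent — but drop attribution follows the
stated order, first failing rule wins.

Retained genes are screened against a Cancer Gene Census list and counted
per functional category (immune, cell cycle, proliferation, DNA repair,
adhesion). The gene-to-category table is deliberately a configuration
input: the category concept is standard but no canonical gene lists
exist, so the package ships a small curated table and accepts
replacements. Category enrichment is a hypergeometric upper tail per set
with Benjamini--Hochberg adjustment across sets.

## Clonal structure: a finite binomial mixture as a PyClone stand-in

Cancer cell fractions are estimated by inverting the standard
allele-sampling model,

`ccf = vaf * (purity * CN + (1 - purity) * 2) / (purity * multiplicity)`,

capped at 1.5 (values above 1 indicate copy-state misspecification, not
biology; the cap keeps them visible without letting them dominate).
Multiplicity is 1 outside gains and `round(vaf * CN / purity)` clipped to
`[1, CN]` inside them.

Full Dirichlet-process clustering is replaced by a finite binomial
mixture over alternative read counts: component *k* gives mutation *i* a
success probability `ccf_k * f_i`, where `f_i` is the mutation's
CCF-to-VAF conversion factor. EM with k-means++-style seeding is run for
`K = 1..6` with 50 restarts (defaults), and K is chosen by BIC with
`2K - 1` parameters. This is deterministic given a seed, runs in seconds
per focus, and produces the same qualitative output — the number of
clones and their CCF means — which is all the downstream analysis
consumes. It is a stand-in, not a reproduction: it has no Dirichlet prior
and no MCMC posterior.

Numerical choices: the E-step works in log space with a row-wise
log-sum-exp; the M-step maximizes each component's weighted binomial
likelihood exactly (the objective is concave in the CCF, so a moment
start plus a few Newton steps converges; the search interval keeps the
success probability strictly below 1). Convergence is declared when the
log-likelihood changes by less than `1e-8` in relative terms, with a
500-iteration cap; component weights are floored at `1e-12` to avoid
degenerate log terms. Ties in BIC resolve to the smaller K. Fewer than 5
mutations yield a single cluster with a warning rather than a fit.

A focus is *monoclonal* when K = 1. A mutation is *key* when its cluster
mean CCF is at least 0.5 — cluster mean, not raw per-mutation CCF,
because the clone is the unit of interpretation — and it is predicted
deleterious: SIFT ≤ 0.05 or PolyPhen-2 ≥ 0.957, both bounds inclusive,
missing scores never qualifying. Driver recurrence reports, per gene, the
foci with a key mutation over the foci with any mutation.

## CNV, LOH and neoantigen recurrence

Segments are 0-based half-open with integer copy number, B-allele
frequency (≤ 0.5), and a genotype string. Status is ploidy-relative
(gain above, loss below, default ploidy 2); LOH is a genotype with
exactly one distinct allele symbol and at least one copy — this includes
copy-neutral LOH (`AA` at CN 2) and hemizygous deletion (`A` at CN 1).
Gene overlap uses any-overlap (≥ 1 bp), matching how recurrent-gene
figures are usually labeled; reciprocal-overlap refinements are out of
scope. Recurrence cutoffs read "more than 2 foci" literally as ≥ 3,
exposed as `min_foci`.

Neoantigen candidacy takes the affinity table as input (HLA typing and
binding prediction are upstream tools) and keeps records with mutant
affinity strictly below 500 nM and strictly below the wild-type peptide.
Recurrence counts distinct foci per mutation, multiple peptides in one
focus counting once.

## What the synthetic cohort emulates — and what it does not

The generator is the package's study-conditions definition, not a tuning
dial. The packaged fixture encodes 10 patients sequenced at 50× tumor /
30× normal with purity 0.8: six MC-like entries with target shared
fractions {0, 0.004, 0.009, 0.013, 0.018, 0.024} — inside the reported
0--2.7% band, with the largest target kept below the band edge because
LOH exclusions shrink the denominator and push realized fractions a few
tenths of a percent above target — and four ME-like entries at {0.58,
0.61, 0.65, 0.676}, the reported band endpoints plus two interior points.
The trunk size solves `s / (2n - s) = target` (floor for MC, ceiling for
ME, so realized fractions cannot leave their bands in the wrong
direction). Per-patient somatic burden is not reported in the source
cohorts; the default of 200 nonsynonymous somatic variants per focus is a
placeholder of realistic order for esophageal tumors, exposed in the
config.

Read depths are Poisson around the configured means and alternative
counts Binomial at the expected VAF given CCF, purity and local copy
number — the standard allele-sampling model, needed because no deeper
read model is specified anywhere. Truth-shared variants are guaranteed at
least one alternative read in both foci; truth-unique variants have none
in the partner unless deliberately planted inside a partner LOH region
(two per focus by default) to exercise the exclusion rule. LOH regions
(1--12 Mb) live on a gene-sparse contig so that only planted variants
fall into them; CNV loss segments elsewhere also count as LOH, so a few
additional exclusions arise naturally. Cluster structure per focus is
1--3 clones with CCF menus {1.0}, {1.0, 0.4}, {1.0, 0.55, 0.25}; trunk
variants and planted drivers are always clonal. Driver hotspots (TP53
always, MUC16 and DGKZ with probabilities 0.7 and 0.5) are shared across
patients but deliberately distinct between the two foci of one patient,
reflecting the observation that recurrent driver genes are hit at
different sites in paired independent foci; this also makes cross-focus
neoantigen recurrence attainable. Germline totals have equal group means
(about 60 retained variants per patient) while immune-category counts
separate the groups (MC 8--13 vs ME 2--5), plus engineered noise sets
that fail exactly one filter rule each. Affinities are log-uniform in
[10, 5000] nM with driver records forced below 500 nM and below wild
type.

The generator does **not** emulate: sequencing error or mapping artifacts
(every emitted alternative read is real support), realistic chromosome
coordinates (a toy genome of eight 40 Mb contigs), mutational signatures,
subclonal copy number, kataegis, or correlated germline haplotypes.
Passing tests therefore demonstrate that the *inference machinery* is
correct under the stated statistical model — they do not certify
performance on noisy real pileups, where the high-quality-read definition
and the coverage gate carry more weight.

## Problem sizes and determinism

The packaged analyses run the 10-patient fixture (about 420 somatic
calls, 1,260 evidence rows, 116 germline variants per patient); the
clustering stage fits 20 foci of ~210 mutations each, the dominant cost
(a few minutes with default restarts). Every stochastic step draws from a
per-patient seed derived from the cohort base seed, so cohorts are
byte-identical across reruns and every pipeline output is reproducible
from `base_seed` alone. Test fixtures use smaller cohorts (40--100
variants per focus) and fewer EM restarts; the statistical checks
(band membership, rank-sum exactness to 1e-12, cluster-count recovery in
≥ 90% of seeds) are unchanged by this scaling.

## Known limitations

* The origin threshold (0.10) is a design choice inside an empirically
  empty interval; cohorts with intermediate sharing (e.g. late
  metastatic seeding) would need a calibrated decision rule.
* The mixture stand-in underestimates cluster-count uncertainty relative
  to a Dirichlet-process posterior; K is a point estimate.
* The sharing classifier trusts the partner pileup: contamination or
  index hopping would masquerade as sharing. Real-data use should gate on
  the high-quality flag from a caller-aware pileup.
* Enrichment uses a flat gene-set table, not an ontology DAG; p-values
  between overlapping sets are not decorrelated.
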