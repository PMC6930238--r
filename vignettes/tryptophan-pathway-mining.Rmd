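---
title: "Mining gut-bacterial tryptophan catabolism: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gut-bacterial tryptophan catabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tryptomine)
```

## The problem

Gut bacteria catabolize dietary tryptophan into a family of neuro-active
compounds — kynurenine, quinolinate, indole, indole acetic acid (IAA),
indole propionic acid (IPA) and tryptamine — that can signal along the
gut–brain axis. Whether a given strain can produce a given compound is, to
a first approximation, a genome-annotation question: does the genome
encode the characterized enzymes of the route? `tryptomine` makes that
question operational as a declarative rulebook applied to standard
annotation products, then aggregates strain answers into genus-level
potential scores and connects them to case/control microbiome shifts.

This vignette explains the model, its assumptions and every numeric choice
a user might want to revisit.

## Evidence model and the six rules

Three evidence primitives underlie all rules, chosen per pathway by how
specific the available signals are:

1. **Domain presence.** Some routes have an enzyme whose Pfam functional
   domain occurs (essentially) nowhere else. Kynurenine is predicted from
   the tryptophan 2,3-dioxygenase domain Trp_dioxygenase (PF03301) alone;
   quinolinate from the conjunction of 3-HAO (PF06052, enzyme HAD),
   FAD_binding_3 (PF01494, KMO) and Aminotran_5 (PF00266, KYN) — those
   three genes are not reliably clustered across producers, so no
   proximity condition is imposed. A domain counts when a hit matches the
   accession (version suffixes ignored) with independent e-value at or
   below `domain_evalue_max`.

2. **Whole-protein homology.** Tryptophanase's domain (Beta_elim_lyase)
   occurs in many unrelated enzymes, so indole is instead called from a
   BLAST homolog of a characterized tryptophanase. The same logic covers
   IAA (tryptophan 2-monooxygenase *or* indolepyruvate decarboxylase —
   alternate routes characterized in different organisms, so the rule is a
   disjunction) and tryptamine (tryptophan decarboxylase homologs from two
   characterized producers, pooled so a hit to either query counts). Hits
   pass at identity ≥ 70 %, query coverage ≥ 90 % and e-value ≤ 1e-5; all
   boundaries inclusive, the conventional reading of a "threshold".
   Coverage is computed as `100 · min(alignment_length, query_length) /
   query_length` because the 12-column BLAST tabular format carries no
   coverage column; the clip at 100 handles gapped local alignments longer
   than the query.

3. **Gene-cluster proximity.** The IPA route requires five co-located
   genes (phenyllactate dehydratase FldABC, its activator FldI and the
   AMP-binding FldL). The rule demands the domain evidence for all five
   roles *and* a window on one contig in which consecutive member genes
   are separated by at most `proximity_max_gap` intervening genes. Gaps
   are counted in genes, not base pairs: this is robust to intergenic
   length variation, and no distance in nucleotides is canonical for
   "operonic". The default window of 3 intervening genes is a standard
   operon heuristic; it is a package decision, configurable per catalog.
   Strand agreement is *not* required for the five-gene locus (mixed-
   strand arrangements of accessory genes are common), but it *is*
   required for the TnaB screen below, where the biology is explicitly
   operonic.

The rulebook ships as `default_catalog()` and is overridable field-by-field
from a YAML file (`load_catalog()`), so curated Pfam accessions or extra
homolog queries can be dropped in without code changes. The Fld* and TnaB
accessions and all homolog query tags in the shipped catalog are synthetic
placeholders (PF9xxxx series, `tnaA_ECOLI`-style names): they make the rule
engine fully testable and are expected to be overridden with curated values
for production use on real genomes.

Two scoping decisions mirror the biology rather than convenience: the
kynurenine call requires the TDO domain only (not kynurenine formamidase,
whose gene is not consistently co-located in characterized producers), and
the quinolinate call does not additionally require TDO — downstream-route
genes occur in genomes lacking the upstream precursor enzyme, consistent
with cross-feeding of intermediates between community members.

## Transporter screen

Indole producers are additionally screened for three tryptophan importers.
TnaB's gene is operonic with the tryptophanase gene *tnaA*, so TnaB is
called only when a gene carrying its functional domain lies on the same
strand within the proximity window of a passing tryptophanase homolog.
AroP and Mtr are generic permeases detected by homology under the same
thresholds as the pathway rules. The screen is restricted to indole
producers by default — the anchor gene only exists there, and that was the
population of interest — with `restrict_to_indole = FALSE` available to
widen it.

## The genus score

For genus *j* and metabolite *i*:

$$\mathrm{SCORBPEO}_{ij} = P \cdot \alpha \cdot \beta, \qquad
P \in [0,1],\; \alpha \in \{1..10\},\; \beta \in [1,5]$$

so the raw score spans 0–50 and is rescaled linearly (division by 5) to the
reported 0–10 scale.

* **P** is the proportion of the genus's strains called positive.
* **α (confidence)** rewards well-sampled genera: the genus's strain count
  is turned into an inclusive percentile among all genera
  (`100 · #{genera with count ≤ own} / #genera`) and ceiling-mapped to
  deciles 1..10. The inclusive-decile mapping is the simplest monotone
  scheme that gives the best-represented genus the full rank of 10 and a
  lone genus (percentile 100) likewise 10. Ties in strain counts share a
  rank, as a percentile should.
* **β (gut weightage)** rewards gut enrichment. With gut prevalence
  `g = n_gut_with/n_gut` and non-gut prevalence `h = n_other_with/n_other`
  (a prevalence is 0 when its denominator is 0), the gut share
  `s = g/(g+h)` (0 when both are 0) is mapped affinely to `β = 1 + 4s`.
  This form is bounded, symmetric (equal prevalence gives the midpoint 3),
  maximal (5) when the pathway occurs only in gut strains, and degrades
  gracefully when a genus has no non-gut strains (then `h = 0`, so any gut
  occurrence yields 5 and absence yields 1).

Both mappings are package design choices: a percentile-to-rank rule and an
enrichment-to-[1,5] rule must be chosen to make the score concrete, and
several monotone alternatives exist. The two used here are recorded in the
pipeline's run log so downstream users can tell exactly which variant
produced a matrix. Useful consequences, all tested: the rescaling is exact
(`score = raw/5`), `score = 0` exactly when `P = 0`, and the score is
strictly increasing in each factor when the others are positive.

## Case/control stage

Abundance tables are normalized to relative abundances per sample (the
only normalization applied; rarefaction is deliberately not). Per genus,
case and control samples are compared with the two-sided Wilcoxon rank-sum
test; genera at raw p ≤ 0.01 are kept. No multiple-testing correction is
applied — the threshold is used as a raw screening rule — and the
two-sided default is the neutral reading when no direction is
pre-specified. The test is delegated to `stats::wilcox.test`: exact by
enumeration when the combined sample size is ≤ 20 without ties, otherwise
the normal approximation with tie-corrected variance and continuity
correction (the realistic branch for cohort-sized groups, since relative
abundances of count data tie frequently). The reported statistic is the
rank-sum `W` of the case sample. Direction comes from group medians (means
break median ties; a full tie is flagged ambiguous rather than guessed).

Each retained genus contributes one Sankey edge per metabolite with a
positive score, weighted by the score; zero-score pairs emit no edge. The
edge list is written as a deterministic JSON nodes/links document that any
Sankey renderer can consume.

Note one statistical caveat the synthetic tests make visible: relative
abundances are compositional, so a strong planted shift in one genus
induces opposite shifts in others (exactly, when only two genera exist).
The differential stage reports what the data show; interpretation of
secondary, compositionally induced hits is the analyst's.

## What the synthetic generator emulates — and what it does not

`make_collection()` draws strain-level pathway presence from per-genus
gut/non-gut prevalences and emits gene tables, domtblout-style domain hits
and outfmt-6 homology hits that satisfy the default catalog's rule for each
planted pathway *minimally*: deleting any single planted evidence item
flips that call (verified by mutation tests). Planted evidence sits far
from the thresholds (identity 95, coverage 100, e-values ≤ 1e-25) so that
rule-logic tests are not entangled with boundary behavior; dedicated
boundary fixtures sit exactly at 70/90/1e-5. Decoy evidence — Pfam
accessions referenced by no rule, hits to an unused query, sub-threshold
hits to a real query — exercises specificity. The default prevalences
(indole 0.6 gut / 0.3 non-gut, IAA 0.4/0.3, the kynurenine-route and
tryptamine pathways 0.3/0.2, IPA 0.15/0.05) reproduce the qualitative
gradient observed across gut bacteria: indole most widespread, the
clustered IPA locus rare.

`make_abundance_study()` uses a log-normal composition model: per-genus
baseline log-abundances drawn once from N(0, 1), per-sample noise N(0,
0.5), case compositions of effect genera multiplied by their fold change
before renormalization, then scaling to a uniform 20,000–50,000 depth and
rounding. A within-group log-SD of 0.5 represents moderate biological
variability at genus level; under the default design (20 genera, two
4-fold effect genera, 15 vs 15 samples) the rank-sum screen at p ≤ 0.01
then recovers the planted genera with per-genus power ≈ 0.99, so planted
structure is reliably visible to the tests.

What passing these tests shows is that the pipeline's logic is correct:
calls equal the planting plan, filters equal their predicates, windows
equal exhaustive enumeration, p-values equal enumeration oracles. What it
does not show: performance on real genomes (annotation quality, split
contigs, paralog confusion), realistic phylogenetic correlation between
strains, overdispersion and zero-inflation of real 16S counts, or the
adequacy of the placeholder accessions — those must come from curated
catalogs and real data.

## Numerical and degenerate-input choices

* Gene order ties (identical start) break by end, then gene id, so ranks —
  and therefore every proximity result — are deterministic.
* Cluster windows are *minimal*: no proper sub-window also covers all
  roles; candidate genes on the required strand (when strandedness is on)
  are grouped into chains before the two-pointer scan, so other-strand
  genes count only as intervening genes.
* An empty candidate set for any cluster role short-circuits to "no
  cluster".
* `filter_homology_hits` preserves input order and is a pure filter:
  idempotent, monotone under threshold loosening.
* All-zero abundance samples are a hard error (they cannot be normalized),
  as are samples without a group label and negative counts.
* Genera whose strains disagree on phylum are rejected at manifest load:
  genus-level aggregation needs a single taxonomy path.
* Problem sizes in the shipped tests — a 40-strain collection (5 genera ×
  8 strains), 30-gene contigs for window enumeration, 8-vs-8 exact-test
  oracles, a 100 × 100 null grid for the type-I check — were chosen as the
  smallest designs in which every behavior of interest (per-phylum
  structure, multi-chain windows, exact-branch discreteness) actually
  occurs.

## Known limitations

* Published per-genus score values cannot be reproduced without the 2019
  genome snapshot they were computed on; the package ships the machinery,
  not that corpus, and its analytic guarantees (score bounds, rule logic,
  test behavior) are what the acceptance checks verify.
* The α and β mappings are one consistent instantiation of
  "percentile-derived rank" and "gut enrichment on 1–5"; alternatives
  would change score magnitudes (not orderings within a factor). They are
  pluggable via the exported functions and recorded in the run log.
* Homology evidence treats any passing hit as sufficient; no
  reciprocal-best or synteny checks are applied.
* The differential stage models no covariates and applies no multiplicity
  correction, by design fidelity; treat its output as a screen, not
  confirmatory inference.
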