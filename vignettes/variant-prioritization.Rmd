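---
title: "Prioritizing structural and intronic variants in inherited retinal disease cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing structural and intronic variants in inherited retinal disease cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irddx)
```

## The model

`irddx` implements a rule-based prioritization of whole-genome variant
calls for Mendelian retinal disease. The underlying model is the
standard one for rare monogenic disorders: in each family a single gene
carries a genotype of large effect — one dominant allele, two recessive
alleles (homozygous or compound heterozygous in trans), or a hemizygous
X-linked allele in males — and that genotype is (i) technically
trustworthy, (ii) rare in unaffected populations, (iii) predicted to
disrupt the gene product in the disease tissue, and (iv) consistent with
the segregation of disease in the family. The pipeline applies these
four requirements as successive filters and reports, per variant, the
first stage that eliminated it. All assumptions are the classical ones:
full penetrance (an unaffected carrier of a complete causal genotype
falsifies the hypothesis), locus homogeneity within a family, and
independence of the two recessive alleles.

The distinctive element is tissue-aware SV interpretation. Because genes
often express several transcripts at very different levels in retina, an
SV that truncates only a marginal isoform is poor evidence of disease.
For an SV in gene $g$ with transcripts $t$ of retinal expression
$\mathrm{TPM}_t$, the transcript disruption ratio is

$$ \mathrm{TDR} = \frac{\sum_{t\,\text{disrupted}} \mathrm{TPM}_t}
                       {\sum_{t \in g} \mathrm{TPM}_t} \in [0, 1], $$

and SVs with $\mathrm{TDR} < 0.20$ are excluded as benign. A deletion or
duplication disrupts a transcript when it overlaps any of its exons. For
inversions the package uses its own documented rule (the source analysis
defines disruption only implicitly): an inversion disrupts a transcript
when it touches an exon or places a breakpoint strictly inside the
transcript span, *unless* it contains the transcript entirely — a fully
contained transcript is relocated intact. The same logic motivates the
classification rule that an exon-overlapping inversion spanning the
whole gene is not called pathogenic. Duplications currently share the
deletion disruption rule; this is flagged to users because a full-gene
duplication need not ablate expression (no pathogenic duplication was
observed in the motivating data, so the choice is untested in practice).

## Parameters

All cutoffs live in `threshold_config()`; each is used with a *strict*
comparator in the printed direction, so boundary values pass:

| parameter | default | units | role |
|---|---|---|---|
| `dp_min`, `dp_max` | 10, 400 | reads | genotype depth window |
| `gq_min` | 25 | phred | genotype quality |
| `het_ab_low/high` | 0.25 / 0.75 | alt fraction | het allele balance |
| `homref_ab_max`, `homalt_ab_min` | 0.1, 0.9 | alt fraction | hom allele balance |
| `inbreeding_min` | −0.3 | — | site inbreeding coefficient |
| `hwe_min` | 1e−6 | p | Hardy–Weinberg |
| `af_max` | 0.01 | frequency | rarity, in **every** panel |
| `sv_overlap_min` | 0.8 | fraction | SV consolidation/matching |
| `spliceai_min` | 0.5 | delta score | splice-effect evidence |
| `cadd_min` | 20 | scaled | deleteriousness evidence |
| `deep_intron_bp` | 100 | bp | deep-intronic boundary |
| `tdr_min` | 0.20 | fraction | benign-SV exclusion (strictly below) |
| `benign_panel_min_samples` | 2 | carriers | benign SV set |

Two conventions were genuinely open and are configurable:

* **SV overlap denominator.** "Greater than 80% overlap" does not say
  whether the fraction is reciprocal or query-relative. The default is
  reciprocal relative to the *longer* interval — the stricter convention,
  under which matching is symmetric — with `sv_overlap_denominator =
  "query"` available.
* **SV allele frequency.** Panels supplying allele counts give
  AF = AC/AN; panels supplying only carrier counts fall back to carrier
  frequency with a logged caveat (an upper bound on AF when carriers may
  be heterozygous).

Coordinates are 1-based and fully inclusive everywhere internally
(`chr4:633534-637421` has length end − start + 1), with explicit tested
converters at the VCF (1-based) and BED (0-based half-open) boundaries.
Exon distance for the 100 bp deep-intronic rule is computed against the
union of exons of **all** transcripts of the gene — the conservative
reading of "the nearest exon" — and is gene-local: exons of other,
overlapping genes are not considered. The canonical splice site is taken
as the ±2 intronic dinucleotide; intronic positions 3–99 bp from an exon
are non-canonical splice-site territory. Strand affects cDNA-style
labels only, never distances or overlaps.

## Segregation semantics

* Dominant: every genotyped affected carries the allele, no genotyped
  unaffected relative does; de novo is allowed (parents need not carry).
  No reduced-penetrance allowance is made — an unaffected carrier always
  falsifies the hypothesis.
* Compound heterozygous: "not carried by unaffected relatives" is
  interpreted as *no unaffected relative carries both alleles*; an
  unaffected parent carrying exactly one is the expected recessive
  carrier state. With both parents genotyped, two alleles inherited from
  the same unaffected parent fail as cis (that parent carries both);
  without genotyped parents the pair passes flagged `phase_unresolved`.
* X-linked: carrier females are exempt from the dominant-style
  exclusion; unaffected males must not carry; an affected female fails
  the hemizygous model with `mode_inconsistent`.
* Competing hypotheses are ranked by segregation evidence (full
  pedigree support before sporadic/phase-unresolved), then by summed
  severity rank of the variants (truncating > splice > exonic SV >
  missense > intronic); ties across genes are all reported and flagged
  ambiguous. A gene may support dominant and recessive hypotheses in
  different families; the mode is resolved per family, never globally.
* Mitochondrial inheritance is out of scope.

Reported percentages round half up to the nearest integer (34/271 →
13%), matching the convention of the summaries the package reproduces.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates trio/quad families over a fixed synthetic
gene world: ten genes across several chromosomes (including one
X-linked), each with a highly expressed main transcript (TPM ~
U(50, 200)) and a low-TPM minor isoform (U(0.1, 2)) owning a private
tail exon. These ranges are chosen so that a main-exon SV always has
TDR ≥ 50/202 ≈ 0.25 (above the 20% cutoff) and a tail-exon-only SV
always has TDR ≤ 2/52 ≈ 0.04 (below it), i.e. the generator states a
world in which the published threshold separates the two populations the
way the motivating analysis observed. Each family receives one causal
configuration from seven modes (dominant SV, homozygous recessive SV,
compound-het SNV+SV, compound-het SV+SV, X-linked hemizygous deletion,
homozygous recessive deep-intronic SNV, dominant intronic SNV) and
decoys covering every rejection route: common SVs/SNVs present in the
panels at AF ≥ 1% (emulating population-specific AF sharing: panel AFs
differ between the large European-like and smaller East-Asian-like
panel), rare minor-isoform SVs (TDR), a rare exonic SV shared with the
unaffected father (segregation), a rare nonsense call at DP 5 (QC), and
a rare missense below both CADD and EVE evidence (classification).
Reference panel sizes default to 831 and 196 individuals, matching the
two reprocessed population sets of the motivating study.

The simulator works at the variant-record level: annotation scores
(CADD, SpliceAI, EVE) are generated attributes, not computed from
sequence, because the pipeline consumes them as external annotations.
Consequently a green end-to-end test establishes that the *filtering
logic* is faithful — that planted causal genotypes survive every stage
and each decoy dies at its designated stage — not that the upstream
callers or annotators would produce such records from reads. Features of
real data the simulator does not emulate include: multi-allelic sites
(assumed decomposed upstream), mosaicism and reduced penetrance,
SV breakpoint uncertainty, LCR site annotations (absent by default, so
that check is skipped with a notice), and linkage between background
variants.

## Numerical and degenerate-input choices

* TDR of an unexpressed gene (total TPM 0) is defined as 0 with a
  warning and the SV is excluded — no expression, no evidence of
  disruption.
* TDR exactly 0.20 retains; exclusion requires strictly "below 20%".
* `is_rare()` with no configured panels is an error, not a default.
* Insertion/breakend SV records are rejected with a clear message:
  interval-overlap matching and the TDR rules are defined for DEL, DUP
  and INV only (the motivating findings involve only deletions and one
  inversion).
* A genotype failing QC is set to missing rather than dropping the
  site; a site is removed only when site-level QC fails or all its
  genotypes end up missing. `apply_qc` is idempotent.
* The benign-SV set applies the two computable criteria (exon overlap
  with a candidate gene; carried by ≥ 2 panel samples); the original
  protocol's third, manual IGV review, is recorded as not applied.
* `sample.int`-based offset sampling is used in property tests to avoid
  R's `sample(x:y)` scalar pitfall; all randomness is seed-controlled.

## Known limitations

* Compound-het phasing uses parental genotypes only; sibling-based or
  read-backed phasing is not attempted (`phase_unresolved` marks the
  gap).
* The per-row disease-group tallies follow the printed tables, so a
  gene observed under two phenotypes (e.g. a deletion dominant in a
  macular-dystrophy family and recessive in RP families) contributes to
  both groups, one row each.
* No phenotype-driven gene ranking: candidate genes come from the panel
  file, and competing genes are adjudicated only by segregation evidence
  and variant severity.
* The cohort-level diagnostic yield of the motivating study (34/271) is
  not recomputable without its deposited patient data; the package's
  empirical claims are confined to what its tests and acceptance script
  compute on the fixtures and simulations.
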