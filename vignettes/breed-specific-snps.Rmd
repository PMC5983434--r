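---
title: "Finding breed-specific SNPs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding breed-specific SNPs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(breedsnp)
library(dplyr)
```

## The problem

Cattle breeds have been under divergent artificial selection for centuries.
When many individuals of several breeds are sequenced and genotyped against
a single species reference, some variant sites are *fixed* for the
alternative allele within one breed while absent from all the others. Those
sites are the molecular signature of the breed, and substituting them into
the species reference yields a breed-specific reference genome — a better
template for alignment, imputation and association analyses within that
breed. `breedsnp` implements the discovery side of that programme: a
hard-filter cascade over per-breed multi-sample VCFs, a within-breed
fixation screen, cross-breed exclusivity logic, consensus construction, and
a compact coding-consequence classifier.

This vignette records the model assumptions, every tunable that matters,
the numerical conventions, and the design decisions taken where the
procedure was genuinely open.

## The site-filter cascade

Each breed's VCF is filtered independently, in a fixed order; every removed
record is labelled in the filter trace with the *first* predicate it
failed:

| stage | predicate (defaults) | trace label |
|---|---|---|
| 1 | exactly one ALT allele | `multiallelic` |
| 2 | variant class is SNP or InDel (MNPs removed) | `other_class` |
| 3 | DP4 alt-forward ≥ 1 **and** alt-reverse ≥ 1 | `strand` |
| 4 | QUAL ≥ 20, MQ ≥ 30 | `qual`, `mq` |
| 5 | 10 ≤ DP ≤ median(DP) + 3·SD(DP) | `depth_low`, `depth_high` |
| 6 | (contig, pos) unique | `duplicate_pos` |
| 7 | proximity rules (below) | `prox_*` |

Conventions worth pinning down:

* **Strand support** demands at least one alternative read on *each*
  strand, not a summed minimum: a variant never observed on both strands is
  discarded.
* **Depth ceiling.** The ceiling is estimated per input VCF from the
  records that survived stages 1–4, using the *sample* standard deviation
  (n − 1 denominator; the estimator is not dictated by the procedure, so we
  fix the unbiased one). DP is the site-level pooled depth across the
  breed's samples, because calling is done jointly per breed. Statistics
  are genome-wide, not per chromosome. With fewer than two usable depth
  values no distribution can be estimated and only the lower bound is
  applied.
* **Duplicate positions.** *All* members of a position collision are
  removed, including the first: two calls at one base pair are jointly
  untrustworthy.
* **Proximity** is a single pass over the post-deduplication set: a SNP is
  removed if any other SNP lies at distance < 3 bp or any InDel at < 5 bp;
  an InDel is removed if any other InDel lies at < 10 bp. "Closer than" is
  strict, so a pair exactly at the threshold survives. Distances use the
  VCF anchor position (`POS`) only — InDel spans are ignored, since no span
  convention is given by the procedure the cascade follows. Removals do not
  cascade: a SNP removed because of a nearby InDel still counts as a
  neighbour for other records in the same pass. A SNP near an InDel does
  not remove the InDel; InDel survival is governed solely by the
  InDel–InDel rule.
* **Missing annotations** (null QUAL/MQ/DP/DP4) fail their filter under the
  default strict policy; `site_filter_config(strict_missing = FALSE)`
  inverts this for call sets that omit an annotation entirely.

A note on idempotence: rerunning the cascade on its own output is a no-op
under realistic depth distributions (and is property-tested under the
synthetic generator's model), but it is not a mathematical identity —
removing extreme depth outliers shrinks the estimated SD, so a
sufficiently pathological depth mixture can lose further records on a
second pass. The pipeline applies the cascade exactly once, matching the
procedure it implements.

## Fixation within a breed

A site-filtered SNP is *fixed* in a breed when

* its genotype missingness over the breed's samples is **not higher than
  7%** (`max_missing_rate = 0.07`), and
* its alternative allele frequency among the non-missing genotypes is
  **exactly 1**.

Both criteria are evaluated in exact integer arithmetic: missingness as
`missing · 10^6 ≤ round(rate · 10^6) · n`, fixation as
`alt_count == 2 · called_count`. No floating-point tolerance is involved,
so 7 missing of 100 passes and 8 of 100 fails, by construction rather than
by luck of binary rounding. The two criteria interact: since AF is computed
over non-missing genotypes only, "fixed with ≤ 7% missing" means *every
observed genotype is homozygous-alternative*. (Counting missing genotypes
as reference would make AF = 1 unsatisfiable at any missingness.)
Genotypes are treated as unphased diploid autosomal calls; half-calls such
as `./1` count as missing. InDels never enter this stage — they exist in
the pipeline only to drive the proximity filter.

## Breed specificity and the Venn partition

Cross-breed identity is the exact `(contig, pos, ref, alt)` tuple: the same
position with a different alternative allele is a different variant,
because it is the allele that gets substituted into the reference.
`venn_partition()` assigns every key in the union of the per-breed fixed
sets to exactly one of the 2^B − 1 cells labelled by the subset of breeds
carrying it; `breed_specific_sets()` returns the singleton cells.
"Absent from the other breeds" means absent from the other breeds'
*fixed-SNP* sets — the semantics under which the partition of
post-filtration variants is drawn. Cells are disjoint by construction and
their counts sum to the union size; both properties are tested against a
per-key membership-vector oracle.

## Consensus references

`build_breed_reference()` substitutes single bases only: the template base
at each position must equal the variant's reference allele
(case-insensitively, but IUPAC ambiguity codes are a hard mismatch), and
the template's case is preserved so soft-masking survives. Sequence
lengths never change; InDels are never applied, as fixation filtering
yields pure substitutions and coordinate-shifting consensus is out of
scope. The substitution log and `diff_references()` are mutually inverse,
which the tests assert on random substitution sets, together with the fact
that applying the same set twice must fail the reference check.

## The consequence classifier

The annotator is deliberately small: CDS gene models from GFF3 (features of
type `CDS` grouped by `Parent`), the standard genetic code only, and the
reduced term vocabulary `synonymous_variant`, `missense_variant`,
`stop_gained`, `stop_lost`, `start_lost`, `splice_region_variant`,
`intron_variant`, `intergenic_variant`. The affected codon is rebuilt from
the template (reverse-complemented on the minus strand) and both codons
are translated; the splice region follows the Sequence Ontology convention
used by mainstream annotators — 1–8 intronic or 1–3 terminal exonic bases
of a CDS/intron junction — with donor/acceptor sub-terms collapsed into
the one label. One call is reported per variant, the most severe across
transcripts under the order `start_lost > stop_gained > stop_lost >
missense > splice_region > synonymous > intron > intergenic`; an exonic
splice-region hit is reported only when no protein-changing term applies.
UTR and regulatory vocabulary is intentionally collapsed into the
intron/intergenic bins. This is a stand-in for a full annotator, not a
claim of parity with one: strand symmetry and agreement with a
translate-both-codons oracle over all nine SNVs of every codon of a
fixture gene are the tested contract.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` stands in for a resequenced multi-breed bull cohort at
desk scale. Defaults: seven breeds with 10–20 samples each, two contigs
totalling 1.2 Mb, and per category

```{r}
str(cohort_config()[4:16])
```

* planted **breed-specific** SNPs (fixed in every sample of one breed,
  absent elsewhere), **shared** SNPs (fixed in all breeds),
  **partial-subset** SNPs (fixed in a named subset — pairs with a shared
  breeding history get the larger counts), and **segregating** SNPs
  (guaranteed ≥ 1 non-homozygous-alternative genotype);
* one decoy category per site filter (low QUAL, low MQ, strand bias, depth
  outliers, duplicated positions, SNP clusters at 2 bp, SNP–InDel pairs at
  4 bp, InDel pairs at 9 bp, multi-allelic sites). Decoys are planted in a
  *single* breed with fixed genotypes, so any leak through the cascade
  surfaces as a false breed-specific call in the end-to-end comparison.

Depths follow a negative-binomial-like model (mean 12, SD 4 — a plausible
mid-range genome coverage for such cohorts) clipped into the admissible
window for records meant to survive, while depth-outlier decoys sit at
mean + 12 SD; the generator verifies that the ceiling the cascade will
estimate separates the two groups and refuses to emit a cohort where it
does not. Missingness is injected per site below the 7% threshold
(default range 0–5%) and never into segregating records, so no planted
fate can flip. Planted units occupy 25 bp slots, guaranteeing ≥ 16 bp
between units so proximity interactions occur only within a unit. Short
two-exon ORFs (ATG … stop, alternating strands) are carved into the first
contig so consequence annotation has real coding sequence to hit.

What the generator does **not** model: linkage disequilibrium, demographic
structure, read-level errors, genotype-likelihood uncertainty, sex
chromosomes, or reference bias. A green end-to-end suite therefore shows
the *logic* is right — each filter removes exactly its targets and nothing
else, fixation and exclusivity are exact, consensus is faithful — not that
the thresholds are optimal for any particular real call set.

## Numerical conventions

* Report rounding is decimal **half-up** (`floor(x·10^d + 0.5)/10^d`):
  filtration percentages to 3 decimals, cohort composition to 2,
  consequence percentages to 1. Base R's round-half-to-even disagrees at
  some boundaries with the convention the published tables follow.
* Output ordering is always (contig, pos) lexicographic, making runs
  byte-identical; the pipeline manifest carries an MD5 checksum per
  artifact and the determinism is tested by rerunning into a fresh
  directory.
* The cascade's kept set is independent of input order (sorting is
  internal), and equality with an O(n²) all-pairs brute-force
  implementation is asserted over randomised fixtures of up to 200
  records.

## Problem sizes

The shipped tests run the full pipeline on the default cohort (seven
breeds, ~4,700 planted units, ~6,500 records across the breed VCFs) in
well under a minute, plus randomised property checks (100 oracle fixtures,
multi-seed determinism). These sizes were chosen so the whole suite
completes in about a minute on one CPU while still exercising every
category and code path; the generator scales linearly if larger cohorts
are wanted.

## Known limitations

* One VCF per breed is the only supported cohort layout; merging a joint
  VCF into per-breed files is out of scope.
* BCF, tabix indexing and genotype phasing are unsupported; `|` and `/`
  are read as equivalent.
* The depth ceiling assumes a unimodal genome-wide depth distribution;
  heavily heterogeneous coverage (e.g. mixed exome/genome) would warrant
  per-region statistics, which the configuration does not currently
  expose.
* The consequence classifier does not handle InDels, multi-nucleotide
  substitutions, selenocysteine recoding or non-standard codon tables, and
  its severity ordering is a pragmatic reduction, not an ontology import.
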