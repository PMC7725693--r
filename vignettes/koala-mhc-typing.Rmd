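---
title: "High-throughput MHC typing of koalas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-throughput MHC typing of koalas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

koalamhc implements an amplicon-sequencing workflow for profiling the
allelic diversity of six koala (*Phascolarctos cinereus*) MHC gene
targets — the classical class I genes UA and UC and the class II beta
genes DAB, DBB, DCB and DMB — from multiplexed 2×250 bp paired-end
Illumina reads, and the downstream analyses that validate and exploit
those profiles: Mendelian congruence checking in family units, haplotype
clustering, and allele–phenotype association tests. A simulator
generates pedigrees and reads with known truth so every stage can be
tested without sequencing data.

```{r setup}
library(koalamhc)
```

## The amplicon design and its consequences

Each gene target is a PCR amplicon spanning the receptor-binding groove
(exon 2), 200–397 bp including primers (`koala_loci()`). All six targets
are pooled per animal before barcoding, so a sample's read pair file
mixes loci; the PCR primer at the 5' end of each mate identifies its
target. Three structural facts drive the design of the calling rules:

* **Copy number.** DAB and DBB are present as three gene copies in the
  koala genome, so a single animal can legitimately carry up to six
  distinct alleles at those targets; UC, DCB and DMB are single copy
  (one or two alleles).
* **Co-amplification.** The UA primer pair also amplifies the
  paralogous UB gene. Because UA and UB alleles are too similar to
  assign to a gene of origin, the pipeline treats UA as one pooled
  target with an allele bound of four; the simulator reproduces this by
  generating two independent single-copy genes whose reads share the UA
  label (observed profiles then show 1–3, occasionally 4, UA alleles).
* **Overlap.** With 2×250 bp reads on amplicons of at most 397 bp, the
  mates always overlap, so a failed merge indicates a problem rather
  than an expected state.

## Read processing

`assign_locus()` matches both primers against the mate prefixes,
IUPAC-aware (the DAB reverse primer contains an R), allowing up to 2
substitutions per primer and no indels; ambiguous or unmatched pairs are
left unassigned. The tolerance is a package default: substitution-only
matching keeps trimming coordinates exact, and at 2 mismatches the six
primer pairs remain mutually distinguishable by a wide margin.

`trim_reads()` removes each mate's own primer from the 5' end and any
3' read-through into (or past) the reverse complement of the opposite
primer, using an adapter-style scan (tolerated mismatches are 10% of the
matched overlap, minimum overlap 3). Trimmed mates therefore carry
amplicon *interior* only, directly comparable to the primer-trimmed
reference alleles. Pairs with a trimmed mate shorter than 150 bp are
culled; the rule is strictly "shorter than", so a 150 bp mate survives.

`merge_pair()` reverse-complements the reverse mate and scans every
overlap offset. Admissible offsets need an overlap of at least 10 bp
with a mismatch fraction of at most 0.25 (common merger defaults,
stated explicitly because they are tunable); among admissible offsets
the longest overlap wins, ties resolved by fewest mismatches and then
smallest offset, which makes the output deterministic and testable. The
consensus takes the higher-quality base at conflicts, with quality ties
going to the forward base. The merge core is implemented in C++ — the
one hot loop in the package — and is checked against an exhaustive
pure-R oracle in the test suite.

## Genotype calling

`tally_reads()` matches each merged read against the reference database
for its locus: exact sequence equality first, then Hamming distance for
equal lengths, then end-free pairwise alignment when lengths differ.
Identity is matched bases over the longer sequence; the default cutoff
of 0.98 accepts the residual sequencing errors that survive merging
while rejecting cross-allele matches (simulated allele pools are kept at
pairwise Hamming distance ≥ 5, and real exon-2 alleles are at least as
distinct). A read tied between two alleles is AMBIGUOUS and counted
toward neither — double-counting between near-identical alleles would
otherwise inflate both.

`call_alleles()` applies the core decision rule: an allele is present
when it holds **strictly more than 10%** of the target's reads in that
animal. The strictness matters at the boundary (a 10.0% fraction is
excluded) and the suite pins it. The rule is scale invariant, so calls
depend only on read fractions. Loci with reads but no allele above
threshold are reported NO_CALL; loci with no reads are NO_DATA, which
pedigree checking later treats as "skip", never as evidence.

`detect_novel()` addresses alleles missing from the reference:
exact-duplicate clusters among unmatched reads whose fraction clears
the same >10% rule (and a floor of 10 supporting reads, guarding
shallow targets) are registered as provisional alleles named
`LOCUS*novel-NNN` — a namespace that cannot collide with published
labels. The tally is then repeated with the augmented reference; the
loop stops when a round finds nothing new, with a cap of three rounds
to bound work (one round suffices in practice because candidates are
exact read sequences). Using one threshold for reference and novel
calling keeps the two symmetric; the supporting count floor is the only
extra guard.

## Mendelian congruence

With both parents genotyped (a dam–sire–joey trio), a joey's set of
alleles at a locus is congruent when it is a subset of the parental
union and shares at least one allele with each parent. Incongruent
cases are classified, one class per family×locus in precedence order:
no allele shared with either parent (NEITHER_PARENT), no allele shared
with exactly one parent (MISSING_PARENTAL), otherwise an allele outside
the parental union (EXTRA_ALLELE). With a single genotyped parent only
sharing with that parent can be required — alleles the parent lacks are
attributed to the unknown parent and not flagged. These operational
rules were chosen so that, applied to the packaged captive family
tables, they flag exactly the cells marked as discrepant in the
published tables — all nine, and no others — which the acceptance suite
verifies. Multi-copy loci use the same set-based rule because per-copy
inheritance cannot be checked without phasing. Reported percentages
round halves up (31/36 → 86%, 62.5% → 63%).

## Population analyses

Profiles are encoded as a binary allele-presence matrix
(`build_presence_matrix()`). On symmetric binary attributes with equal
weights, Gower's coefficient reduces to simple matching, so
`gower_dissimilarity()` is the proportion of differing columns — the
natural reading of "Gower on presence/absence profiles". An alternative
encoding (one categorical variable per locus) was considered and
rejected: set-valued genotypes at multi-copy loci have no faithful
single-category representation. `complete_linkage()` is a deterministic
agglomerative implementation (closest pair, lowest index on ties,
merged clusters appended) returning an `hclust`-compatible object;
export via Newick (`as_newick()`) or a merge table.

`fisher_exact_2x2()` and `chi_squared_test()` delegate to the standard
R tests (two-sided Fisher by the "probabilities ≤ observed" convention;
Pearson chi-squared without continuity correction, df = (r−1)(c−1)),
and are verified in the suite against brute-force enumeration and
direct summation. `allele_association()` builds the carrier × outcome
table for one allele and reports group prevalences with the raw Fisher
p-value; no multiple-testing correction is applied, and reports say so.

## The simulator

`sim_config()` defaults describe the captive study design: 46 founders
plus 18 trio joeys and 18 single-parent-pair joeys (82 animals), allele
pool sizes per locus matching the diversity observed in that population
(7 UA including UB paralog alleles, 5 UC, 10 DAB, 8 DBB, 3 DCB, 4 DMB),
2×250 bp reads at 500 pairs per animal per target, fixed Q35 base
qualities and a 0.2% per-base substitution error rate — a conservative
figure for a MiSeq run after merging. Founders draw alleles per
chromosome per gene copy (uniform frequencies unless configured);
joeys inherit one chromosome per gene copy from each parent,
independently across gene copies (gene copies are treated as unlinked,
which overstates recombination but does not affect any set-based
analysis in the package). Reads are allocated uniformly over
chromosome copies — there is no PCR amplification-bias model, no
chimera formation and no indel error, which are the main respects in
which passing tests on simulated data do not certify behaviour on real
libraries. Quality values are constant because the pipeline uses them
only to break consensus ties.

Determinism is part of the contract: a config and seed reproduce
byte-identical FASTQ output, and every downstream stage is
deterministic given its input.

## Numerical and degenerate-input choices

* Trimming coordinates are exact (substitution-only primer matching);
  all string coordinates are handled 1-based inside R and 0-based
  half-open in the C++ merge core.
* Identity ties in allele matching are compared within 1e-12; Fisher
  two-sided summation uses the standard 1e-7 relative tolerance of the
  underlying implementation.
* Empty inputs fail fast with named errors (no loci, empty joey set,
  missing profile for a pedigree member); an all-absent individual is
  rejected when building the presence matrix.
* `NO_DATA` is distinguished from an empty call everywhere so that
  absence of evidence never counts as incongruence.

## Problem sizes used in validation

The end-to-end recovery experiment simulates 20 animals × 6 targets at
depth 500 with 0.2% substitution error over five seeds (600
animal×locus comparisons) and requires ≥ 99% exact call-set recovery;
the novel-allele holdout withholds a carried single-copy allele and
requires its sequence back verbatim. The oracle checks cover all 2×2
tables with total ≤ 30 for Fisher, 100 random 6-point matrices for
clustering, and 1000 random pairs for merging. These sizes keep the
full suite to a few minutes on one core while leaving the acceptance
quantities fully recomputed from scratch.

## Known limitations

* Alleles are called as sets; chromosomal phase and gene-of-origin
  within multi-copy families (including UA vs UB) are not resolved.
* The >10% rule can drop a real allele at a three-copy locus when
  amplification is skewed or depth is low; at the simulated study
  depth this is rare, but real PCR bias is not modelled.
* Congruence checking validates profiles against a stated pedigree; it
  does not infer parentage.
* Association reports are observational: a carrier–phenotype
  association says nothing about causation, and the package prints raw
  p-values without correction.
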