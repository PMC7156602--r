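---
title: "Scoring SNP-induced RNA structural disruption: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring SNP-induced RNA structural disruption: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasmc)
```

## The model

`rnasmc` treats an RNA secondary structure as a nested (pseudoknot-free) set
of base pairs over a sequence. Every such structure decomposes uniquely into
five element kinds: each closing pair (i, j) is classified by the pairs it
directly encloses — none gives a hairpin (H); one, flush on both sides, is a
stacked pair absorbed into a stem (S); one with unpaired bases on exactly
one side gives a bulge (B), on both sides an interior loop (I); two or more
give a multibranch loop (M). Stems are maximal runs of stacked pairs and
carry the paired bases of both strands; loop elements carry only unpaired
bases. Bases exterior to every pair belong to no element, a deliberate
choice: the score below sums ten terms over exactly five kinds, and an
extra "exterior" kind would change its maximum of 10.

Two decompositions are compared with the RNAsmc score: for each kind, the
Jaccard index of the two position sets plus the ratio of the smaller to the
larger element count, summed over kinds. Positions are compared as absolute
1-based indices — a single substitution preserves length, so wild-type and
mutant structures are always directly comparable; the score remains defined
for unequal lengths.

### Degenerate cases and the empty-kind convention

When a kind is absent from both structures, its Jaccard and ratio terms are
0/0. Under the default `"zero"` convention both terms are 0; this makes the
two calibration anchors exactly realizable — identical structures carrying
all five kinds score 10, and a folded structure scored against a fully
unpaired one scores 0. The cost is that *identical* structures missing some
kinds score less than 10 (a lone stem-hairpin against itself scores 4). The
`"one"` convention (both-empty terms count 1) restores SS(A, A) = 10
universally and is available everywhere via `empty_kind = "one"`; both
conventions agree whenever every kind occurs in at least one structure. The
two behaviours cannot be reconciled in a single convention, so the choice is
exposed rather than hidden.

A related boundary case: the dot-bracket string `"()"` encodes a hairpin
enclosing zero unpaired bases. `decompose()` accepts it (the element is
counted; its position set is empty) so that the decomposition is total on
all balanced strings; structures from any folder respecting a minimum
hairpin size never contain such loops.

## Folding

The built-in folder is a Nussinov-style dynamic program maximizing the
number of nested pairs drawn from {AU, UA, GC, CG, GU, UG} subject to a
minimum hairpin size (`min_hairpin = 3`, the steric minimum; a pair (i, j)
requires j − i > 3). Ties in the traceback are broken deterministically —
leave the interval's last base unpaired when optimal, otherwise pair it with
the smallest admissible partner — so folding is a pure function. It is *not*
a thermodynamic model: it ignores stacking energies and loop penalties, and
its structures differ from MFE predictions. The scoring and significance
machinery only consume structures, so any folder can stand behind the
`folding_backend()` contract (fixed CT files, or the `RNAfold` adapter when
ViennaRNA is installed); the built-in folder is the default because it makes
every result bit-reproducible offline. The DP is implemented in C++ (Rcpp):
significance runs fold tens of thousands of sequences.

## Significance

Both schemes rank the observed wild-type/mutant score in a null
distribution with the add-one empirical p-value
p = (1 + #{b ≤ SS_obs}) / (n + 1). Disruption means *low* similarity, so
the left tail is the alternative: a variant whose observed score sits below
nearly all background scores gets a small p. The add-one correction keeps
p > 0 and is standard for permutation tests. Significance calls use
p < 0.05.

* **RS1** draws `n_perm` permutations of the transcript positions outside
  the variant sites (sites fixed). One permutation is shared by the
  permuted-WT and permuted-MT member of each background pair, so the
  background isolates the allele effect from shuffle noise. The reference
  analysis scale is 10,000 permutations; `run_pipeline()` defaults to 1,000
  as a practical screen. "Flanking sequence" is read as the whole transcript
  outside the sites — the least arbitrary null; the `window` argument
  restricts shuffling to within W nt of each site for the local reading.
* **RS2** folds all 3N single-point mutants (position-major, alphabetical
  order) as the background, observed mutant included. It is exhaustive and
  deterministic; reruns are bit-identical.
* **Haplotypes** are variant lists on one transcript; the mutant carries all
  alleles simultaneously and significance is RS1 with every site fixed. A
  haplotype of one SNP reduces exactly to `rs1()`.

`run_pipeline()` flags a variant significant when *every* computed method's
p is below alpha — the consensus-of-both-schemes rule; single-method runs
flag on that method alone.

### Calibration of the permutation p-value

The test suite checks the rank machinery under an exchangeable null: scores
s_i = SS(fold(seq), fold(perm_i(seq))) are computed for 201 independent
permutations of an 80-nt sequence, one draw is taken as "observed" against
the other 200 as background, and over 200 replicates the resulting p-values
are required to pass a Kolmogorov–Smirnov uniformity check at α = 0.01.
Scoring each permutation against the fixed reference fold is the
construction for which the exchangeability guarantee holds exactly; the
paired WT-versus-MT null can concentrate ties at SS = 10 whenever a single
allele swap rarely changes a fold, which makes the add-one `≤` rank
conservative rather than uniform.

## SNP repositioning

dbSNP-style records give a SNP's 25-nt upstream and downstream flanks.
`map_flanks()` finds exact occurrences of both flanks (and of their reverse
complements for the minus strand) in each transcript and accepts a placement
when the two flank starts are exactly 26 nt apart — the only geometry that
leaves precisely one base, the SNP, between two abutting 25-nt flanks. The
transcript base at that position must equal the read's ref allele (its
complement on the minus strand). Exact substring matching replaces
heuristic short-read alignment: it is bit-reproducible and matches the
strict end-to-end intent; `max_mismatch` relaxes it when needed. T/U
normalization is applied to transcripts and flanks alike so DNA-convention
flanks align to RNA. A read may map to several transcripts and a transcript
may host several reads; every consistent flank pairing yields a record.

## The fixture generator

`generate_fixtures()` emulates the study's inputs at desk scale: random
transcripts (default 120–200 nt, GC 0.5 — long enough for 25-nt flanks on
both sides of a planted SNP, short enough to fold in milliseconds), an
implanted 8-bp perfectly complementary helix with a 4-nt loop (guaranteeing
the built-in folder finds pairs, hence at least one stem and hairpin), SNPs
planted at interior positions at least 26 nt from both ends carrying the
transcript's own base as ref, and flank reads cut from the planted context
on a random strand (half minus by default, since dbSNP records either
orientation). Everything derives from one seed; two calls with the same
seed are byte-identical.

What the generator does *not* emulate: real lncRNA lengths (hundreds to
thousands of nt), biological base composition and repeat structure,
thermodynamic folding ensembles, linkage structure among SNPs, or
alignment ambiguity from paralogous sequence. Passing tests therefore
demonstrate the correctness of the algorithms and the calibration of the
statistics — not that any particular biological variant is or is not a
riboSNitch.

## Problem sizes and numerical choices

The shipped checks use: exhaustive decomposition validation on all balanced
dot-bracket strings up to 10 nt against a brute-force loop classifier;
exhaustive folding validation on 200 random 4–12-nt sequences against
enumeration of all nested pairings; 100 random 80-nt structure pairs for
score bounds; 100 synthetic transcripts for planted-SNP recovery; 200
replicates × 200 permutations on 80-nt sequences for p-value calibration;
a 60-nt fixture for RS2 exactness. Scores are reported to 4 decimal places
in text output and kept at full precision internally. All RNG flows through
explicit seeds; `permute_nonfixed()` restores the global RNG state.

## Known limitations

* Pseudoknots are rejected, not broken: the score presumes the unique
  nested decomposition.
* The built-in folder maximizes pair count; energy-based folders will
  disagree on real transcripts, and results are folder-dependent by design.
* Indels and multi-nucleotide variants are out of scope (SNVs only).
* RS1 at 10,000 permutations on transcript-scale sequences is
  computationally heavy; the pipeline default of 1,000 trades p-value
  resolution (minimum p ≈ 0.001) for speed.
* Multiple-testing correction across variants is not applied; p-values are
  reported raw.
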