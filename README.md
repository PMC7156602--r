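# rnasmc

Quantifying how single-nucleotide variants and haplotypes perturb RNA
secondary structure.

A SNP inside a (long non-coding) RNA transcript can refold the molecule — a
riboSNitch — and thereby change what the RNA binds and does. `rnasmc` is a
toolkit for asking, for any variant mapped onto a transcript: *how different
is the mutant structure from the wild type, and is that difference larger
than chance?* It is aimed at structural bioinformaticians screening variant
tables against transcript sets.

## The score

A pseudoknot-free secondary structure decomposes uniquely into five element
kinds: stems (S, maximal runs of stacked pairs), hairpin loops (H), interior
loops (I), bulges (B) and multibranch loops (M). For two structures, let
u_p1(k), u_p2(k) be the sets of base positions in elements of kind k and
u_n1(k), u_n2(k) the element counts. The RNAsmc similarity score is

    SS = Σ_k |u_p1(k) ∩ u_p2(k)| / |u_p1(k) ∪ u_p2(k)|
       + Σ_k min(u_n1(k), u_n2(k)) / max(u_n1(k), u_n2(k)),   k ∈ {S,H,I,B,M}

Ten terms, each in [0, 1], so SS ∈ [0, 10]: identical element layouts score
10, structures with no overlap score 0. Two empirical significance schemes
rank the observed wild-type/mutant SS against a null:

* **RS1** — shuffle the sequence flanking the variant sites (the sites stay
  fixed), refold both alleles per shuffle, and take the add-one empirical
  rank p = (1 + #{background ≤ observed}) / (n + 1).
* **RS2** — fold all 3N single-point mutants of the N-nt transcript as an
  exhaustive, fully deterministic background.

SNPs supplied as dbSNP-style 25-nt flank reads are repositioned onto
transcripts by exact matching: a read is accepted where its upstream and
downstream flank starts are exactly 26 nt apart on one strand, which places
precisely one base — the SNP — between them.

Folding uses a built-in deterministic Nussinov-style pair-maximization
folder, so the whole pipeline is reproducible and dependency-free; CT or
dot-bracket output from thermodynamic folders plugs in through the backend
contract (`folding_backend()`, including an `RNAfold` adapter).

## Worked example

```r
library(rnasmc)

fx  <- generate_fixtures(n_transcripts = 1, length_range = c(90, 90), seed = 42)
seq <- fx$transcripts[[1]]
v   <- fx$variants            # rs_syn_0001: A31G on tx_001

wt <- fold_nussinov(seq, id = "WT")
mt <- fold_nussinov(apply_variants(seq, v), id = "MT")
rnasmc_score(decompose(wt), decompose(mt))
#> RNAsmc score SS = 8.0000 (empty-kind convention: zero)
#>             S H I B M
#> jaccard     1 1 0 1 1
#> count_ratio 1 1 0 1 1

rs1(seq, v, n_perm = 1000, rng_seed = 7)
#> RS1: observed SS = 8.0000, p = 0.7143 (background n = 1000, seed 7)
rs2(seq, v)
#> RS2: observed SS = 8.0000, p = 1 (background n = 270)
```

The A31G substitution removes the interior-loop overlap (both I terms drop
to 0) but leaves the other element kinds intact, so SS = 8 of 10 — a mild
rearrangement. Neither null finds it unusual: 71% of flank shuffles (RS1)
and every one of the 270 point mutants' scores (RS2) sit at or below the
observed score, so p is far above 0.05 and the variant would not be called
structure-disrupting.

The same flow is available from the shell via the installed `exec/rnasmc`
script (`fold`, `decompose`, `score`, `mutate`, `map`, `rs1`, `rs2`,
`haplotype`, `simulate`, `run`).

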