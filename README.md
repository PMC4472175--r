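# csphylo — consensus-site phylogenomics from cross-species RNA-Seq mapping

csphylo builds codon-partitioned phylogenetic data matrices directly from
RNA-Seq reads of non-model species, **without transcriptome assembly**.
Reads from each sample are mapped in protein space onto the coding
sequences (CDS) of a single well-annotated reference species; reference
positions where the mapped reads agree become the phylogenetic characters.
Because every sample is laid out on the same reference coordinates, the
concatenated supermatrix needs no multiple sequence alignment, and samples
from different tissues, developmental stages and sequencing protocols can
be combined. It is aimed at researchers building species-level phylogenies
for clades (plants, insects, ...) whose nearest sequenced reference is tens
of millions of years away.

## The method in brief

1. **Paralog-collapsed reference.** All-vs-all protein homology hits are
   thresholded at the nearest-rank upper 95th-percentile E-value of *known*
   paralog pairs; connected components form paralog groups; the longest
   member of each group makes the minimal reference **m-CDS** (the
   paralog-free subset is **s-CDS**).
2. **Decoy-calibrated translated mapping.** Reads are placed by a seeded
   translated aligner (7-aa exact seeds, ungapped nucleotide rescoring,
   +1/−1; BLAT PSL can be ingested instead). The score cutoff is the
   smallest integer c at which

   FDR(c) = (reads passing c on the hexamer-preserving shuffled decoy) /
   (reads passing c on the real reference) < 1%.

3. **Site classification.** Per reference position with depth n and
   majority-base count m:
   **CS** (upper case) if n ≥ 10 and m/n ≥ 0.8; **UNS** (`-`) if n = 0;
   **AS** (lower case) otherwise. Genes with CS on < 10% of their length
   are dropped.
4. **Supermatrix.** A codon is kept iff all three positions are CS in
   *every* sample; kept codons are concatenated in (gene, codon) order with
   codon-position partitions (1/2/3) for downstream GTR+GAMMA+I inference
   in RAxML / MrBayes.
5. **Hybrid screening.** At lineage marker sites (group 1 consensus base b1
   ≠ group 2 consensus base b2), a query is *both-alleles* if each marker
   base has ≥ 40% read support, a single-allele expresser at ≥ 90%, else
   uncertain.
6. **Smoke tests.** Jukes–Cantor distances, neighbor joining and
   Robinson–Foulds comparison verify that a matrix carries the expected
   topological signal.

A full simulator (reference CDS, evolution along a known tree, reads,
paralog families, two-haplotype hybrids) makes every stage testable with
recorded ground truth.

## Worked example

Four species on a known tree, reads simulated at 30× with 1% error, mapped
and filtered at the decoy-calibrated cutoff, then matrix → NJ:

```r
library(csphylo)
tree <- "((A:0.02,B:0.02):0.05,(C:0.02,D:0.02):0.05);"
cfg <- sim_config(n_genes = 12, gene_length_nt = 300, tree = tree,
                  mean_depth = 30, read_length_nt = 80, error_rate = 0.01,
                  seed = 101)
ref  <- simulate_reference(cfg)
spp  <- evolve_along_tree(ref, tree, seed = 102)

decoy <- shuffle_klet(ref$sequences, k = 6, seed = 103)
idx   <- seed_index(ref$sequences)
derived <- list()
for (s in names(spp)) {
  rds <- simulate_reads(spp[[s]], cfg, species = s)
  aln <- translated_map(rds$reads, idx)
  cut <- choose_score_cutoff(aln, translated_map(rds$reads, decoy))
  derived[[s]] <- derive_sequences(
    build_pileup(aln[aln$score >= cut$cutoff, ], ref$sequences), s)
}
mx <- build_cs_matrix(derived)
print(mx)
tr <- neighbor_joining(jc_distance(mx))
cat(ape::write.tree(tr), "\n")
rf_distance(tr, tree)
```

Output:

```
sample A: cutoff 57, q = 0.0094 (1280 real / 12 decoy)
cs_matrix: 4 taxa x 2922 sites ( 974 codons from 12 genes )
(D:0.01614780382,C:0.02536337631,(A:0.02431644163,B:0.017556533):0.09281559072);
RF to generating topology: 0
```

Reading this: for sample A the smallest score cutoff with decoy/real ratio
below 1% is 57 (12 decoy vs 1280 real passing reads, realized q = 0.94%);
2,922 of the 3,600 reference sites survive the all-samples consensus-codon
intersection; neighbor joining on that matrix reproduces the generating
topology exactly (Robinson–Foulds distance 0).

A thin command-line front end over the same functions ships in
`inst/cli/csphylo` (subcommands `simulate`, `refprep`, `map`, `sites`,
`matrix`, `nj`, `rf`, `hybrid`).

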