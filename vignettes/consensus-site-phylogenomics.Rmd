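---
title: "Consensus-site phylogenomics from cross-species RNA-Seq mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-site phylogenomics from cross-species RNA-Seq mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csphylo)
```

## The problem

Building phylogenies for non-model clades from RNA-Seq usually starts with a
transcriptome assembly, followed by orthology assignment and multiple
sequence alignment. csphylo implements an assembly-free alternative: RNA-Seq
reads of every sample are mapped, in protein space, directly onto the coding
sequences (CDS) of a single well-annotated reference species, and the
phylogenetic characters are taken from reference positions where the mapped
reads speak with one voice. Because every sample's derived sequence lives on
the same reference coordinate system, concatenation into a supermatrix needs
no multiple sequence alignment at all, and samples from different tissues,
developmental stages and sequencing protocols can be combined freely.

The cost of this design is that only reference-mappable, conserved coding
sequence contributes characters, and that each sample is reduced to a single
consensus haplotype. Both are deliberate: the method targets species-level
topology from moderately diverged clades mapped against a reference tens of
millions of years away, not population-level variation.

## The pipeline and its rules

**Reference preparation.** Cross-mapping between paralogs is the dominant
artifact when mapping a foreign species onto a reference. The package
collapses the reference to a *minimal* CDS set (m-CDS): an all-vs-all
protein homology table is thresholded at an E-value cutoff, qualifying pairs
are joined into paralog groups by connected components, and each group keeps
only its longest member (`build_paralog_groups()`, `build_reference()`).
The cutoff itself is calibrated from a list of *known* paralog pairs as the
nearest-rank upper 95th percentile of their E-values
(`select_evalue_cutoff()`) — permissive enough to cover 95% of known
paralogy. The stricter *singleton* set (s-CDS) keeps only genes without any
paralog. Nearest-rank was chosen over interpolated percentiles because it is
unambiguous and reproducible across software; pairs reported in both BLAST
directions are merged with the smaller of the two E-values, on the view that
a pair is paralogous if either direction says so.

**Decoy-calibrated translated mapping.** Reads are compared against the
reference in protein space (`translated_map()`): exact 7-amino-acid seed
words shared between any of the six read frames and the three forward target
frames propose diagonals, and each candidate diagonal is rescored in
nucleotide space as the maximal ungapped segment under +1 match / −1
mismatch. The mapper is intentionally simple — the contribution of the
pipeline is everything downstream of mapping — and external BLAT PSL output
can be ingested instead (`read_psl()`). A read keeps only its unique
best-scoring placement; exact score ties across targets discard the read as
ambiguous, the conservative reading of "mapped". Alignments below a floor
score of 18 are dropped (the same floor used for short-read BLAT runs;
configurable).

How good must a score be for the placement to be trusted? The package
answers empirically with a decoy: the reference is shuffled preserving its
hexamer (k = 6) composition (`shuffle_klet()`, an Euler-path shuffle on the
5-mer De Bruijn multigraph — the k-mer multiset of every sequence is
*exactly* conserved, as is every shorter word multiset, while longer-range
structure is randomized). The mapping false discovery rate at a cutoff c is
estimated as (reads passing c against the decoy) / (reads passing c against
the real reference), and `choose_score_cutoff()` returns the smallest
integer cutoff whose estimate falls below 1% (requiring at least one real
read to pass, so the vacuous "pass nothing" solution is rejected). Because
the rule picks the *smallest* qualifying cutoff, the realized ratio
typically lands just below the 1% bound rather than far below it.

**Site classification.** For each gene the filtered alignments are piled up
into per-position A/C/G/T counts (`build_pileup()`; read Ns contribute
nothing). Each position is then called (`classify_site()`):

* **CS** (consensus), written upper case: depth ≥ 10 and the majority base
  carries ≥ 80% of the reads;
* **UNS** (uncovered), written `-`: zero mapped reads;
* **AS** (ambiguous), written lower case: covered but failing the CS rule.

Both thresholds are inclusive ("greater or equal to 10", "no less than
80%"); the threshold comparison is done with a 1e-9 slack so that exact
fractions such as 8/10 are never lost to floating-point rounding. A tie for
the majority base resolves to the alphabetically first tied base — the rule
text only asks for "the base with the highest count", and a deterministic
tie-break is required for reproducible matrices. Genes whose CS positions
cover less than 10% of the CDS length are dropped from further analysis
(`derive_sequence()`'s `retained` flag). Multiple libraries of one species
can be pooled *at the count level* (`pool_pileups()`), after which
classification is re-applied — pooling can rescue sites that are too shallow
in each library separately. Pooling counts (rather than intersecting each
library's CS calls) matches re-mapping the pooled reads, and never lowers
the depth at any site.

**The supermatrix.** A reference codon enters the matrix only if all three
of its positions are CS in *every* sample and the gene passed the 10%
filter in every sample (`build_cs_matrix()`). Columns are ordered by
(gene id, codon index) and each carries its codon position (1/2/3) in the
partition map; `write_matrix()` exports relaxed PHYLIP, FASTA or NEXUS plus
RAxML-style or NEXUS-sets partitions. Requiring the retention flag in every
sample (the per-sample filter's natural cross-sample extension) and
stepping through the fixed reference reading frame codon by codon (rather
than overlapping windows, which would duplicate columns) were both design
choices; out-group taxa are treated like any other sample. Downstream ML/BI
inference is deliberately external — the matrices produced here were
designed for GTR+GAMMA+I runs in RAxML (500 bootstraps) and MrBayes
(1,000,000 generations, 2000 burn-in); the package itself only provides a
neighbor-joining smoke test.

**Hybrid screening.** Putative hybrids are examined through lineage marker
sites (`define_marker_sites()`): positions where every species of one group
shares one consensus base, every species of a second group shares a
different consensus base, and any member being AS/UNS skips the site (AS
calls are untrustworthy by the encoding's own definition). A query sample's
pileup is then classified at each marker (`classify_marker_site()`): *both
alleles* if each marker base is supported by ≥ 40% of the mapped reads;
otherwise a *single-allele* call if one marker base reaches ≥ 90%;
otherwise *uncertain*. The both-alleles rule is tested first — the only
precedence consistent with a 58%/42% site being a hybrid site while a
90%/10% site is a pure one. Fractions use the site's total depth as
denominator, including reads showing neither marker base; sites dominated
by neither base are folded into *uncertain* but flagged `neither_base`, and
zero-coverage sites are flagged `no_coverage`. A balanced F1 hybrid shows a
high both-alleles proportion with a roughly 50/50 dominant split, while a
pure member of either group shows essentially none.

**Smoke-test phylogenetics.** `jc_distance()` (closed-form Jukes–Cantor on
the mismatch fraction; an error is raised at saturation p ≥ 0.75),
`neighbor_joining()` (standard Saitou–Nei/Studier–Keppler via ape, with
negative branch lengths clamped to zero) and `rf_distance()`
(Robinson–Foulds via phangorn) exist so matrix quality and simulator
topology recovery can be asserted without external tree-search software.
JC rather than GTR is used internally because it is closed-form and
dependency-free, which is all a topology smoke test needs.

## The simulator, and what passing tests mean

Every stage is testable without downloads through the simulator: random
frame-clean reference CDS (ATG start, no in-frame stops), optional paralog
families at a stated divergence, per-site Jukes–Cantor evolution along a
user tree, uniform read sampling with uniform per-base errors, optional
paired fragments, and two-haplotype hybrids sampled 1:1 per fragment
(`simulate_reference()`, `evolve_along_tree()`, `simulate_reads()`,
`make_hybrid()`). A codon that mutation turns into a stop is redrawn, so
frames stay clean — the pipeline assumes intact ORFs and has no indel
handling (reads map or they don't), so indels are not simulated either.
Read starts are uniform along the gene with no expression-level variation;
sequencing error is a uniform substitution process at a single rate with
constant base quality. Fixed seeds make every simulator output
bit-reproducible.

These choices mean the simulator emulates the *coverage logic* of real
RNA-Seq, not its biology: no expression dispersion, no splicing, no
machine-specific error profiles, no contamination. Tests passing on
simulated data therefore demonstrate the correctness of the rules and their
implementation — threshold boundaries, codon intersection, FDR
self-consistency, topology recovery under the stated model — not robustness
to every artifact of real libraries.

## Numerical and scale choices

* Threshold comparisons (80%, 10%, 90%, 40%) carry a 1e-9 slack toward
  acceptance so exact rational boundaries are decided by arithmetic, not by
  floating-point representation.
* Alignment coordinates follow the PSL convention (0-based, half-open) in
  alignment tables; pileups and all human-readable output are 1-based.
* Overlapping mates are counted as two observations; no mate-aware
  deduplication is applied (the effect is quantifiable from `pair_stats()`).
* The automated checks run at desk scale: the FDR self-consistency check
  simulates 200 genes of 900 nt with ~50,000 80-nt reads at 1% error; the
  end-to-end check uses 6 taxa, 20 genes of 300 nt at 40× error-free
  coverage plus one balanced hybrid; the decoy k-mer checks use sequences up
  to 100 kb. Each completes in seconds to a couple of minutes on one CPU.

## Known limitations

* The internal mapper trades sensitivity for simplicity: a read with no
  exact 7-aa seed word in common with its source (possible at high
  divergence plus sequencing error) is not placed. At the divergences the
  method targets this loss is small, and real BLAT output can be substituted
  via PSL.
* Single-allele consensus: heterozygosity and allele-specific expression
  are folded into the 80% rule; the hybrid module is the only place where
  biallelic signal is examined explicitly.
* Genes under the 10% CS-coverage rule and codons failing intersection
  drop out silently from the matrix; low-coverage samples therefore shrink
  the matrix for everyone (the intersection is monotone in the number of
  samples).
* `jc_distance()` refuses saturated pairs (p ≥ 0.75) rather than guessing;
  such matrices need proper ML inference, not a smoke test.
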