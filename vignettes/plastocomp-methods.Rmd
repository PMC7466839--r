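---
title: "Methods: comparative plastome analysis with plastocomp"
author: "plastocomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastocomp)
```

# Scope

`plastocomp` analyses sets of chloroplast genomes (plastomes) the way a
comparative-genomics study of a plant genus would: it detects the
quadripartite structure (LSC, SSC and the two inverted repeats) and the gene
distances to the IR/single-copy junctions, scans for microsatellites,
imperfect tandem arrays and dispersed repeats, aligns each genome to a
designated reference to call SNPs, substitution blocks and indels, tests
whether mutations co-occur with tandem repeats in 150 bp windows, estimates
per-locus nucleotide diversity (Pi) and Nei-Gojobori Ka/Ks, summarizes codon
usage (RSCU), and builds a neighbor-joining tree from whole-genome
p-distances. A synthetic plastome generator provides fully specified inputs
with known ground truth, so every stage is testable without any downloads.

This vignette explains the models and the numerical conventions, in the
spirit of the methods sections of the established omics packages: what each
statistic is, which knobs matter, and what passing the simulation-based
checks does and does not establish about real data.

# Coordinates, records and the quadripartite partition

All internal coordinates are 1-based inclusive, matching GenBank; the BED
track writer is the only 0-based, half-open surface. Records are parsed from
GenBank flat files (compound `join`/`order` locations, `complement`,
`/codon_start`, trans-splicing flags) or plain FASTA.

Plastomes are analyzed as linearized in the deposited orientation: the
origin sits in the LSC and the regions follow in the order LSC, IRB, SSC,
IRA (the grass convention). `detect_quadripartite()` searches for the
maximal pair of near-identical inverted segments. Candidate diagonals of the
sequence-versus-reverse-complement comparison are located by exact seed
matches (seed length derived by the pigeonhole principle from the mismatch
budget, implemented in C++); on each candidate diagonal the longest window
whose mismatch count stays within `max_mismatch_frac` (default 0.001) of its
own length, with match columns at both ends, is selected. Requiring match
columns at the ends matters: otherwise a window could annex a run of pure
mismatches beyond the true junction and report a slightly inflated IR. Ties
between distinct maximal pairs raise an ambiguity error that lists the
candidates, and the absence of any pair at least `min_ir_len` (default
10 kbp) long raises a "no-IR" error. Because the IRA/LSC junction coincides
with the linearization origin of a circular molecule, the junction report
gives both linear and circular (shortest way around) distances.

# Repeat detection

**SSRs** follow the MISA rules: maximal perfect runs of a 1-6 bp motif with
class minima of 10, 6, 5, 5, 5, 5 copies; a run whose motif is itself
periodic is reported only at its smallest period; N breaks runs. Simple SSRs
whose spacer is at most 100 bp (the MISA default; composite joining can be
disabled with a negative join distance) merge into composite hits that keep
their members. Motifs of length two and above are canonicalized to the
lexicographically smallest rotation; mononucleotide motifs stay literal.

**Imperfect tandem arrays** use a substitution-only array model. For each
unit length `u` (default 7-95 bp; 13-75 bp is available as the narrower
preset some repeat surveys quote — the two ranges circulate in the
literature and the package treats the wider one as canonical), the sequence
is compared to itself at lag `u`. Maximal stretches of this period-match
profile containing no run of `min(u, 3)` consecutive mismatches — three
adjacent substitutions are taken to break an array — form candidates. A
candidate is scored against the perfect tiling of its consensus unit
(per-phase majority, ties to the alphabetically smallest base):
`identity = 100 * matches / length`. Candidates under `min_identity`
(default 85%) drop their shorter terminal exact-match run (ties drop the
right one) until they pass — a lone exact run is a perfect array — or fall
under `min_copies` (default 2.0) and disappear. Overlaps across unit
lengths are resolved greedily by score (match count), ties to the smaller
unit, then leftmost. The terminal-run trim rule was chosen over trimming
whole periods because chance period-matches adjacent to a short array
otherwise drag genuine two-copy arrays below the copy minimum. This model
is deliberately exact and testable; a gapped tandem finder will produce
different absolute counts on real data, which is why downstream statistics
treat tandem counts per window, not global totals, as the quantity of
interest.

**Dispersed repeats** are maximal segment pairs of length at least 21 bp
within Hamming distance 2 (both configurable), in four orientations:
forward, reverse, complement and palindromic (inverted). Detection is
seed-and-extend with exact seeds of length `floor(min_len/(max_hamming+1))`;
the pigeonhole principle guarantees completeness. Maximality means extension
on either side exits the sequence or the budget. Self-overlapping pairs are
excluded; a pair qualifying in several orientations (rare) is reported once
with priority forward, palindromic, reverse, complement.

All three detectors are validated against brute-force oracles — an
exhaustive motif scan, an independent loop implementation of the array
contract, and full-diagonal scans — on hundreds of seeded strings.

# Alignment and variant events

Collinear genome pairs are aligned by anchor chaining: k-mers (k = 21)
unique in both sequences are chained by a highest-weight strictly increasing
chain; inter-anchor segments are aligned globally with affine gaps
(match +1, mismatch -2, gap open -5, gap extend -2; plastome pairs at >99%
identity are insensitive to reasonable score choices). Segments larger than
`max_gap_span` (default 5 kbp) are re-anchored recursively with
segment-local unique k-mers — this is how the duplicated IR, whose k-mers
are not genome-unique, gets anchored. A chain that would imply an inversion
or transposition raises a "non-collinear" error rather than a bad alignment.

Variant events are read off the alignment columns: maximal gap runs in the
query are deletions and in the reference insertions, anchored at the
reference base immediately 5' and left-normalized VCF-style; isolated
mismatch columns are SNPs; two or more contiguous mismatch columns form one
substitution block. The SNP/substitution split is a documented convention
(contiguity) — comparative studies plot the two classes separately without
defining the split operationally, and contiguity is the reading that makes
them disjoint products of one alignment. Every query is aligned to the one
designated reference independently and events are pooled with a query label.

# Windowed co-occurrence statistics

Events (by reference anchor) and tandem arrays (by midpoint) are counted in
non-overlapping 150 bp windows; the short final window is kept so column
sums equal event totals. The association surface is: Spearman rank
correlations for tandem-indel, tandem-SNP and indel-SNP, with the Akoglu
strength bands (under 0.1 none, 0.1-0.19 very weak, 0.20-0.29 weak,
0.30-0.39 moderate, 0.40-0.69 strong, extended with 0.70-1.00 very strong);
and Mann-Whitney U tests of indel and SNP counts in tandem-present versus
tandem-absent windows. No multiple-testing correction is applied — the
convention of the comparative-plastome literature this mirrors — and the
report says so explicitly.

Spearman rho is the Pearson correlation of average ranks. Its two-sided
p-value is exact for n up to 10 — computed from the full permutation
distribution by a subset-sum dynamic program, so ties are handled exactly —
and the t approximation with n-2 degrees of freedom above that. The
Mann-Whitney p-value is exact (all group assignments) for n1+n2 up to 12
and otherwise uses the tie-corrected normal approximation with continuity
correction. Under the null generator (enrichment factor 1) the empirical
type-I error of the tandem-indel test at alpha 0.01 sits near 0.6% over
thousands of replicates — slightly conservative, as expected for a
t approximation on heavily tied Poisson counts.

# Nucleotide diversity and Ka/Ks

Locus alignments use a deterministic center-star strategy: the medoid by
4-mer frequency distance (ties to the alphabetically first id) is the
center, all other members are aligned to it globally, and insertions are
merged by position, left-justified. Pi follows the average-pairwise
definition with pairwise deletion (columns with a gap or N in either member
of a pair are excluded for that pair), the default behavior of standard
polymorphism software; complete deletion is available as a flag. Hotspots
are ranked by descending Pi, genes and intergenic loci separately, ties
broken by name.

Ka/Ks implements Nei-Gojobori (1986) with equal-weight pathway averaging:
per-codon synonymous site fractions (changes to stop codons count as
nonsynonymous) averaged over both sequences; codon pairs differing at d
positions average over all d! minimal pathways, excluding pathways through
stop codons (if all are blocked, the steps count as nonsynonymous). pN and
pS receive the Jukes-Cantor correction -(3/4)log(1-4p/3), reported as NA
when p >= 3/4 makes the logarithm undefined — which necessarily happens for
single-codon synonymous toys, where the uncorrected proportions remain
informative and are always reported alongside. The ratio is NA when Ks is
zero. Genes duplicated in the IR enter once, via the IRB copy. The genetic
code is translation table 11 (plastid/bacterial), whose codon assignments
coincide with the standard table. Because the original study's Ka/Ks tool
and model choice are not reproducible from its methods, this layer is
validated against exhaustive single-codon enumeration, not against printed
per-gene values.

# Codon usage

Codon counts include stop codons and count IR-duplicated CDS annotations
per occurrence. RSCU divides each codon's count by its synonymous family
mean, with the three stop codons as one family (the CodonW convention);
single-codon families (AUG, UGG) are identically 1, and the per-family RSCU
mean is exactly 1 — an identity the tests assert. Reports use the RNA
alphabet. Codon-position base composition gives AT% and GC% at positions
1-3.

# Distance phylogeny

Whole-genome p-distances (mismatches over gap-free shared columns) are
computed on the reference-projection of the pairwise alignments — each
query's bases laid onto reference coordinates, insertions dropped — and fed
to Saitou-Nei neighbor joining with taxa pre-sorted by label for
deterministic tie-breaks and negative branch lengths clamped to zero. This
is a deliberate, desk-scale surrogate for likelihood phylogenomics: the
package asserts only topology-level statements (clade recovery), and
exposes a column-resampling bootstrap for completeness without treating
support values as an inference surface.

# The synthetic plastome generator

`synthetic_spec()` fixes the study conditions once: a 136 kbp circular
quadripartite genome (LSC 80,000 bp, IR 21,600 bp twice, SSC 12,800 bp,
scaled proportionally for other lengths), 38.5% GC, ~50 protein-coding genes
with the positional AT bias of grass plastome CDSs (52.7/60.3/70.0% AT at
codon positions 1-3), ~700 planted tandem arrays per 136 kbp with unit
lengths skewed to 7-10 bp, and ~25 SSRs, mostly A/T mononucleotide runs —
densities and compositions chosen to match what comparative surveys of
grass plastomes report. Repeats are planted in single-copy intergenic space
with period-breaking flanks, and the inner IR junctions are hardened with
forced mismatch columns, so planted coordinates are exactly recoverable;
the IRA is the exact reverse complement of the IRB with mirrored
annotations.

Derived species draw SNP and indel events per 150 bp window as Poisson with
rate `lambda * beta^[window overlaps a planted tandem]`; baseline rates
(0.09 SNPs and 0.022 indels per species per window) are back-computed from
the pooled variant totals such surveys report over ~900 windows and a dozen
query genomes; indel lengths are geometric with mean 4, capped at 50;
insertions slightly outnumber deletions (58.5%). The default enrichment
beta = 2 mirrors the moderate tandem-indel association observed in real
plastomes; beta = 1 is the null. Enrichment acts on window rates rather
than on a mechanistic slippage model: it is the minimal generative model
under which the windowed statistics are well-posed and type-I error and
power can be measured. Event footprints never overlap within a species, so
the recorded truth is exactly what the sequence edits apply; with
`materialize = FALSE` only the event list is drawn — the distributionally
identical fast path used for the replicated calibration studies, while the
sequence-editing path is round-trip tested separately (alignment plus
variant calling recovers planted events exactly when they are well
separated).

Calibration runs use L = 30,000 (200 windows) and the default 12 species:
1,000 null replicates put the alpha-0.01 rejection rate inside
[0.005, 0.02]; mean tandem-indel rho is monotone over beta in {1, 2, 5, 10};
and at beta = 5 the test rejects in over 95% of replicates. Passing these
checks shows the statistics are calibrated and powered **under the
generator's assumptions** — independent Poisson counts, substitution-only
arrays, no rearrangements, no concerted IR evolution, no base-compositional
heterogeneity along the genome. They do not certify Phobos- or
Mauve-identical counts on real accessions, where detector internals and
alignment choices shift absolute numbers; the accession-level checks are
therefore kept as a separate, data-dependent layer that runs whenever the
GenBank records are supplied locally.

# Degenerate inputs and numerical conventions

All-N sequences make GC content undefined (error); N never matches in any
detector and breaks SSR runs; codons containing N are excluded, as are
codon pairs with N in Ka/Ks; alignments of identical sequences shortcut to
gap-free columns; empty gene lists produce empty junction reports; a
constant count vector makes Spearman undefined (error) rather than silently
zero. GC content and composition percentages round half-up to two decimals,
matching the precision of published genome tables. The generator keeps all
derived seeds below 2^31.

# Limitations

Tandem and dispersed repeat counts are model-specific proxies for
Phobos/REPuter output, not re-implementations of their scoring; the
SNP-versus-substitution split is a convention; NJ on p-distances stands in
for ML phylogenomics at topology level only; the generator's mutation model
is windowed-Poisson, not a mechanistic slippage or recombination model; and
junction reports assume the deposited LSC-first orientation (origin
re-rotation is out of scope).
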