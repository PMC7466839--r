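# plastocomp

Comparative analysis of chloroplast genomes (plastomes) in R, built for the
kind of question a genus-level plastome survey asks: how is the genome
organized, where do repeats sit, do mutations cluster around tandem
repeats, which loci are diversity hotspots, how strong is selection on the
coding genes, and how do the species group?

The package covers, end to end:

- **Quadripartite structure** — detection of the two inverted repeats and
  the LSC/IRB/SSC/IRA partition, with gene-to-junction distance reports
  (linear and circular, since the IRA/LSC junction sits at the
  linearization origin).
- **Repeats** — MISA-rule microsatellites (SSRs, with composite joining),
  imperfect tandem arrays under an explicit substitution-only model
  (unit 7–95 bp, identity ≥ 85%), and dispersed repeats (forward, reverse,
  complement, palindromic; length ≥ 21 bp, Hamming distance ≤ 2) via
  pigeonhole seed-and-extend, plus classification by region and annotation
  context.
- **Variants** — anchored collinear alignment of each genome against a
  designated reference (affine-gap DP between unique-k-mer anchors,
  recursive re-anchoring across the IR) and event calling: SNPs,
  substitution blocks (≥ 2 contiguous mismatch columns), left-normalized
  insertions and deletions.
- **Co-occurrence statistics** — tandem/indel/SNP counts in 150 bp windows;
  Spearman rank correlations with Akoglu strength labels and exact
  small-sample p-values; Mann-Whitney U tests of mutation counts in
  tandem-present vs tandem-absent windows.
- **Molecular evolution** — per-locus nucleotide diversity
  (Pi = 2/(n(n−1)) Σ d_ij/L_ij, pairwise deletion) with hotspot ranking,
  and Nei–Gojobori (1986) Ka/Ks with pathway enumeration and Jukes–Cantor
  correction.
- **Codon usage** — codon counts, RSCU (per-family mean exactly 1),
  amino-acid usage, AT/GC content by codon position.
- **Phylogeny** — whole-plastome p-distances from reference-projected
  alignments and a Saitou–Nei neighbor-joining tree with Newick I/O.
- **Synthetic data** — a generator that plants a quadripartite genome,
  genes, SSRs and tandem arrays with exact recorded truth, and derives
  "species" whose per-window mutation rates are enriched by a factor beta
  in tandem-containing windows. Every stage of the pipeline is validated
  against this ground truth and against brute-force oracles.

## A worked example

Simulate a 30 kbp plastome with tandem-enriched mutations (enrichment
beta = 5), run the structural and association layers, and read the result:

```r
library(plastocomp)

spec <- synthetic_spec(seed = 42, L = 30000, beta = 5, n_species = 6)
syn  <- synthesize_reference(spec)

detect_quadripartite(syn$plastome, min_ir_len = 2000)
#> <region_partition> LSC 1-17647 | IRB 17648-22412 | SSC 22413-25235 |
#>   IRA 25236-30000 (IR 4765 bp, 0 mismatches)
gc_content(syn$plastome)
#> [1] 38.92

mut     <- mutate_species(syn$plastome, syn$truth, spec)
events  <- do.call(rbind, lapply(mut$species, function(q)
  call_variants(align_collinear(syn$plastome, q))))
tandems <- find_tandem_repeats(syn$plastome$sequence)
wt      <- bin_counts(events, tandems, 30000)
association_report(wt)$correlations
#>           pair   rho  p_value   n strength significant
#> 1 tandem-indel 0.290 3.18e-05 200     weak        TRUE
#> 2   tandem-snp 0.362 1.40e-07 200 moderate        TRUE
#> 3    indel-snp 0.254 2.84e-04 200     weak        TRUE
```

The partition recovers the planted region boundaries exactly (0 mismatches
between IRB and the reverse complement of IRA); the GC content reflects the
AT-rich base composition typical of grass plastomes; and with beta = 5 all
three window correlations are significant at alpha = 0.01, with the
strengths labeled on the Akoglu bands. `run_all()` executes the same
pipeline—plus diversity, Ka/Ks, codon usage and the NJ tree—on any set of
GenBank/FASTA records and writes a TSV/JSON/BED/Newick bundle with a
manifest:

```r
cfg <- run_config(syn$plastome, mut$species, out_dir = "out",
                  min_ir_len = 2000)
res <- run_all(cfg)
```

A thin command-line front-end with `simulate`, `run-all` and `cooccur`
subcommands is installed under `inst/scripts/plastocomp`.

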