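# guidelib

Design and screen analysis of pooled CRISPR sgRNA libraries, for any genome
supplied as FASTA + GFF3/GTF.

Pooled CRISPR screens need custom guide libraries — a few hundred genes to
genome scale — where every guide is chosen for three things at once: a good
position in the gene model, genome-wide sequence uniqueness, and predicted
cutting efficiency. guidelib implements the whole design path and the count
analysis used to evaluate the result:

* **PAM scanning** on both strands (`scan_targets()`), IUPAC PAM patterns
  (NGG default, Cpf1-style 5' PAMs supported), 23-nt target sites
  (20-nt protospacer + PAM), poly-T exclusion, region filters
  (CDS/exon/codons/TSS windows for CRISPRi/a).
* **Exact off-target search** (`find_offtargets()`): a pigeonhole
  seed-and-verify aligner that is provably set-equal to an exhaustive
  Hamming scan, with 5' masking, 3' trimming, and a mismatch-free PAM
  requirement.
* **Scoring and ranking**. The specificity score starts at 100 and the
  off-targets, ranked *i* = 1, 2, ... by descending homologous nucleotides
  *h_i*, each subtract *h_i / i* — a perfect first 20-nt off-target costs
  20, a perfect second 10. The annotation score adds `5/exon_number` per
  overlapping exon or CDS, `+1` per transcript, `+1` per start/stop codon,
  and `-1` per CpG island. Rule Set 1 (`doench_score()`), a position-weight
  score (`xu_score()`), and user plug-ins (`custom_score()`) rate on-target
  efficiency. `rank_designs()` sorts hierarchically: annotation,
  specificity, efficacy.
* **Library assembly** (`assemble_and_filter()`): 5'-G substitution for U6
  expression, cloning adapters, restriction-site exclusion on the full
  oligo, per-gene selection (default 30 guides), coverage enforcement,
  deterministic FASTA/GFF3/TSV output.
* **Non-targeting controls** (`generate_nontargeting()`): 20,000 seeded
  random 20-mers, rejected on motifs (TTTTT/GGGGG), BbsI sites, and loose
  genome alignment (ignore 4 5' bases, <= 3 mismatches, both strands).
* **Screen analysis**: guide counting from FASTQ via the cassette pattern
  `ACCG(.{20})T{2,4}AGAGC` (`count_guides()`), median normalization and
  control-centred log2 fold changes (`normalize_and_fold_change()`),
  gene-level Wilcoxon rank-sum tests against the non-targeting set
  (`gene_test()`, with `tidy()`/`glance()`/`autoplot()`), and z-score
  functional classification (`classify_functional()`).
* **Deterministic fixtures** (`make_genome_fixture()`,
  `make_screen_fixture()`): seeded toy genomes with certified planted
  on-/off-target structure and simulated screen reads, so everything is
  testable offline.

## Worked example

```r
library(guidelib)

dir <- tempfile(); dir.create(dir)
fx <- make_genome_fixture(fixture_spec(rng_seed = 1), dir = dir)
writeLines(c("gene01", "gene02"), file.path(dir, "genes.txt"))
writeLines(c("guides_per_gene=5", "min_coverage=2", "region_filter=exon",
             "trim_3prime=4",
             "adapter5=TATATATCTTGTGGAAAGGACGAAACACCG",
             "adapter3=GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAG"),
           file.path(dir, "params.txt"))

res <- run_end_to_end(file.path(dir, "genome.fa"),
                      file.path(dir, "annotation.gff3"),
                      file.path(dir, "genes.txt"),
                      file.path(dir, "params.txt"),
                      file.path(dir, "out"))
res$summary
#> # A tibble: 2 × 4
#>   gene_id candidates after_region_filter designed
#>   <chr>        <int>               <int>    <int>
#> 1 gene01          69                  50        5
#> 2 gene02          77                  61        5

head(res$library[, c("design_id", "protospacer_final",
                     "annotation_score", "specificity_score", "doench")], 3)
#> # A tibble: 3 × 5
#>   design_id  protospacer_final    annotation_score specificity_score doench
#>   <chr>      <chr>                           <dbl>             <dbl>  <dbl>
#> 1 gene01_001 GGATGTCTATGATCACCCGA               11               100  0.865
#> 2 gene02_001 GGTCAAGTAACGTAACCCTT               11               100  0.672
#> 3 gene01_002 GTAACAATTAGAGGAGTGGA               11               100  0.626
```

`candidates` is the number of PAM sites scanned in each gene body,
`after_region_filter` those whose protospacer overlaps an exon, and
`designed` the guides accepted into the library. Every accepted design
starts with `G` (U6 transcription), scores annotation 11 here
(exon 1 + CDS 1 + transcript = 5 + 5 + 1) and specificity 100 (no
off-target within 3 mismatches); `doench` is the Rule Set 1 efficiency in
(0, 1). The written `library.fasta` contains the ready-to-order oligos
(adapter + G-substituted protospacer + adapter):

```
>gene01_001
TATATATCTTGTGGAAAGGACGAAACACCGGGATGTCTATGATCACCCGAGTTTTAGAGCTAGAAATAGCAAGTTAAAATAAG
```

A thin command-line driver with the same stages (`design`, `scan`,
`offtargets`, `controls`, `quantify`, `analyze`) ships at
`system.file("cli", "guidelib", package = "guidelib")`.

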