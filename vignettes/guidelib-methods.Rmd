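---
title: "Designing and evaluating pooled sgRNA libraries with guidelib"
author: "guidelib authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating pooled sgRNA libraries with guidelib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidelib)
```

## The problem

Pooled CRISPR screens require libraries of tens of thousands of single guide
RNAs (sgRNAs), each a ~20-nt protospacer adjacent to a PAM (NGG for SpCas9).
A useful library balances three concerns per guide: where in the gene model
it cuts (early, coding, common exons work best), how unique its sequence is
in the genome (off-target cuts confound phenotypes), and how efficient the
protospacer is expected to be given its sequence context. guidelib implements
the full design path — scan, filter, score, rank, assemble — for any genome
supplied as FASTA + GFF3/GTF, plus the downstream count analysis used to
evaluate a designed library in a pooled screen.

## Candidate enumeration

`scan_targets()` enumerates every protospacer+PAM occurrence on both strands
of the requested region. The PAM is an IUPAC pattern (`pam_spec()`, default
NGG following a 20-nt protospacer; 5'-side PAMs of Cpf1-class enzymes are
supported). A target site is always protospacer plus PAM — 23 nt for the
default geometry. Guides whose protospacer contains `TTTTT` are removed by
default because a poly-T run terminates RNA-polymerase-III transcription;
protospacers containing `N` are never emitted. Each site carries a 30-nt
strand-oriented context window (4-nt 5' flank, protospacer, PAM, 3-nt 3'
flank) used by context-dependent on-target scores; sites too close to a
contig edge have no context and therefore no context score.

Region filtering (`filter_by_region()`) keeps a site if its protospacer
interval has a *nonempty intersection* with at least one qualifying feature
per active mode (CDS, exon, start/stop codon, TSS window). Overlap rather
than containment was chosen deliberately: it maximizes recall at the
enumeration stage, and the annotation score downstream discriminates the
quality of the overlap. TSS windows serve CRISPRi/CRISPRa designs and are
strand-aware: the window `[TSS+lower, TSS+upper)` is anchored at the
transcript's 5' end, which on the minus strand is its highest coordinate.

## Annotation score

Every feature overlapping the protospacer contributes additively:

* exon or CDS: `+5 / exon_number` — each overlapping feature separately, so a
  guide in exon 1 of a transcript collects more than one in exon 7, encoding
  the preference for cuts near the transcription start;
* transcript: `+1` (guides in common exons hit many transcripts);
* start or stop codon: `+1`;
* CpG island: `-1` (CpG-island promoters are often methylation-regulated and
  poorly cut);
* gene: `0` (the gene feature spans everything and carries no signal).

Where both an exon and its CDS overlap the guide, both contribute — the
additive reading is a design choice; the alternative (one combined increment
per exon) compresses the dynamic range and was rejected because it weakens
the early-exon preference the score exists to express. CpG islands are
consumed as annotation features; `detect_cpg_islands()` offers a standard
sliding-window rule (>= 200 nt, GC >= 0.5, observed/expected CpG >= 0.6,
merged windows) for annotations that lack them, since no single canonical
predictor exists.

## Off-target search and specificity score

Off-target search is an exact, internal aligner rather than a wrapper around
a heuristic read mapper, so its results are reproducible and provably
complete within the declared policy. The policy (`search_policy()`) trims
`trim_3prime` bases from the protospacer 3' end and masks `ignore_5prime`
bases at the 5' end (the PAM-distal bases contribute least to Cas9
specificity), then requires at most `max_mismatches` mismatches in the
remaining query and a *perfectly matching* PAM from `allowed_pams` (default:
all NGG and NAG trinucleotides). `N` bases in the genome mismatch everything.

The algorithm is pigeonhole seed-and-verify over an exact k-mer index
(`build_seed_index()`, default k = 4): the query is split into
`max_mismatches + 1` contiguous chunks; any window within the mismatch
budget must contain at least one exact chunk, so looking up each chunk and
verifying every candidate window enumerates the complete hit set. The test
suite checks set-equality against an exhaustive Hamming scan across policies
and random genomes up to 100 kb. The candidate's own locus is recognized by
coordinate identity — a second, sequence-identical copy elsewhere is a
genuine off-target.

The specificity score starts at 100; the off-targets, ranked `i = 1, 2, ...`
by descending homologous nucleotides (query length minus mismatches),
subtract `homologous_nt / i` each. A perfectly matching first 20-nt
off-target costs 20 points, a perfect second costs a further 10. The
rank divisor is forced by those two fixed points; ties are broken by
coordinate for determinism. The score is floored at 0 so that heavily
repetitive guides still rank below everything rather than wrapping into
meaningless negatives.

## On-target scores

`doench_score()` implements the Rule Set 1 logistic model over the 30-mer
context: intercept, a penalty per unit of protospacer GC count away from 10
(separate slopes below and above), and position-specific mono- and
dinucleotide weights, mapped through the logistic function — the output is
strictly inside (0, 1). The coefficient table ships as packaged constants
(`rule_set1_weights()`, version `rule_set1/v1`) and is not refit here.

`xu_score()` is a purely additive position-by-base weight-matrix score over
the same 30-mer. The scoring engine is exact (a one-base change moves the
score by exactly the weight difference); the shipped matrix
(`xu_weights()`) is a synthetic calibration of this package carrying the
qualitative structure of published spacer position-weight models — strong
PAM-proximal effects, G favoured at protospacer position 20 — and should be
replaced by a laboratory's own matrix where absolute values matter.

A custom score (`custom_score()`) may be plugged in as a pure function of
the 30-mer; its contract — one numeric value in [0, 1] — is enforced at call
time and violations abort the run with the offending value.

`rank_designs()` sorts hierarchically, each key descending — by default
annotation score, then specificity, then the chosen efficacy score — with
residual ties broken by genomic coordinate so repeated runs are
byte-identical.

## Library assembly

`assemble_and_filter()` walks each gene's ranked designs: the protospacer's
first base is replaced by `G` (U6-driven transcription initiates on G,
`finalize_protospacer()`), adapters are added, and any oligo containing a
forbidden restriction site — checked on the *assembled* oligo including the
adapter junctions, since the motive is cloning compatibility — is dropped
and the next-ranked design promoted. Acceptance stops at `guides_per_gene`
(default 30); genes finishing below `min_coverage` (default: fully
coverable) are removed and reported. Duplicate final protospacers across the
library collapse to the first occurrence by rank. Adapters have no default:
they are a property of the cloning strategy and must be supplied.
`write_outputs()` emits FASTA, GFF3 and TSV deterministically.

## Non-targeting controls

`generate_nontargeting()` rejection-samples random 20-mers (default 20,000
candidates from a mandatory, recorded seed): candidates containing `TTTTT`
or `GGGGG` (polymerase-hostile) or a BbsI site (`GAAGAC`/`GTCTTC`, cloning
incompatibility) are rejected outright; the rest are mapped back to the
genome under a deliberately loose policy — first four 5' bases ignored, up
to three further mismatches, both strands, no PAM requirement — and any
candidate that aligns anywhere is rejected. Both-strand search is the
conservative choice for "does not map to the genome". Survivors are returned
in generation order with full provenance.

## Screen analysis

`count_guides()` extracts the protospacer from each read through the
expression-cassette pattern `ACCG(.{20})T{2,4}AGAGC` and matches it exactly
against the library; matched plus unmatched always equals total reads.
`normalize_and_fold_change()` divides each sample by its median, computes
per-guide log2 ratios of mean treated over mean control, and centres the
distribution so the median non-targeting fold change is exactly zero —
correcting for global coverage loss under treatment. The pseudocount that
guards the ratio against zero counts is expressed in read-count units
(default 0.5 reads, converted through each arm's median): on the
median-normalized scale typical values are ~1, and a constant added on that
scale would visibly shrink true fold changes, whereas half a read is
negligible at screening depth.

`gene_test()` compares each gene's guide fold changes against the
non-targeting set with a Wilcoxon rank-sum test (normal approximation with
tie correction), one-sided for enrichment by default with two-sided and
depletion alternatives available by flag; the gene fold change is the
median of its guides. `classify_functional()` z-scores guides within their
gene (sample standard deviation) and labels `z > 1` functional and `z < -1`
non-functional.

## Fixtures and what the tests do (and do not) show

`make_genome_fixture()` builds seeded toy genomes with planted protospacers
inside annotated exons and planted mismatched copies elsewhere; the
background is regenerated until an exhaustive scan certifies that each
planted guide occurs exactly its planted number of times within the mismatch
budget, so planted truth counts are exact. `make_screen_fixture()` simulates
per-guide abundances (lognormal base weights, per-gene effect multipliers,
multinomial sampling) and writes FASTQ reads in the cassette layout.
Problem sizes used by the shipped checks: fixture chromosomes of 2.5-8 kb
for scanning/controls, twenty 100-kb random genomes for search-vs-oracle
equivalence, and screens of 150-46,000 guides at 500 reads per guide.

Two statistical points deserve emphasis. First, gene-level p-values in a
screen all condition on the same realized non-targeting control set, so they
are positively correlated; a distributional uniformity check (e.g.
Kolmogorov-Smirnov) over genes is only valid when each simulated null gene
is tested against its own independent control draw, which is how the
calibration fixture is built. In a real screen this correlation means the
family of gene p-values can shift coherently with the luck of the control
set — a caveat inherent to the design, not to the implementation. Second,
the fixtures emulate count structure, not genome biology: no repeats,
isochores, GC heterogeneity, or sequencing error. Passing tests demonstrate
algorithmic correctness and statistical calibration under the stated model,
not performance on real genomes.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open everywhere; GFF I/O converts at
the file boundary. Unknown chromosomes in overlap queries warn and return
empty rather than failing a batch run. Zero spread in guide z-scoring labels
everything intermediate with a warning. A sample whose median count is zero
cannot be median-normalized and is a named error. Ranking treats missing
scores as smallest. All randomness flows through explicit seeds
(`withr::with_seed`), and every artifact writer is byte-deterministic given
identical inputs.

## A worked design run

```{r example, eval = FALSE}
fx <- make_genome_fixture(fixture_spec(rng_seed = 1), dir = "fixture")
writeLines(c("gene01", "gene02"), "fixture/genes.txt")
writeLines(c("guides_per_gene=5", "min_coverage=2", "region_filter=exon",
             "trim_3prime=4",
             "adapter5=TATATATCTTGTGGAAAGGACGAAACACCG",
             "adapter3=GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAG"),
           "fixture/params.txt")
res <- run_end_to_end("fixture/genome.fa", "fixture/annotation.gff3",
                      "fixture/genes.txt", "fixture/params.txt", "out")
res$summary
```

The same pipeline is scriptable from the shell through the thin CLI at
`system.file("cli", "guidelib", package = "guidelib")`, whose subcommands
(`design`, `scan`, `offtargets`, `controls`, `quantify`, `analyze`) wrap the
functions above one-to-one.

## Known limitations

Off-target detection is homology-limited: bulges/indels and sites beyond the
mismatch budget are invisible, as with any Hamming-distance search. The
annotation score inherits the quality of the supplied gene models. The
packaged position-weight matrix for `xu_score()` is a synthetic calibration
(see above). The end-to-end driver scans annotated gene bodies exactly as
given — no flanking slack — and paired-nickase two-guide designs are out of
scope.
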