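---
title: "Methods: discovering and profiling endogenous viral elements with evescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and profiling endogenous viral elements with evescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evescreen)
```

## The problem

Endogenous viral elements (EVEs) are fragments of viral genomes — in
mosquitoes, typically flaviviral NS1/NS5-like sequences — integrated into the
host germ line and inherited. Characterizing them from shotgun sequencing data
poses three linked questions that this package answers with three linked
analyses:

1. **Which elements exist, and in what structural form?** Aedes genomes are
   50–70% repetitive, and EVEs sit inside that repetitive DNA, so standard
   whole-genome assembly fragments exactly where the interesting loci are. The
   screen here instead *baits* the loci: recruit raw reads similar to known
   seed elements, assemble only those, keep long contigs, and re-seed with the
   contigs so each round walks further into the unknown flanking sequence.
2. **Do they make small RNAs, and of which class?** EVE loci produce
   PIWI-interacting RNA (piRNA)-like small RNAs: ~27–29 nt, almost exclusively
   antisense to the viral open reading frame, with a strong uridine bias at
   the first position (1U). Flanks may additionally emit 21-nt siRNAs. The
   profiler computes strand-resolved size distributions, positional
   nucleotide frequencies, and classifies loci from them.
3. **Are they really in the genome, and in what copy context?** Depth and
   continuity of DNA-read coverage along an element support a
   presence/partial/absent call, and flank coverage far above element
   coverage indicates integration in multicopy DNA.

A ground-truthed synthetic-data generator emulates the genome structure and
both library types, so every stage is verifiable end to end at desk scale.

## The discovery screen

Each iteration performs four steps: (i) ungapped seed-and-extend alignment of
the current queries against the raw read pool with a Karlin–Altschul E-value
threshold of $10^{-20}$ (E $= Kmn\,e^{-\lambda S}$, with $m$ the total query
bases and $n$ the total read bases); (ii) extraction of reads with at least
one passing hit — by default recruiting a read also recruits its mate, since
assemblies benefit from intact pairs; (iii) de Bruijn unitig assembly of the
recruited reads; (iv) retention of contigs strictly longer than 400 bases.
The first iteration seeds with the known elements; later iterations use the
deduplicated union of all contigs found so far. The loop is capped at 5
iterations and stops early when an iteration contributes no new contig;
repetitive flanks make matches balloon with each round, which is also why a
`recruit_cap` (default 200,000 reads, highest-scoring kept, event logged)
bounds the worst case.

Alignment is deliberately **ungapped**. Recruitment needs read-level
sensitivity, not base-perfect alignment, and at the ~0.5–1% substitution
rates of modern short reads a 151-nt read essentially never requires a gap.
Ungapped extension keeps an exact brute-force oracle feasible — every aligner
in the package is tested against an exhaustive scan. Extension uses an x-drop
rule (default 20): the extension stops once the running score falls 20 below
its maximum, which with +1/−2 scoring tolerates local mismatch clusters of up
to ~10 mismatches before giving up. Karlin–Altschul parameters default to the
conventional ungapped DNA values for +1/−2 scoring ($\lambda \approx 1.28$,
$K \approx 0.46$); word size defaults to the classic 11. Ties on the same
(query, diagonal, strand) keep the leftmost maximal extension.

### The assembler

Assembly is a deterministic de Bruijn unitig assembler over canonical k-mers
(lexicographic minimum of a k-mer and its reverse complement), k = 31 by
default. k-mers with multiplicity below `min_kmer_count` are dropped; every
maximal non-branching path is emitted, oriented to its lexicographically
smaller strand, sorted by length then sequence. The output is therefore a
pure function of the read multiset — read order cannot change a byte.

`min_kmer_count` defaults to **3**, and the reason is worth recording. An
error k-mer only matters if it survives the count filter, and at depth $d$
with per-base error rate $e$ the number of reads carrying the *same*
substitution at the same position is roughly Poisson with mean $de/3$. At
30–60× and $e$ around 0.5–1%, two-read coincidences are common enough to
survive a count-2 filter every few hundred base pairs — and each survivor
branches the graph and cuts a unitig in two. Three-read coincidences are
rarer by another factor of ~30, while genuine k-mers at 30× have effective
depth ~17+ and are essentially never lost at a count-3 threshold. A count
filter is the only graph cleaning performed; tip and bubble removal are out
of scope, so deeply sequenced data with higher error rates should be
downsampled or pre-corrected upstream.

### Deduplication, annotation, presence

A contig is a duplicate if an ungapped chain of word matches to a longer (or
equal) retained contig covers ≥ 90% of its length at ≥ 95% identity, on
either strand; contigs are processed longest-first. These two thresholds are
this package's operationalization of "the same element" and are exposed in
`screen_config()`.

Annotation aligns every seed element to a contig on both strands; maximal
non-overlapping hit intervals at identity ≥ 0.8 become element-labeled
segments (overlaps resolved by score, ties by lower start, lower-scoring
hits trimmed to their non-overlapping remainder, segments shorter than 30 nt
discarded), and the residue is labeled `non-EVE`. The 0.8 floor tolerates the
≤ 5% simulated repeat divergence plus sequencing error while excluding chance
word chains.

Presence calls map the DNA reads to each element reference independently and
ask for covered fraction ≥ 0.95 with no internal zero-depth gap longer than
50 nt (`present`), covered fraction ≥ 0.3 (`partial`), else `absent`. The
0.95/50/0.3 triple operationalizes "depth and continuity of coverage" and is
likewise configurable. Multicopy inference compares mean flank depth to mean
element depth; a ratio ≥ 3 (configurable, always reported with the raw
ratio) is called multicopy.

## Small-RNA profiling

Reads of 15–40 nt are placed exhaustively on both strands of each reference
at Hamming distance ≤ 1 (N never matches). Among minimum-mismatch placements
one is reported per read, chosen uniformly at random under an explicit seed —
emulating a short-read mapper's default single-report behavior — and an
`all_best` mode reports every best placement for the oracle tests. The
profile counts per-position coverage by strand, size histograms over the
18–35-nt window by strand, and the positional nucleotide frequencies of a
chosen length class using each read's own 5′→3′ sequence.

Classification applies explicit cutoffs to the paper-style qualitative
criteria: primary-piRNA-like requires modal length in 27–29 nt, antisense
fraction ≥ 0.8, and first-position U frequency ≥ 0.4 among antisense reads of
the modal class; an siRNA peak requires ≥ 20% of mapped reads at exactly
21 nt; profiles with fewer than 100 mapped reads are `insufficient_data`.
The secondary peak length reported alongside is the modal length below the
piRNA band (18–23 nt). A ping-pong diagnostic counts opposite-strand 5′–5′
overlaps (bin $k$ = a $k$-nt overlap) and reports the z-score of the 10-nt
bin; primary-only loci have all reads on one strand and an undefined z10.

## The synthetic-data generator

The generator is a pure function of its specification and seed, and it
emulates exactly the features the analyses key on:

- **Genome**: i.i.d. background at GC 0.4 (culicine genomes are AT-rich),
  with mutated copies (uniform divergence in [0, 0.05], random strand) of
  repeat-family consensi overwritten at random non-overlapping positions
  until 60% of the genome is repeat-derived — the middle of the 50–70% range
  reported for Aedes genomes. Divergence stays under 5% so multicopy flanks
  inflate mapped depth without defeating the mapper.
- **Integrations**: full, 5′-truncated, fusion (5′ half of one element
  joined to the whole of another, the ALFE4-like structure), and interrupted
  (a host-like insert splitting the element). Each integration carries 1-kb
  flanks per side; `flank_copy_number − 1` extra copies of each flank are
  inserted elsewhere. Flanks are GC-matched *random* sequence rather than
  copies of genome segments: copying from a 60%-repetitive genome would make
  the flank's true copy number ill-defined (the original segment plus
  whatever repeats it contains), destroying the ground truth the multicopy
  ratio test recovers against.
- **DNA reads**: 2 × 151 paired ends from ~200-bp fragments (normal, sd 20,
  truncated at the read length), uniform start and strand, substitution
  errors at 0.5% by default, constant quality 37.
- **Small RNAs**: piRNA-class reads uniform over element-plus-flank loci,
  lengths from a discretized normal (mean 28, sd 1, truncated to 25–31 nt),
  antisense with probability 1 by default; the 5′ base is set to T with
  probability `u1_prob` = 0.7 and to a random non-T base otherwise, so the
  realized 1U frequency equals the parameter exactly and is directly
  testable. The siRNA class (21 nt, both strands) is restricted to flanks of
  loci flagged `sirna`; its share of the library is `sirna_fraction` = 0.2
  of non-background reads. Background defaults to 0, so the default library
  is the pure locus signature.

What the generator does **not** emulate — quality-score decay, indels,
GC-coverage bias, chimeric fragments, 3′ small-RNA modification chemistry,
true transposon phylogenies — bounds what green tests mean: they demonstrate
the algorithms recover the signatures they model, not that real libraries
are free of artifacts these analyses would misread.

## Choices on genuinely open points

- **Adaptor sequences** are a required configuration input with no default:
  they are a property of the library preparation, not of the method. Quality
  trimming is the deterministic BWA-style running-sum rule at Phred 20 (the
  suffix maximizing $\sum(20 - q_i)$ is removed when positive; ties cut
  least).
- **Mate rescue** during recruitment is on by default and exposed as a flag.
- **Fusion composition** follows the ALFE4 precedent: 5′ half of the first
  element, whole second element.
- **Reporting mode** of the small-RNA mapper (single best vs all best) and
  the 18–35-nt histogram window are configuration, as neither is dictated by
  the method itself.
- **Problem sizes in the test suite** (genomes of 15–100 kb, 20–30×
  coverage, 2,000–10,000 small-RNA reads, oracle instances of a few hundred
  reads) are chosen so every claim — including the 10-seed planted-recovery
  study on 100-kb genomes with five integration structures — reruns from
  scratch in minutes on one CPU while keeping each statistical check
  comfortably powered.

## Known limitations

Gapped alignment, translated searches, scaffolding, probabilistic
copy-number segmentation, taxonomy assignment of discovered elements, and
genome-wide piRNA cluster discovery are out of scope. The screen's
sensitivity inherits the seed-and-extend word size: diverged elements
sharing no exact 11-mer with any query are invisible (word size is
configurable). The presence caller assumes reads map uniquely enough that
coverage reflects the locus; paralogous elements sharing long identical
stretches inflate each other's depth, which the fusion test intentionally
exercises.
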