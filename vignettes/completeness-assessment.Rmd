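---
title: "Assessing genome completeness with protein and non-coding markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing genome completeness with protein and non-coding markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A draft fungal genome assembly rarely captures the whole genome. A practical
proxy for *how much* it captures is to search it for genes that evolution
says must be there: families of conserved proteins found across the fungal
kingdom. The fraction of such marker families recovered intact is the
completeness estimate. `mycomplete` implements this idea end to end, with
three additions beyond protein markers alone: highly conserved non-coding
DNA elements (HDEs) give a signal that does not depend on gene prediction;
families known to occur in multiple copies per genome expose collapsed
repeats when fewer copies than expected are found; and unassembled long
reads can be assessed directly, before any assembly exists.

Input is expected to come from a single species; metagenomes, contaminant
screening and functional annotation are out of scope.

## Marker families and their thresholds

A marker family is a set of orthologous peptides from reference species,
summarised as a position-specific scoring matrix (PSSM): one vector of
log-odds scores per alignment column,

$$ s_j(a) \;=\; \log_2 \frac{(c_j(a) + w\,b(a))\,/\,(n_j + w)}{b(a)}, $$

where $c_j(a)$ counts residue $a$ in column $j$, $n_j$ is the number of
non-gap residues in the column, $b$ a background frequency vector (uniform
by default) and $w$ a pseudocount weight (default 1). Columns with at least
50% gaps are dropped. A PSSM is a deliberately lighter model than a profile
HMM: it keeps the thresholding semantics that the method depends on while
every score remains an explicit, testable sum.

Each family's detection threshold is **80% of the weakest member's score
against its own family profile**. This makes the threshold self-calibrating:
by construction every member clears its family's threshold, and a candidate
gene model is held to a standard derived from the family's own diversity
rather than a global cutoff.

Scoring a sequence against a profile uses a local dynamic programme in which
aligning a residue to a column adds the column score and skipping either a
column or a residue costs a flat 2 bits per position. The flat penalty was
chosen over affine gaps for transparency: the optimum can be verified
against a naive full-matrix implementation, which the test suite does.
`X` scores 0 at every column; stop codons (`*`) score a BLOSUM-like −4 bits
so that extensions die at stops through the normal termination rule rather
than a special case.

When building marker sets from candidate ortholog clusters, two filters
apply: a cluster must span at least `ceiling(presence_fraction × n_species)`
of the reference species (default 99%, so small panels require all
species), and it must be unambiguous — every member's self-score must
strictly exceed its score against every other candidate's profile
(`paralog_margin`, default 0 bits). The margin rule is this package's
quantification of "unambiguously identifiable"; the original used an
E-value cutoff, which has no analogue without calibrated score statistics.
Two identical clusters eliminate each other, which is the desired behaviour
for paralogous families.

## Scanning an assembly

Each contig is translated in all six frames (standard code, `*` retained,
codons containing ambiguous bases become `X`), with an invertible mapping
between peptide positions and forward-strand genome coordinates (0-based,
half-open throughout). The search then proceeds BLAST-like:

1. **Seeding.** Exact 4-mer matches between any family member and a frame
   peptide anchor a diagonal. Seeding on member sequences rather than a
   profile consensus guarantees recall on sequences close to any member.
2. **Extension.** Greedy ungapped extension in both directions, scored
   against the profile, terminating when the running score falls 20 bits
   (`xdrop`) below its maximum. HSPs under 15 bits are discarded;
   overlapping HSPs on one diagonal keep the best score.
3. **Chaining.** Per family, contig and strand, a quadratic dynamic
   programme assembles the best colinear chain: successors advance strictly
   in both genome and profile coordinates, genomic gaps (introns) up to
   10 kb are allowed, profile overlaps up to 10 columns are tolerated with
   the overlap's score trimmed at the lower-scoring HSP's per-column rate.
   Ties break toward the smaller genome start, then the lexicographically
   smaller exon fingerprint, so results are deterministic. The best chain is
   extracted, its HSPs (and any HSP mostly inside its span) removed, and
   chaining repeats so that tandem gene copies each yield a model.
4. **Classification.** A model at least `aberrant_factor` (2.0) times the
   family's mean member length is *aberrant* — typically a gene-model
   artifact — and never counts toward completeness, though it is reported.
   Otherwise the model is *complete* if its score reaches the family
   threshold **and** it covers at least 70% of profile columns, *partial*
   if its score reaches 30% of the threshold, and discarded below that.
   Whether the original method required coverage in addition to score is
   not documented; both are required here because score alone would let a
   high-identity fragment of a long protein count as complete. The 30%
   partial floor is likewise this package's quantification of a category
   the method names but never defines; boundary cases are inclusive.

Per family, the representative model is the longest non-aberrant one (ties:
higher score, then smaller genome start). The headline percentage counts
complete families only; the complete-or-partial percentage is always
reported alongside, since the source method's own report does not say which
definition enters its published numbers.

## Non-coding elements and the multi-copy audit

HDEs are nucleotide profiles (4-letter PSSMs, built from alignments of loci
at least 200 bp long with at least 70% identity). Detection mirrors the
protein path with 12-mer seeds — longer than the protein seed because the
nucleotide alphabet is smaller — and reuses the 80%-of-weakest-member
threshold, the package's choice where the original gives no nucleotide
cutoff.

For families expected in $k > 1$ copies (the minimum copy number across a
survey of reference genomes, floored at 1), the audit counts models that
reach the full family threshold at distinct loci — pairwise genomic overlap
below 50% of the smaller model. Fewer than $k$ such loci flags the family
as a potentially collapsed region. The flag is deliberately described as
*potential*: fewer-than-expected copies cannot distinguish a collapsed
repeat from merely unassembled sequence, so the report carries that caveat
verbatim rather than resolving it.

## Completeness from raw long reads

Before assembly, completeness can be estimated from reads directly. The
read set is split into blocks (default $10^4$ reads), 1000 blocks are drawn
by single-pass reservoir sampling (Algorithm R, uniform by construction,
deterministic given a seed), and blocks are scanned one per iteration
against the families not yet detected. A family is detected when any HSP in
a block reaches 30% of its threshold — the partial floor again, because a
single read covers a gene fragment, not a full-length model. Scanning stops
after 20 consecutive iterations without a new family (`stop_patience`), or
when blocks run out; the resulting rarefaction curve makes saturation
visible. An "unsuccessful attempt" is read as one scanned block with zero
newly detected families, checked after each iteration. All three constants
are user-settable; the defaults are the method's published settings. The
mode targets long reads; short-read support is a non-goal.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `seed_k` | 4 | residues | protein seed length; guarantees recall on embedded members |
| `hde_seed_k` | 12 | bases | nucleotide seed length |
| `xdrop` | 20 | bits | extension termination |
| `min_hsp_score` | 15 | bits | HSP reporting floor |
| `aberrant_factor` | 2.0 | ratio | aberrant-length rule |
| `coverage_complete` | 0.70 | proportion | profile coverage for *complete* |
| `partial_floor` | 0.30 | of threshold | *partial* floor; read-mode detection floor |
| `presence_fraction` | 0.99 | proportion | species-presence filter |
| `paralog_margin` | 0 | bits | self-vs-cross ambiguity margin |
| `max_genome_gap` | 10000 | bases | intron allowance in chaining |
| `max_profile_overlap` | 10 | columns | chaining overlap tolerance |
| `pseudocount` | 1.0 | — | profile pseudocount weight |
| `block_size` | 10000 | reads | read-mode block size |
| `n_blocks` | 1000 | blocks | reservoir size |
| `stop_patience` | 20 | iterations | read-mode stopping rule |

## The synthetic test bed

Real marker resources require ortholog inference over dozens of proteomes;
the package instead ships generators that create the same *structure* with
known ground truth. `make_marker_families()` draws a random ancestor
peptide per family (about 300 residues by default, the scale of typical
conserved proteins) and derives members by independent substitutions
(default 6 members at 0.1 substitutions/site — within-family divergence at
which profile search is comfortably reliable, yet members are far from
identical). `make_genome()` reverse-translates one member per family with
uniform codon choice (codon bias is irrelevant to recovery), inserts it at
a random locus and strand — multi-copy families as many times as expected,
element members verbatim — in uniform-GC background sequence, optionally
with up to two random introns of 50–500 bp per gene.

`truncate_assembly()` reproduces the degradation experiment used to
validate the method: non-overlapping windows are deleted uniformly at
random until the target fraction (5–30%) of sequence is gone, each deletion
splitting its contig; because sampling stops at the first crossing of the
target, the overshoot is bounded by one window. With loci placed uniformly,
the number of markers losing *complete* status is approximately binomial
with success probability near the deleted fraction (slightly above it,
because a window overlapping roughly a fifth of a gene already breaks the
threshold), and the acceptance suite checks observed losses against the
99% binomial band, pooled over seeds.

`simulate_reads()` draws reads from uniform positions and strands with
normal lengths truncated at 500 bp and substitution-only errors: the
homology engine is deliberately not frameshift-tolerant, so indel errors
would probe a declared non-goal rather than the method. That is the main
respect in which the simulated reads are kinder than real PacBio/Nanopore
data, and a recovery result here should be read accordingly: passing tests
show the search, chaining, classification and sampling machinery are
correct, not that real noisy-read recall will match.

The synthetic background is also uniform random sequence without repeats,
transposable elements or compositional structure; real genomes will produce
more spurious seeds and more paralog-like confusion than these tests
exercise.

## Numerical choices and degenerate inputs

Scores are plain doubles in bits; chain-score comparisons use a 1e-9 slack
so that floating-point noise cannot flip a tie, and ties are then broken
structurally (genome start, exon fingerprint). FASTA headers are truncated
at the first whitespace to form ids, and duplicate ids are an error because
ids key every downstream table. Lowercase (soft-masked) bases are
uppercased and *not* treated as masked; `U` maps to `T`; ambiguity codes
other than `N` collapse to `N` with a warning. Empty records, sequences
before a header, and FASTQ length mismatches are hard errors. An empty
assembly, an empty marker set, an empty read stream and a non-positive
contig length all raise immediately rather than propagating NaNs.

Problem sizes in the test suite — 10–20 families of ~300 residues, 0.6–2 Mb
genomes, 20× read depth over 1 Mb — were chosen as the smallest scales at
which every behaviour of interest (multi-copy recovery, truncation
statistics, read saturation) is still clearly expressed.

## Known limitations

- Weak "partial" models can arise by chaining chance HSPs across the 10 kb
  gap allowance in large random regions. They never reach the complete
  threshold and never enter copy counting, but the complete-or-partial
  percentage should be read with this in mind.
- The aligner tolerates substitutions, not frameshifts; a single indel
  inside an exon truncates the recovered model at that point.
- Copy-number flags cannot distinguish collapsed repeats from unassembled
  data (reported, not resolved).
- The element count in a marker set is whatever the bundle provides; no
  fixed panel size is assumed.

## A minimal session

```r
library(mycomplete)

ms <- make_marker_set(n_families = 20, n_multicopy = 3, n_hde = 5,
                      rng_seed = 1)
g  <- make_genome(ms, genome_size = 2e6, rng_seed = 2)

rep <- full_report(g$assembly, ms)
rep                       # completeness, elements, flags, contiguity
cat(write_report(rep, "tsv"))

tr <- truncate_assembly(g$assembly, f = 0.10, window = 5000, rng_seed = 3)
full_report(tr$assembly, ms)$pct_complete

reads <- simulate_reads(g$assembly, n_reads = 5000, length_mean = 8000,
                        error_rate = 0.05, rng_seed = 4)
reads_completeness(reads, ms, scan_params(block_size = 250, n_blocks = 40,
                                          rng_seed = 5))$pct_detected
```
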