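---
title: "Assembling small circular genomes with mitoforge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling small circular genomes with mitoforge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoforge)
```

## The problem

A whole-genome shotgun library of an animal contains a small fraction of
reads from the mitochondrial genome (mitogenome), a circular molecule of
roughly 16.5 kb in primates. Because mitochondria are abundant, that small
fraction still represents enormous coverage of the mitogenome — typically
hundreds to thousands of reads per base while the rate of mitochondrial
reads among all reads is a few hundredths of a percent. mitoforge assembles
the mitogenome from such a library by *reference-assisted de novo assembly*:
a congeneric reference mitogenome is used only to *recruit* candidate reads;
the sequence itself is then assembled de novo, so the result is not biased
toward the reference at the base level.

The design rests on a consensus idea: instead of trusting a single assembly,
the same read set is stratified into six quality pools and each pool is
assembled at fifteen k-mer sizes. Each of the 90 jobs independently either
recovers the circle or fails. Candidates that pass a size window are reduced
to a rotation- and strand-independent canonical form, and the final genome
is the sequence supported by the *largest number of identical candidates*.
Identical support from many independent parameterizations is strong evidence
that the sequence is the true major genome copy rather than an assembly
artifact or a nuclear mitochondrial insertion (NUMT).

## Pipeline stages

### 1. Read baiting

The reference is treated as circular and decomposed into canonical seed
k-mers (`seed_k = 31`, odd so that no seed equals its own reverse
complement; canonical form is the lexicographic minimum of a k-mer and its
reverse complement). A read pair is recruited when at least one mate
contains at least `min_hits = 1` seed present in the index, and *both*
mates of a recruited pair are kept ("pair rescue"). Exact seed containment
replaces gapped read mapping here: it is deterministic and dependency-free,
and the downstream consensus is robust to the impurities (NUMT reads) and
omissions (reads over highly diverged regions) that exact matching admits.
With a reference ~4–5% diverged from the target, a 90 bp read has a good
chance of containing at least one clean 31-mer window, and pair rescue
roughly doubles sensitivity; recruitment of 85–90% of target-origin pairs
at essentially 100% purity is typical in the simulations below, which
leaves ample coverage.

### 2. Quality pools

Reads are filtered by the *all-bases* rule: a mate passes threshold $t$
when every base has Phred quality $\ge t$. For each $t \in \{20, 25, 30\}$
two pools are formed: `PE` (pairs in which both mates pass) and `PE+SE`
(the same pairs plus the surviving mate of broken pairs) — six pools in
total. Pool coverage is estimated by the closed form

$$C = \frac{N_{\mathrm{pairs}} \cdot L \cdot 2 + N_{\mathrm{singles}} \cdot L}{G}$$

with read length $L$ and assumed genome size $G$ (default 16,500 bp),
reported as the nearest integer (half-up — the convention that reproduces
published coverage tables exactly; half-even rounding does not). Actual
base counts are summed when read lengths vary.

### 3. Multi-k de Bruijn assembly

Each pool is assembled independently at every odd $k$ from 61 to 89.
Counting is canonical (both strands contribute to one k-mer) and two
cleanup rules are applied: a coverage floor (`min_count = 3`) that removes
k-mers seen fewer than three times, and iterative clipping of *tips* —
unitigs with exactly one dead end and length $< 2k$ — which removes
error-induced dead-end branches that survive the floor. Contigs are the
maximal non-branching paths (unitigs) of the cleaned graph. There is no
bubble popping (the organelle is effectively haploid at high coverage), no
paired-end scaffolding and no gap filling: on a repeat-free ~16.5 kb circle
at the coverage these libraries provide, unitigs alone recover the genome,
so the scaffolding machinery of a general-purpose assembler is deliberately
omitted. Small k tolerates low coverage and high error; large k resolves
repeats; sweeping both directions is what makes the consensus informative.

Determinism: unitig walks start at the lexicographically least unvisited
canonical k-mer, and contigs are emitted sorted by canonical sequence, so a
job's output is byte-reproducible. Each contig's strand orientation is the
traversal's own — arbitrary with respect to biology, exactly as with any
assembler — which is why candidate bookkeeping below records strand forms.

### 4. Finishing

A linear assembly of a circular molecule carries a duplicated region at its
two ends: the suffix of the contig re-reads the bases already present at
its prefix. `find_end_overlap()` finds the longest suffix–prefix match
(`min_overlap = 20` by default; in practice the overlap of a full circular
unitig is exactly $k - 1 \ge 60$, so 20 is conservative). Exact matches are
the string's *borders*, enumerated in linear time with the Knuth–Morris–Pratt
failure function; a mismatch-tolerant scan (rate $\le$ `max_mismatch_rate`)
is available but off by default. Circularization removes the duplicated
copy once.

Candidates within the inclusive size window [16,500, 16,700] bp (the span
of known macaque mitogenomes; both bounds kept inclusive for least
surprise) are *canonicalized*: the canonical form of a circular sequence is
the lexicographically least string among all rotations of the sequence and
all rotations of its reverse complement, computed with Booth's linear-time
least-rotation algorithm on each strand. Two circular sequences are the
same molecule exactly when their canonical forms are equal, so clustering
is plain string equality — deliberately stricter than similarity-threshold
clustering, matching the "identical sequences" consensus criterion. Each
cluster records how many members arrived in forward vs reverse strand form
relative to the canonical string.

The consensus is the representative of the largest cluster. A tie for the
largest cluster raises a hard error carrying both representatives
(condition class `mitoforge_tie`): silently picking one would be
unreproducible science. The canonical rotation is an arbitrary
linearization; `rotate_like()` optionally rotates and strand-matches the
final sequence to a chosen reference's start for reporting.

## Annotation arithmetic

`annostats` functions operate on 1-based inclusive coordinates (GenBank
convention) over a circular genome:

* feature length $= \mathrm{end} - \mathrm{start} + 1$;
* intergenic spacer between consecutive features
  $= \mathrm{start}_{b} - \mathrm{end}_{a} - 1$, negative values being
  overlapping bases; strand is ignored, as adjacent genes on opposite
  strands still overlap or abut in genome coordinates;
* the wrap gap across the origin
  $= (G - \mathrm{end}_{\mathrm{last}}) + (\mathrm{start}_{\mathrm{first}} - 1)$,
  which for a typical vertebrate mitogenome is the control region (D-loop);
* base composition with percentages to two decimals and CpG counted as
  `CG` dinucleotides on the presented strand, linearly (no origin wrap) —
  the counting convention is configurable in principle but this default is
  recorded explicitly because published tables rarely state theirs;
* terminal codons of protein-coding genes, extracting the gene sequence
  (reverse-complemented for L-strand genes) and rendering incomplete stop
  codons — genes whose length is not a multiple of three, completed
  post-transcriptionally by polyadenylation — as the leftover base(s)
  followed by dashes (`"T--"`).

The package ships the published organization table of the Taiwanese macaque
mitogenome (`inst/extdata/mcyclopis_mito_features.tsv`, 16,563 bp) both as
a realistic fixture and as a worked example: recomputing lengths and
spacers from its coordinates reproduces the published Length and
Intergenic spacer columns, including the 46 bp ATP8/ATP6 and 28 bp
COX1/tRNA-Ser overlaps and the 1,088 bp control region.

## The simulator

`simulate_dataset()` emulates the sequencing design the pipeline targets,
with ground truth retained so that recovery is checkable exactly:

* a repeat-free circular genome (default 16,563 bp, GC 0.44; i.i.d. bases
  regenerated until no 100-mer repeats on the circle, so the true genome is
  single-unitig assemblable at every k in the sweep);
* 2×90 bp pairs from ~500 bp fragments (truncated normal, SD 25 bp —
  a tight gel-excised size selection), fragments drawn uniformly on the
  circle *with wrap-around*, so the junction is covered and circularization
  is genuinely exercised;
* substitution errors, Bernoulli per base at 1% by default;
* per-read quality tiers (high/mid/low with probabilities 0.45/0.30/0.25;
  correct-base Phred ranges 30–40 / 25–29 / 20–24) and error bases at
  Phred 2–19. Coupling low quality to errors makes the all-bases QV filter
  meaningful: the three thresholds carve genuinely nested, genuinely
  different pools, and erroneous reads are largely excluded from every
  pool — which is also why the real pipeline's pools were nearly free of
  ambiguous bases;
* decoy pairs (default 20% of the total 37,500 pairs, leaving 30,000
  genome-origin pairs ≈ 326× raw coverage) drawn from an independent
  50 kb linear sequence at GC 0.40, rejection-checked to share no
  canonical 31-mer with the target — a stand-in for the nuclear background;
* a baiting reference derived from the truth by 4.4% substitution
  divergence, the distance of a congeneric reference mitogenome
  (~95.6% identity).

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: indel sequencing errors, platform-specific
error spectra and quality correlations along the read, PCR duplicates,
coverage bias, true NUMTs (decoys share no k-mer with the target, real
NUMTs share many), heteroplasmy, and reference divergence with indels or
rearrangements. The consensus mechanism is expected to tolerate several of
these (NUMT reads recruit but produce minority candidates), but that
expectation is only tested here for the substitution-only model.

## Numerical and degenerate-input choices

* Rounding of reported rates and coverages is half-up (away from zero),
  matching published tables; base R's `round()` is half-even and disagrees
  on exact halves.
* k is required odd everywhere (seeds and assembly) so canonical k-mers are
  well-defined without self-complementary ties.
* Reads shorter than k contribute nothing at that k; a read exactly k long
  contributes one k-mer.
* Empty FASTQ files parse to empty read sets; an empty pair stream baits to
  an empty selection with a zeroed report; an empty candidate set is a
  "no candidate" error at consensus, not a silent empty result.
* String order everywhere that determinism matters (k-mer sorting, cluster
  ties, contig output) uses byte/radix order, independent of locale.
* Quality scores are modelled in [0, 60] (Phred+33); legacy Phred+64 input
  is converted on ingest when declared, never auto-detected. Ambiguity
  codes other than N are rejected rather than coerced.

## Problem sizes used by the test suite

The shipped tests validate each stage against brute-force oracles at small
sizes (1–5 kb genomes, tens to thousands of reads) and run the complete
pipeline twice: once at a 5 kb / 6,000-pair scale for the pipeline tests
and once at the full study design point — 16,563 bp, 37,500 pairs, 1%
error, 20% decoys, the complete 6-pool × 15-k sweep — for the end-to-end
recovery check. The full-scale run takes on the order of two minutes on a
single CPU; the sizes are chosen so the whole suite stays comfortably
interactive while still exercising the design point itself, not a scaled
stand-in.

## Known limitations

* Exact-seed baiting will under-recruit reads from regions where the
  reference is locally more diverged than about one substitution per seed
  length; coverage dips there and large-k jobs may fragment. The multi-k
  consensus absorbs this (small-k jobs still circularize), but a reference
  beyond roughly 10% divergence will need a smaller `seed_k` or more
  `min_hits` tuning.
* Exact-identity clustering means two candidates differing by a single
  base are different clusters. That is the point of the consensus design,
  but it also means the method reports *a* major haplotype, not a
  heteroplasmy-aware mixture.
* Unitig-only assembly assumes the target is repeat-free at the smallest k
  used (61 bp). Vertebrate mitogenomes generally satisfy this; long tandem
  repeats in some control regions would break the single-unitig property
  and such a genome would surface as "no candidate" rather than as a wrong
  sequence.
* The tie-is-an-error rule can halt a run on pathological data; the two
  representatives are attached to the condition so the user can decide.
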