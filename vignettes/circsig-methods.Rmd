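---
title: "circsig: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circsig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-genome sequencing of engineered yeasts has to answer two questions
that generic assembly pipelines answer badly: *are the engineered
constructs — chromosomal integrations and episomal plasmids — present,
complete, and contiguous?* and *at what copy number?*  Long-read
assemblers resolve chromosomes well, but they emit circular plasmids
either flagged as circular or, very commonly, as **collapsed tandem
multimers**: a linear contig consisting of several concatenated copies of
the true plasmid monomer, with no circular flag.  Engineered constructs
also share parts (promoters, terminators, origins, markers) with each
other and with the host genome, which defeats naive presence/absence
checks.

`circsig` implements the computational stages around an external
assembler: routing contigs to a circular-resolution path, reducing tandem
multimers to consensus circular monomers validated by origin-spanning
reads, locating engineering signatures under explicit identity/coverage
gates, classifying per-construct failure modes, estimating plasmid and
tandem-repeat copy numbers from read depth, and reporting
telomere-to-telomere completeness.  A fully seeded synthetic-data module
generates ground-truthed genomes, reads, collapsed assemblies and
metagenome spike-in mixtures, so every stage is testable by parameter
recovery with no external data.

## Circular resolution

**Candidate gate.**  A contig enters the circular path if the assembler
flagged it circular, or if it is shorter than 50 kb *and* its self-repeat
structure covers at least half its length.  The 50-kb bound separates
plasmid-scale sequences from chromosomes; the 50% coverage rule follows
from the structure of a collapsed k-mer: a tandem k-multimer aligns to
itself over a fraction (k−1)/k ≥ 1/2 of its length for k ≥ 2, while
incidental repeats (telomere arrays, dispersed elements) cover far less.

**Self-repeat scan.**  Maximal exact matches (MEMs, "maxmatch"
semantics: every left- and right-inextensible exact match, unique or
not) of the contig against itself are computed by start-anchored hashed
seeding: every MEM of length ≥ *L* begins with a k-mer (k ≤ L) whose
preceding characters differ, so scanning one sequence's k-mers against a
hash index of the other enumerates each MEM exactly once, and extension
costs are bounded by total match length.  Seeds chain into collinear
clusters (diagonal drift ≤ 10% of the running span, positional gap ≤ 500
bp, no backward jumps).  Clusters shorter than 2 kb are discarded, and a
cluster's identity is measured by banded alignment of its two spans with
a 99% floor — the same thresholds a nucmer-based screen would apply to
*reported alignments* (a 2-kb floor on exact seeds would be
self-defeating: at even 0.5% divergence exact matches average a few
hundred bases).  N never matches anything, including itself, so identity
percentages stay well defined on contigs with ambiguous bases.

**Period detection and monomerization.**  Candidate periods come from
the match-length-weighted histogram of self-match offsets (minimum 500
bp — anything smaller is a microsatellite, not a plasmid; a candidate
whose window is itself periodic below that floor is rejected for the
same reason).  Each candidate is validated by aligning the leading
period-length window against every later window; the smallest period
with mean window identity ≥ 95 and ≥ 1.5 copies wins.  The validation
floor is deliberately *below* the 99% cluster gate: its job is to accept
noisy-but-correctable copies, because the consensus step that follows
removes exactly that noise.  The monomer is a column-wise majority vote
across the ⌊copies⌋ aligned windows (an error private to one copy is
outvoted), reported in **canonical form**: the lexicographic minimum
over all rotations of both strands, so any rotation of either strand of
the same circle maps to one string (Booth's least-rotation algorithm).

**Junction validation.**  A monomer is called circular when at least one
long read aligns contiguously across the canonical origin with ≥ 500
exact-seed-supported bases on each side, assessed against the doubled
monomer.  Reads from a linearized molecule cannot cross the cut, so this
cleanly separates true circles from linear tandem arrays.

## Signature annotation and failure modes

Parts are located by seed-and-extend glocal alignment (15-mer seeds,
both strands, per-diagonal-band chaining, banded local extension).
Identity is BLAST-style — identities over alignment columns, gap columns
included.  Collinear same-strand chains on one contig merge when the gap
is at most 10% of the query, and query coverage is the union of matched
query positions; this keeps a part split by one small indel from failing
the coverage gate, the analogue of judging merged HSPs rather than a
single HSP.  Acceptance needs identity ≥ 98 *and* coverage ≥ 98,
mirroring stringent BLASTN screening; an 80% pre-filter bounds compute
without ever excluding anything near the gate.  Sub-threshold best
evidence is kept separately so a missing fragment can be distinguished
from a completely absent part.  Genome features (telomere, centromere,
mitochondrion) instead use a single highest-scoring hit (score = matched
bases; ties broken by contig id then start) with no gates.

Circular contigs (resolved monomers) are annotated against their doubled
sequence, with duplicate second-copy hits folded out — otherwise the
part spanning the arbitrary linearization origin would appear broken.

Construct verdicts reproduce the standard failure-mode vocabulary:

* `absent` — no part has a passing hit;
* `missing_fragment` — some parts pass, at least one does not ("white
  space");
* `contig_break` — all parts pass but no single contig carries them in
  consistent order and orientation ("red line");
* `complete_contiguous` — one contig carries every part, on one strand,
  in declared order (cyclic order for circular contigs).

Order violations map to `contig_break`: a construct whose parts are
shuffled is structurally broken even if every part is present.  The
orientation rule requires all parts on one strand; per-part strand
declarations are not currently modelled because every shipped construct
is co-oriented.

## Copy number from read depth

The depth mapper assigns each read once, to its best (target, strand,
diagonal-band) bucket by minimizer voting (k = 15, w = 10), chains the
bucket's seeds, and projects the chain to approximately full read length
(unseeded extension capped at 150 bp so a read clipped at a structural
difference does not smear depth past its matched region).  Reads with
fewer than 3 supporting seeds stay unassigned.  Circular targets are
indexed doubled and depth is folded modulo length — essential, because
reads from a plasmid routinely wrap its origin and would otherwise be
undercounted near the linearization point.  A PAF file can substitute
for the built-in mapper as the depth source.

*Plasmid copy number* is the mean per-base depth over the plasmid's
marker locus divided by mean depth over a single-copy reference locus
(ACT1-like).  Mean depth, not read counts, because the loci differ in
length.  *Tandem-repeat copy number* is computed two ways on purpose:
from the assembly (bases covered by ≥ 90%-identity unit alignments of at
least 100 bp, over unit length) and from raw reads (read base-mass
assigned to a multi-copy concatenation of the unit, over unit length ×
genome mean depth).  Assemblers collapse long tandem arrays, so the
read-based estimate exceeding the assembly-based one is itself the
diagnostic signature of a collapsed array.  *Hemizygous regions* are
windows (1 kb) whose median depth falls to 0.35–0.65 of the flanking
±10-window median over at least 2 consecutive windows; the band excludes
both noise (above) and homozygous zero-depth deletions (below), and
windows within 3 of a contig end are excluded because linear-end
coverage taper mimics a half-depth dip.

## Telomere-to-telomere completeness

Each reference chromosome is matched to the single contig covering the
largest aligned fraction of it (union of ≥ 500-bp MEMs).  A chromosome is
*complete* when one contig covers ≥ 95% of it and its centromere's best
hit lands on that contig.  Telomere presence (terminal alignment within
10 kb of an end, or ≥ 30% exact motif coverage of the terminal 500 bp) is
reported but **not required**: telomere arrays are the one feature
long-read assemblies routinely fail to finish, and requiring them would
make the statistic report telomere chemistry rather than assembly
structure.  The 95% threshold is exposed as a parameter.

## The synthetic-data module

The generator emulates exactly the structures the pipeline must handle:
linear chromosomes with terminal telomere arrays and a centromere;
planted tandem arrays; multi-part integrations; circular plasmids built
by part concatenation at origin-specific copy numbers; long reads whose
per-template base yield is proportional to length × copy number, with
log-normal lengths (mean 8 kb, shape factor 1.6), uniform starts that
wrap circular templates (at most one origin traversal — tagmentation
linearizes a monomeric circle at a single point), i.i.d. per-base
substitution/insertion/deletion errors (3%/3%/3% default); collapsed,
fragmented, and deletion-bearing assemblies; and base-pair-ratio
metagenome dilutions against generated background "species".

The `fey2_genome_spec()` preset mirrors a heavily engineered strain: a
200-kb chromosome with a four-part pathway integration and a 1-kb
single-copy ACT1-like locus, a low-copy plasmid at copy number 2 and a
high-copy plasmid at copy number 20 (the approximate per-cell copy
numbers of CEN6/ARSH4-type and 2μ-type origins), the two plasmids
sharing one promoter and one terminator.  `fey15_genome_spec()` is the
leaner spike-in preset (500-kb chromosome, one integration, one
high-copy plasmid).

What the generator does **not** model: realistic platform error
profiles (homopolymer bias, quality-score structure), multi-pass
rolling-circle reads, chimeras, and real metagenome composition
(background is random sequence — composition is irrelevant to detection
logic that keys on focal sequence).  Tests passing on this generator
therefore demonstrate the *logic* of routing, monomerization, gating,
classification and depth arithmetic under calibrated noise — not
robustness to every basecaller artifact.

## Numerical choices

* Alignment scoring: match 2, mismatch −4, gap −5 (linear).  The gap is
  strictly costlier than the mismatch pair it could replace, so adjacent
  compensating substitutions are realized as mismatch columns rather than
  gap pairs; with a cheaper gap, optimal alignments of mutated tandem
  windows drifted by 1–2 bp and corrupted consensus columns.
  Tied dynamic-programming moves prefer the diagonal.
* Identity everywhere = matches / alignment columns × 100, gaps counted.
* Consensus ties at a column fall back to the most frequent character by
  table order; insertions relative to the reference window are included
  only when a majority of windows agree on the identical inserted string.
* Degenerate inputs: empty read sets give junction support 0; a period
  with fewer than 2 full windows falls back to the first window with a
  warning; reference depth of 0 is an error, not an NaN ratio.

## Study conditions used by the checks

The shipped checks run at deliberate desk scale, chosen once as
conditions a laptop reproduces in minutes: copy-number recovery on the
FEY2-like preset at 50X long reads, with the marker:ACT1 ratio averaged
over 8 replicate read sets — the single-run estimator carries ~16% CV
because the 1-kb reference locus is 8× shorter than the mean read, so
its depth is essentially one correlated Poisson draw; replication is
variance reduction, not tuning.  At this chromosome size (~200 kb)
interior loci also run ~4% above genome-mean depth (a fraction of the
chromosome comparable to the read length lies in the end-taper), so the
ratio's expectation is ~19.3 rather than 20; on a real 12-Mb genome the
effect is negligible.  Circular resolution is checked over 20 seeds of
3-kb plasmids collapsed in triplicate with 1% per-copy noise; failure
modes over 20 seeds × 4 assembly variants of a 30-kb preset; the
dilution series on a 0.5-Mb focal genome at 2X focal long reads against
generated background at 1:1, 1:10, 1:100, 1:1000 by base pairs; repeat
copy number on a 50-copy 2-kb array collapsed to 5 copies in the
assembly, 10 seeds.

## Known limitations

* The resolver always prefers the consensus monomer over the original
  contig; the original sequence is preserved in `decisions.tsv` rather
  than arbitrated against the consensus.
* Copy-number estimates inherit the mapper's single-assignment rule:
  multi-mapping reads go to their best chain only, so repeat
  quantification uses base-mass on the unit consensus, not per-copy
  assignment.
* Ploidy is out of scope; hemizygous detection sees depth, not
  haplotypes.
* SNP/small-variant calling, polishing beyond majority-vote consensus,
  and re-assembly from reads are not attempted.
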