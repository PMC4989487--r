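---
title: "Detecting RNA-editing sites from matched DNA-seq and RNA-seq data"
author: "editscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA-editing sites from matched DNA-seq and RNA-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## The problem

RNA editing changes bases post-transcriptionally, so the mature RNA differs
from the genome that encoded it. In metazoa the dominant mechanism is
adenosine-to-inosine (A-to-I) deamination by ADAR enzymes; inosine is read
as guanosine, so true editing appears as A-to-G mismatches on the transcript
strand of RNA-seq reads. The difficulty is that an RNA/DNA mismatch has
three mundane explanations that each outnumber genuine editing in raw data:
a genetic variant (the site is heterozygous, or differs from the reference),
a sequencing error, or a mapping error (reads from a paralogous copy or a
splice junction placed at the wrong locus).

`editscan` addresses all three with matched data from the same sample: the
DNA-seq layer establishes that the genomic site is reliably homozygous, an
exact binomial test bounds what sequencing error could produce, and a
cascade of positional and realignment filters removes mapping artifacts.
The package works from pre-aligned, coordinate-sorted SAM/BAM; it does not
run an aligner.

## Homozygosity: ploidy-aware genotype models

A site can only be an editing site if the DNA carries a single allele.
Three interchangeable models decide this per site from the DNA base stack
(`callBayes`, `callBinomial`, `callFrequency`), all parameterized by the
sample's ploidy: one diploid individual is ploidy 2; a pool of m diploid
individuals behaves as ploidy 2m.

The genotype space contains the 4 homozygous genotypes plus every biallelic
composition of each of the 6 unordered base pairs, i.e. `6p - 2` genotypes:
10 at ploidy 2, 22 at ploidy 4. Compositions with more than two distinct
alleles are excluded; with realistic depths they are never distinguishable
from a biallelic composition plus error, and their inclusion would only
dilute the prior.

The Bayesian model scores genotype g for observations with bases $b_i$ and
Phred-derived error probabilities $e_i = 10^{-q_i/10}$ as

$$P(b_i \mid g) = \sum_{a \in g} \frac{c_g(a)}{p}\Big[(1-e_i)\,\mathbb{1}(a=b_i) + \frac{e_i}{3}\,\mathbb{1}(a \ne b_i)\Big],$$

where $c_g(a)$ counts allele a in g and p is the ploidy. Posteriors are
computed over the whole space (log-sum-exp normalized); a site passes when
the maximum-posterior genotype is homozygous, its posterior reaches
`minPosterior` (0.95 by default; 0.99 for stricter work) and DNA depth
reaches `minDnaDepth` (10). The prior is uniform by default, with an
optional heterozygote-downweighted prior (`genotypePrior("hom_het_weighted")`).
Uniform is assumption-minimal, and at depth 10 or more the posterior
threshold dominates the prior choice.

The binomial model asks whether the minor-allele count k out of depth n is
consistent with sequencing error: it computes $P(X \ge k)$,
$X \sim \mathrm{Bin}(n, e)$, with e the mean per-base error of the DNA
observations (floored at $10^{-4}$), and declares homozygosity when that
probability is at least `alpha` (0.05). The frequency model simply caps the
alternative-allele fraction (`maxAltFreq`, default 0 — the strictest
reading, configurable). On clean simulated homozygous stacks the three
agree essentially always (see `test-genotype.R`).

## Candidate detection and the filter cascade

RNA bases below Phred 30 are discarded at pileup time, which bounds the
per-base error of everything downstream at $10^{-3}$ (0.1%). The first and
last 6 sequencing cycles of every read are masked (read ends concentrate
sequencing, priming and indel-alignment artifacts); masking happens at
pileup, not by rewriting records, so original alignments remain available
to the realignment filter. Both thresholds derive per read from its own
length, so mixed-length inputs behave consistently.

A candidate site needs at least 3 *non-redundant* supporting RNA reads —
distinct (start, end, strand, mate) footprints, so PCR-duplicate stacks
cannot manufacture support — and an editing level (k/n over non-redundant
reads) of at least 5%. Eleven verdicts are then recorded per candidate:

1. `dna_homozygous` — the genotype gate above.
2. `known_snp_excluded` — the site is not in a user-supplied SNP list.
3. `multi_type` — only one alternative base is observed; sites with two or
   more distinct alternatives are mapping-error-prone and discarded.
4. `support` and 5. `level` — the thresholds above.
6. `mid_read` — at least one supporting read carries the site in its
   central half, cycles `floor(L/4)+1 .. L-floor(L/4)` (23–68 for a 90-bp
   read); sites seen only near read ends are junction/end artifacts.
7. `splice_distance` — intronic sites within 6 bp of a splice boundary are
   discarded (the first intronic base has distance 1); exonic sites are
   unaffected.
8. `homopolymer` — sites inside runs of 5 or more identical reference
   bases are discarded.
9. `depth_cap` — DNA depth above twice the genome-wide mean covered depth
   indicates collapsed copy-number variation; the boundary is inclusive
   (depth equal to twice the mean is kept). A modal-depth alternative can
   be supplied via `meanDnaDepth`.
10. `realign_qualified` — the realignment check below.
11. `fdr_pass` — the sequencing-error test below.

The final call is the conjunction. Filters 1–10 are pure per-site
predicates, so their outcome is independent of candidate order and of the
order of application; every failure reason is retained in the output for
reporting.

## Realignment against paralogs

Reads that support editing carry a mismatch to the reference — precisely
the reads a mapper may have pulled from a near-identical paralog. Each
supporting read is therefore realigned from scratch by an internal
seed-and-extend local aligner: exact 11-mer seeds sampled along the read
(both orientations) nominate loci, each locus is scored by ungapped
comparison of the full read, and the score is the number of matching bases
(a match-count score in the BLAT tradition). A read *qualifies* when its
best hit covers the candidate site and any second-best hit scores strictly
below 95% of the best; the candidate survives only when the qualifying
fraction strictly exceeds 50% (so 2 of 4 fails). A read whose sequence
cannot be recovered is counted as non-qualifying — the conservative
direction.

Two deliberate simplifications: extension is ungapped (the 95%/50% contract
is a score *ratio*, robust to the exact scorer, and the decisive signal —
a second locus at ≥95% identity — needs no gap handling), and spliced
supporting reads are realigned on the aligned block containing the
candidate site rather than spliced-realigned genome-wide, which stays
within the junction-library scope. With a match-count score, a paralog at
sequence identity ≥ 0.95 yields a second hit at ≥ 95% of the best score and
the read correctly fails; a mismatch-penalized score would let ~97%
paralogs through.

## Sequencing error and FDR

For each surviving candidate with k supporting reads out of n, the exact
upper tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n, p)$ is computed with p the
per-base error ceiling implied by the quality gate ($10^{-\mathrm{minBaseQual}/10}$,
so 0.001 by default; overridable). P-values are Benjamini–Hochberg adjusted
and sites with q above the cutoff (0.05 default; 0.01 for stricter work)
are rejected. The correction is computed per sample over the candidates
that survived the non-statistical filters: including already-rejected sites
would only dilute the correction with hypotheses that were never going to
be called. Candidates rejected non-statistically therefore carry an
undefined (NA) FDR verdict rather than a false one — they never reached the
test.

## Junction library and lift-over

Splice-junction-spanning RNA reads cannot map to the genome directly. The
junction library (`buildJunctionLibrary`) emits, per distinct junction, one
contig made of the last `readLength - 1` exonic bases upstream and the
first `readLength - 1` downstream. The flank length of read length minus
one guarantees no read can hit both the genome and a junction contig;
junction alignments that do not span the contig midpoint are rejected as
redundant with the genomic hit. `liftJunctionAlignment` converts a
spanning alignment into a split genomic alignment with an N-gap CIGAR;
offsets at most `flank` map to `left_exon_end - (flank - offset)`, larger
ones to `right_exon_start + (offset - flank - 1)`, and the lift round-trips
exactly (`projectToJunction`). Flanks are truncated at exon and contig
boundaries and flagged `short_flank` rather than concatenated across
further exons — multi-exon concatenation would claim junction evidence the
read placement cannot actually distinguish.

All external coordinates are 1-based inclusive (SAM/GTF convention).

## Multiple samples

Discovery is deliberately stringent, so a site edited at a low level in one
tissue is easily missed there while being plainly real in another. With
several samples, `runMultiSample` first takes the union of sites passing
the full cascade in at least one sample, discards any position whose DNA is
not reliably homozygous in *every* sample, and then re-queries each sample
at those editable positions under liberal criteria: at least one supporting
read and a BH FDR at or below the cutoff, recomputed per sample over
exactly the queried set (retrieval is a targeted re-query, not a
genome-wide scan; uniqueness and splice-distance properties are inherited
from the discovery verdicts). The merged table reports per-sample counts,
levels, q-values and a status of discovered / retrieved / absent, ordered
deterministically by position.

## Read filtering and strand rules

Only uniquely aligned reads with no suboptimal hits are used: when
BWA-style X0/X1 (or NH) tags are present, exactly one best hit and zero
suboptimal hits are required; otherwise a mapping-quality floor (default
20) applies, with a notice. Duplicate groups — identical mapping
coordinates, pair coordinates for pairs — keep only the highest-mapping-
quality member, ties broken by read name for determinism.

For strand-specific dUTP libraries, the transcript strand is inferred from
supporting-read orientation: second-in-pair reads match the transcript
strand; single-end and first-in-pair reads are antisense. The convention
can be inverted (`invertStrandRule`) for the opposite chemistry. For
unstranded libraries the strand comes from a uniquely overlapping gene
model, else the site is reported on the plus-strand convention with strand
".", and A-to-I summaries count only strand-assigned sites to avoid double
counting.

## The simulator, and what passing it does (and does not) show

`simulateDataset` builds a fully self-contained truth-tabled fixture: a
random genome with multi-exon genes on both strands, heterozygous SNPs
placed at a per-bp rate with ploidy-valid genotypes, editing sites planted
on transcript strands (genomic A on plus-strand genes, T on minus) in exon
interiors with levels drawn from a configured range, uniform DNA reads and
transcript-uniform spliced RNA reads honoring the dUTP convention,
quality-profiled base errors at $10^{-q/10}$, PCR duplicates that
re-sequence the same fragment, and an optional intergenic paralogous decoy
copied at a configured identity. Reads are emitted truth-aligned (SAM), so
no external aligner is needed; FASTQ is written alongside.

The default configuration is the package's standard validation regime: a
50-kb genome, 10 genes, diploid, SNPs at 1/kb, 50 edits at levels 0.1–0.9,
30× DNA and 50× RNA coverage of 90-bp reads at mean Phred 35, 5%
duplicates. These are realistic small-genome study conditions — DNA depth
safely above the 10× genotype gate, RNA depth at which a 10% site has
~89% chance of 3 supporting reads. Unit fixtures use a scaled-down variant
(20 kb, 4 genes, 15 edits, 25×/40×) to keep the suite fast; the vignette
and tests state these sizes as the package's chosen problem sizes.

Passing on simulated data shows the machinery is self-consistent: planted
edits are recovered (recall ≥ 0.9, precision ≥ 0.95 at the standard
regime), heterozygous SNPs are rejected, a 97%-identity paralog flips its
region's candidates to realignment failure, and liberal retrieval recovers
a level-0.03 site at the $1-(1-\beta)^n$ rate. It does *not* show
robustness to what the simulator omits: indels and mapper-specific
misalignment, position- and context-dependent error profiles (beyond
homopolymers being filtered, not simulated), expression-level variation,
degraded or contaminated libraries, or incomplete reference assemblies.
On real data those enter through the supplied alignments, and the filter
thresholds — not the simulator — are what defends against them.

## Numerical and degenerate-input choices

Posterior normalization uses log-sum-exp; posteriors sum to 1 within 1e-9
across the genotype space. Genotype ties break by canonical (lexicographic)
order; major-allele ties break by reference base, then lexicographically.
Zero DNA depth yields a call with `passes = FALSE` and NA score rather than
an error; an empty RNA layer yields an empty site table; an empty gene
model yields an empty junction library. Binomial tails use `pbinom`
upper-tail (exact, not approximated) and were checked against an explicit
summation oracle for all k ≤ n ≤ 30; BH uses `p.adjust` and was checked
against a brute-force step-up on random vectors. The 50% qualifying
fraction and the 95% second-hit ratio are strict inequalities at their
boundaries; the depth cap and editing-level thresholds are inclusive.

## Known limitations

Only substitution editing is handled (no insertion/deletion editing);
hyper-edited clustered reads are not specially treated; repeat annotation
is an input, not discovered; the internal realigner is ungapped and
unspliced as discussed; retrieval FDR is per sample rather than pooled
across samples (the pooled variant would couple samples' error rates);
and per-chromosome parallelism is a contract of the design (chromosome
work units are independent and mergeable) rather than a built-in scheduler.
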