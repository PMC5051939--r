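---
title: "A Bayesian model for the mapping quality of multi-mapped reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian model for the mapping quality of multi-mapped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remapq)
```

## The problem

Repetitive elements — pseudogenes, paralog families, transposons, tandem
repeats — make a large fraction of short sequencing reads map to more than
one genomic locus. Aligners typically resolve the ambiguity by a heuristic
("best" score, random hit, or discarding multi-mappers), and the MAPQ values
they report are empirical. `remapq` instead asks the aligner for *all*
candidate alignments of each read and treats the choice as Bayesian
inference: which candidate locus generated this read?

## The model

For a read with candidate alignment set $A$, the posterior of candidate $i$
is

$$\Pr(\mathrm{map}_i \mid A) =
  \frac{\Pr(\mathrm{loc}_i)\,\Pr(\mathrm{align}_i \mid \mathrm{loc}_i)}
       {\sum_{k \in A} \Pr(\mathrm{loc}_k)\,\Pr(\mathrm{align}_k \mid \mathrm{loc}_k)},$$

with the locus prior proportional to the alignment length,
$\Pr(\mathrm{loc}_i) = L_i / L_G$. The effective genome size $L_G$ and the
normalization constant cancel, so neither is ever evaluated. The reported
mapping quality is the phred-scaled probability that the chosen mapping is
wrong:

$$\mathrm{mapQ}_i = -10\,\lg\bigl(1 - \Pr(\mathrm{map}_i \mid A)\bigr),$$

rounded half-up and capped (default 250; 255 is reserved by SAM for
"unavailable").

The alignment likelihood is a sum of independent per-base terms in log10
scale. Each SAM record is expanded, via its CIGAR string and MD tag (or
`=`/`X` ops), into one status per alignment position:

| status      | contribution                  |
|-------------|-------------------------------|
| match       | $\lg(1 - 10^{-Q/10})$         |
| mismatch    | $-Q/10$                       |
| gap open    | $-Q/10 - \gamma_o$            |
| gap extension | $-Q/10 - \gamma_e$          |
| soft clip   | $-Q/10 - \gamma_s$            |
| hard clip   | $-\hat Q/10 - \gamma_h$       |
| N / P       | $0$ (ignored)                 |

Each $\gamma$ is the relative chance of that status compared to a plain
mismatch, in log10 units; defaults are $\gamma_o = 2$, $\gamma_e = \gamma_s
= \gamma_h = 1$ (`penalty_config()`), all user-settable. $\hat Q$ is the
quality of hard-clipped bases, which are absent from the record; it is
estimated per end as the mean of the `clip_window = 5` observed bases
adjacent to the clip.

Two representation choices the model itself does not dictate:

* **Deleted reference bases** carry no read base, hence no quality. To keep
  the sum total over all non-ignored positions we synthesize their quality
  as the mean of the two flanking read-base qualities (one flank at an
  alignment end).
* **Clipped bases count toward $L_i$.** The prior weight and the ±20%
  evaluation rule use the number of non-ignored expanded positions. Since
  the likelihood sums penalties over clips, excluding them from the prior
  while charging them in the likelihood would treat the same positions
  asymmetrically.

### Paired-end reads

Mates are scored independently and combined jointly over candidate *pairs*:

$$\Pr(\mathrm{pair}_i \mid P) \propto
  L_i^{\mathrm{fwd}} L_i^{\mathrm{rev}}\,
  \Pr(\mathrm{align}_i^{\mathrm{fwd}})\,
  \Pr(\mathrm{align}_i^{\mathrm{rev}})\,
  \Pr_{\mathrm{pair}}(d_i),$$

where the pairing density is Gaussian in the outer mate distance,
$\varphi(d; \mu, \sigma^2)$, with $\mu, \sigma$ estimated from pairs whose
two reads each map uniquely and concordantly. The estimate is trusted only
when at least `min_frag_n = 1000` such pairs exist and $0 < \sigma < 2\mu$;
otherwise the density is a constant, which cancels inside any group where
all pairs use it (the intended behaviour for RNA-seq mates separated by
introns). We define the mate distance as the outer span (rightmost end
minus leftmost start) of a same-reference pair; pairs on different
references always get the constant density.

When one mate has no candidate at all, the pair still competes: the missing
mate is synthesized as an all-soft-clip pseudo-read (its own qualities if
its unmapped record is present, otherwise the mapped mate's length and mean
quality), so unpaired alignments are not systematically preferred over
paired ones. Orphan pairs are pooled into the same normalization as
concordant pairs — a deliberate asymmetry: concordant pairs use the Gaussian,
orphans the constant.

Normalization is computed in log space with max-subtraction, so groups with
likelihood gaps far beyond double-precision range remain exact; the test
suite checks agreement with the naive linear-space formula to $10^{-9}$.
Ties in posterior are broken deterministically (reference name, start,
strand) so repeated runs select the same primary.

### Known variants

A mismatch that coincides with a known polymorphism is not a sequencing
error. Given a VCF of known variants, a mismatch whose observed base equals
a known SNV's alternate allele may take the variant-aware term
$\lg(1 - 10^{-Q/10}) - \gamma$ instead of $-Q/10$, where $\gamma$ is
$\gamma_v$ (default 1) or $-\lg \mathrm{AF}_{\mathrm{alt}}$ when the allele
frequency is available. Per variant, the larger of the plain and
variant-aware terms is used, independently across variants (realistic for
sparse common SNPs in short reads), so the variant-aware likelihood never
falls below the plain one.

The form of the variant-aware term deserves a note. Written literally with
the mismatch kernel, a known-SNP term $-Q/10 - \gamma_v$ can never exceed
the plain mismatch term $-Q/10$, and the per-variant maximum would make
variant awareness a no-op. We therefore treat a read base that matches a
known alternate allele as *correctly sequenced* — contributing the match
term — and charge only the variant prior $\gamma$. A known variant then
helps exactly when $\gamma < Q/10 + |\lg(1 - 10^{-Q/10})|$, i.e. when the
allele is not rarer than a sequencing error is improbable. The literal form
remains available as `strict_literal = TRUE` for comparison.

Indels and MNPs are matched as whole events: a gap run matches a known
indel when its left-aligned position and inserted/deleted sequence both
agree, and then the single $\gamma_g$ (or AF-derived) penalty replaces the
run's gap-open/extension penalties while the per-base $-Q/10$ terms stay.
MNP blocks are matched whole, not per base, with one $\gamma_b$ for the
block; per-base matching is already covered by SNV entries where a
resource provides them.

## Insert-range re-estimation (1DP)

Reads can carry non-genomic sequence — untrimmed adapters, barcodes,
polyadenylation, exon/intron overhang — which aligners without local
alignment force into the alignment as dense mismatches. Scoring each
expanded position ($a_m = 1$ for a match, $a_x = -2$ for a mismatch,
$-\gamma$ for gaps and clips, 0 for N/P so introns bridge a range) and
maximizing the contiguous sum

$$S(i) = \max\{S(i-1) + A_i,\, 0\}$$

finds the best-supported insert in linear time. Ties are resolved leftmost
first, then longest. Positions outside the range become soft clips,
reference-consuming positions are dropped with the start coordinate
advanced, and CIGAR and MD are rewritten so the record stays valid for
downstream tools; a boundary inside a deletion run extends the trim to the
run boundary, because a deletion cannot be half-kept. The default
$a_m{=}1, a_x{=}-2$ makes one mismatch cost two matches, the usual
local-alignment ratio. Trimming is idempotent, and an all-negative score
vector (no credible insert) marks the record unmapped.

## The synthetic-data generator

`simulate_reads()` emulates the error structure of Illumina-like data well
enough to stress the model:

* fragments drawn from uniform locations (optionally restricted to feature
  intervals) with truncated-Gaussian sizes — defaults
  $\mathcal N(300, 50^2)$ truncated to $[150, 600]$ bp;
* per-base qualities Gaussian (sd 3) around a positional mean: flat at
  phred 30 across a 25 bp seed, then decaying linearly at 0.1 phred/base,
  clamped to $[2, 41]$; forward and reverse reads draw independently;
* each base then mutates with probability $10^{-Q/10}$, the event being a
  substitution / insertion / deletion with ratio 0.90/0.05/0.05.

The true interval and strand of every read are encoded in its name, so the
evaluator needs no sidecar file. A read maps "correctly" when both aligned
boundaries are within 20% of the alignment length of the truth, on the same
reference and strand. `sim_genome()` supplies a worst-case substrate: a
random chromosome with planted segment duplications at a chosen identity
(default 95%), which produces exactly the ambiguous multi-mapping structure
the posterior is meant to resolve. What the generator does **not** model:
real base-composition bias, CNVs, rearrangements, RNA editing, PCR
duplicates, or platform-specific error motifs — passing tests on synthetic
data say nothing about those. Spliced reads can be simulated by passing a
transcript FASTA as the reference; truths are then in transcript
coordinates.

The companion `toy_align()` reports *every* locus within a configurable
edit budget. It splits each read into at least `max_edits + 1` disjoint
exact segments, so by the pigeonhole principle any alignment within the
budget contains an exact seed hit; all seed hits (both strands) are found
in one dictionary pass per chromosome and each implied locus verified, by
direct comparison when ungapped or by a windowed pairwise alignment
otherwise. That keeps the guarantee of an exhaustive scan at a small
fraction of its cost, which is what makes the evaluation studies below
practical on one core. Distinct loci closer than `max_edits` bases collapse
to one candidate — irrelevant for genuinely distinct repeats. It is a test
instrument for references up to about a megabase, not a production aligner.

## Problem sizes used in the shipped studies

The package's own evaluation (tests and `scripts/acceptance.R`) runs on a
200 kb synthetic chromosome with ten planted 2 kb duplications at 95%
identity, 2,000 single-end 100 bp reads per replicate and five replicates,
with the fixture aligner's edit budget at 3. These sizes give stable
estimates (binomial standard error on a precision near 0.98 is about 0.3%)
while keeping a full replicate under half a minute on one core. On this
substrate, posterior best-hit selection consistently beats the uniform
random-hit baseline in overall precision, and the FDR at mapQ ≥ 20 never
exceeds the FDR at mapQ ≥ 0.

## Numerical and degenerate-input conventions

* mapQ rounds half-up; a posterior of exactly 1 (or close enough that
  $1-p$ underflows) maps to the cap.
* A single-candidate read gets posterior 1 and mapQ = cap.
* Empty groups, unmapped-only reads, and header-only inputs pass through
  untouched; a coordinate-sorted input or a name order violation is a hard
  error rather than silent mis-grouping.
* Duplicate candidates (same reference, start, CIGAR, strand) are collapsed
  before normalization; secondary/supplementary input flags are otherwise
  ignored.
* Multi-allelic VCF records expand to one variant per alternate allele with
  per-allele AF; symbolic alleles and breakends are skipped with a warning,
  as are variants whose REF contradicts the reference base implied by the
  alignment's MD tag.

## Known limitations

* SAM text only; pipe BAM through `samtools view -h`. Input must be
  name-grouped.
* Chimeric/split alignments are not modeled as pairs, and the fragment-size
  model is a single Gaussian — bimodal libraries will fall back to the
  constant density via the dispersion sanity check.
* The filter is single-threaded by design; throughput is dominated by I/O
  and scales linearly in the number of records.
* Variant awareness uses population frequencies, not per-sample genotypes.
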