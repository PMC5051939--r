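# remapq

Bayesian recalculation of mapping qualities for multi-mapped
next-generation sequencing reads.

## The problem

Repetitive genomes make many short reads map to several loci, and the MAPQ
values aligners attach to their "best" hits are heuristic. `remapq` takes a
SAM file containing **all** candidate alignments of each read
(multi-mapping enabled, name-grouped) and treats hit selection as
inference. For the candidate set $A$ of one read,

$$\Pr(\mathrm{map}_i \mid A) =
  \frac{L_i \Pr(\mathrm{align}_i \mid \mathrm{loc}_i)}
       {\sum_{k \in A} L_k \Pr(\mathrm{align}_k \mid \mathrm{loc}_k)},
\qquad
\mathrm{mapQ}_i = -10 \lg\bigl(1 - \Pr(\mathrm{map}_i \mid A)\bigr),$$

where the alignment likelihood is a per-base sum in log10 scale over the
expanded CIGAR/MD positions — matches contribute $\lg(1-10^{-Q/10})$,
mismatches $-Q/10$, and gap/clip positions $-Q/10$ minus a configurable
penalty. Paired-end reads are scored jointly over candidate *pairs* with a
Gaussian fragment-size density; known variants from a VCF can absolve
mismatches and indels that match a population polymorphism; and an optional
linear-time dynamic program re-estimates the true insert of each alignment,
soft-clipping non-genomic tails and rewriting CIGAR/MD consistently.

The package also ships the pieces needed to study the method end to end
without external data: a synthetic read simulator with a positional
quality-decay error model, a genome generator that plants segment
duplications, a small aligner that reports every locus within an edit
budget (exhaustive by the pigeonhole principle), and a
precision/sensitivity/FDR evaluator over mapQ cutoffs. See
`vignette("mapping-quality")` for the full model.

## Worked example

`inst/extdata/toy.sam` holds four reads; `r001` maps both to `chr1` (clean)
and to `chr2` (one mismatch at base quality 40):

```r
library(remapq)
sam <- read_sam(system.file("extdata", "toy.sam", package = "remapq"))
res <- boost_alignments(sam, mode = "se")
```

The filtered records (abbreviated):

```
r001  0    chr1  101  40   10M     MD:Z:10   XL:f:-0.0004  XP:f:0.9999  XN:i:2
r001  256  chr2  501  0    10M     MD:Z:4T5  XL:f:-4.0004  XP:f:0.0001  XN:i:2
r002  16   chr1  201  250  4M1D4M  MD:Z:4^G4 XL:f:-6.0003  XP:f:1       XN:i:1
r003  0    chr1  301  250  2S6M2S  MD:Z:6    XL:f:-20.0003 XP:f:1       XN:i:1
r004  4    *     0    0    *
```

Reading `r001`: the clean candidate's log10 likelihood is $10\lg(1-10^{-4})
\approx -0.0004$; the mismatched one pays $-40/10 = -4$ more. With equal
lengths the posterior odds are $10^4$, so the primary gets
$\mathrm{mapQ} = -10\lg(10^{-4}) = 40$ and the secondary (flag 256) gets 0.
Single-candidate reads (`r002`, `r003`) get posterior 1 and the cap (250);
`XM`/`XO` count mismatches and indel runs; the unmapped `r004` passes
through untouched.

A command-line interface wraps the same functions
(`system.file("exec", "remapq", package = "remapq")`):

```sh
remapq sim      --ref ref.fa --out reads.fq --n 2000 --seed 1
remapq toyalign --ref ref.fa --fq reads.fq --out cand.sam --max-edits 3
remapq filter   --in cand.sam --out best.sam --mode se [--enable-1dp] [--vcf known.vcf]
remapq eval     --in best.sam --out sweep.tsv --n-total 2000
```

`filter` accepts a flat `key=value` configuration file (`--config`) with
command-line override; unknown keys are an error. BAM users: convert with
`samtools view -h` first; input must be name-grouped.

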