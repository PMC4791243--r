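---
title: "Methods: variant, editing and fusion characterization of tumour cell lines"
author: "gbmcharter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant, editing and fusion characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmcharter)
```

# Scope and design

`gbmcharter` re-implements, as a tested and reusable pipeline, the
post-alignment characterization applied to panels of tumour cell lines
sequenced by whole-exome and RNA-seq: variant spectrum statistics, a
cancer-specific SNV decision cascade, an RNA-editing detection cascade,
multi-caller gene-fusion consensus with in-frame ORF prediction, and
differential-expression direction concordance. Read alignment, the variant
caller itself, duplicate marking and external annotators are out of scope:
the package consumes their outputs (VCF, GTF, BED, caller tables) and owns
everything downstream.

The repository is organised as an analysis: the computation lives in the
package under `R/` (so tests and the acceptance script can call it), and the
numbered drivers under `analysis/` are thin narratives that run each stage
over the synthetic study and write their tables under `results/`. The
orchestration the drivers share is also exposed as one package function,
`run_cohort()`, which runs every stage from a directory of inputs in the
external formats and writes the per-stage reports plus a JSON run manifest;
together with the drivers it is the package's operational surface, so no
separate command-line wrapper is provided.

Internally all coordinates are 1-based inclusive (the VCF convention); BED
input is converted at the boundary, so for a BED interval `[s, e)` the
contained points are exactly `s+1 .. e`. Multi-allelic VCF records are split
into per-allele calls before anything else, because every downstream rule
classifies alleles, not loci.

# The cancer-specific SNV cascade

Calls first pass three call-level filters (inside the capture target, base
quality at least 30, at least 6 reads carrying the variant base). "Quality
above 30" is implemented inclusively (`>= 30`) to agree with the Phred
cutoff stated as an inequality elsewhere in the protocol; all cascade
comparisons are likewise inclusive as printed.

Surviving SNVs are then classified by the first matching rule, in this
order:

1. ESP6500 frequency >= 9e-05 — non-specific (population polymorphism);
2. 1000 Genomes frequency >= 5e-04 — non-specific;
3. present in COSMIC — cancer-specific;
4. present in the TCGA GBM call set — cancer-specific;
5. dataset frequency (fraction of cohort samples carrying the identical
   allele) >= 0.5 — non-specific;
6. present in dbSNP 137 — non-specific;
7. otherwise cancer-specific (novel candidate).

The order is taken literally from the protocol text: the two
population-frequency removals precede the COSMIC/TCGA rescue, so a common
allele is removed even when COSMIC lists it. Database lookups require the
full `(chrom, pos, ref, alt)` allele; positional matches are not accepted.
An allele absent from a frequency table has frequency 0, which is the right
neutral element for "remove if frequency >= cutoff" rules. Dataset frequency
counts *samples*, not calls: a duplicated record inside one sample's file
contributes once. The cascade is defined for SNVs; an explicit
`allow_indels` flag (default off) extends it to indels, since the protocol
text does not state whether indels were run through it.

# Variant spectrum statistics

Transitions are A<->G and C<->T; the six unordered change types are counted
and Ti/Tv reported, with a zero-transversion set reported as undefined (`NA`)
rather than infinite. The functional classifier is a deliberately simplified
location/consequence annotator (full annotator re-implementation is a
non-goal): per overlapping transcript it assigns CDS codon classes
(silent/missense/nonsense/nonstop, and any change in the first codon as a
translation-start change), frameshift or in-frame for coding indels by size
modulo 3, UTRs by side of the CDS, non-coding-gene exon overlap as `rna`
(our reading of the "RNA" category: overlap with a non-coding biotype),
splice site within 2 intronic bases of an exon edge (the standard
donor/acceptor window — deliberately distinct from the editing pipeline's
4-base junction distance, which the protocol does state), 5' flank within
3,000 bases upstream of the TSS (protocol silent; configurable), then
intron/intergenic. The variant-level call is the most severe transcript
class under the fixed ranking nonsense > frameshift > nonstop >
translation-start > splice-site > missense > in-frame indel > silent > UTR >
rna > intron > flank > intergenic (a standard annotator convention; the
protocol is silent). The classifier is validated exhaustively against a
brute-force oracle that translates whole mutated coding sequences, over
every possible substitution of a 30-codon synthetic CDS (270 cases) and
spot-checked on minus-strand transcripts.

# The RNA-editing cascade

Candidates are RNA-side SNVs. Stages, in order, with every removal
attributed to exactly one stage:

1. **Polymorphism subtraction** — any candidate whose allele is listed in
   dbSNP 137, 1000 Genomes or ESP6500. Bare membership is used at this
   stage (not the frequency cutoffs of the DNA cascade); the protocol lists
   the three sources without thresholds here, and we note the asymmetry.
2. **Read-start trim** — the first 6 bases of every read are discarded
   (random-hexamer mispriming) and site support is recomputed from the
   retained observations.
3. **Alu split** — sites inside Alu intervals bypass the five artifact
   filters entirely, as the protocol applies them to non-Alu sites only.
4. **Five filters on non-Alu sites** — support (at least 3 altered-base
   reads *and* altered-base frequency at least 0.1, both inclusive; a site
   that passed before the trim but fails after it is logged under
   `read_trim`, otherwise under `support`); simple-repeat membership;
   distance of at most 4 bases (inclusive) to an annotated splice junction,
   junctions being the exon/intron edges of the gene models; reference
   homopolymer run of length at least 5 containing the site (the site's own
   base counts toward the run — the protocol is silent on inclusion);
   and a sequence-uniqueness filter: the 51-base window centred on the site
   (flank 25, configurable) must occur exactly once in the genome across
   both strands. The uniqueness window is this package's deterministic
   stand-in for the protocol's BLAT similarity search, whose flank length
   and identity threshold are not stated; it is exact, dependency-free and
   testable against a planted duplicated segment.
5. **Known-editome and matched-WES subtraction** — alleles present in the
   normal-brain editome, then positions carrying a DNA variant in the same
   sample's exome calls. A sample without a matched exome set is an error,
   because skipping the subtraction silently would inflate the call set.
6. **Typing and breakdowns** — A>G / T>C are ADAR-type, C>T / G>A
   APOBEC-type, anything else `other`, reported on reference-strand
   alleles; region (Alu / non-Alu repeat / non-repeat, overlaps resolved
   Alu > simple repeat > other), genic class (coding-exon, UTR, intron,
   intergenic) and cross-sample recurrence of identical alleles.

Each stage is a pure filter, so the candidate set is non-increasing and the
attrition counts sum exactly to input minus output — both are asserted in
the tests and, defensively, inside the pipeline itself.

# Fusion consensus and ORF assembly

The three callers' tab-separated outputs are normalized from their
documented dialects. Consensus is keyed on the ordered gene-symbol pair,
not on coordinates, because the callers report breakpoints in different
conventions; an all-tool intersection is reported alongside the pairs seen
by at least two tools. Breakpoint tuples are reconciled by majority, ties
falling back to the most stringent caller's coordinates (PRADA) when it
called the pair.

Breakpoints follow the convention: last retained genomic base of the 5'
partner, first retained base of the 3' partner, both 1-based. The assembler
concatenates the retained coding sequence of the 5' partner (from its start
codon) with the 3' partner's coding sequence from the breakpoint onward,
strand-aware on both sides. With `L5` retained 5' coding bases and `phi`
the 3' entry phase (coding bases upstream of the 3' breakpoint, modulo 3),
the chimera is in frame iff `L5 mod 3 == phi`; translation always proceeds
from the 5' start codon to the first stop, never past it, so an unlucky
junction codon yields a truncated, flagged product even when the phase
algebra says in-frame. All nine `(L5 mod 3) x phi` combinations are checked
against direct translation of the concatenated sequence.

The primer scheme for wet-lab confirmation mirrors the standard three-
amplicon design: a forward primer upstream of the junction on the 5'
partner, a reverse primer downstream on the 3' partner, and wild-type
companion primers, with the three predicted amplicon lengths required to be
pairwise distinct and the fusion pair required to yield no product on
either wild-type template.

# The synthetic study

The generator is first-class, tested code, and its defaults *are* the study
conditions; they are never tuned against test outcomes. It builds a ~1 Mb
three-chromosome genome carrying, by construction: labelled Alu, simple-
repeat and other-repeat intervals (labels only — the pipeline never
inspects Alu sequence content, so planting real Alu sequence would add
nothing the track does not); a 7-base homopolymer run; one exactly
duplicated 200-base segment (the uniqueness-filter substrate); capture
targets; and ten multi-exon genes whose coding sequences (start codon, no
internal stops, terminal stop) are written into the genome, including a
20-exon 5' fusion partner whose exons 1–3 carry 489 coding bases ending at
an exon boundary in phase 0 and a 5-exon 3' partner whose exons 2–5 carry
177 coding bases plus the stop — the published exon architecture of the
worked NUP93–CYB5B-style junction, which assembles to 163 + 59 = 222
residues.

Planted conditions follow the study's reported composition: cohort of six
samples; zygosity drawn at a hom:het ratio of 1:8 and substitutions at
Ti/Tv 2.42 (the reported cancer-specific and cohort-level values); each
planted SNV's database annotations force exactly one cascade reason, and a
mix whose annotations cannot force the requested reason (e.g. a COSMIC
"rescue" planted above the ESP6500 cutoff, which step order would override)
is rejected as impossible. Editing truth defaults to 50 Alu-region sites
(75% ADAR-type, the reported Alu composition) and 10 clean non-Alu sites,
plus exactly one artifact per removal stage, each constructed to fail only
its intended stage; candidate positions are re-drawn deterministically
until categories are disjoint. Fusion tables default to 389 calls across
the three tools with an all-tool intersection of 5, of which exactly 2
assemble in frame. The DE tables plant 3,428 significant genes, 2,214
shared with the comparison table and 1,621 concordant (73.2%).

What the generator does **not** emulate: read-level sequencing error,
alignment artifacts, mapping-quality structure, real Alu sequence, or
copy-number effects. Passing the closed-loop tests therefore demonstrates
that the decision logic implements the stated rules exactly — not that the
rules themselves would behave identically on real reads. An optional noise
mode (binomial perturbation of read support) exists to exercise boundary
behaviour and is off by default.

Problem sizes were chosen so a full test run stays comfortably
interactive: a ~1 Mb genome, ~200 cohort SNVs plus 40 indels, 72 editing
candidates, 389 fusion calls, and a 10,000-variant cohort for the
statistical-recovery check (its tolerance is a 99.9% binomial band around
the planted rates). Everything is a pure function of one integer seed;
writing a bundle twice gives byte-identical files.

# Numerical and degenerate-input choices

Undefined ratios (Ti/Tv with no transversions, hom:het with no
heterozygotes, concordance with no common genes) are reported as `NA`,
never as infinity or zero. Empty inputs yield empty outputs with zeroed
attrition. An empty capture-target set is an error, distinct from "no
overlap". Duplicate alleles with conflicting frequencies in one annotation
source are an error at load time. Zygosity of a multi-allelic genotype is
hom only when both chromosomes carry the same ALT allele. A degenerate CDS
(shorter than one codon) under a coding variant is an error rather than a
guess.

# Known limitations

* The functional classifier handles SNVs and simple indels against
  single-transcript models; it does not produce HGVS protein notation and
  does not re-implement transcript-selection heuristics of full annotators.
* The sequence-uniqueness filter is an exact-match stand-in for a local
  alignment search; diverged repeats that BLAT would flag can pass it.
* The editing pipeline's polymorphism stage uses membership, not
  frequency; sites that are rare but catalogued are removed.
* Fusion consensus keyed on gene symbols cannot separate two distinct
  breakpoints of the same gene pair; coordinate reconciliation is
  secondary by design.
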