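---
title: "Screening and characterizing heavy-ion-beam induced mutations with IonMut"
author: "IonMut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and characterizing heavy-ion-beam induced mutations with IonMut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IonMut)
```

# The problem

Carbon-ion-beam (CIB) irradiation is a high-LET physical mutagen used to
build mutant populations in rice and other crops. A typical design
irradiates dry seed (M0), grows the irradiated M1 plants, harvests single
panicles separately, and whole-genome sequences one M2 plant per panicle
together with non-irradiated controls. The analysis questions are then:

* which variants in each M2 sample are *induced* mutations (as opposed to
  pre-existing polymorphisms, shared germline variation or sequencing
  noise);
* what the induced-mutation spectrum looks like (substitution classes,
  Ts/Tv, InDel sizes, zygosity, per-dose load and per-bp frequency);
* how mutations distribute across panicles of one M1 plant — under the
  progenitor-cell hypothesis different panicles derive from different
  embryonic cells and share few mutations;
* which genes are affected, and which homozygous high/moderate-impact
  hits are candidate causal genes in stable phenotypic mutants;
* how M1 biological endpoints respond to dose, summarized by target-theory
  survival parameters (D0, N, Dq, LD50).

IonMut implements this pipeline end to end, together with a synthetic
cohort generator so every stage is testable without raw sequencing data.

# The screening model

Screening operates on per-site allele-count tables (depth, reference reads
and variant reads per sample), the representation produced by
mpileup-style callers. Within a detection group a variant is accepted for
a focal sample when:

1. **Callability** — no sample in the group is uncallable at the site.
   "Uncertain base" is operationalized as depth below `minCallableDepth`
   (default 8, the mpileup-family default), since callability is otherwise
   undefined for count tables.
2. **Background cap** — in the default *interpreted* mode at most
   `maxOtherVariantSamples` (default 1) other samples show any read
   supporting the allele. A *literal* mode is provided that applies the
   printed rule "samples with genomic reference bases ≤ 1" verbatim; note
   that rule contradicts criterion 3 for a sample-unique mutation (twelve
   reference samples remain), which is why interpreted mode is the
   default.
3. **VAF thresholds** — focal variant allele frequency (variant reads over
   total depth) at least 0.30 while below 0.10 in every other sample of
   the group.

Calls with VAF ≥ 0.75 are homozygous (inclusive threshold), otherwise
heterozygous. Variants supported at ≥ 0.10 VAF in any non-irradiated
control are removed everywhere (pre-existing), and identical variants
called in two or more distinct M1 plants are removed as shared germline or
artifactual.

**Group structure.** Detection groups contain one panicle per M1 plant
plus all controls (the default grouping is by dose and panicle index).
This mirrors the practice of keeping panicle samples of the same plant in
separate detection groups: a mutation carried by two panicles of one plant
would otherwise violate the "below 0.10 in all other samples" criterion
and be lost, making panicle-sharing rates unobservable. The cross-plant
filter still operates cohort-wide.

Multi-allelic sites are evaluated per alternate allele; a sample keeps at
most one call per site (highest VAF, ties broken by allele order, so the
procedure is deterministic).

# The synthetic cohort generator

The generator emulates the study conditions of a CIB M2 screen:

* **Genome** — a miniature random genome (default two 500 kb chromosomes,
  GC 0.44 as in rice) carrying non-overlapping protein-coding genes with
  UTRs, GT..AG introns and internally consistent CDSs (ATG start, single
  terminal stop, length a multiple of 3). It stands in for a rice
  reference assembly at roughly 1/400 scale.
* **Dose response of mutation load** — mean mutations per line follow
  $m(D) = m_{max}(1 - e^{-D/\tau})$. Two printed anchors (105.23/line at
  100 Gy and 98.17/line at 150 Gy) decrease slightly with dose, which no
  nondecreasing saturating curve can reproduce, so a two-parameter least
  squares on the anchors alone degenerates to a flat line. We therefore
  fix $\tau = 100/3$ Gy — so that 95% of saturation is reached at 100 Gy,
  encoding "saturation at approximately 100 Gy" — and least-squares fit
  $m_{max}$ to both anchors, giving $m_{max} = 104.78$. The plateau ratio
  m(150)/m(100) is 1.04, within the observed stability of the load across
  100–150 Gy.
* **Spectrum** — mutation types default to 72.3% SBS / 23.5% deletion /
  4.2% insertion; the six strand-collapsed substitution-class
  probabilities default to midpoints of the reported per-dose ranges
  (G:C>A:T 0.35, A:T>G:C 0.20, A:T>T:A 0.17, G:C>T:A 0.12, A:T>C:G 0.08,
  C:G>G:C 0.08), which imply Ts/Tv = 0.55/0.45 ≈ 1.22, inside the
  reported 1.17–1.50 band. Deletion sizes use bins 1 / 2–10 / >10 bp with
  probabilities 0.4516/0.4803/0.0681 capped at 38 bp; insertions
  0.7575/0.2343/0.0082 capped at 17 bp. Within-bin sizes are uniform (the
  source material reports only bin totals and ranges).
* **Panicle lineage** — each mutation is carried by 1, 2 or 3 panicles
  with probabilities 0.709/0.212/0.079: the reported rates 66.9/20/7.5
  sum to 94.4, so they are normalized to one; the original denominator
  convention is not recoverable from the text.
* **Mendelian segregation** — each carrying panicle contributes one
  selfed M2 seed whose genotype is absent/heterozygous/homozygous with
  probabilities exactly 1/4, 1/2, 1/4 (the M1 germline is heterozygous).
* **Sequencing noise** — depths are negative binomial with mean 30 and
  size 25 (coverage CV ≈ 0.27, typical of short-read WGS); variant reads
  are binomial with p = 0.5 (het), 1 − e (hom) or e (absent),
  e = 0.1% by default.

What the generator does **not** emulate: alignment and mapping artifacts,
strand bias, error clustering in repeats, structural variants, GC-coverage
coupling, or selection against deleterious homozygotes. Passing the
end-to-end tests therefore demonstrates correctness of the screening
logic under idealized read evidence, not robustness to real-data artifact
modes (which the count-table representation abstracts away by design).

Two consequences of the model worth knowing when interpreting outputs:

* With exact Mendelian segregation, detected het:hom ratios center at
  2.0 and slightly below (heterozygotes are occasionally missed below the
  0.30 VAF cut or misclassified above 0.75), while field observations in
  CIB rice sit at 2.02–2.30. The gap is consistent with selection against
  deleterious homozygotes, which the generator deliberately does not
  model; the acceptance suite documents this by checking the observed
  band against the simulated cohort.
* Sharing rates measured from screened M2 calls understate the generative
  panicle-sharing probabilities, because a mutation shared by three
  panicles is seen in all three M2 samples only when none of the three
  independent segregations comes up absent (probability (3/4)^3). The
  lineage recovery tests therefore partition the truth lineage directly;
  the same deflation affects real M2-based sharing estimates.

# Effect annotation

Gene models are held as a `GRanges` of gene/exon/CDS/UTR features (GFF3
in and out via `rtracklayer`). Region precedence is exon (CDS) > UTR >
splice site > intron > upstream/downstream > intergenic, with a 5,000 bp
up/downstream window (the convention of the widely used annotators; the
window is configurable). For up/downstream the nearest gene wins, with a
deterministic gene-id tie-break. Splice sites are the 2 bp at each intron
end and are HIGH impact, as are InDels whose footprint crosses an
exon–intron boundary. One primary annotation is reported per call.

Coding effects translate the affected codon on the coding strand
(standard genetic code): synonymous, missense, stop_gained, stop_lost,
start_lost (any change destroying the ATG initiator), frameshift (CDS
InDel with length not a multiple of 3) or inframe_indel. Impact classes
follow the fixed table HIGH {stop_gained, stop_lost, start_lost,
frameshift, splice_disruptor}, MODERATE {missense, inframe_indel}, LOW
{synonymous}, MODIFIER {noncoding}. The test suite verifies the codon
arithmetic against an independent whole-protein translation oracle,
including reverse-strand genes, and candidate genes are exactly the
homozygous HIGH/MODERATE gene hits deduplicated per line and gene.

The amino-acid change matrix counts ordered (from, to) pairs over the 20
standard residues; coverage is the number of distinct observed changes
over the 380 possible ordered pairs.

# Dose–response fitting

The single-hit multi-target survival model is
$S(D) = 1 - (1 - e^{-D/D_0})^N$, evaluated as
`-expm1(N * log1p(-exp(-D/D0)))` to stay accurate when the curve is
within double precision of 0 or 1. The shoulder dose is defined as
$D_q = D_0 \ln N$ (the standard target-theory definition; the source
material names Dq without defining it), and `shmtDoseAt()` gives the
closed-form inverse $-D_0\ln(1-(1-f)^{1/N})$, verified against bisection
in the tests.

Fitting is bounded nonlinear least squares (`minpack.lm`) from a fixed
multi-start grid (D0 ∈ {10, 20, 40, 80, 160} Gy × N ∈ {1, 2, 5, 10, 20,
50}); the lowest residual sum of squares wins, so fits are deterministic
without a seed and scale-equivariant in dose. Responses are fitted on the
relative (fraction-of-control) scale. Data that increase with dose are
rejected as not survival-like.

A caveat the tests encode explicitly: D0 and N are individually poorly
identified from noisy survival data (their errors are strongly
anticorrelated along the fitted shoulder), while the functionals Dq and
LD50 are stable. With Gaussian noise of σ = 0.03 and three replicates,
LD50 and Dq are recovered within 5% in every simulation replicate, but N
alone can deviate by tens of percent. Reporting and downstream use should
prefer Dq and LD50.

For endpoints that rise above the control at low dose, the Brain–Cousens
hormesis curve $y(D) = c + (d - c + fD)/(1 + e^{b(\ln D - \ln e)})$ is
fitted the same way. This specific functional form is the package's
choice of a standard stimulation model; the source material plots a
"dose-response-stimulation" fit without printing its form. When no
stimulation signal is present the monotone log-logistic (f = 0) is
fitted instead and flagged. The slope b shares the identifiability caveat
of N; the control level d and inflection dose e are the stable
parameters.

# Numerical and design choices

* Detection-group screening, parental filtering and cross-plant filtering
  are pure functions of the count table and sample sheet; screening the
  evidence of an already-screened call set reproduces it unchanged, and
  tightening either VAF threshold can only remove calls (both properties
  are tested).
* InDel identity matching (for the cross-plant filter and panicle
  partition) first normalizes representations by left alignment against
  the genome, so equivalent descriptions at repeat stretches compare
  equal.
* Per-dose standard deviations use the n−1 denominator; lines with zero
  calls count as zeros in per-line means; a dose with a single line
  reports SD 0 with a flag.
* VAF uses total site depth as denominator ("by read count"), not
  ref+alt.
* All simulation entry points take one integer seed; the RNG state of the
  caller is saved and restored, and two runs with equal seed and
  configuration are byte-identical through every writer.

# Problem sizes

The default synthetic cohort is six doses (25–150 Gy) × 10 M1 plants × 3
panicles plus 3 controls at 30× depth on a 1 Mb genome — about 5,300
truth mutations and 183 samples, which screens in a few seconds. The test
suite uses this full design for end-to-end recovery and smaller genomes
(50–200 kb) elsewhere; spectrum and lineage recovery use 10,000 sampled
mutations, and the annotation oracle compares 1,000 random CDS
substitutions. These sizes were chosen so the whole suite exercises every
stage at statistically meaningful scale while remaining quick to run.

# Limitations

* The pipeline consumes allele-count tables; it does not construct
  pileups from BAM files or recalibrate base qualities.
* No structural-variant or MNP calling; equal-length multi-base alleles
  are rejected explicitly.
* GO enrichment and expression-based candidate ranking are out of scope.
* The synthetic cohort's idealized noise model means measured
  precision/recall bound real-data performance from above.

# Session info

```{r}
sessionInfo()
```
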