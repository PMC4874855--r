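---
title: "Frequency-based MHC amplicon genotyping and diversity analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-based MHC amplicon genotyping and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliMHC)
```

## The problem

MHC class IIB exon 2 encodes the antigen-binding groove of class II
molecules and is among the most polymorphic regions of vertebrate genomes.
In many non-model species (here, the motivating system is a small viperid
snake), a single degenerate primer pair co-amplifies an unknown number of
paralogous loci, so an individual's amplicon contains a mixture of 1 to
2·L alleles for L loci. Deep amplicon sequencing resolves that mixture, but
PCR substitution errors and template-switching chimeras create hundreds of
low-frequency artifactual variants per run. The analytical problem is to
decide which unique sequences are real alleles, assemble per-individual
multilocus genotypes, and only then compute selection and diversity
statistics.

## The genotyping model

The pipeline is a stepwise filter with two inclusive 10% thresholds:

1. **Perfect demultiplexing.** A read is used only if (in one orientation)
   it begins with a known 10-bp MID, continues with the forward primer, and
   ends with the reverse complement of the reverse primer, with IUPAC
   degeneracy codes matching any of their allowed bases. Anything else is
   discarded with a reason (`no_mid`, `no_primer`, `multiple_mid`). This is
   deliberately strict: with artifact filtering downstream, losing reads is
   cheaper than mis-assigning them.
2. **Reference-identity screen.** Each unique trimmed variant must reach
   ≥ 70% identity over ≥ 120 nt in a gap-tolerant local alignment against a
   supplied FASTA of known MHC sequences. This replaces a remote BLASTn
   check, which is not reproducible offline; "best hit is MHC" becomes
   "best local alignment against the supplied MHC references passes". A
   same-length exact-position identity pre-pass short-circuits the dynamic
   programming for the bulk of near-identical variants (a speedup only: any
   variant failing the pre-pass still gets the full alignment).
3. **Global MPAF filter.** MPAF(v) = max_s count(s, v)/total(s). Variants
   with MPAF < 0.10 are artifacts. The rationale: a true allele is at high
   frequency in at least the amplicons of low-copy-number carriers, whereas
   each individual artifact is rare in every amplicon. The threshold is
   inclusive (MPAF = 0.10 is kept) and applied once, to the pooled run.
4. **Within-amplicon call.** In each amplicon, a catalog allele is called
   iff its count is ≥ 0.10 × the count of the most frequent *catalog*
   allele there (inclusive). Restricting the reference count to catalog
   alleles is one of two defensible readings of "most frequent variant";
   both are implemented (`within-ref raw` would use the raw top variant),
   with the catalog reading as default because raw top variants can
   themselves be high-frequency artifacts in shallow amplicons. Ties for
   the top allele are broken lexicographically by sequence, for determinism.
5. **Depth QC.** Samples with fewer than `min_reads = 100` usable reads are
   excluded from genotyping. The emulated study excluded four shallow
   samples without stating its cutoff; 100 sits just below its reported
   minimum retained depth (105 reads), so it reproduces that decision
   boundary without inventing a stricter one.
6. **Pseudogene flagging.** Alleles whose length is incongruent with the
   expected fragment length modulo 3 (frameshift) or whose translation has
   an internal stop are flagged non-functional. They stay in genotypes (they
   are real sequences, informative for richness) but never enter distance or
   dN/dS computations.

A diploid individual with k called alleles implies ≥ ⌈k/2⌉ loci; the package
reports this bound and a Spearman check that per-individual allele counts
are not driven by read depth.

## Selection statistics

dN/dS uses the modified Nei–Gojobori method with Jukes–Cantor correction.
Site counting weights the one transition at each codon position by
R/(R + 1) and each of the two transversions by 1/(2(R + 1)), where R is the
assumed transition/transversion ratio (so R = 0.5, i.e. no bias given the
1:2 opportunity, reduces to the unmodified equal-1/3 weighting). Changes
that would create a stop codon are counted as nonsynonymous, which keeps
synonymous + nonsynonymous sites equal to exactly 3 per codon. Differences
between codon pairs are averaged with equal weight over all minimal
substitution pathways, excluding pathways that pass through an intermediate
stop codon (all pathways are used if every one is blocked). Per-pair
proportions pN, pS are corrected by d = −(3/4)·ln(1 − 4p/3) (undefined at
p ≥ 0.75; such pairs are dropped with a warning) and averaged over all
pairs.

Choices worth stating:

* **R defaults to 2.0** (a typical empirical value for nuclear coding
  sequence) and is configurable; the unmodified method is available as
  R = 0.5. The motivating study does not state its R.
* **Standard errors** come from resampling codon positions within the
  analysed partition with replacement (1000 replicates by default, seeded).
  The Z statistic uses the bootstrap SE of the *joint* difference dN − dS
  rather than adding independent SEs, because dN and dS estimated from the
  same codons are positively correlated and independence would overstate
  the SE. The test is one-tailed for positive selection (dN > dS).
* **The ABS mask is user input** (1-based codon positions), since
  antigen-binding-site assignments come from structural homology to the
  human molecule and belong to the configuration, not the code. The
  pipeline default is a 14-codon mask mirroring the count of
  human-homology ABS residues in the 55-codon fragment.
* **Tamura–Nei distances** use the pair's own empirical base frequencies,
  the closed-form TN93 estimator with two transition classes, and no gamma
  rate variation (the plain distance is what the motivating analysis
  names). Saturated log arguments return NA rather than a clamped value.

## Population statistics

* π is the mean pairwise proportion of differing sites; its SE uses Nei's
  (1987) sampling variance. For population-level π and Tajima's D the
  default sequence set is the *distinct* alleles observed in the population
  (each counted once); a carrier-weighted mode (one count per carrying
  individual) is provided because presence/absence genotypes without locus
  assignment make the "sample of sequences" genuinely ambiguous.
* Tajima's D follows the 1989 constants exactly; p-values are reported from
  both the fitted beta approximation on the asymptotic [Dmin, Dmax] support
  and the normal approximation, two-tailed. D is tested against zero.
* Rarefied allelic richness: microsatellites use Hurlbert's closed form on
  allele copy counts at g gene copies (per locus, averaged with SE over
  loci); MHC presence sets are rarefied by resampling g individuals
  (seeded, SD over 1000 subsamples), because copy numbers per individual
  are unknowable without locus assignment. When g equals the population
  size the observed richness is returned with SE 0, which is why the
  smallest population's rarefied value carries no error bar.
* Heterozygosities: Ho is the fraction of heterozygous individuals; He is
  Nei's unbiased estimator (2n/(2n−1))(1 − Σp²); population values are
  across-locus means with SEs over loci. Missing genotypes are dropped
  locus-wise; no imputation.
* Randomization tests permute individuals between two populations
  preserving sizes, two-tailed on |Δ statistic|, with the +1/(n+1)
  correction in Monte-Carlo mode; when the number of distinct splits is
  small the test enumerates all of them exactly instead (no correction
  needed, the null distribution is complete).
* Known offspring can be flagged and are removed from population-level
  summaries (they duplicate maternal alleles and would bias richness).

## The synthetic world

The generator emulates the motivating study's stated conditions: three
populations of unequal size (default 79/17/6 — the analysis sample sizes),
≥ 6 loci with 1–12 alleles per individual (sizes uniform on 1..2·n_loci), a
24-allele functional pool plus one pseudogene carrying a 13-bp deletion at
positions 111–123, per-amplicon depth lognormal with mean 2214 and SD 1603
(the reported mean ± SD; the acceptance world uses mean 200 as its criterion
states), per-base substitution errors at 0.005 and per-read chimera
probability 0.05 (the study reports no artifact rates; these are the
calibration the build contract fixes). Population allele pools are nested
subsets of descending size, producing the descending-richness gradient the
study observed. Chimeras form only between alleles of the same individual
(PCR chimeras arise within a reaction) at a uniform breakpoint. The fragment
is 165 nt — the nearest codon multiple to the assayed 166-bp fragment — so
translation is frame-clean.

What the simulator does **not** emulate: 454 flowgram noise and
homopolymer indel errors (point errors are substitutions only), quality
score structure (FASTQ output is constant Q40), PCR efficiency differences
among alleles (all genotype alleles are amplified evenly), and
transition-biased mutation. The last one matters for interpretation: pool
divergence and point errors are transversion-neutral, so selection analyses
of *simulated* catalogs should use R = 0.5; running them at the real-data
default R = 2 inflates dN/dS on simulated alleles (synonymous changes are
transition-enriched, so overweighting transitions inflates the synonymous
site count and deflates pS). The simulator's stop-codon avoidance also
slightly depletes nonsynonymous divergence paths, so even matched-R runs sit
a little above dN/dS = 1. A green end-to-end test therefore establishes
that the *filtering and arithmetic* are correct, not that the simulator
reproduces the biological selection signal.

## Numerical choices and degenerate inputs

* Both 10% thresholds are inclusive, with a 1e-9/1e-12 epsilon guard
  against floating-point rounding at exact boundaries.
* Jukes–Cantor and TN93 return NA (with a warning where informative) on
  saturation instead of clamping.
* Zero-read samples are excluded from MPAF maxima; samples with no catalog
  allele observed are flagged ungenotypeable rather than given empty
  genotypes.
* All randomness flows from one master seed through named substreams
  (`derive_seed(seed, stage)`), so each stage is individually reproducible
  and two runs with equal configs are byte-identical; derived seeds stay
  below 2^31.
* Spearman correlations delegate to `stats::cor.test` (midrank ties,
  t-approximation, exact enumeration for small tie-free samples).

## Known limitations

* No quality-aware denoising or ASV-style clustering; the frequency filter
  is deliberately conservative and can under-call alleles of high-copy
  individuals (low per-allele within-amplicon frequency), exactly as the
  motivating method acknowledges. Rarely carried true alleles can also fail
  the global MPAF filter in small samples.
* Codon-model maximum likelihood (M1a/M2a, M7/M8, Bayes Empirical Bayes
  site identification) is out of scope; the dN/dS machinery here is the
  counting method only.
* The reference screen is only as good as the supplied reference FASTA; it
  is a similarity filter, not an orthology assignment.
* Alleles are assumed alignable without gaps (equal length after trimming);
  frameshifted alleles are excluded from sequence statistics rather than
  realigned.
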