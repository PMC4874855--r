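# ampliMHC

Genotyping multilocus MHC class IIB exon 2 alleles from MID-tagged amplicon
deep-sequencing reads, with downstream tests of selection and
population-genetic summaries. The package is aimed at conservation and
evolutionary geneticists who genotype hypervariable immune loci (many similar
loci co-amplified by one degenerate primer pair) in non-model species, where
PCR point errors and chimeras generate large numbers of artifactual sequence
variants that must be separated from true alleles before any diversity
statistic is meaningful.

## The method

**Artifact filtering.** Reads are kept only if they carry, in either
orientation, a perfect match to one of the supplied 10-bp multiplex
identifiers (MIDs), the forward primer and the reverse primer (IUPAC
degeneracy honoured); MID and primers are trimmed and exact trimmed sequences
are tallied per amplicon. After a reference-identity screen (a local,
reproducible stand-in for a remote BLASTn check), each variant *v* is scored
by its **maximum per-amplicon frequency**,

MPAF(*v*) = max over samples *s* of *n*(*s*, *v*) / *N*(*s*),

the highest within-amplicon read fraction it reaches anywhere in the run.
Variants with MPAF < 0.10 are treated as artifacts; the rest form the
putative allele catalog. Within each amplicon, a catalog allele is called
only if its count is ≥ 0.10 × the count of that amplicon's most frequent
catalog allele (both thresholds inclusive). Alleles with frameshifting
indels or internal stop codons are flagged as pseudogenes and excluded from
selection analyses. A diploid individual with *k* called alleles implies at
least ⌈*k*/2⌉ loci.

**Selection.** On the functional alleles the package computes pairwise
amino-acid p-distances and Tamura–Nei (1993) distances, and partitioned
dN/dS (total / antigen-binding sites / non-ABS) by the modified Nei–Gojobori
method: per-codon site counts weighted by a transition/transversion ratio
*R*, differences averaged over minimal substitution pathways, Jukes–Cantor
correction d = −(3/4)·ln(1 − 4p/3), codon-bootstrap standard errors, and a
one-tailed Z-test of dN > dS.

**Diversity.** Per population: nucleotide diversity π, Tajima's D (with
beta- and normal-approximation p-values), observed/private/rarefied allelic
richness (Hurlbert's closed form for microsatellite gene copies, seeded
individual resampling for MHC presence sets), Nei's unbiased expected
heterozygosity, and randomization tests between populations. Per individual:
multilocus microsatellite heterozygosity, MHC allele counts and π, and
Spearman correlations between them.

**Synthetic data.** A first-class simulator generates a diverse allele pool
(including a pseudogene with a 13-bp deletion at positions 111–123),
multilocus genotypes of 1–12 alleles across three populations of unequal
size, lognormal per-amplicon depth, per-base point errors and
within-individual PCR chimeras — with full read provenance, so the whole
pipeline is testable against known truth.

## Worked example

```r
library(ampliMHC)
cfg <- run_config(out_dir = "run", mode = "all", seed = 42,
                  sim = sim_config(seed = 42,
                                   individuals_per_population = c(79, 17, 6),
                                   depth_mean = 200, depth_sd = 60),
                  ts_tv = 0.5)   # simulator mutations have no transition bias
res <- run_pipeline(cfg)
genotype_accuracy(res$genotypes, res$truth, res$catalog)
```

This simulates ~20,000 reads for 102 individuals (24 functional alleles + 1
pseudogene), genotypes them, and prints (seed 42):

```
catalog: 24 alleles, 23 functional
min loci: 6
depth bias: n=102 rho=0.087 p=0.382
  partition    dN  se_dN    dS  se_dS dn_ds     Z      p
1     Total 0.451 0.0435 0.324 0.0598  1.39 1.793 0.0365
2       ABS 0.613 0.1270 0.319 0.1347  1.92 1.370 0.0854
3   non-ABS 0.405 0.0475 0.337 0.0758  1.20 0.887 0.1876
  population n_mhc mhc_richness mhc_private mhc_rarefied    pi tajima_d
1       pop1    79           24           7         19.9 0.302     1.45
2       pop2    17           17           0         15.5 0.298     1.41
3       pop3     6           11           0         11.0 0.322     1.36
recall 0.965 precision 1.000
```

Reading this: the MPAF filter recovered 24 of the 25 simulated alleles and
correctly flagged the deletion-bearing pseudogene; one individual carried 12
alleles, implying ≥ 6 loci; allele counts are uncorrelated with read depth
(no depth-driven genotyping bias); per-individual genotype recall is 0.965
with no false-positive alleles. The population summary recovers the
simulated richness gradient (nested allele pools of descending size). The
mildly elevated dN/dS reflects the simulator's stop-codon avoidance, not
selection — see the methods vignette.

The command-line entry point wraps the same stages:

```sh
Rscript -e 'ampliMHC::pipeline_main()' --mode all --seed 42 --out run
```

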