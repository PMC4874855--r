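# nucleotide diversity, Tajima's D, richness, rarefaction, heterozygosity,
# randomization tests, Spearman correlation, population summary

test_that("nucleotide diversity is the mean pairwise p-distance", {
  expect_equal(nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTAC")), 0)
  expect_equal(nucleotide_diversity(c("ACGTACGTAC", "AGGTACGTAT")), 0.2)
  expect_true(is.na(nucleotide_diversity("ACGT")))
  set.seed(1)
  seqs <- vapply(1:6, function(i) random_dna(1, 50), character(1))
  d <- pairwise_distances(stats::setNames(seqs, 1:6), method = "p")
  expect_equal(nucleotide_diversity(seqs), mean(d[upper.tri(d)]),
               tolerance = 1e-12)
  expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs), tolerance = 1e-12)
  # weights: duplicating a sequence equals weighting it twice
  w <- nucleotide_diversity(seqs, weights = c(2, 1, 1, 1, 1, 1))
  dup <- nucleotide_diversity(c(seqs[1], seqs))
  expect_equal(w, dup, tolerance = 1e-12)
})

test_that("Tajima's D matches the straight-from-the-formulas oracle", {
  set.seed(2)
  base <- random_dna(1, 60)
  seqs <- vapply(1:10, function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(60, sample(0:6, 1))
    ch[idx] <- vapply(ch[idx], function(bse)
      sample(setdiff(c("A", "C", "G", "T"), bse), 1), character(1))
    paste(ch, collapse = "")
  }, character(1))
  res <- tajimas_d(seqs)
  expect_equal(res$D, oracle_tajima_d(seqs), tolerance = 1e-10)
  expect_true(res$p_beta >= 0 && res$p_beta <= 1)
  expect_true(res$p_normal >= 0 && res$p_normal <= 1)
  # no segregating sites -> undefined
  mono <- rep(base, 5)
  expect_true(is.na(tajimas_d(mono)$D))
  expect_error(tajimas_d(seqs[1:3]), "at least 4")
  # coalescent-free neutral null: each segregating site gets a derived allele
  # at frequency i with probability proportional to 1/i (the neutral site
  # frequency spectrum), so D should be loosely centred near 0 across seeds
  ds <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 10; L <- 100; S <- 25
    mat <- matrix("A", n, L)
    pfs <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
    for (s in seq_len(S)) {
      i <- sample(n - 1, 1, prob = pfs)
      mat[sample(n, i), s] <- "G"
    }
    tajimas_d(apply(mat, 1, paste, collapse = ""))$D
  }, numeric(1))
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.8)
})

test_that("allelic richness counts distinct and private alleles", {
  geno <- list(i1 = c("a", "b"), i2 = c("a"), i3 = c("c", "d"), i4 = c("a", "c"))
  pop <- c(i1 = "P", i2 = "P", i3 = "Q", i4 = "Q")
  r <- allelic_richness(geno, pop, kind = "mhc")
  expect_equal(r$richness[r$population == "P"], 2L)  # a, b
  expect_equal(r$richness[r$population == "Q"], 3L)  # c, d, a
  expect_equal(r$private[r$population == "P"], 1L)   # b
  expect_equal(r$private[r$population == "Q"], 2L)   # c, d
  # union over populations >= per-population counts
  expect_gte(length(unique(unlist(geno))), max(r$richness))
  # all individuals identical homozygotes -> 1
  ms <- data.frame(individual = c("x", "y"), population = "P",
                   locus = "L1", allele1 = "07", allele2 = "07")
  expect_equal(allelic_richness(ms, kind = "microsat")$richness, 1)
})

test_that("rarefied richness: Hurlbert closed form and resampling agree", {
  # worked value: copies {3,1}, g = 2 -> 1 + (1 - C(3,2)/C(4,2)) = 1.5
  expect_equal(rarefied_richness(c(3, 1), g = 2, mode = "analytic")$value, 1.5)
  # g = N returns observed richness with SE 0
  expect_equal(rarefied_richness(c(3, 1), g = 4, mode = "analytic")$value, 2)
  sets <- list(a = c("x", "y"), b = "x", c = c("z"), d = c("x", "z"))
  r_full <- rarefied_richness(sets, g = 4, mode = "resampling")
  expect_equal(r_full$value, 3)
  expect_equal(r_full$se, 0)
  expect_error(rarefied_richness(c(3, 1), g = 5, mode = "analytic"), "exceeds")
  # Monte-Carlo subsampling of gene copies matches Hurlbert within 3 SE
  counts <- c(12, 5, 2, 1)
  g <- 8
  analytic <- rarefied_richness(counts, g, mode = "analytic")$value
  set.seed(5)
  copies <- rep(seq_along(counts), counts)
  mc <- vapply(1:2000, function(i) length(unique(sample(copies, g))),
               numeric(1))
  expect_lt(abs(analytic - mean(mc)), 3 * stats::sd(mc) / sqrt(length(mc)))
  # monotone nondecreasing in g
  vals <- vapply(1:20, function(gg)
    rarefied_richness(counts, gg, mode = "analytic")$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("heterozygosities follow Nei's unbiased estimator", {
  g <- data.frame(individual = c("i1", "i2"), locus = "L1",
                  allele1 = c("A", "A"), allele2 = c("A", "B"))
  h <- heterozygosities(g)
  expect_equal(h$ho, 0.5)
  expect_equal(h$he, (4 / 3) * (1 - 0.75^2 - 0.25^2))  # = 0.5
  mono <- data.frame(individual = c("i1", "i2"), locus = "L1",
                     allele1 = "A", allele2 = "A")
  hm <- heterozygosities(mono)
  expect_equal(hm$ho, 0)
  expect_equal(hm$he, 0)
  # Hardy-Weinberg simulated data: mean Ho ~ He
  cfg <- sim_config(seed = 21L, individuals_per_population = 500L)
  ms <- simulate_microsats(cfg, n_loci = 1L,
                           allele_freqs = list(c(a = 0.4, b = 0.35, c = 0.25)))
  hw <- heterozygosities(ms)
  expect_lt(abs(hw$ho - hw$he), 0.05)
})

test_that("multilocus heterozygosity uses the genotyped-locus denominator", {
  g <- data.frame(
    individual = rep(c("i1", "i2", "i3"), each = 6),
    locus = rep(paste0("L", 1:6), 3),
    allele1 = c("A", "A", "A", "B", "C", "D",   # i1: 3 het of 6
                rep("A", 6),                    # i2: all hom
                "A", "B", NA, NA, "C", "D"),    # i3: missing loci
    allele2 = c("B", "B", "B", "B", "C", "D",
                rep("A", 6),
                "B", "C", NA, NA, "C", "D"))
  mlh <- multilocus_heterozygosity(g)
  expect_equal(unname(mlh["i1"]), 0.5)
  expect_equal(unname(mlh["i2"]), 0)
  expect_equal(unname(mlh["i3"]), 0.5)  # 2 het of 4 typed
})

test_that("randomization test matches exhaustive enumeration and nulls", {
  # size-(2,2) groups: all 6 splits enumerated exactly
  a <- c(10, 12); b <- c(1, 2)
  res <- randomization_test(a, b, statistic = function(x) mean(unlist(x)),
                            mode = "exhaustive")
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(4, 2)
  pool <- c(a, b)
  vals <- apply(splits, 2, function(ia)
    abs(mean(pool[ia]) - mean(pool[-ia])))
  expect_equal(res$p, mean(vals >= obs - 1e-12))
  expect_equal(res$n_used, 6L)
  # identical populations -> p near 1
  same <- randomization_test(c(5, 5, 5), c(5, 5, 5),
                             statistic = function(x) mean(unlist(x)),
                             mode = "exhaustive")
  expect_equal(same$p, 1)
  expect_error(randomization_test(a, b, mean, n_perm = 0), "n_perm")
})

test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, rev(1:10))$rho, -1)
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
  set.seed(6)
  x <- sample(1:5, 50, TRUE); y <- sample(1:5, 50, TRUE)  # heavy ties
  s <- spearman_cor(x, y)
  expect_true(abs(s$rho) <= 1 && s$p >= 0 && s$p <= 1)
})

test_that("population summary recovers simulated diversity gradients", {
  cfg <- sim_config(seed = 31L, individuals_per_population = c(30L, 12L, 6L),
                    n_alleles_pool = 18L, depth_mean = 150, depth_sd = 40,
                    point_error_rate = 0, chimera_rate = 0)
  pool <- simulate_allele_pool(cfg)
  truth <- simulate_genotypes(pool, cfg)
  gt <- structure(list(mhc = lapply(truth$genotype, identity),
                       population = truth$population,
                       microsat = simulate_microsats(cfg),
                       read_totals = NULL),
                  class = "genotype_table")
  smry <- population_summary(gt, pool, n_resample = 300, seed = 2)
  expect_equal(nrow(smry), 3L)
  expect_equal(smry$n_mhc, c(30L, 12L, 6L))
  # nested pool subsets: descending observed richness
  expect_true(all(diff(smry$mhc_richness) <= 0))
  # rarefied <= observed; smallest population rarefied == observed, SE 0
  expect_true(all(smry$mhc_rarefied <= smry$mhc_richness + 1e-9))
  expect_equal(smry$mhc_rarefied[3], smry$mhc_richness[3])
  expect_equal(smry$mhc_rarefied_se[3], 0)
  expect_true(all(smry$ho >= 0 & smry$ho <= 1, na.rm = TRUE))
  expect_true(all(smry$he >= 0 & smry$he <= 1, na.rm = TRUE))
  expect_true(all(smry$pi >= 0, na.rm = TRUE))
  # exclusions flow through
  smry2 <- population_summary(gt, pool, n_resample = 50, seed = 2,
                              exclude = stats::setNames("offspring",
                                                        names(gt$mhc)[1]))
  expect_equal(smry2$n_mhc[1], 29L)
})
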