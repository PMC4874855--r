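# Population- and individual-level diversity statistics: nucleotide diversity,
# Tajima's D, allelic richness (observed, private, rarefied), expected and
# observed heterozygosity, multilocus heterozygosity, randomization tests and
# Spearman rank correlations, assembled into a population summary table.

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing nucleotide sites (pairwise deletion
#' of gaps/ambiguous bases). With \code{weights}, pairs are weighted by the
#' product of their sequence weights (occurrence-weighted mode).
#'
#' @param seqs character vector of equal-length sequences (>= 2).
#' @param weights optional non-negative per-sequence weights.
#' @param variance also return the sampling variance (Nei 1987, eq. 10.7).
#' @return pi, or list(pi, variance) when \code{variance = TRUE}; NA with
#'   fewer than 2 sequences.
#' @export
nucleotide_diversity <- function(seqs, weights = NULL, variance = FALSE) {
  n <- length(seqs)
  if (n < 2L) {
    return(if (variance) list(pi = NA_real_, variance = NA_real_) else NA_real_)
  }
  d <- pairwise_distances(seqs, method = "p")
  iu <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[iu]
  if (is.null(weights)) {
    w <- rep(1, nrow(iu))
    denom <- sum(w[!is.na(dv)])
  } else {
    if (length(weights) != n || any(weights < 0)) stop("bad weights")
    w <- weights[iu[, 1]] * weights[iu[, 2]]
    # equivalent to expanding each sequence into `weight` copies: pairs of
    # identical copies (distance 0) enter the denominator
    W <- sum(weights)
    denom <- W * (W - 1) / 2
  }
  pi <- sum(w * dv, na.rm = TRUE) / denom
  if (!variance) return(pi)
  L <- nchar(seqs[[1]])
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, variance = v)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Computed from the number of segregating sites S and the mean number of
#' pairwise differences, with the standard Tajima (1989) constants. P-values
#' are returned from both the fitted beta approximation (on the asymptotic
#' [Dmin, Dmax] support) and the normal approximation, two-tailed.
#'
#' @param seqs character vector of >= 4 equal-length sequences. Sites with
#'   gaps/ambiguous bases are treated as missing (excluded pairwise for
#'   differences; a site is segregating if it carries >= 2 distinct
#'   unambiguous bases).
#' @return list(D, S, k, n, p_beta, p_normal); D is NA when S = 0.
#' @export
tajimas_d <- function(seqs) {
  n <- length(seqs)
  if (n < 4L) stop("need at least 4 sequences")
  m <- seq_matrix(seqs)
  m[!(m %in% DNA_BASES)] <- NA
  seg <- apply(m, 2, function(col) length(unique(col[!is.na(col)])) > 1L)
  S <- sum(seg)
  # mean pairwise difference count (pairwise deletion)
  pairs <- utils::combn(n, 2)
  k <- mean(apply(pairs, 2, function(ij) {
    a <- m[ij[1], ]; b <- m[ij[2], ]
    ok <- !is.na(a) & !is.na(b)
    sum(a[ok] != b[ok])
  }))
  if (S == 0L) {
    return(list(D = NA_real_, S = 0L, k = k, n = n,
                p_beta = NA_real_, p_normal = NA_real_))
  }
  cst <- tajima_constants(n)
  D <- (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  # beta approximation on the asymptotic support (Tajima 1989)
  Dmin <- (2 / n - 1 / cst$a1) / sqrt(cst$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / cst$a1) / sqrt(cst$e2)
  tmp1 <- 1 + Dmin * Dmax
  tmp2 <- Dmax - Dmin
  a <- -tmp1 * Dmax / tmp2
  b <- tmp1 * Dmin / tmp2
  pb <- stats::pbeta((D - Dmin) / tmp2, b, a)
  p_beta <- if (is.na(pb)) NA_real_ else 2 * min(pb, 1 - pb)
  p_normal <- 2 * stats::pnorm(-abs(D))
  list(D = D, S = as.integer(S), k = k, n = n,
       p_beta = p_beta, p_normal = p_normal)
}

#' Observed allelic richness and private alleles per population
#'
#' For presence/absence MHC genotypes, richness is the number of distinct
#' alleles observed in a population; for codominant microsatellites, per-locus
#' allele counts with their across-locus mean and SE are also returned.
#'
#' @param genotypes for \code{kind = "mhc"}: named list individual -> allele
#'   names; for \code{kind = "microsat"}: data.frame (individual, population,
#'   locus, allele1, allele2).
#' @param population named character vector individual -> population (ignored
#'   for microsat input, which carries its own population column).
#' @param kind "mhc" or "microsat".
#' @return data.frame per population with richness (and private-allele counts
#'   for MHC; per-locus mean/SE for microsatellites).
#' @export
allelic_richness <- function(genotypes, population = NULL,
                             kind = c("mhc", "microsat")) {
  kind <- match.arg(kind)
  if (kind == "mhc") {
    if (is.null(population)) stop("population labels required")
    pops <- unique(population[names(genotypes)])
    sets <- lapply(pops, function(p) {
      unique(unlist(genotypes[names(genotypes)[population[names(genotypes)] == p]]))
    })
    names(sets) <- pops
    private <- vapply(pops, function(p) {
      others <- unique(unlist(sets[setdiff(pops, p)]))
      sum(!sets[[p]] %in% others)
    }, integer(1))
    data.frame(population = pops, richness = lengths(sets),
               private = private, row.names = NULL, stringsAsFactors = FALSE)
  } else {
    g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
    out <- lapply(unique(g$population), function(p) {
      gp <- g[g$population == p, ]
      per_locus <- tapply(seq_len(nrow(gp)), gp$locus, function(i) {
        length(unique(c(gp$allele1[i], gp$allele2[i])))
      })
      data.frame(population = p,
                 richness = mean(per_locus),
                 se = stats::sd(per_locus) / sqrt(length(per_locus)),
                 n_loci = length(per_locus), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
}

#' Rarefied allelic richness
#'
#' Analytic mode (codominant markers): Hurlbert's expectation
#' \code{sum_i [1 - C(N - N_i, g) / C(N, g)]} over allele copy counts
#' \code{N_i} in a sample of \code{N} gene copies rarefied to \code{g} copies.
#' Resampling mode (multilocus presence/absence genotypes): mean and SD of the
#' number of distinct alleles over seeded subsamples of \code{g} individuals.
#'
#' @param x analytic mode: integer vector of allele copy counts; resampling
#'   mode: named list individual -> allele names.
#' @param g rarefaction size (gene copies or individuals; \code{g <= N}).
#' @param mode "analytic" or "resampling".
#' @param n_resample subsamples for resampling mode.
#' @param seed RNG seed for resampling mode.
#' @return list(value, se); se is 0 when g equals the sample size.
#' @export
rarefied_richness <- function(x, g, mode = c("analytic", "resampling"),
                              n_resample = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "analytic") {
    counts <- as.numeric(x)
    N <- sum(counts)
    if (g > N) stop("g exceeds the number of gene copies")
    val <- sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
    list(value = val, se = 0)
  } else {
    n <- length(x)
    if (g > n) stop("g exceeds the number of individuals")
    if (g == n) {
      return(list(value = length(unique(unlist(x))), se = 0))
    }
    set.seed(seed)
    vals <- vapply(seq_len(n_resample), function(b) {
      length(unique(unlist(x[sample.int(n, g)])))
    }, numeric(1))
    list(value = mean(vals), se = stats::sd(vals))
  }
}

#' Observed and expected heterozygosity
#'
#' Per locus: Ho is the fraction of heterozygous individuals; He is Nei's
#' unbiased expectation \code{(2n / (2n - 1)) * (1 - sum p_i^2)} with n
#' genotyped diploids. Population values are across-locus means with SEs over
#' loci. Loci with no genotyped individuals are dropped with a warning.
#'
#' @param genotypes data.frame (individual, locus, allele1, allele2); rows
#'   with NA alleles are missing genotypes.
#' @return list(ho, he, se_ho, se_he, per_locus).
#' @export
heterozygosities <- function(genotypes) {
  g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
  loci <- unique(genotypes$locus)
  dropped <- setdiff(loci, unique(g$locus))
  if (length(dropped))
    warning("dropping loci with no genotyped individuals: ",
            paste(dropped, collapse = ", "))
  per_locus <- lapply(unique(g$locus), function(l) {
    gl <- g[g$locus == l, ]
    n <- nrow(gl)
    ho <- mean(gl$allele1 != gl$allele2)
    p <- table(c(gl$allele1, gl$allele2)) / (2 * n)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    data.frame(locus = l, n = n, ho = ho, he = he, stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, per_locus)
  k <- nrow(per_locus)
  list(ho = mean(per_locus$ho), he = mean(per_locus$he),
       se_ho = stats::sd(per_locus$ho) / sqrt(k),
       se_he = stats::sd(per_locus$he) / sqrt(k),
       per_locus = per_locus)
}

#' Multilocus heterozygosity per individual
#'
#' Number of heterozygous loci divided by the number of genotyped loci;
#' missing loci are excluded from the denominator.
#'
#' @param genotypes data.frame (individual, locus, allele1, allele2).
#' @return named numeric vector; NA for individuals with no genotyped locus.
#' @export
multilocus_heterozygosity <- function(genotypes) {
  ids <- unique(genotypes$individual)
  vapply(ids, function(id) {
    gi <- genotypes[genotypes$individual == id &
                      !is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
    if (nrow(gi) == 0L) return(NA_real_)
    mean(gi$allele1 != gi$allele2)
  }, numeric(1))
}

#' Two-group randomization test
#'
#' Permutes individuals between the two groups (preserving group sizes) and
#' compares the permuted absolute difference in the group statistic with the
#' observed one (two-tailed). Monte-Carlo mode applies the +1/(n+1)
#' small-sample correction; exhaustive mode enumerates every split exactly and
#' reports the exact proportion.
#'
#' @param pop_a,pop_b lists or vectors of per-individual data.
#' @param statistic function mapping one group to a single number.
#' @param n_perm number of Monte-Carlo permutations (>= 1).
#' @param seed RNG seed.
#' @param mode "auto" (exhaustive when there are at most \code{max_exhaustive}
#'   splits), "exhaustive", or "monte_carlo".
#' @param max_exhaustive split-count limit for auto-exhaustive enumeration.
#' @return list(p, observed, n_used, mode).
#' @export
randomization_test <- function(pop_a, pop_b, statistic, n_perm = 10000L,
                               seed = 1L, mode = c("auto", "exhaustive",
                                                   "monte_carlo"),
                               max_exhaustive = 20000) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  pool <- c(pop_a, pop_b)
  na <- length(pop_a); n <- length(pool)
  stat_of <- function(idx_a) {
    abs(statistic(pool[idx_a]) - statistic(pool[setdiff(seq_len(n), idx_a)]))
  }
  obs <- stat_of(seq_len(na))
  n_splits <- choose(n, na)
  if (mode == "auto") {
    mode <- if (n_splits <= max_exhaustive) "exhaustive" else "monte_carlo"
  }
  if (mode == "exhaustive") {
    splits <- utils::combn(n, na)
    vals <- apply(splits, 2, stat_of)
    p <- mean(vals >= obs - 1e-12)
    list(p = p, observed = obs, n_used = ncol(splits), mode = "exhaustive")
  } else {
    set.seed(seed)
    vals <- vapply(seq_len(n_perm), function(b) stat_of(sample.int(n, na)),
                   numeric(1))
    p <- (1 + sum(vals >= obs - 1e-12)) / (n_perm + 1)
    list(p = p, observed = obs, n_used = n_perm, mode = "monte_carlo")
  }
}

#' Spearman rank correlation
#'
#' Midrank handling of ties; p-value by exact enumeration for small samples
#' without ties and by the t-approximation otherwise (delegated to
#' \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(rho, p, n).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Population summary table
#'
#' Assembles, per population: sample sizes, microsatellite allelic richness
#' (observed and rarefied), observed/expected heterozygosity, and MHC Tajima's
#' D, allelic richness (observed, rarefied), nucleotide diversity and mean
#' alleles per individual — the shape of a neutral-vs-functional variation
#' summary table.
#'
#' @param genotypes a \code{genotype_table} (MHC genotypes and populations;
#'   microsatellites attached via \code{microsat}) or a named list with those
#'   elements.
#' @param catalog an \code{allele_catalog} supplying allele sequences for
#'   pi / Tajima's D (all catalog alleles carried by the population are used,
#'   distinct-allele mode by default).
#' @param rarefy_g rarefaction sizes: list(mhc =, microsat =) or NULL for
#'   automatic (smallest population).
#' @param pi_weighted use carrier-weighted (one count per carrier) rather than
#'   distinct-allele sequence sets for pi and Tajima's D.
#' @param exclude named character vector individual -> reason (e.g. known
#'   offspring) removed from population-level analyses.
#' @param n_resample resamples for MHC rarefaction.
#' @param seed RNG seed.
#' @return data.frame with one row per population; per-locus and exclusion
#'   details in attributes.
#' @export
population_summary <- function(genotypes, catalog, rarefy_g = NULL,
                               pi_weighted = FALSE, exclude = NULL,
                               n_resample = 1000L, seed = 1L) {
  mhc <- genotypes$mhc
  population <- genotypes$population
  microsat <- genotypes$microsat
  if (!is.null(exclude)) {
    mhc <- mhc[!names(mhc) %in% names(exclude)]
    if (!is.null(microsat))
      microsat <- microsat[!microsat$individual %in% names(exclude), ]
  }
  population <- population[names(mhc)]
  pops <- unique(population)
  if (!length(pops)) stop("no populated populations")
  seq_of <- stats::setNames(catalog$sequence, catalog$name)
  n_mhc <- vapply(pops, function(p) sum(population == p), integer(1))
  g_mhc <- (rarefy_g$mhc %||% min(n_mhc))
  rich <- allelic_richness(mhc, population, kind = "mhc")
  rows <- lapply(pops, function(p) {
    ids <- names(mhc)[population == p]
    sets <- mhc[ids]
    allele_names <- unlist(sets)
    if (pi_weighted) {
      tab <- table(allele_names)
      seqs <- seq_of[names(tab)]
      w <- as.numeric(tab)
    } else {
      seqs <- seq_of[unique(allele_names)]
      w <- NULL
    }
    # frameshifted alleles cannot enter the gap-free sequence stack
    keep <- nchar(seqs) == max(nchar(seq_of))
    seqs <- seqs[keep]; if (!is.null(w)) w <- w[keep]
    piv <- if (length(seqs) >= 2L) {
      nucleotide_diversity(seqs, weights = w, variance = TRUE)
    } else list(pi = NA_real_, variance = NA_real_)
    taj <- if (length(seqs) >= 4L) tajimas_d(seqs) else
      list(D = NA_real_, p_beta = NA_real_)
    rar <- rarefied_richness(sets, g = g_mhc, mode = "resampling",
                             n_resample = n_resample,
                             seed = derive_seed(seed, paste0("rar_", p)))
    counts <- lengths(sets)
    ms_row <- list(n_microsat = NA_integer_, ms_richness = NA_real_,
                   ms_richness_se = NA_real_, ms_rarefied = NA_real_,
                   ms_rarefied_se = NA_real_, ho = NA_real_, se_ho = NA_real_,
                   he = NA_real_, se_he = NA_real_)
    if (!is.null(microsat)) {
      msp <- microsat[microsat$population == p, ]
      msp_ok <- msp[!is.na(msp$allele1) & !is.na(msp$allele2), ]
      if (nrow(msp_ok)) {
        ms_row$n_microsat <- length(unique(msp$individual))
        ar <- allelic_richness(msp, kind = "microsat")
        ms_row$ms_richness <- ar$richness; ms_row$ms_richness_se <- ar$se
        g_ms <- rarefy_g$microsat %||% {
          n_per <- tapply(!is.na(microsat$allele1), microsat$population, sum) /
            length(unique(microsat$locus))
          2L * as.integer(floor(min(n_per)))
        }
        per_locus_rar <- vapply(unique(msp_ok$locus), function(l) {
          gl <- msp_ok[msp_ok$locus == l, ]
          copies <- table(c(gl$allele1, gl$allele2))
          rarefied_richness(as.integer(copies), g = min(g_ms, sum(copies)),
                            mode = "analytic")$value
        }, numeric(1))
        ms_row$ms_rarefied <- mean(per_locus_rar)
        ms_row$ms_rarefied_se <- stats::sd(per_locus_rar) /
          sqrt(length(per_locus_rar))
        het <- heterozygosities(msp_ok)
        ms_row$ho <- het$ho; ms_row$se_ho <- het$se_ho
        ms_row$he <- het$he; ms_row$se_he <- het$se_he
      }
    }
    data.frame(population = p, n_mhc = length(ids),
               n_microsat = ms_row$n_microsat,
               ms_richness = ms_row$ms_richness,
               ms_richness_se = ms_row$ms_richness_se,
               ms_rarefied = ms_row$ms_rarefied,
               ms_rarefied_se = ms_row$ms_rarefied_se,
               ho = ms_row$ho, ho_se = ms_row$se_ho,
               he = ms_row$he, he_se = ms_row$se_he,
               tajima_d = taj$D, tajima_p = taj$p_beta,
               mhc_richness = rich$richness[rich$population == p],
               mhc_private = rich$private[rich$population == p],
               mhc_rarefied = rar$value, mhc_rarefied_se = rar$se,
               pi = piv$pi, pi_se = sqrt(piv$variance),
               mean_alleles = mean(counts),
               mean_alleles_se = stats::sd(counts) / sqrt(length(counts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rarefy_g_mhc") <- g_mhc
  attr(out, "excluded") <- exclude
  out
}
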