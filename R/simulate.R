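# Synthetic-data generator: allele pools, multilocus MHC genotypes,
# artifact-laden MID-tagged amplicon reads, and diploid microsatellite
# genotypes, all with recorded ground truth. Every downstream stage of the
# package is testable against this truth without external data.

#' Simulation configuration
#'
#' Describes the simulated world: three populations of unequal size, a diverse
#' MHC allele pool feeding up to \code{2 * n_loci} alleles per individual,
#' heavy-tailed per-amplicon read depth, PCR point errors and chimeras, and an
#' optional pseudogene-like allele carrying an internal 13-bp deletion.
#'
#' Defaults reflect the emulated study system: per-amplicon depth lognormal
#' with mean 2214 and SD 1603 reads; a 165-nt in-frame fragment (the nearest
#' codon multiple to the assayed 166-bp exon 2 fragment); deletion span
#' 111-123 (1-based, inclusive) for the pseudogene.
#'
#' @param seed master integer seed; all stages derive named substreams from it.
#' @param individuals_per_population integer vector of population sizes.
#' @param population_names optional labels; default pop1, pop2, ...
#' @param n_alleles_pool number of functional alleles in the pool.
#' @param allele_length_nt fragment length in nt (multiple of 3 recommended).
#' @param n_loci number of MHC loci; individuals carry 1..2*n_loci alleles.
#' @param depth_mean,depth_sd lognormal depth parameters (reads per amplicon).
#' @param point_error_rate per-base substitution error probability.
#' @param chimera_rate per-read probability of being a PCR chimera.
#' @param include_pseudogene add one frameshifted allele with the deletion.
#' @param pseudogene_deletion_span 1-based inclusive nt positions deleted.
#' @param pool_fraction_per_population fraction of the pool accessible to each
#'   population (nested subsets), producing descending allelic richness.
#' @param fwd_primer,rev_primer template-specific primers (IUPAC codes allowed).
#' @param mid_length length of the multiplex identifier barcodes.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       individuals_per_population = c(79L, 17L, 6L),
                       population_names = NULL,
                       n_alleles_pool = 24L,
                       allele_length_nt = 165L,
                       n_loci = 6L,
                       depth_mean = 2214,
                       depth_sd = 1603,
                       point_error_rate = 0.005,
                       chimera_rate = 0.05,
                       include_pseudogene = TRUE,
                       pseudogene_deletion_span = c(111L, 123L),
                       pool_fraction_per_population = NULL,
                       fwd_primer = "AAGGBCSAGTGYTACTWYABBAACGG",
                       rev_primer = "TAGTTGTGSCKGCAGWASGTGTC",
                       mid_length = 10L) {
  cfg <- list(
    seed = as.integer(seed),
    individuals_per_population = as.integer(individuals_per_population),
    population_names = population_names %||%
      paste0("pop", seq_along(individuals_per_population)),
    n_alleles_pool = as.integer(n_alleles_pool),
    allele_length_nt = as.integer(allele_length_nt),
    n_loci = as.integer(n_loci),
    depth_mean = depth_mean, depth_sd = depth_sd,
    point_error_rate = point_error_rate, chimera_rate = chimera_rate,
    include_pseudogene = isTRUE(include_pseudogene),
    pseudogene_deletion_span = as.integer(pseudogene_deletion_span),
    pool_fraction_per_population = pool_fraction_per_population,
    fwd_primer = toupper(fwd_primer), rev_primer = toupper(rev_primer),
    mid_length = as.integer(mid_length))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rate_in_01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!rate_in_01(cfg$point_error_rate) || !rate_in_01(cfg$chimera_rate))
    stop("error/chimera rates must be single values in [0, 1]")
  if (any(cfg$individuals_per_population < 1L))
    stop("individuals_per_population must all be >= 1")
  if (length(cfg$population_names) != length(cfg$individuals_per_population))
    stop("population_names length must match individuals_per_population")
  if (!is.numeric(cfg$depth_mean) || cfg$depth_mean <= 0)
    stop("depth_mean must be > 0")
  if (cfg$n_alleles_pool < 2L) stop("n_alleles_pool must be >= 2")
  if (cfg$n_loci < 1L) stop("n_loci must be >= 1")
  if (cfg$include_pseudogene) {
    span <- cfg$pseudogene_deletion_span
    if (length(span) != 2L || span[2] - span[1] + 1L != 13L)
      stop("pseudogene_deletion_span must cover exactly 13 nt")
    if (span[2] > cfg$allele_length_nt)
      stop("pseudogene_deletion_span outside the fragment")
  }
  invisible(cfg)
}

# Apply n random substitutions to an in-frame sequence, never creating an
# internal stop codon.
mutate_inframe <- function(seq, n_sub) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  done <- 0L
  guard <- 0L
  while (done < n_sub && guard < 50L * n_sub + 100L) {
    guard <- guard + 1L
    pos <- sample.int(L, 1L)
    new <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
    codon_i <- (pos - 1L) %/% 3L
    cs <- codon_i * 3L + 1L
    if (cs + 2L <= L) {
      codon <- chars[cs:(cs + 2L)]
      codon[pos - cs + 1L] <- new
      is_last <- (cs + 2L == L)
      if (!is_last &&
          paste(codon, collapse = "") %in% c("TAA", "TAG", "TGA")) next
    }
    chars[pos] <- new
    done <- done + 1L
  }
  paste(chars, collapse = "")
}

#' Simulate a diverse MHC allele pool
#'
#' Builds \code{n_alleles_pool} distinct in-frame sequences without internal
#' stop codons by diverging a small set of deep lineages from a common
#' ancestor (pairwise divergences roughly 1-58\%), plus, when configured, one
#' pseudogene-like allele carrying the frameshifting deletion.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an \code{allele_catalog} data.frame (name, sequence, aa,
#'   functional, mpaf, pooled_count).
#' @export
simulate_allele_pool <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "pool"))
  L <- config$allele_length_nt
  n <- config$n_alleles_pool
  ancestor <- mutate_inframe(strrep("A", L), 4L * L)  # scrambled, stop-free
  n_lineages <- min(4L, n)
  founders <- vapply(seq_len(n_lineages), function(i) {
    mutate_inframe(ancestor, rpois(1, 0.22 * L))
  }, character(1))
  lineage_of <- rep_len(seq_len(n_lineages), n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    k <- max(1L, rpois(1, runif(1, 0.01, 0.08) * L))
    seqs[i] <- mutate_inframe(founders[lineage_of[i]], k)
  }
  guard <- 0L
  while (anyDuplicated(seqs) && guard < 100L) {
    guard <- guard + 1L
    dup <- which(duplicated(seqs))
    for (i in dup) seqs[i] <- mutate_inframe(seqs[i], 1L)
  }
  if (anyDuplicated(seqs)) stop("failed to generate distinct alleles")
  names <- sprintf("Sim-DAB*%02d", seq_len(n))
  functional <- rep(TRUE, n)
  if (config$include_pseudogene) {
    span <- config$pseudogene_deletion_span
    parent <- seqs[1]
    pseudo <- paste0(substr(parent, 1L, span[1] - 1L),
                     substr(parent, span[2] + 1L, nchar(parent)))
    seqs <- c(seqs, pseudo)
    names <- c(names, sprintf("Sim-DAB*%02d", n + 1L))
    functional <- c(functional, FALSE)
  }
  new_allele_catalog(name = names, sequence = seqs, functional = functional)
}

#' Simulate multilocus MHC genotypes with population structure
#'
#' Each population draws from a nested subset of the allele pool (descending
#' allelic richness across populations); each individual receives an allele
#' set of size uniform on 1..min(2*n_loci, subset size).
#'
#' @param pool an \code{allele_catalog} from \code{\link{simulate_allele_pool}}.
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{sim_truth}: list with \code{pool},
#'   \code{genotype} (named list individual -> allele names) and
#'   \code{population} (named character vector).
#' @export
simulate_genotypes <- function(pool, config) {
  if (nrow(pool) == 0L) stop("allele pool is empty")
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genotypes"))
  n_pop <- length(config$individuals_per_population)
  frac <- config$pool_fraction_per_population %||%
    rev(seq(0.45, 1, length.out = n_pop))
  if (length(frac) != n_pop) stop("pool_fraction_per_population length mismatch")
  all_names <- pool$name
  # nested subsets: later (smaller) populations see a prefix of a fixed
  # shuffled ordering, so populations share alleles
  ord <- sample(all_names)
  # keep the pseudogene (if any) accessible to the first population
  if (any(!pool$functional)) {
    ps <- all_names[!pool$functional][1]
    ord <- c(ps, setdiff(ord, ps))
  }
  subsets <- lapply(frac, function(f) ord[seq_len(max(2L, round(f * length(ord))))])
  genotype <- list()
  population <- character(0)
  for (p in seq_len(n_pop)) {
    n_ind <- config$individuals_per_population[p]
    ids <- sprintf("%s_%03d", config$population_names[p], seq_len(n_ind))
    pool_p <- subsets[[p]]
    max_k <- min(2L * config$n_loci, length(pool_p))
    for (id in ids) {
      k <- sample.int(max_k, 1L)
      genotype[[id]] <- sort(sample(pool_p, k))
    }
    population <- c(population,
                    stats::setNames(rep(config$population_names[p], n_ind), ids))
  }
  structure(list(pool = pool, genotype = genotype, population = population,
                 config = config),
            class = "sim_truth")
}

# realize degenerate IUPAC positions into concrete bases
concretize_primer <- function(primer) {
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

apply_point_errors <- function(seq, rate) {
  L <- nchar(seq)
  n_err <- stats::rbinom(1L, L, rate)
  if (n_err == 0L) return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(L, n_err)
  for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  list(seq = paste(chars, collapse = ""), n = n_err)
}

#' Simulate MID-tagged amplicon reads with PCR artifacts
#'
#' Per individual, read depth is lognormal; each read is a true allele copy, a
#' within-individual PCR chimera (uniform breakpoint), or carries point
#' errors. Reads are MID + forward primer + template + revcomp(reverse
#' primer), emitted in either orientation. Full provenance is recorded.
#'
#' @param truth a \code{sim_truth} from \code{\link{simulate_genotypes}}.
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{sim_reads}: list with \code{reads}
#'   (data.frame read_id, sequence), \code{provenance}, \code{mid_map}
#'   (data.frame mid, sample, population), and the primers.
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "reads"))
  ids <- names(truth$genotype)
  # distinct MIDs, resampled on collision
  mids <- character(0)
  while (length(mids) < length(ids)) {
    need <- length(ids) - length(mids)
    mids <- unique(c(mids, random_dna(need, config$mid_length)))
  }
  mids <- mids[seq_along(ids)]
  mid_map <- data.frame(mid = mids, sample = ids,
                        population = unname(truth$population[ids]),
                        stringsAsFactors = FALSE)
  seq_of <- stats::setNames(truth$pool$sequence, truth$pool$name)
  m <- config$depth_mean; s <- config$depth_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  rc_rev <- revcomp(config$rev_primer)

  out_reads <- vector("list", length(ids))
  out_prov <- vector("list", length(ids))
  read_counter <- 0L
  for (j in seq_along(ids)) {
    id <- ids[j]
    geno <- truth$genotype[[id]]
    depth <- 0L
    while (depth < 1L) depth <- as.integer(round(stats::rlnorm(1, meanlog, sdlog)))
    is_chimera <- stats::runif(depth) < config$chimera_rate & length(geno) >= 2L
    src <- sample(geno, depth, replace = TRUE)
    templates <- character(depth)
    parent_a <- parent_b <- rep(NA_character_, depth)
    breakpoint <- rep(NA_integer_, depth)
    n_err <- integer(depth)
    for (r in seq_len(depth)) {
      if (is_chimera[r]) {
        par <- sample(geno, 2L)
        a <- seq_of[[par[1]]]; b <- seq_of[[par[2]]]
        bp <- sample.int(min(nchar(a), nchar(b)) - 1L, 1L)
        tmpl <- paste0(substr(a, 1L, bp), substr(b, bp + 1L, nchar(b)))
        parent_a[r] <- par[1]; parent_b[r] <- par[2]; breakpoint[r] <- bp
      } else {
        tmpl <- seq_of[[src[r]]]
      }
      if (config$point_error_rate > 0) {
        pe <- apply_point_errors(tmpl, config$point_error_rate)
        tmpl <- pe$seq; n_err[r] <- pe$n
      }
      templates[r] <- tmpl
    }
    fwd <- vapply(seq_len(depth), function(i) concretize_primer(config$fwd_primer),
                  character(1))
    rev_rc <- vapply(seq_len(depth), function(i) concretize_primer(rc_rev),
                     character(1))
    full <- paste0(mids[j], fwd, templates, rev_rc)
    flip <- stats::runif(depth) < 0.5
    full[flip] <- revcomp(full[flip])
    rid <- sprintf("read%08d", read_counter + seq_len(depth))
    read_counter <- read_counter + depth
    out_reads[[j]] <- data.frame(read_id = rid, sequence = full,
                                 stringsAsFactors = FALSE)
    cls <- ifelse(is_chimera, "chimera",
                  ifelse(n_err > 0L, "point_error", "true"))
    out_prov[[j]] <- data.frame(
      read_id = rid, sample = id, class = cls,
      source_allele = ifelse(is_chimera, NA_character_, src),
      parent_a = parent_a, parent_b = parent_b, breakpoint = breakpoint,
      n_errors = n_err, orientation = ifelse(flip, "reverse", "forward"),
      stringsAsFactors = FALSE)
  }
  structure(list(reads = do.call(rbind, out_reads),
                 provenance = do.call(rbind, out_prov),
                 mid_map = mid_map,
                 fwd_primer = config$fwd_primer,
                 rev_primer = config$rev_primer),
            class = "sim_reads")
}

default_microsat_freqs <- function(config, n_loci) {
  n_pop <- length(config$individuals_per_population)
  lapply(seq_len(n_loci), function(l) {
    k <- sample(4:8, 1L)
    alleles <- paste0("a", seq_len(k))
    base <- stats::rexp(k); base <- base / sum(base)
    # smaller populations lose the rarest alleles (drift-like richness loss)
    lapply(seq_len(n_pop), function(p) {
      drop <- min(k - 2L, p - 1L)
      f <- base
      if (drop > 0L) f[order(f)[seq_len(drop)]] <- 0
      f <- f / sum(f)
      stats::setNames(f, alleles)
    })
  })
}

#' Simulate diploid microsatellite genotypes
#'
#' Genotypes are random unions of gametes drawn from population-specific
#' allele frequencies.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_loci number of microsatellite loci.
#' @param allele_freqs optional list (one element per locus) of either a single
#'   named frequency vector shared by all populations, or a list of per-
#'   population named frequency vectors. Frequencies must each sum to 1.
#' @return data.frame (individual, population, locus, allele1, allele2).
#' @export
simulate_microsats <- function(config, n_loci = 6L, allele_freqs = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "microsats"))
  n_pop <- length(config$individuals_per_population)
  if (is.null(allele_freqs)) allele_freqs <- default_microsat_freqs(config, n_loci)
  if (length(allele_freqs) != n_loci) stop("allele_freqs must have one element per locus")
  freqs <- lapply(allele_freqs, function(f) {
    if (!is.list(f)) f <- rep(list(f), n_pop)
    if (length(f) != n_pop) stop("per-locus frequencies must cover every population")
    for (v in f) {
      if (abs(sum(v) - 1) > 1e-9) stop("allele frequencies must sum to 1")
    }
    f
  })
  rows <- list()
  for (p in seq_len(n_pop)) {
    n_ind <- config$individuals_per_population[p]
    ids <- sprintf("%s_%03d", config$population_names[p], seq_len(n_ind))
    for (l in seq_len(n_loci)) {
      fv <- freqs[[l]][[p]]
      g1 <- sample(names(fv), n_ind, replace = TRUE, prob = fv)
      g2 <- sample(names(fv), n_ind, replace = TRUE, prob = fv)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ids, population = config$population_names[p],
        locus = paste0("Scu-", l),
        allele1 = pmin(g1, g2), allele2 = pmax(g1, g2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
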