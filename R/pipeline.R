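# Orchestration: one reproducible run tying simulation -> genotyping ->
# selection -> population summaries, with a manifest recording the seed,
# thresholds and input checksums.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param mode "simulate", "genotype", "stats" or "all".
#' @param seed master seed; every stochastic stage derives a named substream.
#' @param sim a \code{\link{sim_config}} (for simulate/all modes); its seed is
#'   overridden by \code{seed}.
#' @param reads_file,mids_file,refs_file,microsat_file input paths for
#'   genotype/stats modes (filled in automatically in all-mode simulation).
#' @param fwd_primer,rev_primer primers for demultiplexing.
#' @param mpaf_threshold global MPAF cutoff (inclusive).
#' @param within_threshold within-amplicon cutoff (inclusive fraction of the
#'   top allele count).
#' @param min_reads depth-QC threshold.
#' @param min_identity,min_overlap reference-filter thresholds.
#' @param abs_codons 1-based ABS codon positions for the selection table.
#' @param ts_tv transition/transversion ratio for the modified Nei-Gojobori
#'   site counts.
#' @param n_boot bootstrap replicates for the selection table.
#' @param n_perm permutations for population randomization tests.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(out_dir, mode = "all", seed = 1L, sim = sim_config(),
                       reads_file = NULL, mids_file = NULL, refs_file = NULL,
                       microsat_file = NULL,
                       fwd_primer = NULL, rev_primer = NULL,
                       mpaf_threshold = 0.10, within_threshold = 0.10,
                       min_reads = 100L, min_identity = 0.70,
                       min_overlap = 120L,
                       abs_codons = c(5, 7, 9, 11, 24, 26, 28, 30, 33, 37,
                                      48, 50, 52, 54),
                       ts_tv = 2.0, n_boot = 1000L, n_perm = 10000L) {
  if (!mode %in% c("simulate", "genotype", "stats", "all"))
    stop("mode must be simulate, genotype, stats or all")
  for (thr in c(mpaf_threshold, within_threshold))
    if (thr <= 0 || thr > 1) stop("thresholds must be in (0, 1]")
  structure(list(out_dir = out_dir, mode = mode, seed = as.integer(seed),
                 sim = sim, reads_file = reads_file, mids_file = mids_file,
                 refs_file = refs_file, microsat_file = microsat_file,
                 fwd_primer = fwd_primer, rev_primer = rev_primer,
                 mpaf_threshold = mpaf_threshold,
                 within_threshold = within_threshold,
                 min_reads = as.integer(min_reads),
                 min_identity = min_identity,
                 min_overlap = as.integer(min_overlap),
                 abs_codons = abs_codons, ts_tv = ts_tv,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[setdiff(names(config), "out_dir")], file = tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline
#'
#' Executes the configured stages in order (simulate, genotype, selection,
#' summarize), writing every table as seeded, hash-stamped TSV plus a
#' manifest and a plain-text report with the selection and population summary
#' tables. Reruns with an identical config produce identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return (invisibly) list of in-memory results: truth, catalog, genotypes,
#'   selection, summary, paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- c(paste0("seed=", config$seed), paste0("config_hash=", hash))
  paths <- list()
  res <- list()
  p <- function(f) file.path(config$out_dir, f)

  truth <- NULL
  if (config$mode %in% c("simulate", "all")) {
    sim <- config$sim
    sim$seed <- config$seed
    pool <- simulate_allele_pool(sim)
    truth <- simulate_genotypes(pool, sim)
    reads <- simulate_reads(truth, sim)
    microsat <- simulate_microsats(sim)
    write_fastq(stats::setNames(reads$reads$sequence, reads$reads$read_id),
                p("reads.fastq"))
    write_tsv(reads$mid_map, p("mids.tsv"), hdr)
    write_tsv(reads$provenance, p("read_provenance.tsv"), hdr)
    truth_df <- data.frame(
      individual = names(truth$genotype),
      population = unname(truth$population[names(truth$genotype)]),
      alleles = vapply(truth$genotype, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    write_tsv(truth_df, p("truth_genotypes.tsv"), hdr)
    write_tsv(microsat, p("microsats.tsv"), hdr)
    # the "previously known" reference alleles for the identity filter:
    # a subset of the simulated functional pool
    n_ref <- min(5L, sum(pool$functional))
    refs <- stats::setNames(pool$sequence[pool$functional][seq_len(n_ref)],
                            pool$name[pool$functional][seq_len(n_ref)])
    write_fasta(refs, p("refs.fasta"))
    write_fasta(stats::setNames(pool$sequence, pool$name), p("pool.fasta"))
    write_config(list(seed = config$seed, config_hash = hash), p("sim_run.cfg"))
    config$reads_file <- p("reads.fastq")
    config$mids_file <- p("mids.tsv")
    config$refs_file <- p("refs.fasta")
    config$microsat_file <- p("microsats.tsv")
    config$fwd_primer <- sim$fwd_primer
    config$rev_primer <- sim$rev_primer
    paths$reads <- config$reads_file
    res$truth <- truth
  }

  if (config$mode %in% c("genotype", "stats", "all")) {
    for (f in c("reads_file", "mids_file", "refs_file")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("genotype stage: missing input ", f)
    }
    reads <- read_seqs(config$reads_file)
    mid_map <- read_mid_map(config$mids_file)
    refs <- read_seqs(config$refs_file)
    rs <- demultiplex(reads, mid_map, config$fwd_primer, config$rev_primer)
    discards <- rs[!is.na(rs$discard_reason),
                   c("read_id", "discard_reason")]
    write_tsv(discards, p("discards.tsv"), hdr)
    vt <- tally_variants(rs)
    vt <- reference_filter(vt, refs, config$min_identity, config$min_overlap)
    vt <- compute_mpaf(vt)
    write_tsv(vt$mpaf, p("mpaf.tsv"), hdr)
    catalog <- global_allele_filter(vt, config$mpaf_threshold, known = refs)
    catalog <- flag_pseudogenes(catalog)
    write_fasta(stats::setNames(catalog$sequence, catalog$name),
                p("alleles.fasta"))
    write_tsv(as.data.frame(catalog), p("alleles.tsv"), hdr)
    genotypes <- call_genotypes(vt, catalog, config$within_threshold,
                                config$min_reads)
    write_genotype_matrix(genotypes, catalog, p("genotypes.tsv"), hdr)
    bias <- depth_bias_check(genotypes, vt)
    res$catalog <- catalog
    res$genotypes <- genotypes
    res$variant_table <- vt
    res$depth_bias <- bias
    res$min_loci <- infer_min_loci(genotypes)

    if (sum(catalog$functional) >= 2L) {
      sel <- run_selection_table(catalog, abs_codons = config$abs_codons,
                                 R = config$ts_tv, n_reps = config$n_boot,
                                 seed = derive_seed(config$seed, "selection"))
      write_tsv(sel, p("selection_table.tsv"), hdr)
      res$selection <- sel
    }
  }

  if (config$mode %in% c("stats", "all")) {
    genotypes <- res$genotypes
    if (is.null(genotypes)) stop("stats stage requires genotype results")
    if (!is.null(config$microsat_file) && file.exists(config$microsat_file))
      genotypes$microsat <- read_microsat_tsv(config$microsat_file)
    summary <- population_summary(genotypes, res$catalog,
                                  n_resample = 1000L,
                                  seed = derive_seed(config$seed, "summary"))
    write_tsv(summary, p("population_summary.tsv"), hdr)
    res$summary <- summary
    res$individual <- individual_metrics(genotypes, res$catalog)
    write_tsv(res$individual, p("individual_metrics.tsv"), hdr)
  }

  inputs <- c(config$reads_file, config$mids_file, config$refs_file,
              config$microsat_file)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  inputs <- unlist(inputs)
  manifest <- c(
    paste0("package_version=", as.character(utils::packageVersion("ampliMHC"))),
    paste0("seed=", config$seed),
    paste0("config_hash=", hash),
    paste0("mode=", config$mode),
    paste0("mpaf_threshold=", config$mpaf_threshold),
    paste0("within_threshold=", config$within_threshold),
    paste0("min_reads=", config$min_reads),
    paste0("ts_tv=", config$ts_tv),
    paste0("input_md5_", basename(inputs), "=", tools::md5sum(inputs)))
  writeLines(manifest, p("manifest.txt"))
  write_report(res, p("report.txt"), hdr)
  res$paths <- list(out_dir = config$out_dir)
  invisible(res)
}

#' Per-individual metrics table
#'
#' Multilocus microsatellite heterozygosity, MHC allele count, nucleotide
#' diversity over the carried alleles, and usable read counts.
#'
#' @param genotypes a \code{genotype_table} with microsatellites attached.
#' @param catalog an \code{allele_catalog}.
#' @return data.frame, one row per genotyped individual.
#' @export
individual_metrics <- function(genotypes, catalog) {
  ids <- names(genotypes$mhc)
  seq_of <- stats::setNames(catalog$sequence, catalog$name)
  full_len <- max(nchar(seq_of))
  pi_i <- vapply(ids, function(id) {
    seqs <- seq_of[genotypes$mhc[[id]]]
    seqs <- seqs[nchar(seqs) == full_len]
    if (length(seqs) < 2L) return(NA_real_)
    nucleotide_diversity(seqs)
  }, numeric(1))
  mlh <- rep(NA_real_, length(ids))
  if (!is.null(genotypes$microsat)) {
    all_mlh <- multilocus_heterozygosity(genotypes$microsat)
    mlh <- unname(all_mlh[ids])
  }
  data.frame(individual = ids,
             population = if (!is.null(genotypes$population))
               unname(genotypes$population[ids]) else NA,
             n_mhc_alleles = unname(lengths(genotypes$mhc[ids])),
             mhc_pi = unname(pi_i), mlh = mlh,
             reads = if (!is.null(genotypes$read_totals))
               unname(as.integer(genotypes$read_totals[ids])) else NA,
             stringsAsFactors = FALSE)
}

write_report <- function(res, path, hdr) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  if (!is.null(res$catalog)) {
    writeLines(sprintf("Putative alleles: %d (%d functional)",
                       nrow(res$catalog), sum(res$catalog$functional)), con)
    writeLines(sprintf("Minimum loci implied: %d", res$min_loci), con)
    writeLines(sprintf(
      "Depth bias check: n=%d rho=%.3f p=%.3f",
      res$depth_bias$n, res$depth_bias$rho, res$depth_bias$p), con)
  }
  if (!is.null(res$selection)) {
    writeLines("", con)
    writeLines("Selection (modified Nei-Gojobori, Jukes-Cantor corrected):",
               con)
    utils::capture.output(print(res$selection, digits = 3), file = con)
  }
  if (!is.null(res$summary)) {
    writeLines("", con)
    writeLines("Population summary:", con)
    utils::capture.output(print(res$summary, digits = 3), file = con)
  }
  invisible(path)
}

#' Compare called genotypes with simulation truth
#'
#' Per-individual recall (true alleles recovered) and precision (called
#' alleles that are true), averaged over individuals genotyped by the
#' pipeline. Comparison is by sequence, so catalog naming does not matter.
#'
#' @param genotypes a \code{genotype_table}.
#' @param truth a \code{sim_truth}.
#' @param catalog the \code{allele_catalog} the genotypes were called against.
#' @return list(recall, precision, exact, n) where \code{exact} is the
#'   fraction of individuals whose called set equals the truth exactly.
#' @export
genotype_accuracy <- function(genotypes, truth, catalog) {
  ids <- intersect(names(genotypes$mhc), names(truth$genotype))
  if (!length(ids)) stop("no overlapping individuals")
  cat_seq <- stats::setNames(catalog$sequence, catalog$name)
  truth_seq <- stats::setNames(truth$pool$sequence, truth$pool$name)
  per <- vapply(ids, function(id) {
    called <- unname(cat_seq[genotypes$mhc[[id]]])
    truth_set <- unname(truth_seq[truth$genotype[[id]]])
    c(recall = mean(truth_set %in% called),
      precision = mean(called %in% truth_set),
      exact = as.numeric(setequal(called, truth_set)))
  }, numeric(3))
  list(recall = mean(per["recall", ]), precision = mean(per["precision", ]),
       exact = mean(per["exact", ]), n = length(ids))
}

#' Command-line entry point
#'
#' Minimal flag parser driving \code{\link{run_pipeline}}:
#' \code{--mode all --out DIR --seed 1 [--reads R.fastq --mids mids.tsv
#' --refs refs.fasta --fwd-primer SEQ --rev-primer SEQ --microsats m.tsv
#' --mpaf 0.10 --within 0.10 --min-reads 100 --boot 1000 --perms 10000]}.
#'
#' @param args character vector, default \code{commandArgs(trailingOnly=TRUE)}.
#' @return exit status, invisibly.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- list(mode = "all", out = "ampliMHC_run", seed = 1L)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key == "version") {
      cat(as.character(utils::packageVersion("ampliMHC")), "\n")
      return(invisible(0L))
    }
    if (i == length(args)) stop("missing value for --", key)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- run_config(
    out_dir = opt$out, mode = opt$mode, seed = as.integer(opt$seed),
    sim = sim_config(seed = as.integer(opt$seed)),
    reads_file = opt$reads, mids_file = opt$mids, refs_file = opt$refs,
    microsat_file = opt$microsats,
    fwd_primer = opt[["fwd-primer"]], rev_primer = opt[["rev-primer"]],
    mpaf_threshold = as.numeric(opt$mpaf %||% 0.10),
    within_threshold = as.numeric(opt$within %||% 0.10),
    min_reads = as.integer(opt[["min-reads"]] %||% 100L),
    n_boot = as.integer(opt$boot %||% 1000L),
    n_perm = as.integer(opt$perms %||% 10000L))
  run_pipeline(cfg)
  invisible(0L)
}
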