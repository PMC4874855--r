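# Amplicon genotyping: MID demultiplexing with perfect primer/MID matching,
# per-amplicon variant tallying, a local reference-identity filter (stand-in
# for a remote BLASTn screen), maximum per-amplicon frequency (MPAF)
# filtering, within-amplicon genotype calling, depth QC, and pseudogene
# flagging.

#' Allele catalog constructor
#'
#' @param name unique allele names.
#' @param sequence nucleotide sequences.
#' @param functional logical; FALSE for pseudogene-like alleles.
#' @param mpaf,pooled_count filter annotations (NA until computed).
#' @param frame reading frame used for translation.
#' @param note free-text annotation (e.g. pseudogene reason).
#' @return data.frame of class \code{allele_catalog}.
#' @export
new_allele_catalog <- function(name, sequence, functional = TRUE,
                               mpaf = NA_real_, pooled_count = NA_integer_,
                               frame = 1L, note = "") {
  if (anyDuplicated(name)) stop("allele names must be unique")
  df <- data.frame(name = name, sequence = toupper(sequence),
                   aa = translate_nt(sequence, frame),
                   functional = functional, mpaf = mpaf,
                   pooled_count = pooled_count, note = note,
                   stringsAsFactors = FALSE)
  attr(df, "frame") <- as.integer(frame)
  class(df) <- c("allele_catalog", "data.frame")
  df
}

coerce_reads <- function(reads) {
  if (inherits(reads, "sim_reads")) return(reads$reads)
  if (inherits(reads, "DNAStringSet")) {
    return(data.frame(read_id = names(reads) %||% as.character(seq_along(reads)),
                      sequence = as.character(reads), stringsAsFactors = FALSE))
  }
  if (is.character(reads)) {
    return(data.frame(read_id = names(reads) %||% as.character(seq_along(reads)),
                      sequence = unname(reads), stringsAsFactors = FALSE))
  }
  if (is.data.frame(reads)) {
    if (!all(c("read_id", "sequence") %in% names(reads)))
      stop("reads data.frame needs columns read_id and sequence")
    return(reads[, c("read_id", "sequence")])
  }
  stop("unsupported reads input")
}

#' Demultiplex MID-tagged amplicon reads
#'
#' A read is assigned to a sample only if it contains, in one orientation, a
#' perfect match to one of the supplied MIDs at its start, the forward primer
#' immediately after the MID, and the reverse-complemented reverse primer at
#' its end. IUPAC degeneracy codes in the primers match any of their allowed
#' bases. Reverse-orientation reads are detected by reverse-complement
#' matching and canonicalized. MID and primers are trimmed; the retained
#' insert is the \code{variant}.
#'
#' @param reads data.frame (read_id, sequence), character vector, or
#'   \code{DNAStringSet} (or the output of \code{\link{simulate_reads}}).
#' @param mid_map data.frame with columns \code{mid} and \code{sample}
#'   (optionally \code{population}); MIDs must be unique and of equal length.
#' @param forward_primer,reverse_primer primer sequences (IUPAC allowed).
#' @return object of class \code{amplicon_readset}: data.frame (read_id,
#'   sample, orientation, variant, discard_reason) with the population map
#'   attached as an attribute when supplied.
#' @export
demultiplex <- function(reads, mid_map, forward_primer, reverse_primer) {
  if (inherits(reads, "sim_reads") && missing(mid_map)) {
    mid_map <- reads$mid_map
    forward_primer <- reads$fwd_primer
    reverse_primer <- reads$rev_primer
  }
  rdf <- coerce_reads(reads)
  if (anyDuplicated(mid_map$mid)) stop("duplicate MIDs in mid_map")
  if (anyDuplicated(mid_map$sample)) stop("duplicate samples in mid_map")
  mid_len <- unique(nchar(mid_map$mid))
  if (length(mid_len) != 1L) stop("MIDs must all be the same length")
  fwd_re <- paste0("^", iupac_regex(forward_primer))
  rc_rev_re <- paste0(iupac_regex(revcomp(reverse_primer)), "$")
  nf <- nchar(forward_primer)
  nr <- nchar(reverse_primer)
  sample_of <- stats::setNames(mid_map$sample, mid_map$mid)

  match_orientation <- function(seqs) {
    L <- nchar(seqs)
    mid <- substr(seqs, 1L, mid_len)
    smp <- sample_of[mid]
    long_enough <- L > mid_len + nf + nr
    after_mid <- substr(seqs, mid_len + 1L, L)
    ok_fwd <- long_enough & grepl(fwd_re, after_mid)
    ok_rev <- long_enough & grepl(rc_rev_re, seqs)
    variant <- substr(seqs, mid_len + nf + 1L, L - nr)
    list(sample = smp, mid_known = !is.na(smp),
         primers_ok = ok_fwd & ok_rev, variant = variant)
  }

  seqs <- toupper(rdf$sequence)
  f <- match_orientation(seqs)
  r <- match_orientation(revcomp(seqs))
  f_valid <- f$mid_known & f$primers_ok
  r_valid <- r$mid_known & r$primers_ok
  n <- length(seqs)
  sample <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  variant <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  both <- f_valid & r_valid
  ambiguous <- both & (f$sample != r$sample)
  take_f <- f_valid & !ambiguous
  take_r <- r_valid & !f_valid
  sample[take_f] <- f$sample[take_f]; orientation[take_f] <- "forward"
  variant[take_f] <- f$variant[take_f]
  sample[take_r] <- r$sample[take_r]; orientation[take_r] <- "reverse"
  variant[take_r] <- r$variant[take_r]
  reason[ambiguous] <- "multiple_mid"
  unassigned <- is.na(sample) & !ambiguous
  reason[unassigned & !(f$mid_known | r$mid_known)] <- "no_mid"
  reason[unassigned & (f$mid_known | r$mid_known)] <- "no_primer"

  out <- data.frame(read_id = rdf$read_id, sample = sample,
                    orientation = orientation, variant = variant,
                    discard_reason = reason, stringsAsFactors = FALSE)
  if ("population" %in% names(mid_map))
    attr(out, "population") <- stats::setNames(mid_map$population, mid_map$sample)
  class(out) <- c("amplicon_readset", "data.frame")
  out
}

#' Tally unique sequence variants per sample
#'
#' Groups assigned reads by exact trimmed sequence within each sample
#' (amplicon) and pools counts across samples.
#'
#' @param readset an \code{amplicon_readset} from \code{\link{demultiplex}}.
#' @return object of class \code{variant_table}: list with \code{counts}
#'   (sample, variant, count), \code{sample_totals}, \code{pooled} (variant,
#'   pooled_count) and \code{n_assigned}/\code{n_discarded}.
#' @export
tally_variants <- function(readset) {
  assigned <- readset[!is.na(readset$sample), , drop = FALSE]
  if (nrow(assigned) == 0L) {
    counts <- data.frame(sample = character(0), variant = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(assigned))),
                            by = list(sample = assigned$sample,
                                      variant = assigned$variant),
                            FUN = sum)
    counts <- agg[order(agg$sample, -agg$count, agg$variant), , drop = FALSE]
    rownames(counts) <- NULL
  }
  sample_totals <- tapply(counts$count, counts$sample, sum)
  sample_totals <- stats::setNames(as.integer(sample_totals), names(sample_totals))
  pooled_v <- tapply(counts$count, counts$variant, sum)
  pooled <- data.frame(variant = names(pooled_v) %||% character(0),
                       pooled_count = as.integer(pooled_v),
                       stringsAsFactors = FALSE)
  pooled <- pooled[order(-pooled$pooled_count, pooled$variant), , drop = FALSE]
  rownames(pooled) <- NULL
  structure(list(counts = counts, sample_totals = sample_totals,
                 pooled = pooled, n_assigned = nrow(assigned),
                 n_discarded = sum(!is.na(readset$discard_reason)),
                 population = attr(readset, "population")),
            class = "variant_table")
}

# best Hamming identity of same-length variants against same-length references
best_hamming_identity <- function(variants, references) {
  best <- rep(NA_real_, length(variants))
  for (len in unique(nchar(variants))) {
    refs_l <- references[nchar(references) == len]
    if (length(refs_l) == 0L) next
    idx <- which(nchar(variants) == len)
    vm <- seq_matrix(variants[idx])
    for (r in refs_l) {
      rchars <- strsplit(r, "")[[1]]
      ident <- rowMeans(vm == matrix(rchars, nrow = length(idx), ncol = len,
                                     byrow = TRUE))
      best[idx] <- pmax(best[idx], ident, na.rm = TRUE)
    }
  }
  best
}

#' Filter variants by identity to a reference allele set
#'
#' Local stand-in for a remote nucleotide-database screen: a variant is
#' retained if its best gap-tolerant local alignment against any reference
#' meets the identity and overlap thresholds. A fast exact-position identity
#' pre-pass short-circuits the alignment for same-length variants already
#' above the identity threshold over the full fragment; all other variants are
#' scored by dynamic-programming local alignment.
#'
#' @param table a \code{variant_table}.
#' @param references named character vector / \code{DNAStringSet} of reference
#'   MHC sequences.
#' @param min_identity minimum fraction identity over the aligned region.
#' @param min_overlap minimum aligned length in nt.
#' @return filtered \code{variant_table}; removed variants with their best-hit
#'   identity are in \code{attr(, "removed")}.
#' @export
reference_filter <- function(table, references, min_identity = 0.70,
                             min_overlap = 120L) {
  if (inherits(references, "DNAStringSet")) references <- as.character(references)
  if (inherits(references, "allele_catalog")) references <- references$sequence
  references <- toupper(references)
  if (length(references) == 0L) stop("reference set is empty")
  variants <- unique(table$counts$variant)
  if (length(variants) == 0L) return(table)
  ham <- best_hamming_identity(variants, references)
  pass <- !is.na(ham) & ham >= min_identity &
    nchar(variants) >= min_overlap
  best_id <- ifelse(pass, ham, NA_real_)
  best_ov <- ifelse(pass, nchar(variants), NA_integer_)
  todo <- which(!pass)
  if (length(todo)) {
    pats <- Biostrings::DNAStringSet(variants[todo])
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    id_best <- rep(0, length(todo)); ov_best <- rep(0L, length(todo))
    for (r in references) {
      aln <- Biostrings::pairwiseAlignment(pats, Biostrings::DNAString(r),
                                           type = "local",
                                           substitutionMatrix = sm,
                                           gapOpening = 5, gapExtension = 2)
      ov <- Biostrings::nchar(aln)
      id <- ifelse(ov > 0, Biostrings::nmatch(aln) / ov, 0)
      better <- id > id_best
      id_best[better] <- id[better]; ov_best[better] <- ov[better]
    }
    pass[todo] <- id_best >= min_identity & ov_best >= min_overlap
    best_id[todo] <- id_best; best_ov[todo] <- ov_best
  }
  keep <- variants[pass]
  removed <- data.frame(variant = variants[!pass],
                        best_identity = best_id[!pass],
                        best_overlap = best_ov[!pass],
                        stringsAsFactors = FALSE)
  out <- table
  out$counts <- table$counts[table$counts$variant %in% keep, , drop = FALSE]
  tot <- tapply(out$counts$count, out$counts$sample, sum)
  out$sample_totals <- stats::setNames(as.integer(tot), names(tot))
  out$pooled <- table$pooled[table$pooled$variant %in% keep, , drop = FALSE]
  out$n_assigned <- sum(out$counts$count)
  out$mpaf <- NULL  # totals changed; MPAF must be recomputed
  attr(out, "removed") <- removed
  out
}

#' Annotate each variant with its maximum per-amplicon frequency (MPAF)
#'
#' MPAF(v) is the highest within-amplicon read fraction the variant attains in
#' any single sample: \code{max_s count(s, v) / total(s)}. Annotation only; no
#' variant is removed. Samples with zero usable reads are excluded from the
#' maximum.
#'
#' @param table a \code{variant_table}.
#' @return the table with an \code{mpaf} data.frame (variant, mpaf,
#'   pooled_count) added.
#' @export
compute_mpaf <- function(table) {
  counts <- table$counts
  totals <- table$sample_totals[counts$sample]
  ok <- totals > 0
  frac <- counts$count[ok] / totals[ok]
  mpaf_v <- tapply(frac, counts$variant[ok], max)
  mpaf <- data.frame(variant = names(mpaf_v), mpaf = as.numeric(mpaf_v),
                     stringsAsFactors = FALSE)
  mpaf <- merge(mpaf, table$pooled, by = "variant", sort = FALSE)
  mpaf <- mpaf[order(-mpaf$mpaf, -mpaf$pooled_count, mpaf$variant), , drop = FALSE]
  rownames(mpaf) <- NULL
  table$mpaf <- mpaf
  table
}

#' Build the putative allele catalog with the global MPAF filter
#'
#' Variants with MPAF below the threshold are considered PCR/sequencing
#' artifacts and removed; variants at or above it (inclusive) become putative
#' alleles. New alleles are named deterministically by descending pooled read
#' count (ties broken by sequence); variants sequence-identical to a supplied
#' known allele keep the known name.
#'
#' @param table a \code{variant_table} (MPAF is computed if absent).
#' @param mpaf_threshold inclusive MPAF cutoff in (0, 1].
#' @param known optional named character vector of known allele sequences
#'   (names are allele names).
#' @param name_prefix prefix for newly named alleles.
#' @param frame reading frame annotation for the catalog.
#' @return an \code{allele_catalog}.
#' @export
global_allele_filter <- function(table, mpaf_threshold = 0.10, known = NULL,
                                 name_prefix = "DAB*", frame = 1L) {
  if (!is.numeric(mpaf_threshold) || mpaf_threshold <= 0 || mpaf_threshold > 1)
    stop("mpaf_threshold must be in (0, 1]")
  if (is.null(table$mpaf)) table <- compute_mpaf(table)
  keep <- table$mpaf[table$mpaf$mpaf >= mpaf_threshold - 1e-12, , drop = FALSE]
  keep <- keep[order(-keep$pooled_count, keep$variant), , drop = FALSE]
  nms <- rep(NA_character_, nrow(keep))
  if (!is.null(known)) {
    m <- match(keep$variant, toupper(known))
    nms[!is.na(m)] <- names(known)[m[!is.na(m)]]
  }
  newi <- 0L
  for (i in which(is.na(nms))) {
    repeat {
      newi <- newi + 1L
      cand <- sprintf("%s%02d", name_prefix, newi)
      if (!cand %in% nms) break
    }
    nms[i] <- cand
  }
  new_allele_catalog(name = nms, sequence = keep$variant,
                     mpaf = keep$mpaf, pooled_count = keep$pooled_count,
                     frame = frame)
}

#' Flag pseudogene-like alleles
#'
#' An allele is flagged non-functional if its length is not congruent to the
#' expected fragment length modulo 3 (a frameshifting indel) or if its
#' translation contains an internal stop codon. Flagged alleles stay in the
#' catalog (and in genotypes) but are excluded from selection and distance
#' analyses.
#'
#' @param catalog an \code{allele_catalog}.
#' @param expected_length expected fragment length in nt; defaults to the
#'   modal catalog length.
#' @param frame reading frame.
#' @return the catalog with \code{functional} and \code{note} updated.
#' @export
flag_pseudogenes <- function(catalog, expected_length = NULL, frame = 1L) {
  lens <- nchar(catalog$sequence)
  if (is.null(expected_length)) {
    tab <- table(lens)
    expected_length <- as.integer(names(tab)[which.max(tab)])
  }
  frameshift <- (lens %% 3L) != (expected_length %% 3L)
  stops <- has_internal_stop(catalog$sequence, frame)
  catalog$functional <- !(frameshift | stops)
  catalog$note <- ifelse(frameshift, "frameshift indel",
                         ifelse(stops, "internal stop codon", catalog$note))
  catalog
}

#' Exclude samples with poor sequencing depth
#'
#' @param table a \code{variant_table}.
#' @param min_reads minimum usable reads per sample (inclusive retention).
#' @return character vector of excluded sample ids.
#' @export
depth_qc <- function(table, min_reads = 100L) {
  if (min_reads < 1L) stop("min_reads must be >= 1")
  names(table$sample_totals)[table$sample_totals < min_reads]
}

#' Call one sample's genotype with the within-amplicon frequency rule
#'
#' Only catalog alleles observed in the sample are considered. An allele is
#' retained iff its read count is at least \code{within_threshold} times the
#' count of the most frequent catalog allele in that amplicon (inclusive).
#'
#' @param sample_counts named integer vector: variant sequence -> read count
#'   for one sample.
#' @param catalog an \code{allele_catalog}.
#' @param within_threshold fraction of the top allele's count (inclusive).
#' @return character vector of allele names, or \code{NULL} if no catalog
#'   allele was observed (ungenotypeable).
#' @export
call_genotype <- function(sample_counts, catalog, within_threshold = 0.10) {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  idx <- match(names(sample_counts), catalog$sequence)
  obs <- !is.na(idx)
  if (!any(obs)) return(NULL)
  cnt <- sample_counts[obs]
  nm <- catalog$name[idx[obs]]
  ord <- order(-cnt, catalog$sequence[idx[obs]])
  cnt <- cnt[ord]; nm <- nm[ord]
  keep <- cnt >= within_threshold * cnt[1] - 1e-9  # inclusive at the boundary
  sort(nm[keep])
}

#' Call genotypes for every sample passing depth QC
#'
#' @param table a \code{variant_table}.
#' @param catalog an \code{allele_catalog}.
#' @param within_threshold see \code{\link{call_genotype}}.
#' @param min_reads depth-QC threshold (see \code{\link{depth_qc}}).
#' @return object of class \code{genotype_table}: list with \code{mhc} (named
#'   list individual -> allele names), \code{population}, \code{excluded}
#'   (named reasons: low_depth / ungenotypeable), \code{microsat} (NULL until
#'   attached).
#' @export
call_genotypes <- function(table, catalog, within_threshold = 0.10,
                           min_reads = 100L) {
  low <- depth_qc(table, min_reads)
  samples <- names(table$sample_totals)
  mhc <- list()
  excluded <- character(0)
  for (s in samples) {
    if (s %in% low) { excluded[s] <- "low_depth"; next }
    sub <- table$counts[table$counts$sample == s, , drop = FALSE]
    g <- call_genotype(stats::setNames(sub$count, sub$variant), catalog,
                       within_threshold)
    if (is.null(g)) excluded[s] <- "ungenotypeable" else mhc[[s]] <- g
  }
  pop <- table$population
  structure(list(mhc = mhc,
                 population = if (!is.null(pop)) pop[names(mhc)] else NULL,
                 excluded = excluded, microsat = NULL,
                 read_totals = table$sample_totals),
            class = "genotype_table")
}

#' Check for read-depth bias in called allele counts
#'
#' Spearman rank correlation between per-individual usable read counts and
#' called allele counts. A significant positive correlation would indicate
#' depth-driven genotyping bias.
#'
#' @param genotypes a \code{genotype_table}.
#' @param table the \code{variant_table} the genotypes were called from
#'   (optional if read totals were recorded in the genotype table).
#' @return list(n, rho, p), or rho = NA when undefined (constant input).
#' @export
depth_bias_check <- function(genotypes, table = NULL) {
  ids <- names(genotypes$mhc)
  if (length(ids) < 3L) stop("need at least 3 genotyped individuals")
  totals <- if (!is.null(table)) table$sample_totals else genotypes$read_totals
  x <- as.numeric(totals[ids])
  y <- lengths(genotypes$mhc[ids])
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(n = length(ids), rho = NA_real_, p = NA_real_))
  sp <- spearman_cor(x, y)
  list(n = length(ids), rho = sp$rho, p = sp$p)
}

#' Minimum number of loci implied by per-individual allele counts
#'
#' A diploid individual carries at most two alleles per locus, so the maximum
#' observed per-individual allele count implies at least
#' \code{ceiling(max / 2)} loci.
#'
#' @param genotypes a \code{genotype_table} (or a list of allele-name sets).
#' @return integer lower bound on the number of loci.
#' @export
infer_min_loci <- function(genotypes) {
  sets <- if (inherits(genotypes, "genotype_table")) genotypes$mhc else genotypes
  if (length(sets) == 0L) stop("no genotypes")
  as.integer(ceiling(max(lengths(sets)) / 2))
}
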