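# Format plumbing: FASTA/FASTQ via Biostrings, validated TSV tables, GenePop
# import, and flat key=value config files.

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path.
#' @param format "fasta" or "fastq" (guessed from the extension by default).
#' @return named character vector of upper-case sequences.
#' @export
read_seqs <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq"
    else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Write sequences as FASTQ with constant qualities
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param quality_char single quality character applied to every base
#'   (default "I" = Q40).
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep(quality_char, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

read_tsv_checked <- function(path, required, unique_key = NULL,
                             colClasses = NA) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = colClasses)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ", paste(missing, collapse = ", "))
  if (!is.null(unique_key)) {
    dup <- df[[unique_key]][duplicated(df[[unique_key]])]
    if (length(dup))
      stop(path, ": duplicated ", unique_key, ": ",
           paste(unique(dup), collapse = ", "))
  }
  df
}

#' Read a MID-to-sample mapping table
#'
#' TSV with columns mid, sample and optionally population.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_mid_map <- function(path) {
  df <- read_tsv_checked(path, c("mid", "sample"), unique_key = "mid")
  if (anyDuplicated(df$sample))
    stop(path, ": duplicated sample: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  df$mid <- toupper(df$mid)
  df
}

#' Read a microsatellite genotype table
#'
#' TSV with columns individual, population, locus, allele1, allele2; blank
#' alleles are missing genotypes.
#'
#' @param path file path.
#' @return data.frame with NA for missing alleles.
#' @export
read_microsat_tsv <- function(path) {
  df <- read_tsv_checked(path, c("individual", "population", "locus",
                                 "allele1", "allele2"),
                         colClasses = c(allele1 = "character",
                                        allele2 = "character"))
  key <- paste(df$individual, df$locus)
  if (anyDuplicated(key))
    stop(path, ": duplicated individual x locus row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  for (col in c("allele1", "allele2")) {
    v <- as.character(df[[col]])
    v[v == ""] <- NA_character_
    df[[col]] <- v
  }
  df
}

#' Import a GenePop genotype file
#'
#' Supports the standard layout: title line, one locus name per line (or a
#' single comma-separated line), then POP blocks of
#' \code{individual , gtgt gtgt ...} rows with 2- or 3-digit allele codes
#' (all-zero codes are missing).
#'
#' @param path file path.
#' @param population_names optional labels for the POP blocks.
#' @return data.frame (individual, population, locus, allele1, allele2).
#' @export
read_genepop <- function(path, population_names = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop(path, ": not a GenePop file")
  body <- lines[-1]
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop(path, ": no POP line found")
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci[nzchar(trimws(loci))])
  n_pop <- length(pop_idx)
  pop_names <- population_names %||% paste0("pop", seq_len(n_pop))
  if (length(pop_names) != n_pop) stop("population_names length mismatch")
  bounds <- c(pop_idx, length(body) + 1L)
  rows <- list()
  for (p in seq_len(n_pop)) {
    block <- body[seq(bounds[p] + 1L, bounds[p + 1L] - 1L)]
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) != 2L)
        stop(path, ": malformed genotype line: ", ln)
      id <- trimws(parts[1])
      gts <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
      if (length(gts) != length(loci))
        stop(path, ": individual ", id, " has ", length(gts),
             " genotypes for ", length(loci), " loci")
      w <- nchar(gts[1]) %/% 2L
      a1 <- substr(gts, 1L, w)
      a2 <- substr(gts, w + 1L, 2L * w)
      a1[a1 == strrep("0", w)] <- NA_character_
      a2[a2 == strrep("0", w)] <- NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        individual = id, population = pop_names[p], locus = loci,
        allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a table as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @param header_lines optional comment lines (prefixed "#") recording e.g.
#'   the run seed and config hash.
#' @export
write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a flat key=value config file
#'
#' Vector values are comma-separated; numbers and logicals are restored on
#' read.
#'
#' @param config named list of scalar or vector values.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  lines <- vapply(names(config)[keep], function(k) {
    paste0(k, "=", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(path, ": malformed config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- strsplit(substr(ln, eq + 1, nchar(ln)), ",")[[1]]
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) {
      val <- num
    } else if (all(val %in% c("TRUE", "FALSE"))) {
      val <- as.logical(val)
    }
    out[[key]] <- val
  }
  out
}

#' Write a genotype presence/absence matrix
#'
#' @param genotypes a \code{genotype_table}.
#' @param catalog an \code{allele_catalog} (column order).
#' @param path output path.
#' @param header_lines optional comment lines.
#' @return the matrix, invisibly.
#' @export
write_genotype_matrix <- function(genotypes, catalog, path,
                                  header_lines = NULL) {
  ids <- names(genotypes$mhc)
  m <- matrix(0L, length(ids), nrow(catalog),
              dimnames = list(ids, catalog$name))
  for (i in seq_along(ids)) m[i, genotypes$mhc[[i]]] <- 1L
  df <- data.frame(individual = ids,
                   population = if (!is.null(genotypes$population))
                     unname(genotypes$population[ids]) else NA,
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, header_lines)
  invisible(m)
}
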