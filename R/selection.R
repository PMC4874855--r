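# Molecular-evolution statistics on the functional allele set: pairwise
# amino-acid p-distances, Tamura-Nei (1993) nucleotide distances, and
# partitioned dN/dS by the modified Nei-Gojobori method with Jukes-Cantor
# correction, bootstrap standard errors, and a one-tailed Z-test for positive
# selection.

#' Codon alignment container
#'
#' @param sequences named character vector of equal-length, in-frame
#'   nucleotide sequences (length divisible by 3).
#' @param abs_mask per-codon logical marking putative antigen-binding sites,
#'   or a 1-based integer vector of ABS codon positions.
#' @return object of class \code{codon_alignment}.
#' @export
codon_alignment <- function(sequences, abs_mask = NULL) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences must be of equal length")
  if (lens %% 3L != 0L) stop("alignment length must be divisible by 3")
  n_codon <- lens %/% 3L
  if (!is.null(abs_mask)) {
    if (is.numeric(abs_mask)) {
      if (any(abs_mask < 1 | abs_mask > n_codon))
        stop("ABS codon positions out of range")
      abs_mask <- seq_len(n_codon) %in% as.integer(abs_mask)
    }
    if (length(abs_mask) != n_codon) stop("abs_mask length must equal codon count")
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  structure(list(sequences = toupper(sequences), abs_mask = abs_mask,
                 n_codon = n_codon), class = "codon_alignment")
}

#' Uncorrected amino-acid p-distance
#'
#' Proportion of differing amino-acid sites after pairwise deletion of sites
#' where either sequence has a gap ("-") or unknown ("X") residue.
#'
#' @param a,b amino-acid sequences of equal length.
#' @return fraction in [0, 1]; NA if no comparable sites remain.
#' @export
aa_p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences must be of equal length")
  ok <- !(ca %in% c("-", "X", "?")) & !(cb %in% c("-", "X", "?"))
  if (!any(ok)) return(NA_real_)
  mean(ca[ok] != cb[ok])
}

#' Tamura-Nei (1993) nucleotide distance
#'
#' Closed-form TN93 distance with empirical base frequencies taken from the
#' two sequences being compared, distinguishing the two transition classes
#' (A<->G, C<->T) from transversions. Equal rates across sites (no gamma).
#' Sites where either sequence is not an unambiguous A/C/G/T are deleted
#' pairwise.
#'
#' @param a,b nucleotide sequences of equal length.
#' @return distance in substitutions per site; NA when the correction is
#'   undefined (saturation: log of a non-positive argument).
#' @export
tamura_nei_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences must be of equal length")
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  ca <- ca[ok]; cb <- cb[ok]
  L <- length(ca)
  if (L == 0L) return(NA_real_)
  g <- (table(factor(ca, DNA_BASES)) + table(factor(cb, DNA_BASES))) / (2 * L)
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- ca != cb
  P1 <- mean(diff & ((ca == "A" & cb == "G") | (ca == "G" & cb == "A")))
  P2 <- mean(diff & ((ca == "C" & cb == "T") | (ca == "T" & cb == "C")))
  Q <- mean(diff) - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  term <- function(k, w) {
    if (k == 0) return(if (w < 1) NA_real_ else 0)  # class absent from data
    if (w <= 0) return(NA_real_)
    -k * log(w)
  }
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1 - P1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1 - P2
  w3 <- 1 - Q / (2 * gR * gY)
  t1 <- term(k1, w1); t2 <- term(k2, w2); t3 <- term(k3, w3)
  if (anyNA(c(t1, t2, t3))) return(NA_real_)
  t1 + t2 + t3
}

#' Pairwise distance matrix
#'
#' @param seqs named character vector of equal-length sequences.
#' @param method "aa_p" (amino-acid p-distance on already-translated input),
#'   "tn93", or "p" (nucleotide p-distance).
#' @return symmetric numeric matrix.
#' @export
pairwise_distances <- function(seqs, method = c("tn93", "aa_p", "p")) {
  method <- match.arg(method)
  n <- length(seqs)
  fun <- switch(method,
                tn93 = tamura_nei_distance,
                aa_p = aa_p_distance,
                p = function(a, b) {
                  ca <- strsplit(toupper(a), "")[[1]]
                  cb <- strsplit(toupper(b), "")[[1]]
                  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
                  if (!any(ok)) return(NA_real_)
                  mean(ca[ok] != cb[ok])
                })
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- fun(seqs[[i]], seqs[[j]])
  }
  m
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# per-codon synonymous site count under the modified Nei-Gojobori weighting.
# R is the transition/transversion ratio (MEGA convention): the transition
# change at a position has weight R/(R+1), each transversion 1/(2(R+1)), so
# weights sum to 1 per position and R = 0.5 gives the unmodified equal-1/3
# weighting. Changes creating stop codons count as nonsynonymous, keeping
# syn + nonsyn = 3 per codon.
codon_syn_sites <- function(codon, R) {
  code <- Biostrings::GENETIC_CODE
  aa0 <- code[[codon]]
  chars <- strsplit(codon, "")[[1]]
  wt <- R / (R + 1)
  wv <- 1 / (2 * (R + 1))
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, chars[p])) {
      mut <- chars; mut[p] <- b
      mc <- paste(mut, collapse = "")
      w <- if (is_transition(chars[p], b)) wt else wv
      if (!mc %in% STOP_CODONS && code[[mc]] == aa0) s <- s + w
    }
  }
  s
}

# average synonymous / nonsynonymous difference counts between two codons over
# all minimal substitution pathways; pathways through intermediate stop codons
# are excluded (all pathways used if every one is blocked).
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  perms <- switch(length(pos),
                  list(pos),
                  list(pos, rev(pos)),
                  {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  eval_path <- function(ord) {
    cur <- a
    sd <- nd <- 0
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      cc <- paste(cur, collapse = ""); nc <- paste(nxt, collapse = "")
      if (nc %in% STOP_CODONS && !identical(nxt, b)) return(NULL)  # blocked
      syn <- !cc %in% STOP_CODONS && !nc %in% STOP_CODONS &&
        code[[cc]] == code[[nc]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, eval_path)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {  # all pathways pass through stops; fall back to all
    res <- lapply(perms, function(ord) {
      cur <- a; sd <- nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        cc <- paste(cur, collapse = ""); nc <- paste(nxt, collapse = "")
        syn <- !cc %in% STOP_CODONS && !nc %in% STOP_CODONS &&
          code[[cc]] == code[[nc]]
        if (syn) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(res))
  }
  Reduce(`+`, res[ok]) / sum(ok)
}

# Per-pair, per-codon components for dN/dS: matrices [pair x codon] of
# synonymous sites (pair-averaged), nonsynonymous sites, and synonymous /
# nonsynonymous differences. Codons where either sequence has a non-ACGT
# character or a stop codon are dropped pairwise (NA columns for that pair).
ng_components <- function(aln, R) {
  seqs <- aln$sequences
  n <- length(seqs)
  nc <- aln$n_codon
  starts <- seq(1L, by = 3L, length.out = nc)
  codons <- t(vapply(seqs, function(s) substring(s, starts, starts + 2L),
                     character(nc)))
  valid <- matrix(grepl("^[ACGT]{3}$", codons) & !(codons %in% STOP_CODONS),
                  nrow = n)
  ucod <- unique(as.vector(codons[valid]))
  syn_sites <- stats::setNames(vapply(ucod, codon_syn_sites, numeric(1), R = R),
                               ucod)
  pair_idx <- utils::combn(n, 2)
  np <- ncol(pair_idx)
  S <- N <- SD <- ND <- matrix(NA_real_, np, nc)
  diff_cache <- new.env(parent = emptyenv())
  for (k in seq_len(np)) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    for (c in seq_len(nc)) {
      if (!valid[i, c] || !valid[j, c]) next
      c1 <- codons[i, c]; c2 <- codons[j, c]
      s <- (syn_sites[[c1]] + syn_sites[[c2]]) / 2
      S[k, c] <- s
      N[k, c] <- 3 - s
      key <- paste0(c1, c2)
      d <- diff_cache[[key]]
      if (is.null(d)) {
        d <- codon_pair_diffs(c1, c2)
        assign(key, d, envir = diff_cache)
      }
      SD[k, c] <- d[["sd"]]
      ND[k, c] <- d[["nd"]]
    }
  }
  list(S = S, N = N, SD = SD, ND = ND, pairs = pair_idx,
       labels = names(seqs), n_codon = nc)
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' \code{d = -(3/4) log(1 - 4p/3)}; undefined (NA) for p >= 0.75.
#'
#' @param p observed proportion of differences.
#' @return corrected number of substitutions per site.
#' @export
jukes_cantor <- function(p) {
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  d
}

ng_from_components <- function(comp, codon_cols) {
  S <- rowSums(comp$S[, codon_cols, drop = FALSE], na.rm = TRUE)
  N <- rowSums(comp$N[, codon_cols, drop = FALSE], na.rm = TRUE)
  SD <- rowSums(comp$SD[, codon_cols, drop = FALSE], na.rm = TRUE)
  ND <- rowSums(comp$ND[, codon_cols, drop = FALSE], na.rm = TRUE)
  pS <- ifelse(S > 0, SD / S, NA_real_)
  pN <- ifelse(N > 0, ND / N, NA_real_)
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  c(dN = mean(dN, na.rm = TRUE), dS = mean(dS, na.rm = TRUE))
}

partition_codons <- function(aln, partition) {
  nc <- aln$n_codon
  switch(partition,
         total = seq_len(nc),
         abs = {
           if (is.null(aln$abs_mask)) stop("no ABS mask in alignment")
           which(aln$abs_mask)
         },
         non_abs = {
           if (is.null(aln$abs_mask)) stop("no ABS mask in alignment")
           which(!aln$abs_mask)
         },
         stop("unknown partition: ", partition))
}

#' Modified Nei-Gojobori dN and dS with Jukes-Cantor correction
#'
#' Synonymous and nonsynonymous sites are counted per codon with
#' transition/transversion weighting (ratio \code{R}); differences are
#' averaged with equal weight over all minimal substitution pathways between
#' each codon pair (pathways through stop codons excluded). Per-pair
#' proportions are Jukes-Cantor corrected and averaged over all sequence
#' pairs. Pairs whose proportion reaches 0.75 are dropped with a warning.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @param partition "total", "abs" or "non_abs".
#' @param R assumed transition/transversion ratio; R = 0.5 reproduces the
#'   unmodified Nei-Gojobori site counts.
#' @return named vector c(dN, dS) in substitutions per site.
#' @export
nei_gojobori_modified <- function(aln, partition = "total", R = 2.0) {
  comp <- ng_components(aln, R)
  cols <- partition_codons(aln, partition)
  res <- ng_from_components(comp, cols)
  if (anyNA(res)) warning("some pairs saturated (p >= 0.75) or uninformative")
  res
}

#' Codon-resampling bootstrap standard errors for dN, dS and dN - dS
#'
#' Resamples codon positions within the selected partition with replacement
#' and recomputes the statistics; the SE is the standard deviation over
#' replicates.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @param partition "total", "abs" or "non_abs".
#' @param R transition/transversion ratio.
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return list(se_dN, se_dS, se_diff, reps = matrix of replicate values).
#' @export
bootstrap_se <- function(aln, partition = "total", R = 2.0, n_reps = 1000L,
                         seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  comp <- ng_components(aln, R)
  cols <- partition_codons(aln, partition)
  if (length(cols) == 1L) warning("single-codon partition: degenerate SE")
  set.seed(seed)
  reps <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, c("dN", "dS")))
  for (b in seq_len(n_reps)) {
    reps[b, ] <- ng_from_components(comp, sample(cols, replace = TRUE))
  }
  diff <- reps[, "dN"] - reps[, "dS"]
  list(se_dN = stats::sd(reps[, "dN"], na.rm = TRUE),
       se_dS = stats::sd(reps[, "dS"], na.rm = TRUE),
       se_diff = stats::sd(diff, na.rm = TRUE),
       reps = reps)
}

#' One-tailed Z-test for positive selection (dN > dS)
#'
#' @param dN,dS substitution rates.
#' @param se_diff standard error of (dN - dS), e.g. from the joint bootstrap.
#' @return list(Z, p) with p the upper normal tail; both NA if se_diff is 0.
#' @export
z_test_positive_selection <- function(dN, dS, se_diff) {
  if (!is.finite(se_diff) || se_diff <= 0) return(list(Z = NA_real_, p = NA_real_))
  Z <- (dN - dS) / se_diff
  list(Z = Z, p = stats::pnorm(Z, lower.tail = FALSE))
}

#' Partitioned selection table (total / ABS / non-ABS)
#'
#' Runs the modified Nei-Gojobori analysis on the functional alleles of a
#' catalog for the three codon partitions, with joint codon-bootstrap standard
#' errors and one-tailed Z-tests for positive selection.
#'
#' @param catalog an \code{allele_catalog} (pseudogene-flagged alleles are
#'   excluded) or a named character vector of in-frame sequences.
#' @param abs_codons 1-based codon positions of the putative antigen-binding
#'   sites; if NULL, only the total partition is reported (with a warning).
#' @param R transition/transversion ratio.
#' @param n_reps bootstrap replicates.
#' @param seed RNG seed.
#' @return data.frame with one row per partition: partition, dN, se_dN, dS,
#'   se_dS, dn_ds, Z, p, n_codons.
#' @export
run_selection_table <- function(catalog, abs_codons = NULL, R = 2.0,
                                n_reps = 1000L, seed = 1L) {
  if (inherits(catalog, "allele_catalog")) {
    seqs <- stats::setNames(catalog$sequence[catalog$functional],
                            catalog$name[catalog$functional])
  } else {
    seqs <- catalog
  }
  seqs <- seqs[!has_internal_stop(seqs)]
  if (length(seqs) < 2L) stop("need at least 2 functional alleles")
  lens <- nchar(seqs)
  keep_len <- lens == max(lens)  # frameshifted/short alleles cannot align gap-free
  seqs <- seqs[keep_len]
  aln <- codon_alignment(seqs, abs_mask = abs_codons)
  partitions <- if (is.null(abs_codons)) {
    warning("no ABS mask supplied; reporting the total partition only")
    "total"
  } else c("total", "abs", "non_abs")
  rows <- lapply(partitions, function(part) {
    est <- nei_gojobori_modified(aln, part, R)
    se <- bootstrap_se(aln, part, R, n_reps, seed = derive_seed(seed, part))
    zt <- z_test_positive_selection(est[["dN"]], est[["dS"]], se$se_diff)
    data.frame(partition = c(total = "Total", abs = "ABS",
                             non_abs = "non-ABS")[[part]],
               dN = est[["dN"]], se_dN = se$se_dN,
               dS = est[["dS"]], se_dS = se$se_dS,
               dn_ds = est[["dN"]] / est[["dS"]],
               Z = zt$Z, p = zt$p,
               n_codons = length(partition_codons(aln, part)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "R") <- R
  attr(out, "n_bootstrap") <- n_reps
  out
}
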