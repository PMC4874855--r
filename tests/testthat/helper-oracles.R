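# Independent oracles, implemented from the primary definitions with no code
# shared with the package internals.

GC <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(GC)[GC == "*"]

# --- Nei-Gojobori oracle: brute-force site and pathway counting ------------

# synonymous site count of one codon, weighting the transition change by
# R/(R+1) and each transversion by 1/(2(R+1))
oracle_syn_sites <- function(codon, R) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  total <- 0
  for (p in 1:3) {
    from <- substr(codon, p, p)
    for (to in c("A", "C", "G", "T")) {
      if (to == from) next
      mut <- codon
      substr(mut, p, p) <- to
      w <- if (identical(unname(transitions[from]), to)) R / (R + 1)
      else 1 / (2 * (R + 1))
      if (!(mut %in% ORACLE_STOPS) && GC[[mut]] == GC[[codon]])
        total <- total + w
    }
  }
  total
}

# all orderings of the differing positions, recursively
oracle_orderings <- function(pos) {
  if (length(pos) <= 1L) return(list(pos))
  out <- list()
  for (i in seq_along(pos)) {
    for (rest in oracle_orderings(pos[-i])) {
      out[[length(out) + 1L]] <- c(pos[i], rest)
    }
  }
  out
}

# average (syn, nonsyn) difference counts between two codons over minimal
# pathways, excluding pathways visiting an intermediate stop codon
oracle_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- oracle_orderings(pos)
  eval_one <- function(ord, allow_stops) {
    cur <- c1
    sd <- nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && nxt %in% ORACLE_STOPS && nxt != c2) return(NULL)
      syn <- !(cur %in% ORACLE_STOPS) && !(nxt %in% ORACLE_STOPS) &&
        GC[[cur]] == GC[[nxt]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, eval_one, allow_stops = FALSE))
  if (!length(res)) res <- lapply(paths, eval_one, allow_stops = TRUE)
  Reduce(`+`, res) / length(res)
}

# full pairwise dN/dS for two in-frame sequences (mean over the single pair)
oracle_ng_pair <- function(s1, s2, R) {
  nc <- nchar(s1) %/% 3L
  S <- N <- SD <- ND <- 0
  for (c in seq_len(nc)) {
    c1 <- substr(s1, 3 * c - 2, 3 * c)
    c2 <- substr(s2, 3 * c - 2, 3 * c)
    sa <- oracle_syn_sites(c1, R)
    sb <- oracle_syn_sites(c2, R)
    S <- S + (sa + sb) / 2
    N <- N + 3 - (sa + sb) / 2
    d <- oracle_pair_diffs(c1, c2)
    SD <- SD + d[1]
    ND <- ND + d[2]
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  c(dN = jc(ND / N), dS = jc(SD / S), S = S, N = N, SD = SD, ND = ND)
}

# --- Tajima's D oracle: direct evaluation of the 1989 quantities -----------

oracle_tajima_d <- function(seqs) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  diffs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diffs <- c(diffs, sum(mat[i, ] != mat[j, ]))
  }
  khat <- mean(diffs)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_pi <- function(seqs) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(mat[i, ] != mat[j, ])
  }
  tot / choose(n, 2)
}

# --- Smith-Waterman oracle (match 2 / mismatch -3, linear gap -7) ----------
# Used only to cross-check retain/remove decisions of the reference filter on
# clear-cut cases, not to reproduce affine-gap scores exactly.

oracle_sw_identity <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- if (a[i - 1] == b[j - 1]) 2 else -3
    H[i, j] <- max(0, H[i - 1, j - 1] + sc, H[i - 1, j] - 7, H[i, j - 1] - 7)
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  i <- best[1]; j <- best[2]
  matches <- 0; len <- 0
  while (i > 1 && j > 1 && H[i, j] > 0) {
    sc <- if (a[i - 1] == b[j - 1]) 2 else -3
    if (H[i, j] == H[i - 1, j - 1] + sc) {
      matches <- matches + (a[i - 1] == b[j - 1]); len <- len + 1
      i <- i - 1; j <- j - 1
    } else if (H[i, j] == H[i - 1, j] - 7) {
      i <- i - 1; len <- len + 1
    } else {
      j <- j - 1; len <- len + 1
    }
  }
  list(identity = matches / len, length = len, score = max(H))
}

# --- misc fixtures ---------------------------------------------------------

# random in-frame stop-free coding sequence
random_cds <- function(n_codons) {
  sense <- names(GC)[GC != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
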