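# demultiplexing, tallying, reference filter, MPAF, genotype calling

FWD <- "ACGTRYACGT"
REV <- "TTGCATGCAA"
MIDS <- data.frame(mid = c("AAAACCCCGG", "TTTTGGGGCC"),
                   sample = c("s1", "s2"), stringsAsFactors = FALSE)

make_read <- function(mid, template, fwd = "ACGTATACGT") {
  paste0(mid, fwd, template, revcomp(REV))
}

test_that("demultiplex assigns, trims, canonicalizes and discards correctly", {
  tpl <- strrep("ACGT", 10)
  reads <- c(
    ok_fwd = make_read("AAAACCCCGG", tpl),
    ok_rev = revcomp(make_read("TTTTGGGGCC", tpl)),
    bad_mid = make_read("GGGGGGGGGG", tpl),
    bad_primer = paste0("AAAACCCCGG", "ACGTCCACGT", tpl, revcomp(REV)))
  rs <- demultiplex(reads, MIDS, FWD, REV)
  expect_s3_class(rs, "amplicon_readset")
  expect_equal(rs$sample, c("s1", "s2", NA, NA))
  expect_equal(rs$orientation[1:2], c("forward", "reverse"))
  expect_equal(rs$variant[1:2], c(tpl, tpl))
  expect_equal(rs$discard_reason, c(NA, NA, "no_mid", "no_primer"))
  # degenerate positions accept any allowed base: R = A/G at primer pos 5
  r2 <- c(x = make_read("AAAACCCCGG", tpl, fwd = "ACGTGCACGT"))
  expect_equal(demultiplex(r2, MIDS, FWD, REV)$sample, "s1")
  expect_error(demultiplex(reads, data.frame(mid = c("AA", "AA"),
                                             sample = c("a", "b")),
                           FWD, REV), "duplicate MIDs")
})

test_that("tally_variants counts exactly and is order-invariant", {
  tpl1 <- strrep("ACGT", 10)
  tpl2 <- strrep("AGGT", 10)
  reads <- c(r1 = make_read("AAAACCCCGG", tpl1),
             r2 = make_read("AAAACCCCGG", tpl1),
             r3 = make_read("AAAACCCCGG", tpl1),
             r4 = make_read("AAAACCCCGG", tpl2))
  vt <- tally_variants(demultiplex(reads, MIDS, FWD, REV))
  expect_equal(sort(vt$counts$count), c(1L, 3L))
  expect_equal(unname(vt$sample_totals["s1"]), 4L)
  expect_equal(vt$n_assigned, 4L)
  vt2 <- tally_variants(demultiplex(rev(reads), MIDS, FWD, REV))
  expect_equal(vt$counts, vt2$counts)
  # read conservation: assigned + discarded = input
  reads2 <- c(reads, bad = "ACGTACGT")
  rs2 <- demultiplex(reads2, MIDS, FWD, REV)
  expect_equal(sum(!is.na(rs2$sample)) + sum(!is.na(rs2$discard_reason)),
               length(reads2))
})

test_that("reference filter keeps identical variants, drops dissimilar ones", {
  set.seed(1)
  ref <- random_dna(1, 165)
  near <- ref
  substr(near, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(near, 10, 10))[1]
  far <- random_dna(1, 165)  # ~25% identity to ref positionally
  reads <- c(a = make_read("AAAACCCCGG", ref),
             b = make_read("AAAACCCCGG", near),
             c = make_read("AAAACCCCGG", far))
  vt <- tally_variants(demultiplex(reads, MIDS, FWD, REV))
  fv <- reference_filter(vt, c(ref = ref), min_identity = 0.70,
                         min_overlap = 120)
  expect_setequal(fv$pooled$variant, c(ref, near))
  removed <- attr(fv, "removed")
  expect_equal(removed$variant, far)
  # decision agrees with an independent Smith-Waterman oracle
  sw <- oracle_sw_identity(far, ref)
  expect_true(sw$identity < 0.70 || sw$length < 120)
  expect_gte(oracle_sw_identity(near, ref)$identity, 0.70)
  expect_error(reference_filter(vt, character(0)), "empty")
})

test_that("reference filter retains a deletion-bearing variant via alignment", {
  set.seed(2)
  ref <- random_dna(1, 165)
  del <- paste0(substr(ref, 1, 110), substr(ref, 124, 165))  # 13-nt deletion
  reads <- c(a = make_read("AAAACCCCGG", del))
  vt <- tally_variants(demultiplex(reads, MIDS, FWD, REV))
  fv <- reference_filter(vt, c(ref = ref), min_identity = 0.70,
                         min_overlap = 120)
  expect_equal(fv$pooled$variant, del)
})

test_that("MPAF is the max within-amplicon frequency", {
  v1 <- strrep("ACGT", 10)
  v2 <- strrep("AGGT", 10)
  reads <- c(
    stats::setNames(rep(make_read("AAAACCCCGG", v1), 45), paste0("a", 1:45)),
    stats::setNames(rep(make_read("AAAACCCCGG", v2), 5), paste0("b", 1:5)),
    stats::setNames(rep(make_read("TTTTGGGGCC", v1), 80), paste0("c", 1:80)),
    stats::setNames(rep(make_read("TTTTGGGGCC", v2), 20), paste0("d", 1:20)))
  vt <- compute_mpaf(tally_variants(demultiplex(reads, MIDS, FWD, REV)))
  mp <- stats::setNames(vt$mpaf$mpaf, vt$mpaf$variant)
  expect_equal(unname(mp[v2]), 0.20)      # max(5/50, 20/100)
  expect_equal(unname(mp[v1]), 0.90)      # max(45/50, 80/100)
  # a variant that is all reads of its only sample has MPAF 1
  solo <- c(x = make_read("AAAACCCCGG", v1))
  vts <- compute_mpaf(tally_variants(demultiplex(solo, MIDS, FWD, REV)))
  expect_equal(vts$mpaf$mpaf, 1.0)
})

test_that("global allele filter is inclusive, monotone, and names by count", {
  v <- vapply(1:4, function(i) {
    s <- strrep("ACGT", 40); substr(s, i, i) <- "T"; s
  }, character(1))
  # per-sample counts chosen so MPAFs are 0.5, 0.25, 0.10, 0.05
  reads <- c(
    stats::setNames(rep(make_read("AAAACCCCGG", v[1]), 50), paste0("a", 1:50)),
    stats::setNames(rep(make_read("AAAACCCCGG", v[2]), 25), paste0("b", 1:25)),
    stats::setNames(rep(make_read("AAAACCCCGG", v[3]), 10), paste0("c", 1:10)),
    stats::setNames(rep(make_read("AAAACCCCGG", v[4]), 5), paste0("d", 1:5)),
    stats::setNames(rep(make_read("AAAACCCCGG", strrep("ACGT", 40)), 10),
                    paste0("e", 1:10)))
  vt <- compute_mpaf(tally_variants(demultiplex(reads, MIDS, FWD, REV)))
  cat10 <- global_allele_filter(vt, 0.10)
  expect_setequal(cat10$sequence, c(v[1:3], strrep("ACGT", 40)))  # 0.10 kept
  cat25 <- global_allele_filter(vt, 0.25)
  expect_true(all(cat25$sequence %in% cat10$sequence))  # monotone
  expect_equal(cat10$name[1], "DAB*01")
  expect_equal(cat10$pooled_count, sort(cat10$pooled_count, decreasing = TRUE))
  # known-allele names preserved on exact sequence identity
  catk <- global_allele_filter(vt, 0.10, known = c("Known*07" = v[1]))
  expect_true("Known*07" %in% catk$name)
  expect_equal(catk$sequence[catk$name == "Known*07"], v[1])
  expect_error(global_allele_filter(vt, 0), "threshold")
  # degenerate threshold edge: tiny positive threshold keeps everything
  expect_equal(nrow(global_allele_filter(vt, 1e-6)), nrow(vt$mpaf))
})

test_that("within-amplicon genotype calling applies the 10%-of-max rule", {
  catalog <- new_allele_catalog(name = c("A1", "A2", "A3"),
                                sequence = c("AAA", "CCC", "GGG"))
  counts <- c(AAA = 100L, CCC = 30L, GGG = 9L)
  expect_equal(call_genotype(counts, catalog), c("A1", "A2"))
  # boundary inclusive: 10 >= 0.10 * 100
  expect_equal(call_genotype(c(AAA = 100L, GGG = 10L), catalog),
               c("A1", "A3"))
  expect_equal(call_genotype(c(CCC = 7L), catalog), "A2")
  expect_null(call_genotype(c(TTT = 50L), catalog))
  # monotone: raising the threshold never adds alleles
  g10 <- call_genotype(counts, catalog, 0.10)
  g30 <- call_genotype(counts, catalog, 0.301)
  expect_true(all(g30 %in% g10))
})

test_that("depth QC excludes shallow samples", {
  vt <- list(sample_totals = c(s1 = 3L, s2 = 500L))
  expect_equal(depth_qc(vt, 100L), "s1")
  expect_equal(depth_qc(vt, 1L), character(0))
  expect_error(depth_qc(vt, 0L), ">= 1")
})

test_that("pseudogene flagging catches frameshifts and internal stops", {
  set.seed(3)
  full <- random_cds(55)           # 165 nt, stop-free
  short <- paste0(substr(full, 1, 110), substr(full, 124, 165))
  stopped <- paste0(substr(full, 1, 30), "TAA", substr(full, 34, 165))
  cat <- new_allele_catalog(name = c("ok", "del", "stop"),
                            sequence = c(full, short, stopped))
  cat <- flag_pseudogenes(cat, expected_length = 165L)
  expect_equal(cat$functional, c(TRUE, FALSE, FALSE))
  expect_match(cat$note[2], "frameshift")
  expect_match(cat$note[3], "stop")
})

test_that("depth bias check distinguishes monotone from independent counts", {
  gt <- structure(list(
    mhc = stats::setNames(lapply(1:20, function(i) paste0("a", seq_len(i))),
                          paste0("s", 1:20)),
    read_totals = stats::setNames(100 * (1:20), paste0("s", 1:20))),
    class = "genotype_table")
  res <- depth_bias_check(gt)
  expect_equal(res$rho, 1)
  set.seed(7)
  gt2 <- structure(list(
    mhc = stats::setNames(lapply(sample(1:12, 40, TRUE),
                                 function(k) paste0("a", seq_len(k))),
                          paste0("s", 1:40)),
    read_totals = stats::setNames(sample(100:2000, 40), paste0("s", 1:40))),
    class = "genotype_table")
  res2 <- depth_bias_check(gt2)
  expect_lt(abs(res2$rho), 0.35)
  expect_gt(res2$p, 0.05)
})

test_that("minimum locus count is the ceiling of half the max allele count", {
  mk <- function(k) list(a = paste0("x", seq_len(k)))
  expect_equal(infer_min_loci(mk(12)), 6L)
  expect_equal(infer_min_loci(mk(1)), 1L)
  expect_equal(infer_min_loci(mk(7)), 4L)
})
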