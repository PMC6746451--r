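mvh <- "GACCAGCAGGGGGC"

test_that("exact matches are found on both strands", {
  h <- scan_motif(mvh, mvh, max_mismatch = 0)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 14L)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0L)

  h <- scan_motif("GCCCCCTGCTGGTC", mvh, max_mismatch = 0)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$matched_seq, mvh)   # reported in motif orientation
})

test_that("windows containing N never match; short sequences give empty", {
  expect_equal(nrow(scan_motif("GACCAGCANGGGGC", mvh, 2)), 0L)
  expect_equal(nrow(scan_motif("ACGT", mvh, 2)), 0L)
  expect_error(scan_motif("ACGTACGTACGTACGT", "ACNT"), "ambiguity")
})

test_that("region restriction keeps only fully contained windows", {
  seq <- paste0("TTTT", mvh, "TTTT")
  expect_equal(nrow(scan_motif(seq, mvh, 0, region = c(4, 18))), 1L)
  expect_equal(nrow(scan_motif(seq, mvh, 0, region = c(5, 18))), 0L)
  expect_equal(nrow(scan_motif(seq, mvh, 0, region = c(4, 17))), 0L)
})

test_that("scanner equals per-window enumeration on random sequences", {
  withr::with_seed(11, {
    for (rep in 1:12) {
      bases <- random_dna(400)
      motif <- random_dna(sample(6:12, 1))
      k <- sample(0:3, 1)
      got <- scan_motif(bases, motif, k)
      want <- oracle_scan(bases, motif, k)
      expect_equal(got[, names(want)], want)
    }
    # and with Ns sprinkled in
    ch <- strsplit(random_dna(400), "")[[1]]
    ch[sample(400, 12)] <- "N"
    bases <- paste(ch, collapse = "")
    got <- scan_motif(bases, "ACGTAC", 2)
    want <- oracle_scan(bases, "ACGTAC", 2)
    expect_equal(got[, names(want)], want)
  })
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      n <- 300
      bases <- random_dna(n)
      motif <- random_dna(8)
      fwd <- scan_motif(bases, motif, 2)
      rev <- scan_motif(reverse_complement(bases), motif, 2)
      mirrored <- data.frame(start = n - rev$end, end = n - rev$start,
                             strand = ifelse(rev$strand == "+", "-", "+"),
                             mismatches = rev$mismatches,
                             matched_seq = rev$matched_seq,
                             stringsAsFactors = FALSE)
      mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
      rownames(mirrored) <- NULL
      expect_equal(fwd[, names(mirrored)], mirrored)
    }
  })
})

test_that("PFM counts columns and enforces its invariants", {
  pfm <- build_pfm(c("AAC", "AAC", "AAG"))
  expect_equal(pfm$n_sequences, 3L)
  expect_equal(unname(colSums(pfm$counts)), c(3, 3, 3))
  expect_equal(unname(pfm$counts["C", 3]), 2)
  expect_equal(unname(pfm$counts["G", 3]), 1)

  one <- build_pfm("ACGT")
  expect_equal(unname(diag(one$counts[c("A", "C", "G", "T"), ])), rep(1, 4))

  expect_error(build_pfm(character(0)), "zero")
  expect_error(build_pfm(c("AC", "ACG")), "length")
})

test_that("majority consensus breaks ties by fixed base order", {
  expect_equal(consensus_from_pfm(build_pfm(c("AACT", "AACT", "AAGT")))$bases,
               "AACT")
  tie <- consensus_from_pfm(build_pfm(c("ATTT", "CTTT")))
  expect_equal(tie$bases, "ATTT")          # A wins the 1-1 tie
  expect_equal(attr(tie, "ties"), 1L)
  # exact-match scan returns the query as its own consensus
  hits <- scan_motif(paste0("TT", mvh, "AA", mvh, "TT"), mvh, 0)
  expect_equal(consensus_from_pfm(build_pfm(hits))$bases, mvh)
})

test_that("refinement converges to a planted motif and records the trace", {
  spec <- synthetic_locus_spec(length_bp = 120000, n_proximal_segments = 12,
                               n_distal_segments = 4, n_intergenic_sites = 4,
                               n_hotspots = 0,
                               mismatch_probs = c(`0` = 1))
  sim <- generate_locus(spec, seed = 5)
  seed_motif <- "GACCAGCAGGGGTA"         # 2 mismatches from the planted motif
  tr <- refine_search(sim$locus, seed_motif, max_mismatch = 2, max_rounds = 10)
  expect_true(tr$converged)
  expect_lte(length(tr$rounds), 3L)
  expect_gte(tr$rounds[[1]]$n_hits, nrow(sim$truth))
  expect_equal(tr$final$bases, spec$motif$bases)
  # converged traces end with two identical consecutive consensi
  n <- length(tr$rounds)
  expect_equal(tr$rounds[[n]]$consensus$bases,
               tr$rounds[[n - 1]]$consensus$bases)
  # deterministic
  tr2 <- refine_search(sim$locus, seed_motif, max_mismatch = 2, max_rounds = 10)
  expect_identical(tr$rounds[[n]]$hits, tr2$rounds[[n]]$hits)
})

test_that("a zero-hit round flags instead of throwing", {
  expect_warning(
    tr <- refine_search(paste(rep("A", 100), collapse = ""),
                        "CCCGGGCCCGGG", max_mismatch = 1),
    "no hits")
  expect_false(tr$converged)
  expect_true(tr$empty_round)
})

test_that("logo matrix carries information content in bits", {
  allg <- build_pfm(c("G", "G", "G", "G"))
  lm <- logo_matrix(allg)
  expect_equal(attr(lm, "info_content"), 2)
  expect_equal(unname(lm["G", 1]), 2)
  uniform <- build_pfm(c("A", "C", "G", "T"))
  expect_equal(attr(logo_matrix(uniform), "info_content"), 0)
  half <- build_pfm(c("A", "A", "C", "C"))
  lmh <- logo_matrix(half)
  expect_equal(attr(lmh, "info_content"), 1)
  expect_equal(unname(lmh["A", 1]), 0.5)
  expect_equal(unname(lmh["C", 1]), 0.5)
})

test_that("site density is sites per Mb", {
  expect_equal(site_density(144, 3008177), 144 / 3.008177, tolerance = 1e-12)
  expect_equal(site_density(0, 1e6), 0)
  expect_equal(site_density(10, 1e6), 10)
  expect_error(site_density(5, 0), "positive")
})
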