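mvh <- "GACCAGCAGGGGGC"

classify_tiny <- function(gap = 18L, ...) {
  tl <- tiny_locus(gap = gap, ...)
  hits <- scan_motif(tl$locus, mvh, max_mismatch = 2)
  list(tl = tl, cl = classify_sites(hits, tl$segments, tl$rss))
}

test_that("a site 18 bp downstream of the nonamer is canonical RSS-associated", {
  x <- classify_tiny(gap = 18L)
  expect_equal(nrow(x$cl), 1L)
  expect_equal(x$cl$site_class, "RSS_ASSOCIATED")
  expect_equal(x$cl$rss_distance, 18L)
  expect_true(x$cl$canonical)
  expect_true(x$cl$oriented_with_transcription)
  # gap 25: associated but non-canonical; gap 61: outside the window
  x <- classify_tiny(gap = 25L)
  expect_equal(x$cl$site_class, "RSS_ASSOCIATED")
  expect_false(x$cl$canonical)
  x <- classify_tiny(gap = 61L)
  expect_false("RSS_ASSOCIATED" %in% x$cl$site_class)
})

test_that("upstream sites bin by distance to the leader start", {
  mk <- function(d) {
    withr::with_seed(17, {
      site_start <- 50L
      leader_start <- site_start + 14L + d
      chars <- strsplit(random_dna(leader_start + 12000L), "")[[1]]
      chars[(site_start + 1L):(site_start + 14L)] <- strsplit(mvh, "")[[1]]
      seg <- data.frame(segment_id = "u1", family = "J558", functional = TRUE,
                        chrom = "chrT", leader_start = leader_start,
                        leader_end = leader_start + 50L,
                        coding_start = leader_start + 130L,
                        coding_end = leader_start + 430L, strand = "+",
                        stringsAsFactors = FALSE)
      locus <- locus_sequence("chrT", paste(chars, collapse = ""))
      hits <- scan_motif(locus, mvh, 0)
      classify_sites(hits, seg, empty_rss <- data.frame(
        segment_id = character(), chrom = character(),
        heptamer_start = integer(), heptamer_end = integer(),
        spacer_len = integer(), nonamer_start = integer(),
        nonamer_end = integer(), strand = character(),
        stringsAsFactors = FALSE))
    })
  }
  for (case in list(list(800L, "proximal"), list(2500L, "mid"),
                    list(5500L, "far"), list(8000L, "far"))) {
    cl <- mk(case[[1]])
    cl <- cl[cl$start == 50L, ]
    expect_equal(cl$site_class, "UPSTREAM")
    expect_equal(cl$leader_distance, case[[1]])
    expect_equal(cl$upstream_bin, case[[2]])
  }
  # beyond 8 kb: intergenic
  cl <- mk(8001L)
  expect_equal(cl$site_class[cl$start == 50L], "INTERGENIC")
})

test_that("classification is a partition and warns on unannotated chroms", {
  spec <- small_sim_spec()
  sim <- generate_locus(spec, seed = 21)
  hits <- scan_motif(sim$locus, spec$motif, 2)
  cl <- classify_sites(hits, sim$segments, sim$rss)
  expect_equal(nrow(cl), nrow(hits))
  expect_true(all(cl$site_class %in% c("RSS_ASSOCIATED", "UPSTREAM",
                                       "INTERGENIC")))
  counts <- table(cl$site_class)
  expect_equal(sum(counts), nrow(cl))
  # rss_distance present iff RSS_ASSOCIATED, bin iff UPSTREAM
  expect_true(all(is.na(cl$rss_distance) != (cl$site_class == "RSS_ASSOCIATED")))
  expect_true(all(is.na(cl$upstream_bin) != (cl$site_class == "UPSTREAM")))
  other <- hits[1, ]; other$chrom <- "chrOther"
  expect_warning(cl2 <- classify_sites(other, sim$segments, sim$rss),
                 "INTERGENIC")
  expect_equal(cl2$site_class, "INTERGENIC")
})

test_that("rescue scan finds relaxed sites at the recorded gap", {
  tl <- tiny_locus(gap = 19L)
  # degrade the planted site to 3 mismatches from the consensus
  chars <- strsplit(tl$locus$bases, "")[[1]]
  s <- tl$site_start
  chars[s + c(1L, 2L, 3L)] <- c("T", "T", "T")  # GACC... -> GTTT...
  locus <- locus_sequence("chrT", paste(chars, collapse = ""))
  expect_equal(nrow(scan_motif(locus, mvh, 2)), 0L)
  rs <- rescue_scan(locus, tl$rss, mvh, max_mismatch = 4)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$mismatches, 3L)
  expect_equal(rs$rss_distance, 19L)
  expect_equal(rs$label, "relaxed")
  # an RSS with nothing within the window stays empty
  far <- tl$rss; far$nonamer_start <- 20L; far$nonamer_end <- 29L
  far$heptamer_start <- 0L; far$heptamer_end <- 7L
  expect_equal(nrow(rescue_scan(locus, far, mvh, max_mismatch = 4)), 0L)
  # relaxed hits equal brute-force restricted enumeration
  want <- oracle_scan(locus$bases, mvh, 4)
  want <- want[want$start - tl$rss$nonamer_end >= 0 &
                 want$start - tl$rss$nonamer_end <= 60, ]
  expect_equal(rs$start, want$start)
})

test_that("orientation summary counts the majority and resolves ties", {
  base <- data.frame(oriented_with_transcription =
                       c(rep(TRUE, 145), rep(FALSE, 2)))
  os <- orientation_summary(base)
  expect_equal(os$n_total, 147L)
  expect_equal(os$n_preferred, 145L)
  expect_equal(os$preferred_fraction, 145 / 147)
  expect_equal(os$preferred, "with")

  all_with <- orientation_summary(
    data.frame(oriented_with_transcription = rep(TRUE, 10)))
  expect_equal(all_with$preferred_fraction, 1)

  tied <- orientation_summary(
    data.frame(oriented_with_transcription = rep(c(TRUE, FALSE), 3)))
  expect_equal(tied$preferred, "with")
  expect_true(tied$tie)
  expect_equal(tied$preferred_fraction, 0.5)

  expect_error(orientation_summary(
    data.frame(oriented_with_transcription = logical(0))), "empty")
})

test_that("CpG flags read the motif core and its 3' flanking base", {
  run_one <- function(flank) {
    x <- classify_tiny(gap = 18L, flank_after = flank)
    cpg_profile(x$cl, x$tl$locus)
  }
  withG <- run_one("G")
  # core GACCAGCAGGGGGC: (4,5)=C,A (6,7)=G,C are not CpG; C+flank G is
  expect_false(withG$flags$cpg_4_5[1])
  expect_false(withG$flags$cpg_6_7[1])
  expect_true(withG$flags$cpg_14_15[1])
  withA <- run_one("A")
  expect_false(withA$flags$cpg_14_15[1])
})

test_that("CpG fractions recover a planted half-and-half flank split", {
  spec <- synthetic_locus_spec(length_bp = 400000, n_proximal_segments = 15,
                               n_distal_segments = 15,
                               n_intergenic_sites = 10, n_hotspots = 1,
                               cpg_flank_fraction = 0.5)
  sim <- generate_locus(spec, seed = 8)
  hits <- scan_motif(sim$locus, spec$motif, 2)
  cl <- classify_sites(hits, sim$segments, sim$rss)
  cp <- cpg_profile(cl, sim$locus)
  # motif mismatches can strike position 14, so compare against the
  # realised flank G count, tracked per planted site in the truth table
  ord <- order(cl$start)
  m <- merge(cl, sim$truth, by = "start")
  realised <- mean(substr(m$matched_seq, 14, 14) == "C" & m$cpg_flank)
  ov <- cp$summary[cp$summary$site_class == "overall" &
                     cp$summary$pair == "cpg_14_15", ]
  expect_equal(ov$fraction, realised)
  expect_gt(ov$fraction, 0.25)
  expect_lt(ov$fraction, 0.75)
})

test_that("hot spots chain by start-to-start gap and partition the sites", {
  sites <- data.frame(chrom = "chrT", start = c(0L, 40L, 90L),
                      end = c(14L, 54L, 104L))
  hs <- find_hotspots(sites, max_gap = 100, min_sites = 3)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_sites, 3L)
  expect_equal(hs$span_bp, 104L)
  # sites 5 kb apart never chain
  sparse <- data.frame(chrom = "chrT", start = c(0L, 5000L, 10000L),
                       end = c(14L, 5014L, 10014L))
  expect_equal(nrow(find_hotspots(sparse, max_gap = 100)), 0L)
  # random placements equal the transitive-closure oracle
  withr::with_seed(13, {
    for (rep in 1:10) {
      starts <- sort(sample.int(5000L, 40L))
      df <- data.frame(chrom = "chrT", start = starts, end = starts + 14L)
      gap <- sample(c(50L, 120L, 300L), 1)
      hs <- find_hotspots(df, max_gap = gap, min_sites = 2)
      labels <- oracle_cluster(starts, gap)
      want <- table(labels)[table(labels) >= 2]
      expect_equal(sort(hs$n_sites), as.integer(sort(unname(want))))
      # no site in two hotspots
      members <- unlist(hs$members)
      expect_equal(anyDuplicated(members), 0L)
    }
  })
})

test_that("per-class PFMs recover class-specific planted variants", {
  seqs_a <- rep("GACCAGCAGGGGGC", 5)
  seqs_b <- rep("AACCAGCAGGGGGT", 4)
  cl <- data.frame(
    matched_seq = c(seqs_a, seqs_b),
    site_class = c(rep("RSS_ASSOCIATED", 5), rep("UPSTREAM", 4)),
    stringsAsFactors = FALSE)
  pfms <- class_pfms(cl)
  expect_named(pfms, c("RSS_ASSOCIATED", "UPSTREAM"))
  expect_equal(consensus_from_pfm(pfms$RSS_ASSOCIATED)$bases, seqs_a[1])
  expect_equal(consensus_from_pfm(pfms$UPSTREAM)$bases, seqs_b[1])
  expect_equal(unname(colSums(pfms$RSS_ASSOCIATED$counts)), rep(5, 14))
  one <- class_pfms(cl[cl$site_class == "UPSTREAM", ])
  expect_named(one, "UPSTREAM")
})
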