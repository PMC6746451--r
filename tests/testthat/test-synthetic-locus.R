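test_that("the same seed yields byte-identical loci and truth", {
  spec <- small_sim_spec()
  a <- generate_locus(spec, seed = 4)
  b <- generate_locus(spec, seed = 4)
  expect_identical(a$locus$bases, b$locus$bases)
  expect_identical(a$truth, b$truth)
  expect_identical(a$segments, b$segments)
  c <- generate_locus(spec, seed = 5)
  expect_false(identical(a$locus$bases, c$locus$bases))
})

test_that("planted elements match the emitted sequence content", {
  spec <- small_sim_spec()
  sim <- generate_locus(spec, seed = 12)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    win <- substring(sim$locus$bases, tr$start[i] + 1L, tr$end[i])
    if (tr$strand[i] == "-") win <- reverse_complement(win)
    expect_equal(win, tr$planted_seq[i])
    # recorded mismatch count is the Hamming distance to the motif
    expect_equal(sum(strsplit(win, "")[[1]] !=
                       strsplit(spec$motif$bases, "")[[1]]),
                 tr$mismatches[i])
  }
  # RSS sequences are canonical
  for (j in seq_len(nrow(sim$rss))) {
    expect_equal(substring(sim$locus$bases, sim$rss$heptamer_start[j] + 1L,
                           sim$rss$heptamer_end[j]), "CACAGTG")
    expect_equal(substring(sim$locus$bases, sim$rss$nonamer_start[j] + 1L,
                           sim$rss$nonamer_end[j]), "ACAAAAACC")
  }
})

test_that("a spec that cannot fit fails before emitting sequence", {
  spec <- synthetic_locus_spec(length_bp = 20000, n_proximal_segments = 30,
                               n_distal_segments = 10, n_intergenic_sites = 5,
                               n_hotspots = 0)
  expect_error(generate_locus(spec, seed = 1), "does not fit")
  expect_error(synthetic_locus_spec(n_intergenic_sites = 2, n_hotspots = 1,
                                    hotspot_sites = 3), "hot spots")
  expect_error(synthetic_locus_spec(hotspot_span = 20), "overlap")
})

test_that("scrubbed loci contain exactly the planted matches", {
  spec <- small_sim_spec()
  sim <- generate_locus(spec, seed = 31)
  expect_equal(sim$unscrubbed_hits, 0L)
  hits <- scan_motif(sim$locus, spec$motif, spec$scrub_max_mismatch)
  expect_equal(nrow(hits), nrow(sim$truth))
  expect_equal(hits$start, sort(sim$truth$start))
})

test_that("recovered hits reproduce planted class, distance and orientation", {
  spec <- small_sim_spec()
  sim <- generate_locus(spec, seed = 44)
  hits <- scan_motif(sim$locus, spec$motif, 2)
  cl <- classify_sites(hits, sim$segments, sim$rss)
  m <- merge(cl, sim$truth, by = "start")
  expect_equal(nrow(m), nrow(sim$truth))
  expect_equal(m$site_class, m$class)
  expect_equal(m$strand.x, m$strand.y)
  expect_equal(m$mismatches.x, m$mismatches.y)
  rssd <- m$class == "RSS_ASSOCIATED"
  expect_equal(m$rss_distance[rssd], m$distance[rssd])
  expect_true(all(m$canonical[rssd]))
  ups <- m$class == "UPSTREAM"
  expect_equal(m$leader_distance[ups], m$distance[ups])
  # the planted hot spot is found with its configured geometry
  hs <- find_hotspots(cl, max_gap = 500, min_sites = 3)
  expect_equal(nrow(hs), spec$n_hotspots)
  expect_equal(hs$n_sites, spec$hotspot_sites)
  expect_equal(hs$span_bp, spec$hotspot_span + spec$motif$length)
})

test_that("minority orientation fraction is realised over seeds", {
  spec <- small_sim_spec(minority_orientation_fraction = 0.1)
  minority <- 0L; total <- 0L
  for (s in 1:6) {
    sim <- generate_locus(spec, seed = 200 + s)
    minority <- minority + sum(sim$truth$strand == "-")
    total <- total + nrow(sim$truth)
  }
  p <- 0.1
  se <- sqrt(p * (1 - p) / total)
  expect_lt(abs(minority / total - p), 3 * se + 1e-9)
})

test_that("peak coverage is exact by construction and decoys stay site-free", {
  spec <- small_sim_spec()
  sim <- generate_locus(spec, seed = 9)
  n <- nrow(sim$truth)
  pk <- generate_peaks(sim, coverage_fraction = 0.75, n_decoys = 10, seed = 3)
  expect_equal(length(pk$covered_site_ids), round(0.75 * n))
  sites <- sim$truth[, c("chrom", "start", "end")]
  ov <- interval_overlaps(sites, pk$peaks)
  expect_setequal(sim$truth$site_id[unique(ov$query)], pk$covered_site_ids)
  # full coverage, and zero coverage leaves only decoys
  full <- generate_peaks(sim, coverage_fraction = 1, seed = 3)
  expect_equal(length(full$covered_site_ids), n)
  v <- venn_overlap(sites, full$peaks)
  expect_equal(v$sites$occupied, n)
  none <- generate_peaks(sim, coverage_fraction = 0, n_decoys = 15, seed = 3)
  expect_equal(nrow(interval_overlaps(sites, none$peaks)), 0L)
})

test_that("peak width statistics match the generated peaks", {
  spec <- small_sim_spec()
  sim <- generate_locus(spec, seed = 9)
  pk <- generate_peaks(sim, coverage_fraction = 0.8, seed = 5)
  s <- peak_stats(pk$peaks)
  expect_equal(s$n_peaks, nrow(pk$peaks))
  expect_equal(s$mean_width, mean(pk$peaks$end - pk$peaks$start))
})

test_that("fixture directories are self-contained and re-readable", {
  spec <- small_sim_spec()
  sim <- generate_locus(spec, seed = 2)
  dir <- withr::local_tempdir()
  write_synthetic_fixture(sim, dir)
  expect_setequal(list.files(dir),
                  c("locus.fasta", "annotations.bed", "truth.tsv", "spec.json"))
  loc <- read_locus_fasta(file.path(dir, "locus.fasta"))[[1]]
  expect_equal(loc$bases, sim$locus$bases)
  ann <- read_annotations(file.path(dir, "annotations.bed"), "bed")
  expect_equal(nrow(ann$segments), nrow(sim$segments))
  expect_equal(nrow(ann$rss), nrow(sim$rss))
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(sim$truth))
})
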