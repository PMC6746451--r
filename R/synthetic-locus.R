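## Synthetic V_H-like locus generator with recorded ground truth.
##
## The generator lays out gene-segment units on an i.i.d. background:
## distal segments carry an upstream motif site at ~0.8/2.5/5.5 kb
## before the leader exon, proximal segments an RSS-associated site
## 17-19 bp downstream of the nonamer, and intergenic sites (including
## clustered hot spots) sit in annotation-free gaps buffered so they
## cannot fall in any segment's upstream window. Defaults mirror the
## murine study conditions: 144 planted sites (44 RSS-associated, 80
## upstream, 20 intergenic), ~2/147 minority orientation, CpG at the
## motif 3' flank in half of the sites.

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"
SEGMENT_GEOMETRY <- c(leader = 50L, intron = 80L, coding = 300L)

#' Parameters for the synthetic locus generator
#'
#' @param length_bp Total locus length (default 2 Mb).
#' @param base_composition Background probabilities for A/C/G/T.
#' @param motif Planted consensus motif (default the 14-mer V-region
#'   CTCF core `GACCAGCAGGGGGC`).
#' @param n_proximal_segments Segments with an RSS-associated site.
#' @param n_distal_segments Segments with an upstream site.
#' @param n_intergenic_sites Intergenic sites in total, of which
#'   `n_hotspots * hotspot_sites` are clustered.
#' @param rss_gap_choices Gaps (bp) drawn for RSS-associated sites.
#' @param upstream_distance_choices Distances (bp) drawn for upstream
#'   sites.
#' @param mismatch_probs Probabilities of planting 0, 1, 2, ... motif
#'   mismatches per site.
#' @param minority_orientation_fraction Probability a planted site runs
#'   against transcription (default 2/147).
#' @param cpg_flank_fraction Fraction of sites whose first 3' flanking
#'   base is forced to G (a CpG across the motif boundary when the
#'   motif ends in C).
#' @param n_hotspots,hotspot_sites,hotspot_span Hot-spot count, sites
#'   per hot spot and start-to-start span in bp.
#' @param gap_range Range of random gaps between adjacent units (bp).
#' @param scrub Re-randomise background windows that accidentally match
#'   the motif within `scrub_max_mismatch` (clean-field mode for exact
#'   recovery; disable for honest-background statistics).
#' @param scrub_max_mismatch Mismatch radius used by the scrubber.
#' @param locus_name Sequence name of the emitted locus.
#' @return A validated `synthetic_locus_spec` list.
#' @export
synthetic_locus_spec <- function(length_bp = 2e6,
                                 base_composition = rep(0.25, 4),
                                 motif = "GACCAGCAGGGGGC",
                                 n_proximal_segments = 44L,
                                 n_distal_segments = 80L,
                                 n_intergenic_sites = 20L,
                                 rss_gap_choices = c(17L, 18L, 19L),
                                 upstream_distance_choices = c(800L, 2500L, 5500L),
                                 mismatch_probs = c(`0` = 0.25, `1` = 0.5, `2` = 0.25),
                                 minority_orientation_fraction = 2 / 147,
                                 cpg_flank_fraction = 0.5,
                                 n_hotspots = 2L,
                                 hotspot_sites = 3L,
                                 hotspot_span = 100L,
                                 gap_range = c(500L, 1500L),
                                 scrub = TRUE,
                                 scrub_max_mismatch = 2L,
                                 locus_name = "synthetic_VH_locus") {
  stopifnot(length_bp > 0, length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-8,
            all(base_composition >= 0),
            n_proximal_segments >= 0L, n_distal_segments >= 0L,
            n_intergenic_sites >= 0L, n_hotspots >= 0L,
            minority_orientation_fraction >= 0,
            minority_orientation_fraction <= 1,
            cpg_flank_fraction >= 0, cpg_flank_fraction <= 1,
            abs(sum(mismatch_probs) - 1) < 1e-8,
            gap_range[1] >= 100L, gap_range[2] >= gap_range[1])
  if (n_hotspots * hotspot_sites > n_intergenic_sites) {
    stop("hot spots need more sites than n_intergenic_sites provides")
  }
  if (n_hotspots > 0L && hotspot_sites >= 2L) {
    spacing <- floor(hotspot_span / (hotspot_sites - 1L))
    motif_len <- nchar(motif)
    if (spacing <= motif_len) {
      stop("hotspot_span too small: member sites would overlap")
    }
  }
  structure(list(length_bp = as.integer(length_bp),
                 base_composition = base_composition,
                 motif = as_consensus_motif(motif),
                 n_proximal_segments = as.integer(n_proximal_segments),
                 n_distal_segments = as.integer(n_distal_segments),
                 n_intergenic_sites = as.integer(n_intergenic_sites),
                 rss_gap_choices = as.integer(rss_gap_choices),
                 upstream_distance_choices = as.integer(upstream_distance_choices),
                 mismatch_probs = mismatch_probs,
                 minority_orientation_fraction = minority_orientation_fraction,
                 cpg_flank_fraction = cpg_flank_fraction,
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_sites = as.integer(hotspot_sites),
                 hotspot_span = as.integer(hotspot_span),
                 gap_range = as.integer(gap_range),
                 scrub = scrub,
                 scrub_max_mismatch = as.integer(scrub_max_mismatch),
                 locus_name = locus_name),
            class = "synthetic_locus_spec")
}

## Introduce exactly m substitutions at distinct positions.
.mutate_motif <- function(bases, m) {
  if (m == 0L) return(bases)
  chars <- strsplit(bases, "")[[1]]
  pos <- sample.int(length(chars), m)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

.draw_mismatches <- function(spec) {
  ks <- as.integer(names(spec$mismatch_probs))
  sample(ks, 1L, prob = spec$mismatch_probs)
}

#' Generate a synthetic locus with known ground truth
#'
#' All randomness is drawn from one generator seeded with `seed`; the
#' same seed yields a byte-identical locus and truth. The unit plan
#' (element sizes and gaps) is drawn and sized first: a spec whose
#' elements cannot fit in `length_bp` fails before any sequence is
#' emitted.
#'
#' @param spec A [synthetic_locus_spec()].
#' @param seed Integer RNG seed.
#' @return A `synthetic_locus` list: `locus` ([locus_sequence]),
#'   `segments`, `rss` (annotation data frames), `truth` (planted-site
#'   table: interval, strand, class, distance, mismatches, CpG flank,
#'   hot-spot id, planted core), `spec`, `seed`, and
#'   `unscrubbed_hits` (count of accidental matches the scrubber could
#'   not remove; 0 in clean-field mode).
#' @export
generate_locus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_locus_spec"))
  withr::with_seed(as.integer(seed), .generate_locus_impl(spec, seed))
}

.generate_locus_impl <- function(spec, seed) {
  L <- spec$motif$length
  chrom <- spec$locus_name
  geo <- SEGMENT_GEOMETRY
  rss_len <- 7L + 23L + 9L
  intergenic_buffer <- 8100L   # keeps intergenic sites out of upstream windows
  intergenic_lead <- 200L

  ## ---- plan units ----
  draw_gap <- function() sample(spec$gap_range[1]:spec$gap_range[2], 1L)
  n_scatter <- spec$n_intergenic_sites - spec$n_hotspots * spec$hotspot_sites

  units <- list()
  add <- function(u) units[[length(units) + 1L]] <<- u
  distal_units <- c(rep("distal", spec$n_distal_segments),
                    rep("scatter", n_scatter),
                    rep("hotspot", spec$n_hotspots))
  if (length(distal_units)) distal_units <- sample(distal_units)
  for (u in distal_units) add(u)
  for (i in seq_len(spec$n_proximal_segments)) add("proximal")

  site_rows <- list(); seg_rows <- list(); rss_rows <- list()
  cursor <- 0L
  seg_i <- 0L; site_i <- 0L; hs_i <- 0L
  writes <- list()   # deferred sequence writes: list(start0, seq)
  plant <- function(start0, strand, class, segment_id, distance, hotspot_id) {
    start0 <- as.integer(start0)
    site_i <<- site_i + 1L
    m <- .draw_mismatches(spec)
    core <- .mutate_motif(spec$motif$bases, m)
    cpg <- stats::runif(1) < spec$cpg_flank_fraction
    flank <- if (cpg) "G" else sample(c("A", "C", "T"), 1L)
    genomic <- if (strand == "+") paste0(core, flank) else
      reverse_complement(paste0(core, flank))
    gstart <- if (strand == "+") start0 else start0 - 1L
    writes[[length(writes) + 1L]] <<- list(start0 = gstart, seq = genomic)
    site_rows[[site_i]] <<- data.frame(
      site_id = sprintf("site%03d", site_i), chrom = chrom,
      start = start0, end = start0 + L, strand = strand,
      class = class, segment_id = segment_id,
      distance = distance, mismatches = m, cpg_flank = cpg,
      hotspot_id = hotspot_id, planted_seq = core,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  site_strand <- function() {
    if (stats::runif(1) < spec$minority_orientation_fraction) "-" else "+"
  }
  add_segment <- function(leader_start, kind) {
    leader_start <- as.integer(leader_start)
    seg_i <<- seg_i + 1L
    sid <- sprintf("V%03d", seg_i)
    fam <- if (kind == "proximal") sample(c("7183", "Q52"), 1L) else
      sample(c("J558", "3609", "SM7", "Vgam3.8"), 1L)
    coding_start <- leader_start + geo["leader"] + geo["intron"]
    coding_end <- coding_start + geo["coding"]
    seg_rows[[sid]] <<- data.frame(
      segment_id = sid, family = fam,
      functional = stats::runif(1) < 0.9, chrom = chrom,
      leader_start = leader_start, leader_end = leader_start + geo["leader"],
      coding_start = coding_start, coding_end = coding_end,
      strand = "+", stringsAsFactors = FALSE)
    hept_start <- coding_end
    non_start <- hept_start + 7L + 23L
    rss_rows[[sid]] <<- data.frame(
      segment_id = sid, chrom = chrom,
      heptamer_start = hept_start, heptamer_end = hept_start + 7L,
      spacer_len = 23L, nonamer_start = non_start,
      nonamer_end = non_start + 9L, strand = "+",
      stringsAsFactors = FALSE)
    writes[[length(writes) + 1L]] <<- list(start0 = hept_start, seq = RSS_HEPTAMER)
    writes[[length(writes) + 1L]] <<- list(start0 = non_start, seq = RSS_NONAMER)
    list(id = sid, nonamer_end = non_start + 9L)
  }

  seg_footprint <- sum(geo) + rss_len
  for (u in units) {
    cursor <- cursor + draw_gap()
    if (u == "distal") {
      d <- sample(spec$upstream_distance_choices, 1L)
      site_start <- cursor
      leader_start <- site_start + L + d
      seg <- add_segment(leader_start, "distal")
      plant(site_start, site_strand(), "UPSTREAM", seg$id, d, NA_character_)
      cursor <- leader_start + seg_footprint
    } else if (u == "proximal") {
      leader_start <- cursor
      seg <- add_segment(leader_start, "proximal")
      g <- sample(spec$rss_gap_choices, 1L)
      site_start <- seg$nonamer_end + g
      plant(site_start, site_strand(), "RSS_ASSOCIATED", seg$id, g, NA_character_)
      cursor <- site_start + L
    } else if (u == "scatter") {
      cursor <- cursor + intergenic_lead
      plant(cursor, site_strand(), "INTERGENIC", NA_character_, NA_integer_,
            NA_character_)
      cursor <- cursor + L + intergenic_buffer
    } else {  # hotspot
      hs_i <- hs_i + 1L
      hid <- sprintf("hotspot%02d", hs_i)
      spacing <- spec$hotspot_span %/% max(spec$hotspot_sites - 1L, 1L)
      cursor <- cursor + intergenic_lead
      for (k in seq_len(spec$hotspot_sites)) {
        plant(cursor + (k - 1L) * spacing, site_strand(), "INTERGENIC",
              NA_character_, NA_integer_, hid)
      }
      cursor <- cursor + (spec$hotspot_sites - 1L) * spacing + L +
        intergenic_buffer
    }
  }
  if (cursor + 1L > spec$length_bp) {
    stop("synthetic spec does not fit: needs ", cursor,
         " bp but length_bp is ", spec$length_bp)
  }

  ## ---- emit sequence ----
  chars <- sample(DNA_BASES, spec$length_bp, replace = TRUE,
                  prob = spec$base_composition)
  protected <- logical(spec$length_bp)
  for (w in writes) {
    s <- w$start0
    piece <- strsplit(w$seq, "")[[1]]
    idx <- (s + 1L):(s + length(piece))
    chars[idx] <- piece
    protected[idx] <- TRUE
  }
  truth <- do.call(rbind, site_rows)
  segments <- do.call(rbind, seg_rows); rownames(segments) <- NULL
  rss <- do.call(rbind, rss_rows); rownames(rss) <- NULL
  if (is.null(truth)) {
    truth <- data.frame(site_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), class = character(),
                        segment_id = character(), distance = integer(),
                        mismatches = integer(), cpg_flank = logical(),
                        hotspot_id = character(), planted_seq = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(segments)) segments <- empty_segments()
  if (is.null(rss)) rss <- empty_rss()
  rownames(truth) <- NULL

  locus <- locus_sequence(chrom, paste(chars, collapse = ""))
  unscrubbed <- 0L
  if (spec$scrub) {
    planted_key <- paste(truth$start, truth$strand)
    for (iter in 1:25) {
      hits <- scan_motif(locus, spec$motif,
                         max_mismatch = spec$scrub_max_mismatch)
      acc <- hits[!(paste(hits$start, hits$strand) %in% planted_key), ,
                  drop = FALSE]
      ## the two strand-readings of one planted interval are both genuine
      acc <- acc[!(acc$start %in% truth$start & acc$end %in% truth$end), ,
                 drop = FALSE]
      if (nrow(acc) == 0L) { unscrubbed <- 0L; break }
      pos <- unique(unlist(lapply(seq_len(nrow(acc)), function(i) {
        (acc$start[i] + 1L):(acc$end[i])
      })))
      pos <- pos[!protected[pos]]
      if (!length(pos)) {
        warning("scrubber: accidental hit(s) entirely inside protected ",
                "elements; leaving ", nrow(acc), " extra match(es)")
        unscrubbed <- nrow(acc)
        break
      }
      chars[pos] <- sample(DNA_BASES, length(pos), replace = TRUE,
                           prob = spec$base_composition)
      locus <- locus_sequence(chrom, paste(chars, collapse = ""))
      unscrubbed <- nrow(acc)
    }
    if (unscrubbed > 0L && iter == 25L) {
      warning("scrubber did not converge; ", unscrubbed,
              " accidental match(es) remain")
    }
  }

  structure(list(locus = locus, segments = segments, rss = rss,
                 truth = truth, spec = spec, seed = as.integer(seed),
                 unscrubbed_hits = unscrubbed),
            class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat("<synthetic_locus> ", x$locus$name, ": ", x$locus$length, " bp, ",
      nrow(x$segments), " segments, ", nrow(x$truth), " planted sites\n",
      sep = "")
  invisible(x)
}

#' Generate noisy ChIP-like peaks over planted sites
#'
#' Selects a fraction of the planted sites (hot-spot members are
#' selected as one unit, the way a single broad ChIP peak would cover
#' them) and places one peak over each selected unit, plus decoy peaks
#' in site-free regions. Peaks are clipped to stay at least 57 bp away
#' from non-member sites, so downstream `<100 bp` merging can never
#' bridge a peak across a foreign site: the number of occupied sites is
#' exactly `round(coverage_fraction * n_sites)` by construction.
#'
#' @param sim A `synthetic_locus` from [generate_locus()].
#' @param coverage_fraction Fraction of planted sites covered by a peak
#'   (default 0.77).
#' @param width_range Peak width range in bp, drawn uniformly (default
#'   c(10, 2282), mean 1146).
#' @param jitter_max Maximum absolute displacement of the peak centre
#'   from the site centre (bp).
#' @param n_decoys Number of site-free decoy peaks.
#' @param source Label for the peak `source` column.
#' @param seed RNG seed.
#' @return List with `peaks` (peak data frame) and `covered_site_ids`
#'   (the planted sites guaranteed to overlap a peak).
#' @export
generate_peaks <- function(sim, coverage_fraction = 0.77,
                           width_range = c(10L, 2282L), jitter_max = 200L,
                           n_decoys = 20L, source = "chipchip", seed = 1L) {
  stopifnot(inherits(sim, "synthetic_locus"),
            coverage_fraction >= 0, coverage_fraction <= 1)
  withr::with_seed(as.integer(seed), {
    truth <- sim$truth
    n_sites <- nrow(truth)
    if (n_sites == 0L) stop("no planted sites to cover")
    target <- round(coverage_fraction * n_sites)
    unit_of <- ifelse(is.na(truth$hotspot_id),
                      paste0("single:", truth$site_id), truth$hotspot_id)
    unit_ids <- sample(unique(unit_of))
    selected <- character(0); remaining <- target
    for (u in unit_ids) {
      size <- sum(unit_of == u)
      if (size <= remaining) {
        selected <- c(selected, u)
        remaining <- remaining - size
      }
      if (remaining == 0L) break
    }
    if (remaining > 0L) {
      stop("could not hit coverage target exactly (unit sizes too coarse)")
    }
    margin <- 57L   # > (100 - site width)/2 + site half-width: no bridge
    len <- sim$locus$length
    rows <- list()
    for (u in selected) {
      members <- which(unit_of == u)
      span_lo <- min(truth$start[members]); span_hi <- max(truth$end[members])
      w <- sample(width_range[1]:width_range[2], 1L)
      jitter <- sample((-jitter_max):jitter_max, 1L)
      center <- (span_lo + span_hi) / 2 + jitter
      lo <- floor(min(center - w / 2, span_lo))
      hi <- ceiling(max(center + w / 2, span_hi))
      others_end <- truth$end[-members]; others_start <- truth$start[-members]
      left <- others_end[others_end <= span_lo]
      right <- others_start[others_start >= span_hi]
      lo <- max(lo, 0L, if (length(left)) max(left) + margin else 0L)
      hi <- min(hi, len, if (length(right)) min(right) - margin else len)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sim$locus$name, start = as.integer(lo), end = as.integer(hi),
        score = round(stats::runif(1, 1, 100), 1), source = source,
        stringsAsFactors = FALSE)
    }
    ## decoys in site-free space, margin away from every site
    attempts <- 0L; placed <- 0L
    while (placed < n_decoys && attempts < n_decoys * 200L) {
      attempts <- attempts + 1L
      w <- sample(width_range[1]:width_range[2], 1L)
      if (w + 1L >= len) next
      s <- sample.int(len - w, 1L) - 1L
      e <- s + w
      clash <- any(truth$start - margin < e & truth$end + margin > s)
      if (clash) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sim$locus$name, start = s, end = e,
        score = round(stats::runif(1, 1, 100), 1), source = source,
        stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
    peaks <- do.call(rbind, rows)
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
    covered <- truth$site_id[unit_of %in% selected]
    list(peaks = peaks, covered_site_ids = covered)
  })
}

#' Write a self-contained synthetic fixture directory
#'
#' Emits `locus.fasta`, `annotations.bed`, `truth.tsv` and
#' `spec.json` so every downstream stage can run from files alone.
#'
#' @param sim A `synthetic_locus`.
#' @param dir Output directory (created if needed).
#' @param peaks Optional peak data frame to write as `peaks.bed`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixture <- function(sim, dir, peaks = NULL) {
  stopifnot(inherits(sim, "synthetic_locus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_locus_fasta(sim$locus, file.path(dir, "locus.fasta"))
  write_annotations(list(segments = sim$segments, rss = sim$rss,
                         peaks = empty_peaks()),
                    file.path(dir, "annotations.bed"), dialect = "bed")
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- sim$spec
  sp$motif <- sp$motif$bases
  jsonlite::write_json(sp[setdiff(names(sp), "")],
                       file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(peaks)) {
    write_bed(peaks, file.path(dir, "peaks.bed"), score_col = "score")
  }
  invisible(dir)
}
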