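## Independent brute-force oracles and tiny fixture builders used
## across the suite. The oracles deliberately share no code with the
## package implementations they check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

## Per-window enumeration scanner: every window, both strands, counted
## with a character-by-character loop.
oracle_scan <- function(bases, motif, k) {
  L <- nchar(motif); n <- nchar(bases)
  mot <- strsplit(motif, "")[[1]]
  rc <- strsplit(revcomp_chr(motif), "")[[1]]
  rows <- list()
  for (s in seq_len(n - L + 1L)) {
    win <- strsplit(substring(bases, s, s + L - 1L), "")[[1]]
    if (any(win == "N")) next
    for (strand in c("+", "-")) {
      ref <- if (strand == "+") mot else rc
      mm <- sum(win != ref)
      if (mm <= k) {
        ms <- paste(win, collapse = "")
        if (strand == "-") ms <- revcomp_chr(ms)
        rows[[length(rows) + 1L]] <- data.frame(
          start = s - 1L, end = s - 1L + L, strand = strand,
          mismatches = mm, matched_seq = ms, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Transitive-closure interval merging: repeat pairwise joins until
## stable; gap strictly below `gap` (negative = overlap) joins.
oracle_merge <- function(starts, ends, gap) {
  repeat {
    n <- length(starts)
    joined <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        g <- max(starts[i], starts[j]) - min(ends[i], ends[j])
        if (g < gap) {
          starts[i] <- min(starts[i], starts[j])
          ends[i] <- max(ends[i], ends[j])
          starts <- starts[-j]; ends <- ends[-j]
          joined <- TRUE
          break
        }
      }
      if (joined) break
    }
    if (!joined) break
  }
  ord <- order(starts)
  list(start = starts[ord], end = ends[ord])
}

## All-pairs quadratic interval overlap.
oracle_overlaps <- function(a, b, min_overlap = 1L) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      w <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (w >= min_overlap) {
        rows[[length(rows) + 1L]] <- data.frame(query = i, subject = j,
                                                overlap_bp = w)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  }
  do.call(rbind, rows)
}

## Transitive-closure clustering of points by start-to-start gap.
oracle_cluster <- function(starts, max_gap) {
  n <- length(starts)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(starts[i] - starts[j]) <= max_gap &&
            labels[i] != labels[j]) {
          labels[labels == labels[j]] <- labels[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  labels
}

## A hand-built miniature locus: one plus-strand segment with leader,
## coding exon and 23-spacer RSS, and a motif planted `gap` bp after
## the nonamer. Coordinates chosen so everything is easy to read.
tiny_locus <- function(gap = 18L, motif = "GACCAGCAGGGGGC",
                       flank_after = "A", seed = 99L) {
  withr::with_seed(seed, {
    leader_start <- 100L
    coding_start <- leader_start + 50L + 80L
    coding_end <- coding_start + 300L
    hept_start <- coding_end
    non_start <- hept_start + 7L + 23L
    non_end <- non_start + 9L
    site_start <- non_end + gap
    total <- site_start + 14L + 1000L
    chars <- strsplit(random_dna(total), "")[[1]]
    put <- function(s, str) {
      p <- strsplit(str, "")[[1]]
      chars[(s + 1L):(s + length(p))] <<- p
    }
    put(hept_start, "CACAGTG")
    put(non_start, "ACAAAAACC")
    put(site_start, paste0(motif, flank_after))
    segments <- data.frame(
      segment_id = "s1", family = "7183", functional = TRUE, chrom = "chrT",
      leader_start = leader_start, leader_end = leader_start + 50L,
      coding_start = coding_start, coding_end = coding_end,
      strand = "+", stringsAsFactors = FALSE)
    rss <- data.frame(
      segment_id = "s1", chrom = "chrT",
      heptamer_start = hept_start, heptamer_end = hept_start + 7L,
      spacer_len = 23L, nonamer_start = non_start, nonamer_end = non_end,
      strand = "+", stringsAsFactors = FALSE)
    list(locus = locus_sequence("chrT", paste(chars, collapse = "")),
         segments = segments, rss = rss,
         site_start = site_start, nonamer_end = non_end)
  })
}

small_sim_spec <- function(...) {
  synthetic_locus_spec(length_bp = 150000, n_proximal_segments = 8L,
                       n_distal_segments = 5L, n_intergenic_sites = 4L,
                       n_hotspots = 1L, hotspot_sites = 3L, ...)
}
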