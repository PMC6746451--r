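## ChIP peak merging, peak geometry, and predicted-vs-observed overlap
## tables.

#' Merge narrowly spaced peaks
#'
#' Consecutive peaks separated by strictly less than `merge_below_gap`
#' bp (gap = next start - previous end; overlapping peaks have a
#' negative gap and always merge) are combined into one spanning peak.
#' The operation is idempotent and equals transitive-closure merging.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, optionally
#'   `score`, `source`).
#' @param merge_below_gap Gap threshold in bp; a gap of exactly this
#'   size is NOT merged (default 100).
#' @return Merged, sorted peak data frame with `n_merged` recording how
#'   many input peaks each output peak spans.
#' @export
merge_peaks <- function(peaks, merge_below_gap = 100L) {
  stopifnot(merge_below_gap >= 0L)
  if (nrow(peaks) == 0L) return(cbind(peaks, n_merged = integer(0)))
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[ord, , drop = FALSE]
  has_score <- "score" %in% names(p)
  same_chrom <- p$chrom[-1] == p$chrom[-nrow(p)]
  out <- list()
  cur <- p[1, , drop = FALSE]; cur_n <- 1L
  cur_score <- if (has_score) p$score[1] else NA_real_
  for (i in seq_len(nrow(p))[-1]) {
    gap <- p$start[i] - cur$end
    if (same_chrom[i - 1L] && gap < merge_below_gap) {
      cur$end <- max(cur$end, p$end[i])
      cur_n <- cur_n + 1L
      if (has_score) {
        cur_score <- suppressWarnings(max(cur_score, p$score[i], na.rm = TRUE))
        if (!is.finite(cur_score)) cur_score <- NA_real_
      }
    } else {
      cur$n_merged <- cur_n
      if (has_score) cur$score <- cur_score
      out[[length(out) + 1L]] <- cur
      cur <- p[i, , drop = FALSE]; cur_n <- 1L
      cur_score <- if (has_score) p$score[i] else NA_real_
    }
  }
  cur$n_merged <- cur_n
  if (has_score) cur$score <- cur_score
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peak width statistics
#'
#' @param peaks Nonempty peak data frame.
#' @return A `peak_stats` list: `n_peaks`, `min_width`, `max_width`,
#'   `mean_width` (bp, half-open widths).
#' @export
peak_stats <- function(peaks) {
  if (nrow(peaks) == 0L) stop("no peaks")
  w <- peaks$end - peaks$start
  structure(list(n_peaks = nrow(peaks), min_width = min(w),
                 max_width = max(w), mean_width = mean(w)),
            class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("<peak_stats> %d peaks, widths %d-%d bp, mean %.0f bp\n",
              x$n_peaks, x$min_width, x$max_width, x$mean_width))
  invisible(x)
}

#' Pairs of overlapping intervals
#'
#' @param a,b Interval data frames (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param min_overlap Minimum intersection length in bp (default 1).
#' @return Data frame of overlapping pairs: `query` (row in `a`),
#'   `subject` (row in `b`), `overlap_bp`.
#' @export
interval_overlaps <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  }
  gra <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
  grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
  ov <- GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap,
                                    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  width <- pmin(a$end[q], b$end[s]) - pmax(a$start[q], b$start[s])
  data.frame(query = q, subject = s, overlap_bp = width)
}

#' Predicted-site versus peak overlap (Venn) summary
#'
#' A predicted site is "occupied" iff it overlaps at least one peak of
#' a set; a peak "contains a site" iff it overlaps at least one
#' predicted site. Counts are reported from both perspectives, since
#' one symmetric region count cannot express both a fraction of sites
#' occupied and a fraction of peaks containing a site.
#'
#' @param predicted Site data frame (`chrom`, `start`, `end`).
#' @param peaks_a Peak data frame (e.g. ChIP-chip).
#' @param peaks_b Optional second peak set (e.g. ChIP-seq) for a 3-way
#'   summary.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param require_containment Require the site to lie fully inside the
#'   peak rather than any overlap (default FALSE).
#' @param labels Length-2/3 labels for the sets.
#' @return An `overlap_summary` list: `sites` (per-region counts and
#'   fractions from the site perspective) and one `peaks_<label>` table
#'   per peak set, plus `peaks_a_vs_b` when both sets are given.
#' @export
venn_overlap <- function(predicted, peaks_a, peaks_b = NULL,
                         min_overlap = 1L, require_containment = FALSE,
                         labels = c("predicted", "peaks_a", "peaks_b")) {
  if (nrow(predicted) == 0L) stop("empty predicted site set")
  hit_any <- function(sites, peaks) {
    if (nrow(peaks) == 0L) return(rep(FALSE, nrow(sites)))
    ov <- interval_overlaps(sites, peaks, min_overlap = min_overlap)
    if (require_containment) {
      full <- ov$overlap_bp >= (sites$end[ov$query] - sites$start[ov$query])
      ov <- ov[full, , drop = FALSE]
    }
    seq_len(nrow(sites)) %in% ov$query
  }
  in_a <- hit_any(predicted, peaks_a)
  res <- list(labels = labels,
              n_sites = nrow(predicted),
              sites = NULL)
  peak_table <- function(peaks, label) {
    with_site <- hit_any(peaks, predicted)
    list(label = label, n_peaks = nrow(peaks),
         with_site = sum(with_site),
         with_site_fraction = if (nrow(peaks)) mean(with_site) else NA_real_)
  }
  if (is.null(peaks_b)) {
    res$sites <- list(occupied = sum(in_a),
                      unoccupied = sum(!in_a),
                      occupied_fraction = mean(in_a))
    res$peaks_a <- peak_table(peaks_a, labels[2])
  } else {
    in_b <- hit_any(predicted, peaks_b)
    res$sites <- list(occupied_a = sum(in_a),
                      occupied_b = sum(in_b),
                      occupied_both = sum(in_a & in_b),
                      occupied_a_only = sum(in_a & !in_b),
                      occupied_b_only = sum(!in_a & in_b),
                      unoccupied = sum(!in_a & !in_b),
                      occupied_a_fraction = mean(in_a),
                      occupied_b_fraction = mean(in_b))
    res$peaks_a <- peak_table(peaks_a, labels[2])
    res$peaks_b <- peak_table(peaks_b, labels[3])
    ov_ab <- interval_overlaps(peaks_a, peaks_b, min_overlap = min_overlap)
    res$peaks_a_vs_b <- list(
      a_overlapping_b = length(unique(ov_ab$query)),
      b_overlapping_a = length(unique(ov_ab$subject)),
      a_overlapping_b_fraction =
        if (nrow(peaks_a)) length(unique(ov_ab$query)) / nrow(peaks_a)
        else NA_real_)
  }
  res$site_flags <- if (is.null(peaks_b)) data.frame(occupied = in_a) else
    data.frame(occupied_a = in_a, occupied_b = in_b)
  structure(res, class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary> ", x$n_sites, " predicted sites\n", sep = "")
  utils::str(x$sites, no.list = TRUE)
  invisible(x)
}
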