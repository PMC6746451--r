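## End-to-end analysis: search -> classify (+ rescue) -> orientation /
## CpG / hot spots -> peak merging and overlap -> PWM overlap, with a
## machine-readable JSON report and file outputs.

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (FASTA / BED / GFF3 / JASPAR) or in-memory
#' objects of the corresponding classes. Defaults follow the standard
#' study parameters: two mismatches, 17-19 bp canonical RSS gap within
#' a 60 bp association window, 8 kb upstream window, 500 bp hot-spot
#' gap, peaks merged below 100 bp, PWM threshold p <= 1e-4.
#'
#' @param locus FASTA path or [locus_sequence].
#' @param annotations Annotation path or list with `segments`, `rss`
#'   (and optionally `peaks`) data frames.
#' @param annotations_dialect `"bed"` or `"gff3"` when `annotations` is
#'   a path.
#' @param motif Search motif (string or [consensus_motif]).
#' @param refine Iteratively refine the consensus (default TRUE).
#' @param max_mismatch,max_rounds Scan allowance and refinement cap.
#' @param classify Classification parameter overrides, see
#'   [classify_params()].
#' @param rescue_max_mismatch,rescue_gap_window Relaxed re-scan of RSSs
#'   left without a site.
#' @param hotspot_max_gap,hotspot_min_sites Hot-spot chaining.
#' @param merge_gap Peak merge threshold (bp; strict `<`).
#' @param peaks,peaks_b Peak BED paths or data frames (optional).
#' @param pwm JASPAR PFM path, `pfm` or `pwm` object (optional).
#' @param p_threshold PWM scan p-value threshold.
#' @param pwm_background,pwm_pseudocount PWM construction parameters
#'   used when `pwm` is a count matrix.
#' @param out_dir Output directory (optional; no files written when
#'   NULL).
#' @param quiet Suppress progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(locus, annotations,
                            annotations_dialect = "bed",
                            motif = "GACCAGCAGGGGGC",
                            refine = TRUE, max_mismatch = 2L,
                            max_rounds = 10L,
                            classify = list(),
                            rescue_max_mismatch = 4L,
                            rescue_gap_window = c(0L, 60L),
                            hotspot_max_gap = 500L,
                            hotspot_min_sites = 3L,
                            merge_gap = 100L,
                            peaks = NULL, peaks_b = NULL,
                            pwm = NULL, p_threshold = 1e-4,
                            pwm_background = rep(0.25, 4),
                            pwm_pseudocount = 0.1,
                            out_dir = NULL, quiet = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

.resolve_locus <- function(x, quiet) {
  if (inherits(x, "locus_sequence")) return(x)
  loci <- read_locus_fasta(x)
  if (length(loci) > 1L && !quiet) {
    message("multi-record FASTA: analysing first sequence '",
            loci[[1]]$name, "' (the pipeline operates per-sequence)")
  }
  loci[[1]]
}

.resolve_annotations <- function(x, dialect) {
  if (is.list(x) && !is.null(x$segments)) {
    if (is.null(x$rss)) x$rss <- empty_rss()
    if (is.null(x$peaks)) x$peaks <- empty_peaks()
    return(x)
  }
  read_annotations(x, dialect = dialect)
}

.resolve_peaks <- function(x, source) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  read_peaks_bed(x, source = source)
}

.resolve_pwm <- function(x, background, pseudocount) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "pwm")) return(x)
  if (inherits(x, "pfm")) return(pwm_from_pfm(x, background, pseudocount))
  pwm_from_pfm(read_jaspar(x), background, pseudocount)
}

#' Run the full analysis pipeline
#'
#' Executes consensus search (iterative refinement or single scan),
#' site classification with a relaxed rescue scan over RSSs left bare,
#' orientation/CpG/hot-spot summaries, peak merging plus overlap
#' tables when peaks are supplied, and a PWM overlap when a PWM is
#' supplied. Missing optional inputs skip their stage with a logged
#' notice. Identical inputs produce an identical report.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with every computed count and
#'   table; when `config$out_dir` is set, TSV/BED/JSON outputs and a
#'   human-readable summary are written there as well.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!config$quiet) message(...)
  notices <- character(0)
  note <- function(msg) {
    notices <<- c(notices, msg)
    say("note: ", msg)
  }

  locus <- .resolve_locus(config$locus, config$quiet)
  ann <- .resolve_annotations(config$annotations, config$annotations_dialect)
  params <- utils::modifyList(classify_params(), config$classify)

  ## -- search --
  say("scanning ", locus$name, " (", locus$length, " bp) with motif ",
      as_consensus_motif(config$motif)$bases, ", max ", config$max_mismatch,
      " mismatches")
  if (config$refine) {
    trace <- refine_search(locus, config$motif,
                           max_mismatch = config$max_mismatch,
                           max_rounds = config$max_rounds)
    hits <- trace$rounds[[length(trace$rounds)]]$hits
    rounds <- data.frame(
      round = seq_along(trace$rounds),
      consensus = vapply(trace$rounds, function(r) r$consensus$bases, ""),
      n_hits = vapply(trace$rounds, function(r) r$n_hits, 0L))
  } else {
    hits <- scan_motif(locus, config$motif, max_mismatch = config$max_mismatch)
    trace <- NULL
    rounds <- data.frame(round = 1L,
                         consensus = as_consensus_motif(config$motif)$bases,
                         n_hits = nrow(hits))
  }

  ## -- classification + rescue --
  classified <- classify_sites(hits, ann$segments, ann$rss, params)
  bare <- ann$rss[!(ann$rss$segment_id %in%
                      classified$segment_id[classified$site_class ==
                                              "RSS_ASSOCIATED"]), ,
                  drop = FALSE]
  rescued <- rescue_scan(locus, bare, config$motif,
                         max_mismatch = config$rescue_max_mismatch,
                         gap_window = config$rescue_gap_window)
  if (nrow(rescued)) {
    note(paste0(nrow(rescued), " relaxed-mismatch site(s) rescued near ",
                "otherwise bare RSSs"))
  }

  orient <- if (nrow(classified)) orientation_summary(classified) else NULL
  if (!is.null(orient) && orient$tie) {
    note("orientation counts tied; preferred set to transcription-concordant")
  }
  cpg <- if (nrow(classified)) cpg_profile(classified, locus) else NULL
  hotspots <- find_hotspots(classified, max_gap = config$hotspot_max_gap,
                            min_sites = config$hotspot_min_sites)
  pfms <- if (nrow(classified)) class_pfms(classified) else list()

  ## -- peaks --
  peaks_a <- .resolve_peaks(config$peaks, "chipchip")
  peaks_b <- .resolve_peaks(config$peaks_b, "chipseq")
  venn <- NULL; merged_a <- NULL; merged_b <- NULL; stats_a <- NULL
  if (is.null(peaks_a)) {
    note("no peaks supplied; skipping peak overlap stage")
  } else {
    merged_a <- merge_peaks(peaks_a, merge_below_gap = config$merge_gap)
    stats_a <- peak_stats(merged_a)
    if (!is.null(peaks_b)) {
      merged_b <- merge_peaks(peaks_b, merge_below_gap = config$merge_gap)
      venn <- venn_overlap(classified, merged_a, merged_b,
                           labels = c("predicted", "chipchip", "chipseq"))
    } else {
      venn <- venn_overlap(classified, merged_a,
                           labels = c("predicted", "chipchip"))
    }
  }

  ## -- PWM --
  pwm_obj <- .resolve_pwm(config$pwm, config$pwm_background,
                          config$pwm_pseudocount)
  pwm_hits <- NULL; pwm_overlap <- NULL
  if (is.null(pwm_obj)) {
    note("no PWM supplied; skipping PWM overlap stage")
  } else {
    pwm_hits <- pwm_scan(locus, pwm_obj, p_threshold = config$p_threshold)
    sites_with_pwm <- if (nrow(classified))
      length(unique(interval_overlaps(classified, pwm_hits)$query)) else 0L
    pwm_overlap <- list(
      n_pwm_hits = nrow(pwm_hits),
      sites_with_pwm_motif = sites_with_pwm,
      sites_with_pwm_fraction = if (nrow(classified))
        sites_with_pwm / nrow(classified) else NA_real_)
    if (!is.null(merged_a)) {
      pk <- length(unique(interval_overlaps(merged_a, pwm_hits)$query))
      pwm_overlap$peaks_with_pwm_motif <- pk
      pwm_overlap$peaks_with_pwm_fraction <- pk / nrow(merged_a)
    }
  }

  class_counts <- table(factor(classified$site_class, levels = SITE_CLASSES))
  report <- list(
    locus = list(name = locus$name, length_bp = locus$length),
    parameters = list(
      motif = as_consensus_motif(config$motif)$bases,
      max_mismatch = config$max_mismatch, refine = config$refine,
      rss_max_gap = params$rss_max_gap,
      canonical_set = params$canonical_set,
      upstream_max = params$upstream_max,
      hotspot_max_gap = config$hotspot_max_gap,
      merge_gap = config$merge_gap,
      p_threshold = config$p_threshold,
      rss_distance_convention = "bases strictly between nonamer 3' end and motif edge, transcription-oriented"),
    search = list(rounds = rounds,
                  converged = if (!is.null(trace)) trace$converged else NA,
                  final_consensus = rounds$consensus[nrow(rounds)],
                  n_sites = nrow(classified),
                  site_density_per_mb = site_density(nrow(classified),
                                                     locus$length)),
    classes = list(
      n_rss_associated = as.integer(class_counts[["RSS_ASSOCIATED"]]),
      n_upstream = as.integer(class_counts[["UPSTREAM"]]),
      n_intergenic = as.integer(class_counts[["INTERGENIC"]]),
      n_canonical = sum(classified$canonical, na.rm = TRUE),
      upstream_bins = as.list(table(classified$upstream_bin))),
    rescue = list(n_bare_rss = nrow(bare), n_rescued = nrow(rescued),
                  rescued = rescued),
    orientation = if (!is.null(orient)) unclass(orient) else NULL,
    cpg = if (!is.null(cpg)) cpg$summary else NULL,
    hotspots = list(n_hotspots = nrow(hotspots),
                    table = hotspots[, setdiff(names(hotspots), "members")]),
    peaks = if (!is.null(stats_a)) list(
      n_input_peaks = nrow(peaks_a), n_merged_peaks = stats_a$n_peaks,
      min_width = stats_a$min_width, max_width = stats_a$max_width,
      mean_width = stats_a$mean_width) else NULL,
    venn = if (!is.null(venn)) unclass(venn)[c("n_sites", "sites", "peaks_a",
                                               "peaks_b", "peaks_a_vs_b")]
           else NULL,
    pwm = pwm_overlap,
    notices = notices)

  result <- structure(list(report = report, sites = classified,
                           hits = hits, trace = trace, hotspots = hotspots,
                           cpg = cpg, class_pfms = pfms,
                           merged_peaks = merged_a,
                           merged_peaks_b = merged_b,
                           venn = venn, pwm_hits = pwm_hits),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    .write_pipeline_outputs(result, config)
  }
  result
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  sites <- result$sites
  utils::write.table(sites, out("sites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(sites)) {
    write_bed(sites, out("sites.bed"), name_col = "site_class",
              score_col = "mismatches")
  }
  if (nrow(result$hotspots)) {
    hs <- result$hotspots
    hs$name <- sprintf("hotspot_%d_sites", hs$n_sites)
    write_bed(hs, out("hotspots.bed"), name_col = "name")
  }
  if (!is.null(result$merged_peaks)) {
    write_bed(result$merged_peaks, out("merged_peaks.bed"),
              score_col = "score")
  }
  if (!is.null(result$pwm_hits) && nrow(result$pwm_hits)) {
    hits <- result$pwm_hits
    hits$neglog10p <- round(-10 * log10(hits$pvalue), 2)
    write_bed(hits, out("pwm_hits.bed"), score_col = "neglog10p")
  }
  cfg <- config
  cfg$locus <- if (is.character(cfg$locus)) cfg$locus else cfg$locus$name
  cfg$annotations <- if (is.character(cfg$annotations)) cfg$annotations
                     else "<in-memory>"
  for (f in c("peaks", "peaks_b", "pwm")) {
    if (!is.null(cfg[[f]]) && !is.character(cfg[[f]])) cfg[[f]] <- "<in-memory>"
  }
  if (inherits(cfg$motif, "consensus_motif")) cfg$motif <- cfg$motif$bases
  jsonlite::write_json(unclass(cfg), out("config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  jsonlite::write_json(result$report, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE,
                       dataframe = "rows")
  writeLines(utils::capture.output(print(result)), out("report.txt"))
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("== CTCF site analysis:", r$locus$name,
      sprintf("(%d bp) ==\n", r$locus$length))
  cat("search motif:", r$parameters$motif,
      sprintf("(max %d mismatches%s)\n", r$parameters$max_mismatch,
              if (isTRUE(r$search$converged)) ", refinement converged" else ""))
  for (i in seq_len(nrow(r$search$rounds))) {
    cat(sprintf("  round %d: %s -> %d hits\n", r$search$rounds$round[i],
                r$search$rounds$consensus[i], r$search$rounds$n_hits[i]))
  }
  cat(sprintf("sites: %d total (%.2f per Mb)\n", r$search$n_sites,
              r$search$site_density_per_mb))
  cat(sprintf("  RSS-associated %d (canonical %d), upstream %d, intergenic %d\n",
              r$classes$n_rss_associated, r$classes$n_canonical,
              r$classes$n_upstream, r$classes$n_intergenic))
  if (!is.null(r$orientation)) {
    cat(sprintf("orientation: %d/%d (%.1f%%) %s transcription\n",
                r$orientation$n_preferred, r$orientation$n_total,
                100 * r$orientation$preferred_fraction,
                r$orientation$preferred))
  }
  if (!is.null(r$cpg)) {
    ov <- r$cpg[r$cpg$site_class == "overall", , drop = FALSE]
    for (i in seq_len(nrow(ov))) {
      cat(sprintf("CpG %s: %d/%d (%.1f%%)\n", ov$pair[i], ov$n_cpg[i],
                  ov$n_eval[i], 100 * ov$fraction[i]))
    }
  }
  cat(sprintf("hot spots (gap <= %d bp): %d\n", r$parameters$hotspot_max_gap,
              r$hotspots$n_hotspots))
  if (r$rescue$n_rescued > 0 || r$rescue$n_bare_rss > 0) {
    cat(sprintf("rescue: %d bare RSS(s), %d relaxed site(s) recovered\n",
                r$rescue$n_bare_rss, r$rescue$n_rescued))
  }
  if (!is.null(r$peaks)) {
    cat(sprintf("peaks: %d merged (from %d), widths %d-%d bp, mean %.0f bp\n",
                r$peaks$n_merged_peaks, r$peaks$n_input_peaks,
                r$peaks$min_width, r$peaks$max_width, r$peaks$mean_width))
    s <- r$venn$sites
    if (!is.null(s$occupied)) {
      cat(sprintf("  occupied sites: %d/%d (%.1f%%); peaks with site: %d/%d (%.1f%%)\n",
                  s$occupied, r$venn$n_sites, 100 * s$occupied_fraction,
                  r$venn$peaks_a$with_site, r$venn$peaks_a$n_peaks,
                  100 * r$venn$peaks_a$with_site_fraction))
    } else {
      cat(sprintf("  occupied sites: A %d, B %d, both %d, neither %d (of %d)\n",
                  s$occupied_a, s$occupied_b, s$occupied_both, s$unoccupied,
                  r$venn$n_sites))
    }
  }
  if (!is.null(r$pwm)) {
    cat(sprintf("PWM: %d hits; sites with PWM motif %d (%.1f%%)\n",
                r$pwm$n_pwm_hits, r$pwm$sites_with_pwm_motif,
                100 * r$pwm$sites_with_pwm_fraction))
  }
  for (n in r$notices) cat("note:", n, "\n")
  invisible(x)
}
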