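## Core genomic data types and readers/writers.
##
## All coordinates in this package are 0-based half-open [start, end);
## 1-based conventions appear only at the GFF3 boundary and in printed
## reports. BED is the canonical interchange format for peaks and sites.

DNA_BASES <- c("A", "C", "G", "T")
ANNOTATION_ROLES <- c("leader", "coding", "heptamer", "nonamer", "peak")

#' Construct a locus sequence
#'
#' A `locus_sequence` is the substrate every scan operates on: a named
#' DNA string over the alphabet A, C, G, T, N.
#'
#' @param name Sequence identifier (e.g. a chromosome or contig name).
#' @param bases Character scalar of bases; lower case is folded to upper.
#' @return An object of class `locus_sequence` with elements `name`,
#'   `bases` and `length`.
#' @export
locus_sequence <- function(name, bases) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  bad <- gsub("[ACGTN]", "", bases)
  if (nzchar(bad)) {
    stop("illegal character(s) in sequence '", name, "': ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(list(name = name, bases = bases, length = nchar(bases)),
            class = "locus_sequence")
}

#' @export
print.locus_sequence <- function(x, ...) {
  cat("<locus_sequence> ", x$name, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

as_locus_sequence <- function(x, name = "seq") {
  if (inherits(x, "locus_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) return(locus_sequence(name, x))
  stop("cannot interpret object of class ", class(x)[1], " as a locus sequence")
}

#' Read loci from a FASTA file
#'
#' Sequences are upper-cased and validated against the A/C/G/T/N
#' alphabet; any other IUPAC code (including U) is rejected with the
#' offending line number.
#'
#' @param path Path to a single- or multi-record FASTA file.
#' @return A named list of [locus_sequence] objects (one per record).
#' @export
read_locus_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in ", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    bases <- toupper(as.character(set[[i]]))
    if (grepl("[^ACGTN]", bases)) {
      lines <- toupper(readLines(path))
      offending <- which(!startsWith(lines, ">") & grepl("[^ACGTN \t]", lines))
      stop("illegal sequence character in ", path,
           if (length(offending)) paste0(" at line ", offending[1]) else "",
           " (only A/C/G/T/N accepted)")
    }
    nm <- sub("\\s.*$", "", names(set)[i])
    if (!nzchar(nm)) stop("malformed FASTA header (empty name) in ", path)
    out[[i]] <- locus_sequence(nm, bases)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write loci to a FASTA file
#'
#' @param loci A [locus_sequence] or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(loci, path, width = 70L) {
  if (inherits(loci, "locus_sequence")) loci <- list(loci)
  set <- Biostrings::DNAStringSet(vapply(loci, `[[`, "", "bases"))
  names(set) <- vapply(loci, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; an involution over the
#' A/C/G/T/N alphabet.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) stop("illegal character in sequence: ", seq[bad][1])
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

## ---- interval validation -------------------------------------------------

check_interval <- function(start, end, what = "interval") {
  if (any(start < 0L)) stop(what, ": start must be >= 0")
  if (any(end <= start)) stop(what, ": need start < end (0-based half-open)")
  invisible(TRUE)
}

empty_segments <- function() {
  data.frame(segment_id = character(), family = character(),
             functional = logical(), chrom = character(),
             leader_start = integer(), leader_end = integer(),
             coding_start = integer(), coding_end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

empty_rss <- function() {
  data.frame(segment_id = character(), chrom = character(),
             heptamer_start = integer(), heptamer_end = integer(),
             spacer_len = integer(),
             nonamer_start = integer(), nonamer_end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             score = numeric(), source = character(), stringsAsFactors = FALSE)
}

validate_segments <- function(seg) {
  if (nrow(seg) == 0L) return(seg)
  check_interval(seg$leader_start, seg$leader_end, "leader exon")
  check_interval(seg$coding_start, seg$coding_end, "coding exon")
  if (!all(seg$strand %in% c("+", "-"))) {
    stop("gene segment orientation must be '+' or '-'")
  }
  overlap <- pmax(seg$leader_start, seg$coding_start) <
    pmin(seg$leader_end, seg$coding_end)
  if (any(overlap)) {
    stop("leader and coding exon overlap for segment(s): ",
         paste(seg$segment_id[overlap], collapse = ", "))
  }
  seg
}

validate_rss <- function(rss) {
  if (nrow(rss) == 0L) return(rss)
  check_interval(rss$heptamer_start, rss$heptamer_end, "heptamer")
  check_interval(rss$nonamer_start, rss$nonamer_end, "nonamer")
  if (!all(rss$heptamer_end - rss$heptamer_start == 7L)) {
    stop("RSS heptamer must be exactly 7 bp")
  }
  if (!all(rss$nonamer_end - rss$nonamer_start == 9L)) {
    stop("RSS nonamer must be exactly 9 bp")
  }
  gap <- ifelse(rss$strand == "+",
                rss$nonamer_start - rss$heptamer_end,
                rss$heptamer_start - rss$nonamer_end)
  rss$spacer_len <- as.integer(gap)
  if (!all(rss$spacer_len %in% c(12L, 23L))) {
    stop("RSS spacer must be 12 or 23 bp, got: ",
         paste(unique(rss$spacer_len[!rss$spacer_len %in% c(12L, 23L)]),
               collapse = ", "))
  }
  rss
}

## ---- BED / GFF3 annotation I/O ------------------------------------------

granges_to_bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name) else ".",
             score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read gene-segment, RSS and peak annotations
#'
#' Accepts BED6 (the record name carries the element role as
#' `segmentId|role`, role one of leader, coding, heptamer, nonamer,
#' peak) or GFF3 (the type column names the role; the `ID` attribute
#' carries the segment id). GFF3 1-based coordinates are converted to
#' the internal 0-based half-open convention on input.
#'
#' @param path Annotation file.
#' @param dialect `"bed"` or `"gff3"`.
#' @return A list with data frames `segments`, `rss` and `peaks`.
#' @export
read_annotations <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    df <- granges_to_bed_df(gr)
    parts <- strsplit(df$name, "|", fixed = TRUE)
    df$segment_id <- vapply(parts, function(p) p[[1]], "")
    df$role <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, "")
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     role = as.character(gr$type),
                     segment_id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
                     score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
                     stringsAsFactors = FALSE)
  }
  bad_role <- !(df$role %in% ANNOTATION_ROLES)
  if (any(bad_role)) {
    stop("unknown annotation role(s): ",
         paste(unique(df$role[bad_role]), collapse = ", "),
         " (expected ", paste(ANNOTATION_ROLES, collapse = "/"), ")")
  }
  annotations_from_parts(df)
}

## Assemble the role-tagged flat table into segments / rss / peaks.
annotations_from_parts <- function(df) {
  peaks <- df[df$role == "peak", , drop = FALSE]
  peaks_df <- if (nrow(peaks)) {
    data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
               score = if ("score" %in% names(peaks)) peaks$score else NA_real_,
               source = peaks$segment_id, stringsAsFactors = FALSE)
  } else empty_peaks()

  elem <- df[df$role != "peak", , drop = FALSE]
  seg_ids <- unique(elem$segment_id)
  seg_rows <- list(); rss_rows <- list()
  for (sid in seg_ids) {
    e <- elem[elem$segment_id == sid, , drop = FALSE]
    roles <- e$role
    has <- function(r) r %in% roles
    one <- function(r) e[match(r, roles), , drop = FALSE]
    if (has("leader") != has("coding")) {
      stop("segment '", sid, "': leader and coding exon must both be present")
    }
    if (has("heptamer") != has("nonamer")) {
      stop("segment '", sid, "': dangling RSS element (need heptamer and nonamer)")
    }
    if (!has("leader") && !has("heptamer")) {
      stop("segment '", sid, "': dangling role without a gene segment or RSS")
    }
    if (has("leader")) {
      l <- one("leader"); cd <- one("coding")
      if (l$chrom != cd$chrom) stop("segment '", sid, "': elements on different chroms")
      seg_rows[[sid]] <- data.frame(
        segment_id = sid, family = NA_character_, functional = NA,
        chrom = l$chrom, leader_start = l$start, leader_end = l$end,
        coding_start = cd$start, coding_end = cd$end,
        strand = l$strand, stringsAsFactors = FALSE)
    }
    if (has("heptamer")) {
      h <- one("heptamer"); n <- one("nonamer")
      if (h$chrom != n$chrom) stop("segment '", sid, "': RSS elements on different chroms")
      rss_rows[[sid]] <- data.frame(
        segment_id = sid, chrom = h$chrom,
        heptamer_start = h$start, heptamer_end = h$end,
        spacer_len = NA_integer_,
        nonamer_start = n$start, nonamer_end = n$end,
        strand = h$strand, stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else empty_segments()
  rss <- if (length(rss_rows)) do.call(rbind, rss_rows) else empty_rss()
  rownames(segments) <- NULL; rownames(rss) <- NULL
  list(segments = validate_segments(segments),
       rss = validate_rss(rss),
       peaks = peaks_df)
}

annotations_to_parts <- function(ann) {
  rows <- list()
  seg <- ann$segments
  if (nrow(seg)) {
    rows$leader <- data.frame(chrom = seg$chrom, start = seg$leader_start,
                              end = seg$leader_end, segment_id = seg$segment_id,
                              role = "leader", score = 0, strand = seg$strand,
                              stringsAsFactors = FALSE)
    rows$coding <- data.frame(chrom = seg$chrom, start = seg$coding_start,
                              end = seg$coding_end, segment_id = seg$segment_id,
                              role = "coding", score = 0, strand = seg$strand,
                              stringsAsFactors = FALSE)
  }
  rss <- ann$rss
  if (!is.null(rss) && nrow(rss)) {
    rows$heptamer <- data.frame(chrom = rss$chrom, start = rss$heptamer_start,
                                end = rss$heptamer_end, segment_id = rss$segment_id,
                                role = "heptamer", score = 0, strand = rss$strand,
                                stringsAsFactors = FALSE)
    rows$nonamer <- data.frame(chrom = rss$chrom, start = rss$nonamer_start,
                               end = rss$nonamer_end, segment_id = rss$segment_id,
                               role = "nonamer", score = 0, strand = rss$strand,
                               stringsAsFactors = FALSE)
  }
  pk <- ann$peaks
  if (!is.null(pk) && nrow(pk)) {
    rows$peak <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                            segment_id = ifelse(is.na(pk$source), "peak", pk$source),
                            role = "peak",
                            score = ifelse(is.na(pk$score), 0, pk$score),
                            strand = "*", stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[order(df$chrom, df$start, df$role), , drop = FALSE]
}

parts_to_granges <- function(df, name) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"),
    name = name, score = df$score)
}

#' Write annotations to BED6 or GFF3
#'
#' The inverse of [read_annotations()]: writing and re-reading an
#' annotation set yields identical internal records.
#'
#' @param ann List with `segments`, `rss`, `peaks` data frames.
#' @param path Output path.
#' @param dialect `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  df <- annotations_to_parts(ann)
  if (is.null(df) || nrow(df) == 0L) stop("nothing to write")
  if (dialect == "bed") {
    gr <- parts_to_granges(df, name = paste0(df$segment_id, "|", df$role))
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr <- parts_to_granges(df, name = df$segment_id)
    gr$type <- df$role
    gr$ID <- df$segment_id
    gr$name <- NULL
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Write motif hits or generic intervals as BED6
#'
#' @param df Data frame with `chrom`, `start`, `end`, optionally
#'   `strand`, plus the column named by `name_col`/`score_col`.
#' @param path Output path.
#' @param name_col,score_col Columns used for the BED name and score
#'   fields (defaults: a running id and 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL, score_col = NULL) {
  nm <- if (!is.null(name_col)) as.character(df[[name_col]]) else
    sprintf("site%04d", seq_len(nrow(df)))
  sc <- if (!is.null(score_col)) as.numeric(df[[score_col]]) else 0
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(strand %in% c("+", "-"), strand, "*"),
    name = nm, score = sc)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a peak list from BED
#'
#' @param path BED file of peaks.
#' @param source Label recorded in the `source` column (e.g. "chipchip").
#' @return Peak data frame (`chrom`, `start`, `end`, `score`, `source`).
#' @export
read_peaks_bed <- function(path, source = "peaks") {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_bed_df(gr)
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             score = df$score, source = source, stringsAsFactors = FALSE)
}
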