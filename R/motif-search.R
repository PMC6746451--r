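## Mismatch-tolerant consensus scanning, position-frequency matrices,
## consensus derivation and iterative refinement.
##
## Matching is Hamming distance on a fixed-width word (no indels), on
## both strands. Windows containing N never match. Hits are reported in
## motif orientation: a minus-strand hit means the reverse complement
## of the genomic window matches the motif.

#' Construct a consensus motif
#'
#' @param bases Motif string over A/C/G/T (no ambiguity codes).
#' @param label Optional label (e.g. "FII", "mVH-CTCF").
#' @return A `consensus_motif` object.
#' @export
consensus_motif <- function(bases, label = NULL) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  if (grepl("[^ACGT]", bases)) {
    stop("motif may only contain A/C/G/T (no ambiguity codes): ", bases)
  }
  if (nchar(bases) < 4L) stop("motif must be at least 4 bp")
  structure(list(bases = bases, label = if (is.null(label)) bases else label,
                 length = nchar(bases)),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("<consensus_motif> ", x$label, ": 5'-", x$bases, "-3' (", x$length,
      " bp)\n", sep = "")
  invisible(x)
}

as_consensus_motif <- function(x) {
  if (inherits(x, "consensus_motif")) x else consensus_motif(x)
}

## Integer codes for vectorised comparison; N and anything else -> 0.
.base_codes <- function(bases) {
  x <- utf8ToInt(bases)
  code <- integer(length(x))
  code[x == utf8ToInt("A")] <- 1L
  code[x == utf8ToInt("C")] <- 2L
  code[x == utf8ToInt("G")] <- 3L
  code[x == utf8ToInt("T")] <- 4L
  code
}

empty_hits <- function(scored = FALSE) {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   strand = character(), mismatches = integer(),
                   matched_seq = character(), stringsAsFactors = FALSE)
  if (scored) {
    df$mismatches <- NULL
    df$score <- numeric(); df$pvalue <- numeric()
  }
  df
}

## Hamming mismatch count of every window of `code` against `mcode`.
## Returns integer vector of length n - L + 1 (or integer(0)).
.window_mismatches <- function(code, mcode) {
  n <- length(code); L <- length(mcode)
  nw <- n - L + 1L
  if (nw < 1L) return(integer(0))
  mm <- integer(nw)
  idx <- seq_len(nw)
  for (j in seq_len(L)) {
    mm <- mm + (code[idx + (j - 1L)] != mcode[j])
  }
  mm
}

#' Scan a locus for a consensus motif with mismatches
#'
#' Every window of the motif's width, on both strands, whose Hamming
#' distance from the motif is at most `max_mismatch` is reported once.
#' Windows containing N never match. When the same interval matches on
#' both strands, both hits are reported (set `collapse_palindromes` to
#' keep only the plus-strand one).
#'
#' @param locus A [locus_sequence] (or plain character string).
#' @param motif A [consensus_motif] or motif string.
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @param region Optional `c(start, end)` 0-based half-open window
#'   restriction; only windows fully inside it are scanned.
#' @param collapse_palindromes Drop the minus-strand member of a
#'   double-strand match at one interval (default FALSE: report both).
#' @return Data frame of hits: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`, `matched_seq` (the window read
#'   in motif orientation), sorted by start then strand.
#' @export
scan_motif <- function(locus, motif, max_mismatch = 2L, region = NULL,
                       collapse_palindromes = FALSE) {
  locus <- as_locus_sequence(locus)
  motif <- as_consensus_motif(motif)
  stopifnot(max_mismatch >= 0L)
  L <- motif$length
  n <- locus$length
  if (L > n) return(empty_hits())

  code <- .base_codes(locus$bases)
  mcode_fwd <- .base_codes(motif$bases)
  mcode_rev <- .base_codes(reverse_complement(motif$bases))

  mm_plus <- .window_mismatches(code, mcode_fwd)
  mm_minus <- .window_mismatches(code, mcode_rev)

  nw <- length(mm_plus)
  isN <- code == 0L
  cs <- c(0L, cumsum(isN))
  has_n <- (cs[seq_len(nw) + L] - cs[seq_len(nw)]) > 0L

  keep <- !has_n
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 0L, region[2] <= n)
    starts0 <- seq_len(nw) - 1L
    keep <- keep & starts0 >= region[1] & (starts0 + L) <= region[2]
  }

  ip <- which(keep & mm_plus <= max_mismatch)
  im <- which(keep & mm_minus <= max_mismatch)
  if (length(ip) + length(im) == 0L) return(empty_hits())

  window_seq <- function(i) substring(locus$bases, i, i + L - 1L)
  hits <- rbind(
    if (length(ip)) data.frame(chrom = locus$name, start = ip - 1L,
                               end = ip - 1L + L, strand = "+",
                               mismatches = mm_plus[ip],
                               matched_seq = window_seq(ip),
                               stringsAsFactors = FALSE),
    if (length(im)) data.frame(chrom = locus$name, start = im - 1L,
                               end = im - 1L + L, strand = "-",
                               mismatches = mm_minus[im],
                               matched_seq = reverse_complement(window_seq(im)),
                               stringsAsFactors = FALSE)
  )
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  if (collapse_palindromes) {
    dup <- duplicated(hits[, c("start", "end")])
    hits <- hits[!dup, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Build a position frequency matrix from motif hits
#'
#' Hits are counted in motif orientation (minus-strand matches were
#' already reverse-complemented by the scanner), so a single consensus
#' can be derived from two-strand hits.
#'
#' @param hits Hit data frame from [scan_motif()] (needs `matched_seq`),
#'   or a character vector of equal-length sequences.
#' @return A `pfm` object: list with `counts` (4 x L matrix, rows
#'   A/C/G/T) and `n_sequences`; every column sums to `n_sequences`.
#' @export
build_pfm <- function(hits) {
  seqs <- if (is.data.frame(hits)) hits$matched_seq else hits
  if (length(seqs) == 0L) stop("cannot build a PFM from zero sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("all sequences must have the same length")
  }
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  counts <- matrix(0L, nrow = 4L, ncol = nchar(seqs[1]),
                   dimnames = list(DNA_BASES, NULL))
  present <- intersect(rownames(cm), DNA_BASES)
  counts[present, ] <- cm[present, , drop = FALSE]
  if (!all(colSums(counts) == length(seqs))) {
    stop("sequences contain non-ACGT characters; PFM undefined")
  }
  structure(list(counts = counts, n_sequences = length(seqs)), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", ncol(x$counts), " positions, ", x$n_sequences,
      " sequences; consensus ", consensus_from_pfm(x)$bases, "\n", sep = "")
  invisible(x)
}

#' Majority consensus of a position frequency matrix
#'
#' Per-column majority base; ties are broken deterministically by the
#' fixed base order A < C < G < T. Tied columns are reported in the
#' `ties` attribute of the result.
#'
#' @param pfm A `pfm` from [build_pfm()].
#' @param label Label for the derived motif.
#' @return A [consensus_motif]; attribute `ties` lists 1-based tied
#'   column indices (empty when no tie was broken).
#' @export
consensus_from_pfm <- function(pfm, label = "derived") {
  stopifnot(inherits(pfm, "pfm"), pfm$n_sequences >= 1L)
  counts <- pfm$counts
  top <- apply(counts, 2L, which.max)   # which.max takes first => A<C<G<T
  is_tie <- vapply(seq_len(ncol(counts)), function(j) {
    sum(counts[, j] == max(counts[, j])) > 1L
  }, logical(1))
  out <- consensus_motif(paste(DNA_BASES[top], collapse = ""), label = label)
  attr(out, "ties") <- which(is_tie)
  out
}

#' Iteratively refine a consensus by re-scanning
#'
#' Round 1 scans with the seed motif; each subsequent round scans with
#' the majority consensus derived from the previous round's hits. The
#' search stops when the derived consensus repeats (converged) or after
#' `max_rounds` rounds. All rounds are retained.
#'
#' @param locus A [locus_sequence].
#' @param seed Seed [consensus_motif] (or string).
#' @param max_mismatch Mismatch allowance used in every round.
#' @param max_rounds Upper bound on rounds (>= 1).
#' @return A `refinement_trace`: list with `rounds` (each a list of
#'   `consensus`, `hits`, `n_hits`), `converged`, and `empty_round`
#'   flagging a round that produced no hits.
#' @export
refine_search <- function(locus, seed, max_mismatch = 2L, max_rounds = 10L) {
  stopifnot(max_rounds >= 1L)
  locus <- as_locus_sequence(locus)
  query <- as_consensus_motif(seed)
  rounds <- list()
  converged <- FALSE
  empty_round <- FALSE
  for (r in seq_len(max_rounds)) {
    hits <- scan_motif(locus, query, max_mismatch = max_mismatch)
    rounds[[r]] <- list(consensus = query, hits = hits, n_hits = nrow(hits))
    if (r > 1L && query$bases == rounds[[r - 1L]]$consensus$bases) {
      # the consensus repeated: the trace ends with two identical rounds
      converged <- TRUE
      break
    }
    if (nrow(hits) == 0L) {
      warning("refinement round ", r, " produced no hits; stopping")
      empty_round <- TRUE
      break
    }
    query <- consensus_from_pfm(build_pfm(hits),
                                label = paste0("round", r, "-consensus"))
  }
  structure(list(rounds = rounds, converged = converged,
                 empty_round = empty_round,
                 final = rounds[[length(rounds)]]$consensus),
            class = "refinement_trace")
}

#' @export
print.refinement_trace <- function(x, ...) {
  cat("<refinement_trace> ", length(x$rounds), " round(s), ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  for (i in seq_along(x$rounds)) {
    cat(sprintf("  round %d: %s  (%d hits)\n", i,
                x$rounds[[i]]$consensus$bases, x$rounds[[i]]$n_hits))
  }
  invisible(x)
}

#' Information-content logo matrix
#'
#' Letter heights of a Shannon information-content sequence logo:
#' column information is `2 - H(column)` bits (no small-sample
#' correction) and each base's height is its frequency times the column
#' information.
#'
#' @param pfm A `pfm`.
#' @return 4 x L matrix of letter heights (rows A/C/G/T); attribute
#'   `info_content` holds the per-column totals in bits.
#' @export
logo_matrix <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"), pfm$n_sequences >= 1L)
  freq <- sweep(pfm$counts, 2L, colSums(pfm$counts), "/")
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  info <- 2 + colSums(plogp)            # 2 - H
  heights <- sweep(freq, 2L, info, "*")
  attr(heights, "info_content") <- info
  heights
}

#' Site density per megabase
#'
#' @param n_sites Number of sites.
#' @param region_length_bp Length of the searched region in bp (> 0).
#' @return Sites per Mb.
#' @export
site_density <- function(n_sites, region_length_bp) {
  stopifnot(n_sites >= 0)
  if (region_length_bp <= 0) stop("region length must be positive")
  n_sites / (region_length_bp / 1e6)
}
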