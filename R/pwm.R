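## Position weight matrices: log-odds scoring against a background,
## exact score-distribution p-values by dynamic programming over
## discretized scores, and threshold scanning of a locus.

#' Log-odds position weight matrix from a PFM
#'
#' `scores[b, p] = log2(((counts[b, p] + pc * bg[b]) / (n + pc)) / bg[b])`
#' where `pc` is the pseudocount and `bg` the background distribution.
#'
#' @param pfm A `pfm` from [build_pfm()], or a bare 4 x L count matrix
#'   with rows A/C/G/T.
#' @param background Background base probabilities (A, C, G, T); must be
#'   strictly positive and sum to 1. Default uniform.
#' @param pseudocount Total pseudocount added per column, distributed
#'   according to the background (default 0.1).
#' @return A `pwm` object: list with `scores` (4 x L, base-2 log-odds),
#'   `background` and `pseudocount`.
#' @export
pwm_from_pfm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.1) {
  counts <- if (inherits(pfm, "pfm")) pfm$counts else as.matrix(pfm)
  stopifnot(nrow(counts) == 4L)
  n <- if (inherits(pfm, "pfm")) pfm$n_sequences else max(colSums(counts))
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 strictly positive probabilities")
  }
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  prob <- sweep(counts + pseudocount * background, 2L, n + pseudocount, "/")
  scores <- log2(sweep(prob, 1L, background, "/"))
  dimnames(scores) <- list(DNA_BASES, NULL)
  structure(list(scores = scores, background = as.numeric(background),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", ncol(x$scores), " positions, background ",
      paste(signif(x$background, 3), collapse = "/"),
      ", pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

## Per-cell integer discretization shared by the p-value table and the
## scanner, so table lookups during scanning are exact.
.pwm_int_scores <- function(pwm, bins) {
  sc <- pwm$scores
  rng <- range(sc)
  step <- if (diff(rng) > 0) diff(rng) / bins else 1
  list(int = matrix(as.integer(round(sc / step)), nrow = 4L,
                    dimnames = dimnames(sc)),
       step = step)
}

#' Exact p-value table for PWM scores
#'
#' Computes the exact distribution of the PWM score of a random
#' background-distributed word by position-by-position convolution over
#' discretized scores, and returns the upper-tail function
#' `p(s) = P(score >= s)`.
#'
#' @param pwm A `pwm`.
#' @param bins Number of discretization bins across the score range
#'   (default 1e4); must be >= 1.
#' @return A `pwm_pvalue_table`: list with `support` (attainable
#'   discretized scores, ascending), `tail` (matching upper-tail
#'   p-values, non-increasing in score), `step` (bin width in score
#'   units), and `int_scores` (the discretized score matrix).
#' @export
score_pvalue_table <- function(pwm, bins = 1e4L) {
  stopifnot(inherits(pwm, "pwm"))
  if (bins < 1L) stop("resolution must be at least 1 bin")
  if (any(!is.finite(pwm$scores))) stop("PWM scores must be finite")
  disc <- .pwm_int_scores(pwm, bins)
  int <- disc$int
  L <- ncol(int)
  bg <- pwm$background

  lo <- sum(apply(int, 2L, min))
  hi <- sum(apply(int, 2L, max))
  width <- hi - lo + 1L
  ## prob[k] = P(sum of first j columns == lo_j + k - 1)
  prob <- numeric(width); prob[1L] <- 1
  off <- 0L                             # current distribution offset - lo_j
  lo_run <- 0L
  for (j in seq_len(L)) {
    newp <- numeric(width)
    cmin <- min(int[, j])
    for (b in 1:4) {
      shift <- int[b, j] - cmin
      if (bg[b] > 0) {
        idx <- seq_len(width - shift)
        newp[idx + shift] <- newp[idx + shift] + prob[idx] * bg[b]
      }
    }
    prob <- newp
    lo_run <- lo_run + cmin
  }
  stopifnot(abs(sum(prob) - 1) < 1e-9)
  support_int <- (lo_run + seq_len(width) - 1L)
  keep <- prob > 0
  support_int <- support_int[keep]
  p <- prob[keep]
  tail <- rev(cumsum(rev(p)))           # P(score >= support[i])
  structure(list(support = support_int, tail = tail, mass = p,
                 step = disc$step, int_scores = int),
            class = "pwm_pvalue_table")
}

#' Upper-tail p-value of a PWM score
#'
#' @param table A `pwm_pvalue_table` from [score_pvalue_table()].
#' @param score Numeric score(s) on the PWM's log-odds scale.
#' @return `P(random background word scores >= score)`, evaluated on
#'   the table's discretization grid.
#' @export
pwm_pvalue <- function(table, score) {
  stopifnot(inherits(table, "pwm_pvalue_table"))
  int <- as.integer(round(score / table$step))
  .tail_lookup(table, int)
}

## p-value of an already-discretized integer score.
.tail_lookup <- function(table, int) {
  idx <- findInterval(int - 1L, table$support) + 1L  # first support >= int
  out <- numeric(length(int))
  inside <- idx <= length(table$support)
  out[inside] <- table$tail[idx[inside]]
  out[!inside] <- 0
  out[int <= table$support[1L]] <- 1
  out
}

## Integer window scores for every window (both strands), NA where the
## window contains N. Returns list(plus, minus) integer vectors.
.pwm_window_scores <- function(code, int) {
  L <- ncol(int)
  n <- length(code)
  nw <- n - L + 1L
  if (nw < 1L) return(list(plus = integer(0), minus = integer(0)))
  ## minus strand: score of revcomp(window) under the PWM equals the
  ## score of the window under the reverse-complemented PWM
  int_rc <- int[4:1, L:1, drop = FALSE]
  plus <- integer(nw); minus <- integer(nw)
  idx <- seq_len(nw)
  ok <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    b <- code[idx + (j - 1L)]
    good <- b != 0L
    ok <- ok & good
    bj <- ifelse(good, b, 1L)
    plus <- plus + int[cbind(bj, j)]
    minus <- minus + int_rc[cbind(bj, j)]
  }
  plus[!ok] <- NA_integer_
  minus[!ok] <- NA_integer_
  list(plus = plus, minus = minus)
}

#' Scan a locus with a PWM at a p-value threshold
#'
#' Both strands are scanned; windows whose exact upper-tail p-value is
#' at or below the threshold are reported with score, p-value and
#' strand. Windows containing N are skipped.
#'
#' @param locus A [locus_sequence] or character string.
#' @param pwm A `pwm`.
#' @param p_threshold P-value threshold in (0, 1]; default 1e-4.
#' @param table Optional precomputed [score_pvalue_table()] (rebuilt
#'   otherwise).
#' @param bins Discretization bins when `table` is not supplied.
#' @return Data frame of scored hits: `chrom`, `start`, `end`,
#'   `strand`, `score` (log-odds, bits), `pvalue`, `matched_seq`.
#' @export
pwm_scan <- function(locus, pwm, p_threshold = 1e-4, table = NULL,
                     bins = 1e4L) {
  locus <- as_locus_sequence(locus)
  stopifnot(inherits(pwm, "pwm"), p_threshold > 0, p_threshold <= 1)
  if (is.null(table)) table <- score_pvalue_table(pwm, bins = bins)
  int <- table$int_scores
  L <- ncol(int)
  if (L > locus$length) return(empty_hits(scored = TRUE))
  code <- .base_codes(locus$bases)
  ws <- .pwm_window_scores(code, int)

  collect <- function(ints, strand) {
    p <- rep(NA_real_, length(ints))
    known <- !is.na(ints)
    p[known] <- .tail_lookup(table, ints[known])
    i <- which(known & p <= p_threshold)
    if (!length(i)) return(NULL)
    seqs <- substring(locus$bases, i, i + L - 1L)
    if (strand == "-") seqs <- reverse_complement(seqs)
    data.frame(chrom = locus$name, start = i - 1L, end = i - 1L + L,
               strand = strand, score = ints[i] * table$step,
               pvalue = p[i], matched_seq = seqs, stringsAsFactors = FALSE)
  }
  hits <- rbind(collect(ws$plus, "+"), collect(ws$minus, "-"))
  if (is.null(hits)) return(empty_hits(scored = TRUE))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## ---- JASPAR text format --------------------------------------------------

#' Read a count matrix in JASPAR text format
#'
#' Parses the four `A [ ... ]` style rows (brackets optional) following
#' a `>` header line.
#'
#' @param path JASPAR-format file (first matrix is read).
#' @return A `pfm` (counts rounded to integers; `n_sequences` is the
#'   maximum column sum).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!startsWith(trimws(lines), ">")]
  rows <- list()
  for (ln in body) {
    m <- regmatches(ln, regexec("^\\s*([ACGT])\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1]]
    if (length(m) == 3L) {
      rows[[m[2]]] <- as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]])
    }
    if (length(rows) == 4L) break
  }
  if (!setequal(names(rows), DNA_BASES)) {
    stop("not a JASPAR count matrix (need A/C/G/T rows): ", path)
  }
  if (length(unique(lengths(rows))) != 1L) {
    stop("JASPAR rows have unequal lengths in ", path)
  }
  counts <- do.call(rbind, rows[DNA_BASES])
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(list(counts = counts, n_sequences = max(colSums(counts))),
            class = "pfm")
}

#' Write a PFM in JASPAR text format
#'
#' @param pfm A `pfm`.
#' @param path Output path.
#' @param name Matrix name for the header line.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pfm, path, name = "matrix") {
  stopifnot(inherits(pfm, "pfm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (b in DNA_BASES) {
    writeLines(sprintf("%s [ %s ]", b,
                       paste(pfm$counts[b, ], collapse = " ")), con)
  }
  invisible(path)
}
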