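# Position-weight-matrix scanning of loop anchors and TAD boundary windows
# for CTCF motifs, gated on CTCF ChIP peaks. This stands in for a
# motif-finder whose functional contract is: at most one ChIP-supported
# CTCF site per anchor/boundary side.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param probs 4 x W numeric matrix of per-position base probabilities,
#'   rows named A, C, G, T; each column must sum to 1
#' @param background length-4 base probabilities (must sum to 1)
#' @param pseudocount numeric pseudocount mixed into the log-odds score:
#'   score_i = log2((p_i(b) + pseudocount * bg(b)) / ((1 + pseudocount) * bg(b)))
#' @return an object of class `pwm`
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop_fmt("pwm probs must have 4 rows (A,C,G,T)")
  if (is.null(rownames(probs))) rownames(probs) <- BASES
  probs <- probs[BASES, , drop = FALSE]
  if (ncol(probs) < 4) stop_fmt("pwm width must be >= 4")
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop_fmt("pwm column probabilities must sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop_fmt("pwm background must sum to 1")
  if (pseudocount < 0) stop_fmt("pseudocount must be >= 0")
  if (pseudocount == 0 && any(probs == 0))
    stop_fmt("pseudocount 0 requires strictly positive probabilities")
  structure(list(probs = probs, background = as.numeric(background),
                 pseudocount = pseudocount, width = ncol(probs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, max score %.2f bits, consensus %s\n",
              x$width, pwm_max_score(x), pwm_consensus(x)))
  invisible(x)
}

# 5 x W log-odds lookup (rows A,C,G,T,N; N scores 0 at every position).
pwm_log_odds <- function(pwm) {
  lo <- log2((pwm$probs + pwm$pseudocount * pwm$background) /
               ((1 + pwm$pseudocount) * pwm$background))
  rbind(lo, N = 0)
}

#' Maximum attainable log-odds score of a PWM, in bits
#' @param pwm a `pwm` object
#' @return numeric scalar
#' @export
pwm_max_score <- function(pwm) {
  lo <- pwm_log_odds(pwm)[1:4, , drop = FALSE]
  sum(apply(lo, 2, max))
}

#' Consensus sequence of a PWM
#' @param pwm a `pwm` object
#' @return character scalar
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Read a JASPAR-format matrix file into a `pwm`
#'
#' Accepts count or probability rows in the layout
#' `A [ 87 167 ... ]` (brackets optional), preceded by a `>` header line.
#' @param path matrix file path
#' @param background,pseudocount see [pwm()]
#' @return a `pwm` object
#' @export
read_jaspar_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  rows <- list()
  for (ln in lines) {
    base <- toupper(substr(ln, 1, 1))
    if (!base %in% BASES) stop_fmt("%s: unexpected matrix row '%s'", path, ln)
    nums <- gsub("[][]", " ", substring(ln, 2))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "[[:space:]]+")[[1]]))
    if (any(is.na(vals))) stop_fmt("%s: non-numeric entries in row %s", path, base)
    rows[[base]] <- vals
  }
  if (!setequal(names(rows), BASES)) stop_fmt("%s: need rows A, C, G, T", path)
  counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  probs <- sweep(counts, 2, colSums(counts), "/")
  pwm(probs, background = background, pseudocount = pseudocount)
}

#' Write a `pwm` to a JASPAR-style text file (probability rows)
#' @param pwm a `pwm` object
#' @param path output path
#' @param name header name
#' @export
write_jaspar_pwm <- function(pwm, path, name = "PWM") {
  con <- file(path, open = "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf(">%s", name), con)
  for (b in BASES)
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(pwm$probs[b, ], digits = 10), collapse = " ")), con)
  invisible(path)
}

#' The bundled default CTCF position weight matrix
#'
#' A synthetic consensus-style 19-column matrix shipped so the pipeline is
#' runnable offline; replace it with a database-derived CTCF matrix (JASPAR
#' text format) for real analyses.
#' @param background,pseudocount see [pwm()]
#' @return a `pwm` of width 19
#' @export
default_ctcf_pwm <- function(background = rep(0.25, 4), pseudocount = 0.01) {
  read_jaspar_pwm(system.file("extdata", "ctcf_pwm_synthetic.jaspar",
                              package = "teloop", mustWork = TRUE),
                  background, pseudocount)
}

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Log-odds score of one sequence window against a PWM
#'
#' score = sum_i log2((p_i(b_i) + pc * bg(b_i)) / ((1 + pc) * bg(b_i)));
#' N bases contribute 0; the minus strand scores the reverse complement of
#' the window.
#'
#' @param window character sequence of length `pwm$width` over A,C,G,T,N
#' @param pwm a `pwm` object
#' @param strand "+" or "-"
#' @return numeric score in bits
#' @export
log_odds_score <- function(window, pwm, strand = "+") {
  window <- toupper(window)
  if (nchar(window) != pwm$width)
    stop_fmt("window length %d != pwm width %d", nchar(window), pwm$width)
  if (strand == "-") window <- revcomp_string(window)
  codes <- match(strsplit(window, "")[[1]], c(BASES, "N"))
  if (any(is.na(codes))) stop_fmt("window contains characters outside A,C,G,T,N")
  lo <- pwm_log_odds(pwm)
  sum(lo[cbind(codes, seq_len(pwm$width))])
}

#' Scan a genomic region for PWM hits on both strands
#'
#' Scores every start position on both strands and returns hits with
#' score >= `min_score`, sorted by score descending then genome position
#' (then strand, "+" first) for determinism.
#'
#' @param chrom,start,end region to scan (0-based half-open)
#' @param genome named character vector of chromosome sequences
#' @param pwm a `pwm` object
#' @param min_score minimum score in bits; default 60% of the PWM's maximum
#' @return data.frame chrom, start, end, strand, score
#' @export
scan_region <- function(chrom, start, end, genome, pwm,
                        min_score = 0.6 * pwm_max_score(pwm)) {
  if (!chrom %in% names(genome))
    stop_fmt("scan_region: chromosome '%s' not in genome", chrom)
  seqlen <- nchar(genome[[chrom]])
  if (start < 0 || end > seqlen)
    stop_fmt("scan_region: region [%g,%g) outside sequence %s (length %d)",
             start, end, chrom, seqlen)
  W <- pwm$width
  L <- end - start
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (L < W) return(empty)
  seq <- toupper(substr(genome[[chrom]], start + 1, end))
  codes <- match(strsplit(seq, "")[[1]], c(BASES, "N"))
  codes[is.na(codes)] <- 5L
  lo <- pwm_log_odds(pwm)
  # minus-strand lookup: reverse complement the PWM instead of the sequence
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rc <- lo[comp, rev(seq_len(W)), drop = FALSE]
  n <- L - W + 1
  fwd <- numeric(n); rev_ <- numeric(n)
  for (k in seq_len(W)) {
    idx <- codes[k:(k + n - 1)]
    fwd <- fwd + lo[idx, k]
    rev_ <- rev_ + rc[idx, k]
  }
  hit_f <- which(fwd >= min_score)
  hit_r <- which(rev_ >= min_score)
  if (length(hit_f) + length(hit_r) == 0) return(empty)
  hits <- data.frame(
    chrom = chrom,
    start = start + c(hit_f, hit_r) - 1,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(fwd[hit_f], rev_[hit_r]),
    stringsAsFactors = FALSE)
  hits$end <- hits$start + W
  hits <- hits[order(-hits$score, hits$start, hits$strand),
               c("chrom", "start", "end", "strand", "score")]
  rownames(hits) <- NULL
  hits
}

#' Assign at most one ChIP-supported CTCF motif to an anchor
#'
#' Restricts hits to the anchor interval, keeps those overlapping a CTCF
#' ChIP peak by >= 1 bp, and returns the highest-scoring hit (ties broken by
#' smaller start). Absence of a qualifying hit is a valid outcome (NULL).
#'
#' @param anchor list or one-row data.frame with chrom/start/end
#' @param motif_hits data.frame from [scan_region()]
#' @param chip_peaks data.frame of CTCF peaks (chrom/start/end)
#' @return one-row data.frame (chrom, start, end, strand, score) or NULL
#' @export
assign_anchor_ctcf <- function(anchor, motif_hits, chip_peaks) {
  if (is.null(motif_hits) || nrow(motif_hits) == 0) return(NULL)
  h <- motif_hits[motif_hits$chrom == anchor$chrom &
                    motif_hits$start >= anchor$start &
                    motif_hits$end <= anchor$end, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  pk <- chip_peaks[chip_peaks$chrom == anchor$chrom, , drop = FALSE]
  if (nrow(pk) == 0) return(NULL)
  in_peak <- vapply(seq_len(nrow(h)), function(i) {
    any(interval_overlap_bp(h$start[i], h$end[i], pk$start, pk$end) >= 1)
  }, logical(1))
  h <- h[in_peak, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  h <- h[order(-h$score, h$start), , drop = FALSE]
  h[1, , drop = FALSE]
}
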