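# UCSC chain parsing and from-scratch interval lifting. In UCSC chain files
# the "target" (t) side is the assembly coordinates are lifted FROM and the
# "query" (q) side is the assembly they are lifted TO; internally we call
# them source and target respectively, matching lifting direction.

#' Read a UCSC chain file
#'
#' @param path chain file path
#' @return list of chain objects sorted by score descending. Each chain is a
#'   list with `score`, `id`, `source`/`target` (chrom, size, strand, start,
#'   end) and `blocks`, a matrix with columns size, source_gap, target_gap
#'   (gaps follow each block; the last block has zero gaps).
#' @export
read_chain <- function(path) {
  lines <- trimws(readLines(path))
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (f[1] != "chain" || length(f) < 12)
      stop_fmt("%s: expected chain header at line %d", path, i)
    hdr <- list(score = as.numeric(f[2]),
                source = list(chrom = f[3], size = as.numeric(f[4]),
                              strand = f[5], start = as.numeric(f[6]),
                              end = as.numeric(f[7])),
                target = list(chrom = f[8], size = as.numeric(f[9]),
                              strand = f[10], start = as.numeric(f[11]),
                              end = as.numeric(f[12])),
                id = if (length(f) >= 13) f[13] else as.character(length(chains) + 1L))
    i <- i + 1L
    blocks <- list()
    repeat {
      if (i > length(lines))
        stop_fmt("%s: chain %s truncated", path, hdr$id)
      b <- strsplit(lines[i], "[[:space:]]+")[[1]]
      i <- i + 1L
      if (length(b) == 1) { blocks[[length(blocks) + 1L]] <- c(as.numeric(b), 0, 0); break }
      if (length(b) != 3)
        stop_fmt("%s: malformed block line in chain %s", path, hdr$id)
      blocks[[length(blocks) + 1L]] <- as.numeric(b)
    }
    bm <- do.call(rbind, blocks)
    colnames(bm) <- c("size", "source_gap", "target_gap")
    if (any(bm[, "size"] <= 0))
      stop_fmt("%s: chain %s has non-positive block size", path, hdr$id)
    hdr$blocks <- bm
    validate_chain(hdr, path)
    chains[[length(chains) + 1L]] <- hdr
  }
  chains[order(vapply(chains, function(ch) ch$score, numeric(1)),
               decreasing = TRUE)]
}

validate_chain <- function(chain, path = "<chain>") {
  bm <- chain$blocks
  s_span <- sum(bm[, "size"]) + sum(bm[, "source_gap"])
  t_span <- sum(bm[, "size"]) + sum(bm[, "target_gap"])
  if (!isTRUE(all.equal(s_span, chain$source$end - chain$source$start)))
    stop_fmt("%s: chain %s declared source span %g != blocks+gaps %g",
             path, chain$id, chain$source$end - chain$source$start, s_span)
  if (!isTRUE(all.equal(t_span, chain$target$end - chain$target$start)))
    stop_fmt("%s: chain %s declared target span %g != blocks+gaps %g",
             path, chain$id, chain$target$end - chain$target$start, t_span)
  invisible(chain)
}

#' Write chains to a UCSC chain file
#' @param chains list of chain objects (see [read_chain()])
#' @param path output path
#' @export
write_chain <- function(chains, path) {
  con <- file(path, open = "w")
  on.exit(close(con), add = TRUE)
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %s",
                       format(ch$score, scientific = FALSE),
                       ch$source$chrom, as.integer(ch$source$size),
                       ch$source$strand, as.integer(ch$source$start),
                       as.integer(ch$source$end),
                       ch$target$chrom, as.integer(ch$target$size),
                       ch$target$strand, as.integer(ch$target$start),
                       as.integer(ch$target$end), ch$id), con)
    bm <- ch$blocks
    n <- nrow(bm)
    if (n > 1)
      writeLines(sprintf("%d %d %d", as.integer(bm[-n, 1]),
                         as.integer(bm[-n, 2]), as.integer(bm[-n, 3])), con)
    writeLines(sprintf("%d", as.integer(bm[n, 1])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Invert a chain (swap lifting direction)
#'
#' Only supported for chains with both strands "+", which is all the
#' synthetic generator emits.
#' @param chain a chain object
#' @return the inverted chain
#' @export
chain_invert <- function(chain) {
  if (chain$source$strand != "+" || chain$target$strand != "+")
    stop_fmt("chain_invert only supports '+'/'+' chains")
  bm <- chain$blocks[, c("size", "target_gap", "source_gap"), drop = FALSE]
  colnames(bm) <- c("size", "source_gap", "target_gap")
  list(score = chain$score, source = chain$target, target = chain$source,
       id = chain$id, blocks = bm)
}

# Map the portion of [start,end) falling in one chain's aligned blocks.
# Returns list(mapped_bases, images) where images is a matrix of target
# intervals in forward ("+") coordinates.
chain_map_interval <- function(chain, start, end) {
  bm <- chain$blocks
  spos <- chain$source$start
  tpos <- chain$target$start
  mapped <- 0
  images <- list()
  for (k in seq_len(nrow(bm))) {
    size <- bm[k, "size"]
    ov_s <- max(start, spos)
    ov_e <- min(end, spos + size)
    if (ov_e > ov_s) {
      off <- ov_s - spos
      len <- ov_e - ov_s
      t1 <- tpos + off
      t2 <- t1 + len
      if (chain$target$strand == "-") {
        # target coordinates run on the reversed strand; convert to forward
        images[[length(images) + 1L]] <- c(chain$target$size - t2,
                                           chain$target$size - t1)
      } else {
        images[[length(images) + 1L]] <- c(t1, t2)
      }
      mapped <- mapped + len
    }
    spos <- spos + size + bm[k, "source_gap"]
    tpos <- tpos + size + bm[k, "target_gap"]
    if (spos >= end) break
  }
  list(mapped_bases = mapped,
       images = if (length(images)) do.call(rbind, images) else NULL)
}

#' Lift one interval through a set of chains
#'
#' Walks the aligned blocks of chains overlapping the interval. The interval
#' maps when the fraction of its bases falling inside blocks of a single
#' chain reaches `min_match` (UCSC liftOver minMatch semantics); intervals
#' with mapped bases on more than one chain are reported as `split` and
#' treated as unmapped.
#'
#' @param chrom,start,end source interval (0-based half-open)
#' @param chains list of chain objects from [read_chain()]
#' @param min_match minimum fraction of source bases that must map
#'   (default 0.1, the match rate used throughout)
#' @return list with `status` (mapped / unmapped_low_match / unmapped_no_chain
#'   / split), `target` (list chrom/start/end/strand or NULL),
#'   `mapped_fraction`
#' @export
lift_interval <- function(chrom, start, end, chains, min_match = 0.1) {
  if (end <= start) stop_fmt("lift_interval: empty interval")
  len <- end - start
  hits <- list()
  for (ch in chains) {
    if (ch$source$chrom != chrom) next
    if (ch$source$end <= start || ch$source$start >= end) next
    m <- chain_map_interval(ch, start, end)
    if (m$mapped_bases > 0)
      hits[[length(hits) + 1L]] <- list(chain = ch, map = m)
  }
  if (length(hits) == 0)
    return(list(status = "unmapped_no_chain", target = NULL, mapped_fraction = 0))
  if (length(hits) > 1) {
    best <- hits[[which.max(vapply(hits, function(h) h$map$mapped_bases, numeric(1)))]]
    return(list(status = "split", target = NULL,
                mapped_fraction = best$map$mapped_bases / len))
  }
  h <- hits[[1]]
  frac <- h$map$mapped_bases / len
  if (frac < min_match)
    return(list(status = "unmapped_low_match", target = NULL, mapped_fraction = frac))
  img <- h$map$images
  list(status = "mapped",
       target = list(chrom = h$chain$target$chrom,
                     start = min(img[, 1]), end = max(img[, 2]),
                     strand = h$chain$target$strand),
       mapped_fraction = frac)
}

#' Lift a data.frame of intervals
#' @param df data.frame with chrom/start/end
#' @param chains list of chain objects
#' @param min_match see [lift_interval()]
#' @return `df` with added columns lift_status, lift_chrom, lift_start,
#'   lift_end, lift_strand, mapped_fraction
#' @export
lift_intervals <- function(df, chains, min_match = 0.1) {
  n <- nrow(df)
  df$lift_status <- character(n)
  df$lift_chrom <- NA_character_
  df$lift_start <- NA_real_
  df$lift_end <- NA_real_
  df$lift_strand <- NA_character_
  df$mapped_fraction <- NA_real_
  for (i in seq_len(n)) {
    r <- lift_interval(df$chrom[i], df$start[i], df$end[i], chains, min_match)
    df$lift_status[i] <- r$status
    df$mapped_fraction[i] <- r$mapped_fraction
    if (r$status == "mapped") {
      df$lift_chrom[i] <- r$target$chrom
      df$lift_start[i] <- r$target$start
      df$lift_end[i] <- r$target$end
      df$lift_strand[i] <- r$target$strand
    }
  }
  df
}
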