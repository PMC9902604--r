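# Shared fixtures: the default synthetic dataset and pipeline run are
# generated once per session and reused across test files.

the <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(the$ds))
    the$ds <- generate_synthetic_dataset(sim_config(seed = 1))
  the$ds
}

dataset_dir <- function() {
  if (is.null(the$dir)) {
    dir <- file.path(tempdir(), "teloop-default-ds")
    write_synthetic_dataset(default_dataset(), dir)
    the$dir <- dir
  }
  the$dir
}

default_pipeline <- function() {
  if (is.null(the$res))
    the$res <- run_pipeline(pipeline_config_from_dir(dataset_dir(), seed = 1),
                            n_shuffles = 0)
  the$res
}

# Build an in-memory chain object from explicit blocks.
make_chain <- function(blocks, s_chrom = "chr1", s_size = NULL, s_start = 0,
                       t_chrom = "chr1", t_size = NULL, t_start = 0,
                       t_strand = "+", score = 1000, id = "1") {
  bm <- do.call(rbind, blocks)
  colnames(bm) <- c("size", "source_gap", "target_gap")
  s_span <- sum(bm[, 1]) + sum(bm[, 2])
  t_span <- sum(bm[, 1]) + sum(bm[, 3])
  list(score = score, id = id,
       source = list(chrom = s_chrom, size = s_size %||% (s_start + s_span),
                     strand = "+", start = s_start, end = s_start + s_span),
       target = list(chrom = t_chrom, size = t_size %||% (t_start + t_span),
                     strand = t_strand, start = t_start, end = t_start + t_span),
       blocks = bm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent per-base lifting oracle: walks one '+'/'+' chain base by base.
lift_oracle <- function(chain, start, end) {
  images <- numeric(0)
  for (b in start:(end - 1)) {
    spos <- chain$source$start
    tpos <- chain$target$start
    for (k in seq_len(nrow(chain$blocks))) {
      sz <- chain$blocks[k, 1]
      if (b >= spos && b < spos + sz) {
        images <- c(images, tpos + (b - spos))
        break
      }
      spos <- spos + sz + chain$blocks[k, 2]
      tpos <- tpos + sz + chain$blocks[k, 3]
    }
  }
  list(mapped = length(images),
       span = if (length(images)) c(min(images), max(images) + 1) else NULL)
}

# Quadratic brute-force oracle for the best-overlap repeat attribution;
# ties go to the repeat with the smaller start (first in start order).
overlap_oracle <- function(motif, repeats, min_overlap = 10) {
  r <- repeats[repeats$chrom == motif$chrom, , drop = FALSE]
  r <- r[order(r$start), , drop = FALSE]
  best_ov <- 0; best_i <- NA
  for (i in seq_len(nrow(r))) {
    ov <- max(0, min(motif$end, r$end[i]) - max(motif$start, r$start[i]))
    if (ov > best_ov) { best_ov <- ov; best_i <- i }
  }
  if (best_ov >= min_overlap)
    list(origin = "RE_derived", overlap = best_ov,
         subfamily = r$subfamily[best_i])
  else list(origin = "non_RE", overlap = best_ov, subfamily = NA_character_)
}

# Random repeats table on one chromosome.
random_repeats <- function(n, chrom = "chr1", max_pos = 10000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = start + sample(5:400, n, replace = TRUE),
             strand = "+", subfamily = paste0("sub", seq_len(n)),
             family = "fam", class_name = "LINE", score = 0,
             stringsAsFactors = FALSE)
}

# A sharp little PWM whose consensus is the given string.
consensus_pwm <- function(consensus, p = 0.997, pseudocount = 0) {
  chars <- strsplit(consensus, "")[[1]]
  probs <- matrix((1 - p) / 3, 4, length(chars),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[cbind(match(chars, c("A", "C", "G", "T")), seq_along(chars))] <- p
  pwm(probs, pseudocount = pseudocount)
}
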