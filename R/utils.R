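# Internal helpers shared across modules. All coordinates in this package
# are 0-based half-open; these helpers assume that convention.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Base-pair overlap between two interval vectors
#'
#' Vectorised; returns 0 for disjoint pairs.
#' @param start1,end1,start2,end2 numeric vectors of 0-based half-open bounds
#' @return numeric vector of overlap widths in bp
#' @keywords internal
interval_overlap_bp <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}

#' Edge-to-edge gap between two interval vectors (0 when overlapping)
#' @keywords internal
interval_gap_bp <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

interval_midpoint <- function(start, end) (start + end) / 2

#' Stable hash of a configuration object (for report provenance)
#' @keywords internal
config_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

# Synthesize a stable loop id from anchor coordinates.
loop_id_from_coords <- function(chrom, start1, end1, start2, end2) {
  sprintf("%s:%d-%d_%d-%d", chrom,
          as.integer(start1), as.integer(end1),
          as.integer(start2), as.integer(end2))
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
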