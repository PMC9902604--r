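# Repeat-origin classification of anchor/boundary CTCF sites, structure
# (loop/TAD) labels, taxonomy summaries and the shuffle null.

#' Default set of RepeatMasker classes counted as transposable elements
#'
#' SINE/LINE/LTR/DNA plus rolling-circle and retroposon classes; trailing
#' "?" variants (e.g. "DNA?") are normalized before matching.
#' @export
DEFAULT_TE_CLASSES <- c("SINE", "LINE", "LTR", "DNA", "RC", "Retroposon")

normalize_repeat_class <- function(x) sub("\\?$", "", x)

#' Is a repeat class a TE class?
#' @param class_name repeat class names (e.g. "LINE", "DNA?")
#' @param te_classes reference set (default [DEFAULT_TE_CLASSES])
#' @return logical vector
#' @export
is_te_class <- function(class_name, te_classes = DEFAULT_TE_CLASSES) {
  normalize_repeat_class(class_name) %in% te_classes
}

#' Classify one CTCF motif as repeat-derived or not
#'
#' A site is RE-derived when its maximal overlap with a single repeat is at
#' least `min_overlap` bp (10 bp rule). The repeat with the largest overlap
#' is attached; ties go to the repeat with the smaller start.
#'
#' @param motif list or one-row data.frame with chrom/start/end
#' @param repeats data.frame from [read_repeatmasker_out()]
#' @param min_overlap minimum motif/repeat overlap in bp (default 10)
#' @return list with origin ("RE_derived"/"non_RE"), overlap_bp, and (when
#'   RE-derived) repeat_subfamily / repeat_family / repeat_class
#' @export
classify_ctcf_origin <- function(motif, repeats, min_overlap = 10) {
  r <- repeats[repeats$chrom == motif$chrom, , drop = FALSE]
  if (nrow(r) == 0)
    return(list(origin = "non_RE", overlap_bp = 0,
                repeat_subfamily = NA_character_, repeat_family = NA_character_,
                repeat_class = NA_character_))
  ov <- interval_overlap_bp(motif$start, motif$end, r$start, r$end)
  best <- max(ov)
  if (best >= min_overlap) {
    i <- order(-ov, r$start)[1]
    list(origin = "RE_derived", overlap_bp = ov[i],
         repeat_subfamily = r$subfamily[i], repeat_family = r$family[i],
         repeat_class = r$class_name[i])
  } else {
    list(origin = "non_RE", overlap_bp = max(0, best),
         repeat_subfamily = NA_character_, repeat_family = NA_character_,
         repeat_class = NA_character_)
  }
}

#' Classify a table of CTCF sites against repeat annotations
#' @param sites data.frame with chrom/start/end (one row per site)
#' @param repeats repeat annotation data.frame
#' @param min_overlap see [classify_ctcf_origin()]
#' @return `sites` with added columns origin, overlap_bp, repeat_subfamily,
#'   repeat_family, repeat_class
#' @export
classify_ctcf_origins <- function(sites, repeats, min_overlap = 10) {
  n <- nrow(sites)
  sites$origin <- character(n)
  sites$overlap_bp <- numeric(n)
  sites$repeat_subfamily <- NA_character_
  sites$repeat_family <- NA_character_
  sites$repeat_class <- NA_character_
  for (i in seq_len(n)) {
    cl <- classify_ctcf_origin(sites[i, ], repeats, min_overlap)
    sites$origin[i] <- cl$origin
    sites$overlap_bp[i] <- cl$overlap_bp
    sites$repeat_subfamily[i] <- cl$repeat_subfamily
    sites$repeat_family[i] <- cl$repeat_family
    sites$repeat_class[i] <- cl$repeat_class
  }
  sites
}

#' Standardize a published TAD border to a +/- flank window
#'
#' @param point border position in bp
#' @param chrom chromosome name
#' @param assembly a `genome_assembly` (window is clipped to the chromosome)
#' @param flank half-window in bp (default 5000, i.e. a 10 kb window)
#' @return list with chrom, point, window_start, window_end
#' @export
standardize_tad_boundary <- function(point, chrom, assembly, flank = 5000) {
  len <- chrom_length(assembly, chrom)
  if (point < 0 || point >= len)
    stop_fmt("TAD border %g outside chromosome %s [0,%g)", point, chrom, len)
  list(chrom = chrom, point = point,
       window_start = max(0, point - flank),
       window_end = min(len, point + flank))
}

#' Classify a loop or TAD by the repeat origin of its CTCF sites
#'
#' RE-derived when at least one side carries an RE-derived CTCF site;
#' non-RE-derived when both sides carry CTCF sites and none is RE-derived;
#' excluded otherwise (at least one side lacks a CTCF site and no side is
#' RE-derived). Excluded structures are omitted from summary denominators.
#'
#' @param structure_id structure identifier
#' @param kind "loop" or "tad"
#' @param side_sites list of length 2; each element a one-row classified
#'   site (with `origin`, repeat columns) or NULL when that side has no CTCF
#' @param te_classes TE class set for the `te_only` flag
#' @return one-row data.frame: structure_id, kind, label, te_only,
#'   n_ctcf_sides, n_re_sides, repeat_subfamily/family/class of the
#'   RE-derived site (first by side order)
#' @export
classify_structure <- function(structure_id, kind, side_sites,
                               te_classes = DEFAULT_TE_CLASSES) {
  stopifnot(length(side_sites) == 2)
  have <- !vapply(side_sites, is.null, logical(1))
  re <- vapply(seq_along(side_sites), function(i) {
    have[i] && identical(side_sites[[i]]$origin, "RE_derived")
  }, logical(1))
  label <- if (any(re)) "RE_derived"
  else if (all(have)) "non_RE_derived"
  else "excluded"
  contributing <- side_sites[re]
  te_only <- if (any(re)) {
    all(vapply(contributing, function(s) is_te_class(s$repeat_class, te_classes),
               logical(1)))
  } else FALSE
  first_re <- if (any(re)) contributing[[1]] else NULL
  data.frame(structure_id = structure_id, kind = kind, label = label,
             te_only = te_only,
             n_ctcf_sides = sum(have), n_re_sides = sum(re),
             repeat_subfamily = first_re$repeat_subfamily %||% NA_character_,
             repeat_family = first_re$repeat_family %||% NA_character_,
             repeat_class = first_re$repeat_class %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify many structures from a per-side site table
#' @param structure_ids character vector of structure ids
#' @param kind "loop" or "tad"
#' @param sites classified site table with columns structure_id, side (1/2),
#'   origin, repeat_subfamily/family/class
#' @param te_classes see [classify_structure()]
#' @return data.frame, one row per structure
#' @export
classify_structures <- function(structure_ids, kind, sites,
                                te_classes = DEFAULT_TE_CLASSES) {
  out <- lapply(structure_ids, function(sid) {
    side_sites <- lapply(1:2, function(sd) {
      r <- sites[sites$structure_id == sid & sites$side == sd, , drop = FALSE]
      if (nrow(r) == 0) NULL else r[1, , drop = FALSE]
    })
    classify_structure(sid, kind, side_sites, te_classes)
  })
  do.call(rbind, out)
}

# Unique sites by motif coordinates (sites shared by several structures are
# counted once).
dedupe_sites <- function(sites) {
  key <- paste(sites$chrom, sites$start, sites$end, sites$strand %||% "+")
  sites[!duplicated(key), , drop = FALSE]
}

#' Taxonomy summary of repeat-derived CTCF sites
#'
#' Counts unique RE-derived (optionally TE-only) CTCF sites per repeat
#' class/family/subfamily, with percents of the chosen denominator.
#'
#' @param sites classified site table ([classify_ctcf_origins()])
#' @param level "class", "family" or "subfamily"
#' @param te_only restrict numerator and denominator to TE-class sites
#' @param te_classes TE class set
#' @return data.frame name, count, percent; attribute "denominator"
#' @export
summarize_taxonomy <- function(sites, level = c("class", "family", "subfamily"),
                               te_only = FALSE,
                               te_classes = DEFAULT_TE_CLASSES) {
  level <- match.arg(level)
  col <- c(class = "repeat_class", family = "repeat_family",
           subfamily = "repeat_subfamily")[[level]]
  re <- dedupe_sites(sites[sites$origin == "RE_derived", , drop = FALSE])
  if (te_only) re <- re[is_te_class(re$repeat_class, te_classes), , drop = FALSE]
  denom <- nrow(re)
  if (denom == 0) {
    warn_fmt("summarize_taxonomy: no qualifying sites; returning empty summary")
    out <- data.frame(name = character(), count = integer(), percent = numeric())
    attr(out, "denominator") <- 0L
    return(out)
  }
  tab <- sort(table(re[[col]]), decreasing = TRUE)
  out <- data.frame(name = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / denom,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  out
}

#' Percent of unique CTCF sites that are repeat-derived
#'
#' @param sites classified site table for one sample
#' @return numeric percent with attributes "numerator" and "denominator"
#' @export
re_fraction <- function(sites) {
  u <- dedupe_sites(sites)
  denom <- nrow(u)
  if (denom == 0) {
    warn_fmt("re_fraction: no CTCF sites; fraction undefined")
    out <- NA_real_
    attr(out, "numerator") <- 0L
    attr(out, "denominator") <- 0L
    return(out)
  }
  num <- sum(u$origin == "RE_derived")
  out <- 100 * num / denom
  attr(out, "numerator") <- num
  attr(out, "denominator") <- denom
  out
}

#' Pool repeat-derived fractions across samples
#'
#' Pools as sum of unique RE-derived sites over sum of unique CTCF sites
#' (not a mean of per-sample percents).
#' @param site_tables list of classified site tables
#' @return numeric percent with numerator/denominator attributes
#' @export
re_fraction_pooled <- function(site_tables) {
  fr <- lapply(site_tables, re_fraction)
  num <- sum(vapply(fr, function(x) attr(x, "numerator"), numeric(1)))
  denom <- sum(vapply(fr, function(x) attr(x, "denominator"), numeric(1)))
  if (denom == 0) stop_fmt("re_fraction_pooled: empty denominator")
  out <- 100 * num / denom
  attr(out, "numerator") <- num
  attr(out, "denominator") <- denom
  out
}

#' Shuffle null for the repeat-derived fraction
#'
#' Each shuffle re-places every motif uniformly at random on its own
#' chromosome (length- and chromosome-preserving) and re-applies the
#' >= `min_overlap` bp single-repeat rule. Returns the null distribution of
#' the RE-derived percent and an empirical two-sided p value for the
#' observed percent.
#'
#' @param sites classified site table (unique sites are used)
#' @param repeats repeat annotations
#' @param assembly a `genome_assembly`
#' @param n_shuffles number of shuffles (>= 100)
#' @param seed RNG seed (restored afterwards)
#' @param min_overlap overlap rule threshold (default 10)
#' @return list(null = numeric vector of percents, observed, p_value)
#' @export
shuffle_null <- function(sites, repeats, assembly, n_shuffles = 1000,
                         seed = 1, min_overlap = 10) {
  if (n_shuffles < 100) stop_fmt("shuffle_null: n_shuffles must be >= 100")
  u <- dedupe_sites(sites)
  if (nrow(u) == 0) stop_fmt("shuffle_null: no sites")
  widths <- u$end - u$start
  lens <- chrom_length(assembly, u$chrom)
  if (any(widths > lens))
    stop_fmt("shuffle_null: motif longer than its chromosome")
  obs <- as.numeric(re_fraction(u))
  # Precompute, per (chrom, width), the sorted union of start positions at
  # which a placed motif overlaps a single repeat by >= min_overlap:
  # for repeat [rs,re) a start s qualifies iff s in [rs - W + min_overlap,
  # re - min_overlap]. Membership is then a findInterval lookup.
  groups <- unique(data.frame(chrom = u$chrom, width = widths))
  hitzones <- list()
  for (g in seq_len(nrow(groups))) {
    ch <- groups$chrom[g]; W <- groups$width[g]
    r <- repeats[repeats$chrom == ch, , drop = FALSE]
    key <- paste(ch, W)
    if (nrow(r) == 0) { hitzones[[key]] <- cbind(numeric(0), numeric(0)); next }
    lo <- pmax(0, r$start - W + min_overlap)
    hi <- r$end - min_overlap            # inclusive upper bound on start
    keep <- hi >= lo & (r$end - r$start) >= min_overlap
    lo <- lo[keep]; hi <- hi[keep]
    if (length(lo) == 0) { hitzones[[key]] <- cbind(numeric(0), numeric(0)); next }
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    # merge overlapping zones
    mlo <- lo[1]; mhi <- hi[1]; zs <- list()
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= mhi + 1) mhi <- max(mhi, hi[i])
      else { zs[[length(zs) + 1]] <- c(mlo, mhi); mlo <- lo[i]; mhi <- hi[i] }
    }
    zs[[length(zs) + 1]] <- c(mlo, mhi)
    hitzones[[key]] <- do.call(rbind, zs)
  }
  keys <- paste(u$chrom, widths)
  max_start <- lens - widths
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      starts <- floor(stats::runif(nrow(u), 0, max_start + 1))
      hit <- vapply(seq_len(nrow(u)), function(i) {
        z <- hitzones[[keys[i]]]
        if (nrow(z) == 0) return(FALSE)
        j <- findInterval(starts[i], z[, 1])
        j >= 1 && starts[i] <= z[j, 2]
      }, logical(1))
      100 * mean(hit)
    }, numeric(1))
  })
  p <- min(1, 2 * min((1 + sum(null <= obs)) / (n_shuffles + 1),
                      (1 + sum(null >= obs)) / (n_shuffles + 1)))
  list(null = null, observed = obs, p_value = p)
}
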