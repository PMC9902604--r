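# ChromHMM-based functional attribution of loops, enhancer/promoter
# strength subclassification, and the CRISPR candidate-selection filter.

#' Default ChromHMM state vocabulary by role
#'
#' The human vocabulary includes the EnhA1/EnhA2 active-enhancer states;
#' configure `enhancer_states` without them for species whose segmentations
#' lack those states.
#' @export
DEFAULT_CHROMHMM_STATES <- list(
  promoter = c("TssA", "TssAFlnk"),
  enhancer = c("Enh", "EnhG", "EnhA1", "EnhA2"),
  repressive = c("ReprPC", "ReprPCWk"),
  neutral = c("Quies", "TssBiv", "BivFlnk", "EnhBiv", "ZNF/Rpts", "Het",
              "Tx", "TxWk", "TxFlnk")
)

#' Default strong/weak map for enhancer and promoter states
#' @export
DEFAULT_STRENGTH_MAP <- list(
  enhancer = c(EnhA1 = "strong", EnhA2 = "strong", Enh = "weak", EnhG = "weak"),
  promoter = c(TssA = "active", TssAFlnk = "weak")
)

# States whose segments overlap or lie within `window` bp of the anchor
# (edge distance; overlap counts as 0).
states_near_anchor <- function(anchor, segments, window) {
  s <- segments[segments$chrom == anchor$chrom, , drop = FALSE]
  if (nrow(s) == 0) return(character())
  gap <- interval_gap_bp(anchor$start, anchor$end, s$start, s$end)
  unique(s$state[gap <= window])
}

#' Attribute putative regulatory function to one loop
#'
#' A loop is an enhancer-promoter loop when a ChromHMM promoter state lies
#' within `window` bp of one anchor and an enhancer state within `window`
#' bp of the opposite anchor; promoter plus polycomb repression at the
#' opposite anchor gives a repressive loop. When both an enhancer and a
#' repressive state flank the opposite anchor the loop resolves to
#' enhancer_promoter (flagged in `ep_repr_conflict`). Both orientations are
#' tested, so the label is symmetric under anchor swap.
#'
#' @param loop one-row loop data.frame
#' @param segments ChromHMM segmentation ([read_chromhmm_bed()])
#' @param window distance window in bp (default 10000)
#' @param states state vocabulary (see [DEFAULT_CHROMHMM_STATES])
#' @return one-row data.frame: loop_id, label (enhancer_promoter /
#'   repressive / unannotated), promoter_anchor (1/2/NA), ep_repr_conflict
#' @export
attribute_loop_function <- function(loop, segments, window = 10000,
                                    states = DEFAULT_CHROMHMM_STATES) {
  known <- unlist(states, use.names = FALSE)
  unknown <- setdiff(unique(segments$state), known)
  if (length(unknown) > 0 && !isTRUE(getOption("teloop.quiet_unknown_states")))
    warn_fmt("ignoring unknown ChromHMM state label(s): %s",
             paste(unknown, collapse = ", "))
  a1 <- list(chrom = loop$chrom, start = loop$start1, end = loop$end1)
  a2 <- list(chrom = loop$chrom, start = loop$start2, end = loop$end2)
  s1 <- states_near_anchor(a1, segments, window)
  s2 <- states_near_anchor(a2, segments, window)
  prom <- c(any(s1 %in% states$promoter), any(s2 %in% states$promoter))
  enh <- c(any(s1 %in% states$enhancer), any(s2 %in% states$enhancer))
  repr <- c(any(s1 %in% states$repressive), any(s2 %in% states$repressive))
  label <- "unannotated"; prom_anchor <- NA_integer_; conflict <- FALSE
  # enhancer-promoter takes precedence over repressive in either orientation
  for (p in 1:2) {
    o <- 3 - p
    if (prom[p] && enh[o]) {
      label <- "enhancer_promoter"; prom_anchor <- p
      conflict <- repr[o]
      break
    }
  }
  if (label == "unannotated") {
    for (p in 1:2) {
      o <- 3 - p
      if (prom[p] && repr[o]) { label <- "repressive"; prom_anchor <- p; break }
    }
  }
  data.frame(loop_id = loop$id, label = label, promoter_anchor = prom_anchor,
             ep_repr_conflict = conflict, stringsAsFactors = FALSE)
}

#' Subclassify an enhancer-promoter loop by enhancer/promoter strength
#'
#' The strongest qualifying state on each side determines the subclass
#' (strong/weak enhancer x active/weak promoter). Non-E-P loops return
#' "none".
#'
#' @param loop one-row loop data.frame
#' @param loop_function one-row result of [attribute_loop_function()]
#' @param segments ChromHMM segmentation
#' @param window distance window in bp (default 10000)
#' @param strength_map see [DEFAULT_STRENGTH_MAP]
#' @return character subclass, e.g. "strong_enh_active_prom"
#' @export
subclassify_ep <- function(loop, loop_function, segments, window = 10000,
                           strength_map = DEFAULT_STRENGTH_MAP) {
  if (loop_function$label != "enhancer_promoter") return("none")
  p <- loop_function$promoter_anchor
  anchors <- list(list(chrom = loop$chrom, start = loop$start1, end = loop$end1),
                  list(chrom = loop$chrom, start = loop$start2, end = loop$end2))
  prom_states <- states_near_anchor(anchors[[p]], segments, window)
  enh_states <- states_near_anchor(anchors[[3 - p]], segments, window)
  enh_strengths <- strength_map$enhancer[intersect(enh_states,
                                                   names(strength_map$enhancer))]
  prom_strengths <- strength_map$promoter[intersect(prom_states,
                                                    names(strength_map$promoter))]
  enh_s <- if ("strong" %in% enh_strengths) "strong" else "weak"
  prom_s <- if ("active" %in% prom_strengths) "active" else "weak"
  sprintf("%s_enh_%s_prom", enh_s, prom_s)
}

#' Attribute function to a table of loops
#' @param loops loop data.frame
#' @param segments ChromHMM segmentation
#' @param window distance window in bp
#' @param states state vocabulary
#' @param strength_map strength map for the E-P subclass
#' @return data.frame: loop_id, label, promoter_anchor, ep_repr_conflict,
#'   ep_subclass
#' @export
attribute_loop_functions <- function(loops, segments, window = 10000,
                                     states = DEFAULT_CHROMHMM_STATES,
                                     strength_map = DEFAULT_STRENGTH_MAP) {
  known <- unlist(states, use.names = FALSE)
  unknown <- setdiff(unique(segments$state), known)
  if (length(unknown) > 0)
    warn_fmt("ignoring unknown ChromHMM state label(s): %s",
             paste(unknown, collapse = ", "))
  old <- options(teloop.quiet_unknown_states = TRUE)
  on.exit(options(old), add = TRUE)
  out <- lapply(seq_len(nrow(loops)), function(i) {
    lp <- loops[i, , drop = FALSE]
    fn <- attribute_loop_function(lp, segments, window, states)
    fn$ep_subclass <- subclassify_ep(lp, fn, segments, window, strength_map)
    fn
  })
  do.call(rbind, out)
}

#' Select CRISPR deletion candidates among lineage-specific TE-derived loops
#'
#' Filters, applied in order with a per-loop audit trail:
#' \enumerate{
#'   \item at least one anchor CTCF site is RE-derived AND the loop is
#'     lineage-specific (not orthologous in the comparison species);
#'   \item the loop has an attributed function (enhancer-promoter or
#'     repressive; promoter within the window of one anchor, enhancer or
#'     repressor at the opposite anchor);
#'   \item at most one active CTCF ChIP peak lies within
#'     `exclusion_window` bp of the candidate (RE-derived) anchor;
#'   \item the candidate RE-derived CTCF motif does not overlap a p300 peak.
#' }
#' Passing loops are ranked GeneHancer-supported first, then by candidate
#' motif PWM score. When a loop has two RE-derived anchors the
#' higher-scoring motif is audited as the candidate anchor.
#'
#' @param loops loop data.frame
#' @param sites classified anchor site table (structure_id, side, chrom,
#'   start, end, score, origin)
#' @param orthology loop orthology labels
#' @param functions loop function labels
#' @param ctcf_peaks active CTCF peak data.frame
#' @param p300_peaks p300 peak data.frame
#' @param genehancer optional data.frame of validated enhancer/promoter
#'   interval pairs (chrom, enh_start, enh_end, prom_start, prom_end);
#'   absence never excludes a loop
#' @param exclusion_window active-CTCF exclusion window in bp (default 15000)
#' @return data.frame with per-filter booleans, `passed`, `failed_at`
#'   (first failing filter or NA), `candidate_side`, `genehancer_support`,
#'   `candidate_score` and `rank` (NA for rejected loops)
#' @export
select_crispr_candidates <- function(loops, sites, orthology, functions,
                                     ctcf_peaks, p300_peaks,
                                     genehancer = NULL,
                                     exclusion_window = 15000) {
  orth <- stats::setNames(orthology$label, orthology$structure_id)
  fun <- stats::setNames(functions$label, functions$loop_id)
  rows <- lapply(seq_len(nrow(loops)), function(i) {
    lp <- loops[i, , drop = FALSE]
    ls <- sites[sites$structure_id == lp$id, , drop = FALSE]
    re <- ls[ls$origin == "RE_derived", , drop = FALSE]
    f1 <- nrow(re) > 0 && identical(unname(orth[lp$id]), "lineage_specific")
    f2 <- f3 <- f4 <- NA
    cand_side <- NA_integer_; cand_score <- NA_real_; gh <- FALSE
    failed <- NA_integer_
    if (!f1) failed <- 1L
    if (is.na(failed)) {
      f2 <- unname(fun[lp$id]) %in% c("enhancer_promoter", "repressive")
      if (!f2) failed <- 2L
    }
    if (is.na(failed)) {
      re <- re[order(-re$score, re$start), , drop = FALSE]
      cand <- re[1, , drop = FALSE]
      cand_side <- cand$side
      cand_score <- cand$score
      anchor <- if (cand_side == 1)
        list(chrom = lp$chrom, start = lp$start1, end = lp$end1)
      else list(chrom = lp$chrom, start = lp$start2, end = lp$end2)
      pk <- ctcf_peaks[ctcf_peaks$chrom == anchor$chrom, , drop = FALSE]
      n_near <- if (nrow(pk) == 0) 0 else
        sum(interval_gap_bp(anchor$start, anchor$end, pk$start, pk$end) <=
              exclusion_window)
      f3 <- n_near <= 1
      if (!f3) failed <- 3L
      if (is.na(failed)) {
        p3 <- p300_peaks[p300_peaks$chrom == cand$chrom, , drop = FALSE]
        f4 <- nrow(p3) == 0 ||
          all(interval_overlap_bp(cand$start, cand$end, p3$start, p3$end) == 0)
        if (!f4) failed <- 4L
      }
      if (!is.null(genehancer) && nrow(genehancer) > 0) {
        gh <- any(genehancer$chrom == lp$chrom &
                    ((interval_overlap_bp(genehancer$enh_start, genehancer$enh_end,
                                          lp$start2, lp$end2) > 0 &
                        interval_overlap_bp(genehancer$prom_start, genehancer$prom_end,
                                            lp$start1, lp$end1) > 0) |
                       (interval_overlap_bp(genehancer$enh_start, genehancer$enh_end,
                                            lp$start1, lp$end1) > 0 &
                          interval_overlap_bp(genehancer$prom_start, genehancer$prom_end,
                                              lp$start2, lp$end2) > 0)))
      }
    }
    data.frame(loop_id = lp$id,
               filter1_te_specific = f1, filter2_functional = f2,
               filter3_ctcf_isolation = f3, filter4_no_p300 = f4,
               passed = is.na(failed), failed_at = failed,
               candidate_side = cand_side, candidate_score = cand_score,
               genehancer_support = gh, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  ok <- which(out$passed)
  if (length(ok) > 0) {
    o <- ok[order(-out$genehancer_support[ok], -out$candidate_score[ok],
                  out$loop_id[ok])]
    out$rank[o] <- seq_along(o)
  }
  out
}
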