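# Cross-species conservation calls for loops and TAD boundary CTCF sites,
# built on chain lifting, plus the origin-by-orthology cross-tabulation.

#' Conservation test for one lifted loop
#'
#' The source loop's anchors are lifted through the chains; the loop is
#' conserved when some target loop has both anchor midpoints within
#' t = min(source loop span / 2, `cap_bp`) of the lifted anchor midpoints
#' (pairing preserved after genome-ordering both loops). The nearest
#' qualifying target (by the larger of the two anchor distances) is
#' recorded.
#'
#' @param loop one-row loop data.frame (id, chrom, start1, end1, start2, end2)
#' @param lift1,lift2 [lift_interval()] results for anchor1 and anchor2
#' @param target_loops loop data.frame in the target assembly
#' @param cap_bp distance cap in bp (default 50000)
#' @return one-row data.frame: structure_id, label (conserved /
#'   lineage_specific / unliftable), matched_target_id, distance_bp
#' @export
loop_is_conserved <- function(loop, lift1, lift2, target_loops, cap_bp = 50000) {
  res <- function(label, match_id = NA_character_, dist = NA_real_) {
    data.frame(structure_id = loop$id, label = label,
               matched_target_id = match_id, distance_bp = dist,
               stringsAsFactors = FALSE)
  }
  if (lift1$status != "mapped" || lift2$status != "mapped")
    return(res("unliftable"))
  t <- min((loop$end2 - loop$start1) / 2, cap_bp)
  m1 <- interval_midpoint(lift1$target$start, lift1$target$end)
  m2 <- interval_midpoint(lift2$target$start, lift2$target$end)
  # genome-order the lifted pair (a chain may flip anchor order)
  if (m1 > m2) { tmp <- m1; m1 <- m2; m2 <- tmp }
  chrom <- lift1$target$chrom
  if (!identical(chrom, lift2$target$chrom))
    return(res("lineage_specific"))
  tg <- target_loops[target_loops$chrom == chrom, , drop = FALSE]
  if (nrow(tg) == 0) return(res("lineage_specific"))
  d1 <- abs(m1 - interval_midpoint(tg$start1, tg$end1))
  d2 <- abs(m2 - interval_midpoint(tg$start2, tg$end2))
  ok <- d1 <= t & d2 <= t
  if (!any(ok)) return(res("lineage_specific"))
  dmax <- pmax(d1, d2)
  dmax[!ok] <- Inf
  i <- order(dmax, tg$id)[1]
  res("conserved", tg$id[i], dmax[i])
}

#' Conservation labels for a set of loops
#'
#' Lifts both anchors of every source loop and applies
#' [loop_is_conserved()].
#'
#' @param loops source loop data.frame
#' @param chains chains from the source to the target assembly
#' @param target_loops target loop data.frame
#' @param min_match liftOver match rate (default 0.1)
#' @param cap_bp conservation distance cap (default 50000)
#' @return data.frame with one row per loop: structure_id, label,
#'   matched_target_id, distance_bp
#' @export
classify_loops_orthology <- function(loops, chains, target_loops,
                                     min_match = 0.1, cap_bp = 50000) {
  out <- lapply(seq_len(nrow(loops)), function(i) {
    lp <- loops[i, , drop = FALSE]
    l1 <- lift_interval(lp$chrom, lp$start1, lp$end1, chains, min_match)
    l2 <- lift_interval(lp$chrom, lp$start2, lp$end2, chains, min_match)
    loop_is_conserved(lp, l1, l2, target_loops, cap_bp)
  })
  do.call(rbind, out)
}

#' Conservation test for TAD boundary CTCF motifs
#'
#' Each source boundary CTCF motif is lifted; it is conserved when the
#' lifted motif midpoint lies within `max_dist` of any target boundary CTCF
#' motif midpoint on the same chromosome. Unliftable motifs are excluded
#' from conservation denominators by their label.
#'
#' @param boundary_motifs data.frame with id, chrom, start, end (source
#'   boundary CTCF motifs)
#' @param chains chains from source to target assembly
#' @param target_motifs data.frame of target boundary CTCF motifs
#' @param min_match liftOver match rate (default 0.1)
#' @param max_dist distance threshold in bp (default 50000)
#' @return data.frame: structure_id, label, matched_target_id, distance_bp
#' @export
classify_boundaries_orthology <- function(boundary_motifs, chains, target_motifs,
                                          min_match = 0.1, max_dist = 50000) {
  out <- lapply(seq_len(nrow(boundary_motifs)), function(i) {
    b <- boundary_motifs[i, , drop = FALSE]
    lf <- lift_interval(b$chrom, b$start, b$end, chains, min_match)
    if (lf$status != "mapped")
      return(data.frame(structure_id = b$id, label = "unliftable",
                        matched_target_id = NA_character_,
                        distance_bp = NA_real_, stringsAsFactors = FALSE))
    m <- interval_midpoint(lf$target$start, lf$target$end)
    tg <- target_motifs[target_motifs$chrom == lf$target$chrom, , drop = FALSE]
    if (nrow(tg) > 0) {
      d <- abs(m - interval_midpoint(tg$start, tg$end))
      j <- which.min(d)
      if (d[j] <= max_dist)
        return(data.frame(structure_id = b$id, label = "conserved",
                          matched_target_id = tg$id[j], distance_bp = d[j],
                          stringsAsFactors = FALSE))
    }
    data.frame(structure_id = b$id, label = "lineage_specific",
               matched_target_id = NA_character_, distance_bp = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-tabulate repeat origin against conservation
#'
#' Joins structure origin labels with orthology labels on structure_id and
#' tabulates {TE-derived, non-TE} x {conserved, lineage-specific} with
#' counts and within-column percents, plus a subfamily breakdown of the
#' TE-derived structures per orthology label. Unliftable structures are
#' excluded from the table.
#'
#' @param origins data.frame from [classify_structures()] (with `label`,
#'   `te_only`, `repeat_subfamily`)
#' @param orthology data.frame from [classify_loops_orthology()] or
#'   [classify_boundaries_orthology()]
#' @return list(table = counts/percents data.frame, subfamily = data.frame)
#' @export
cross_tabulate <- function(origins, orthology) {
  orphans <- c(setdiff(origins$structure_id, orthology$structure_id),
               setdiff(orthology$structure_id, origins$structure_id))
  if (length(orphans) > 0)
    stop_fmt("cross_tabulate: unmatched structure ids: %s",
             paste(utils::head(orphans, 5), collapse = ", "))
  df <- merge(origins, orthology, by = "structure_id",
              suffixes = c("_origin", "_orth"))
  df <- df[df$label_orth %in% c("conserved", "lineage_specific"), , drop = FALSE]
  df$te_derived <- df$label_origin == "RE_derived" & df$te_only
  grid <- expand.grid(origin = c("TE_derived", "non_TE"),
                      orthology = c("conserved", "lineage_specific"),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(o, k) {
    sum((df$te_derived == (o == "TE_derived")) & df$label_orth == k)
  }, grid$origin, grid$orthology)
  tot <- tapply(grid$count, grid$orthology, sum)
  grid$percent_of_column <- ifelse(tot[grid$orthology] > 0,
                                   100 * grid$count / tot[grid$orthology], 0)
  te <- df[df$te_derived, , drop = FALSE]
  sub <- if (nrow(te) > 0) {
    agg <- stats::aggregate(list(count = te$structure_id),
                            by = list(orthology = te$label_orth,
                                      subfamily = te$repeat_subfamily),
                            FUN = length)
    agg[order(agg$orthology, -agg$count), , drop = FALSE]
  } else {
    data.frame(orthology = character(), subfamily = character(),
               count = integer())
  }
  rownames(sub) <- NULL
  list(table = grid, subfamily = sub)
}
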