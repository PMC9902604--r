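# End-to-end orchestration: motif assignment, repeat attribution,
# orthology, function, candidate selection and contact statistics from one
# declarative configuration, with TSV reports and provenance headers.

#' Default numeric thresholds used throughout the pipeline
#'
#' overlap_bp: motif/repeat overlap for RE-derived calls (10 bp rule);
#' boundary_flank: half-window for standardized TAD borders (+/-5 kb);
#' boundary_motif_flank: half-window for boundary CTCF motifs used in
#' conservation tests (40 kb boundary region); function_window: ChromHMM
#' distance window (10 kb); ctcf_exclusion_window: active-CTCF isolation
#' window for candidates (15 kb); cap_bp: conservation distance cap
#' (50 kb); min_match: liftOver match rate (0.1); min_long_range: long-
#' range contact cutoff (>30 kb); min_score_frac: PWM scan threshold as a
#' fraction of the maximum attainable score; anchor_slop: bp added around
#' anchors before scanning.
#' @export
DEFAULT_THRESHOLDS <- list(
  overlap_bp = 10, boundary_flank = 5000, boundary_motif_flank = 20000,
  function_window = 10000, ctcf_exclusion_window = 15000, cap_bp = 50000,
  min_match = 0.1, min_long_range = 30000, min_score_frac = 0.8,
  anchor_slop = 0)

#' Build a pipeline configuration from a synthetic dataset directory
#'
#' Points every input path at the files written by
#' [write_synthetic_dataset()] and loads the contact-region spec from the
#' manifest.
#'
#' @param dir dataset directory
#' @param thresholds threshold list (see [DEFAULT_THRESHOLDS]); partial
#'   overrides are merged over the defaults
#' @param seed seed for the shuffle null
#' @return a pipeline configuration list
#' @export
pipeline_config_from_dir <- function(dir, thresholds = list(), seed = 1) {
  p <- function(...) file.path(dir, ...)
  man <- yaml::read_yaml(p("manifest.yaml"))
  species <- lapply(c(A = "A", B = "B"), function(sp) {
    list(genome = p(sprintf("genome_%s.fa", sp)),
         chrom_sizes = p(sprintf("%s.chrom.sizes", sp)),
         loops = p(sprintf("loops_%s.bedpe", sp)),
         tads = p(sprintf("tads_%s.bed", sp)),
         repeats = p(sprintf("rmsk_%s.out", sp)),
         ctcf_peaks = p(sprintf("ctcf_%s.narrowPeak", sp)),
         p300_peaks = p(sprintf("p300_%s.narrowPeak", sp)),
         chromhmm = p(sprintf("chromhmm_%s.bed", sp)))
  })
  list(species = species,
       chains = list(a_to_b = p("aToB.chain"), b_to_a = p("bToA.chain")),
       pwm = p("ctcf_pwm.jaspar"),
       genehancer = p("genehancer_A.tsv"),
       contacts = list(
         wt = p("contacts_wt.coo.tsv"), ko = p("contacts_ko.coo.tsv"),
         chrom = man$contact_region$chrom, start = man$contact_region$start,
         end = man$contact_region$end, bin_size = man$config$bin_size,
         roi = range(c(unlist(man$partitions$a), unlist(man$partitions$b))),
         partition_a = unlist(man$partitions$a),
         partition_b = unlist(man$partitions$b)),
       thresholds = utils::modifyList(DEFAULT_THRESHOLDS, thresholds),
       te_classes = DEFAULT_TE_CLASSES,
       seed = seed)
}

# Assign ChIP-gated CTCF sites to every unique loop anchor and TAD
# boundary window of one species.
pipeline_assign_sites <- function(sp_data, pwm, thr) {
  min_score <- thr$min_score_frac * pwm_max_score(pwm)
  genome <- sp_data$genome
  peaks <- sp_data$ctcf_peaks
  loops <- sp_data$loops
  sites <- NULL
  for (i in seq_len(nrow(loops))) {
    for (side in 1:2) {
      st <- if (side == 1) loops$start1[i] else loops$start2[i]
      en <- if (side == 1) loops$end1[i] else loops$end2[i]
      anchor <- list(chrom = loops$chrom[i],
                     start = max(0, st - thr$anchor_slop),
                     end = en + thr$anchor_slop)
      hits <- scan_region(anchor$chrom, anchor$start, anchor$end, genome,
                          pwm, min_score)
      best <- assign_anchor_ctcf(anchor, hits, peaks)
      if (!is.null(best))
        sites <- rbind(sites, data.frame(
          structure_id = loops$id[i], side = side, role = "loop_anchor",
          best, stringsAsFactors = FALSE))
    }
  }
  bnd <- sp_data$boundaries
  for (i in seq_len(nrow(bnd))) {
    w <- standardize_tad_boundary(bnd$point[i], bnd$chrom[i],
                                  sp_data$assembly, thr$boundary_flank)
    anchor <- list(chrom = w$chrom, start = w$window_start, end = w$window_end)
    hits <- scan_region(anchor$chrom, anchor$start, anchor$end, genome,
                        pwm, min_score)
    best <- assign_anchor_ctcf(anchor, hits, peaks)
    if (!is.null(best))
      sites <- rbind(sites, data.frame(
        structure_id = bnd$id[i], side = 1, role = "tad_boundary",
        best, stringsAsFactors = FALSE))
  }
  sites
}

# Unique TAD border points (interval edges) from a TAD call table.
tad_boundary_points <- function(tads) {
  pts <- unique(rbind(data.frame(chrom = tads$chrom, point = tads$start),
                      data.frame(chrom = tads$chrom, point = tads$end)))
  pts <- pts[order(pts$chrom, pts$point), ]
  pts$id <- sprintf("tadb_%s_%d", pts$chrom, as.integer(pts$point))
  rownames(pts) <- NULL
  pts
}

read_species_inputs <- function(paths, name) {
  assembly <- read_chrom_sizes(paths$chrom_sizes, name)
  loops <- read_bedpe_loops(paths$loops, assembly)
  tads <- read_bed(paths$tads, assembly)
  list(assembly = assembly,
       genome = read_fasta_genome(paths$genome),
       loops = loops, tads = tads,
       boundaries = tad_boundary_points(tads),
       repeats = read_repeatmasker_out(paths$repeats, assembly),
       ctcf_peaks = read_narrowpeak(paths$ctcf_peaks, "CTCF", assembly),
       p300_peaks = read_narrowpeak(paths$p300_peaks, "p300", assembly),
       chromhmm = read_chromhmm_bed(paths$chromhmm, assembly))
}

#' Run the full attribution / orthology / function / candidate / contact
#' pipeline
#'
#' Stages run in dependency order; the contact stage is skipped with a
#' notice when no contact matrices are configured, and orthology when no
#' chains are configured. Outputs are deterministic given inputs and seed.
#'
#' @param config configuration list (see [pipeline_config_from_dir()])
#' @param out_dir optional directory for TSV reports
#' @param n_shuffles shuffles for the random-expectation null (0 skips it)
#' @return nested result list (per-species sites/classifications/summaries,
#'   orthology tables, function tables, candidates, contact reports)
#' @export
run_pipeline <- function(config, out_dir = NULL, n_shuffles = 200) {
  thr <- utils::modifyList(DEFAULT_THRESHOLDS, config$thresholds %||% list())
  pwm <- read_jaspar_pwm(config$pwm)
  res <- list(config = config, thresholds = thr)

  sp_names <- names(config$species)
  data <- lapply(sp_names, function(sp)
    read_species_inputs(config$species[[sp]], sp))
  names(data) <- sp_names

  for (sp in sp_names) {
    d <- data[[sp]]
    sites <- pipeline_assign_sites(d, pwm, thr)
    sites <- classify_ctcf_origins(sites, d$repeats, thr$overlap_bp)
    anchor_sites <- sites[sites$role == "loop_anchor", , drop = FALSE]
    boundary_sites <- sites[sites$role == "tad_boundary", , drop = FALSE]
    loop_cls <- classify_structures(d$loops$id, "loop", anchor_sites,
                                    config$te_classes %||% DEFAULT_TE_CLASSES)
    # TADs: one side per flanking border
    tad_sites <- NULL
    bkey <- stats::setNames(boundary_sites$structure_id,
                            boundary_sites$structure_id)
    for (i in seq_len(nrow(d$tads))) {
      for (side in 1:2) {
        pt <- if (side == 1) d$tads$start[i] else d$tads$end[i]
        bid <- sprintf("tadb_%s_%d", d$tads$chrom[i], as.integer(pt))
        row <- boundary_sites[boundary_sites$structure_id == bid, , drop = FALSE]
        if (nrow(row) > 0) {
          row$structure_id <- d$tads$name[i] %||%
            sprintf("tad_%s_%d", d$tads$chrom[i], as.integer(d$tads$start[i]))
          row$side <- side
          tad_sites <- rbind(tad_sites, row)
        }
      }
    }
    tad_ids <- d$tads$name %||% sprintf("tad_%s_%d", d$tads$chrom,
                                        as.integer(d$tads$start))
    tad_cls <- classify_structures(tad_ids, "tad",
                                   tad_sites %||% anchor_sites[0, ],
                                   config$te_classes %||% DEFAULT_TE_CLASSES)
    functions <- attribute_loop_functions(d$loops, d$chromhmm,
                                          thr$function_window)
    res$species[[sp]] <- list(
      sites = sites, anchor_sites = anchor_sites,
      boundary_sites = boundary_sites,
      loop_classifications = loop_cls, tad_classifications = tad_cls,
      re_fraction_anchors = re_fraction(anchor_sites),
      re_fraction_boundaries = re_fraction(boundary_sites),
      taxonomy = list(
        class_re = summarize_taxonomy(anchor_sites, "class"),
        class_te = summarize_taxonomy(anchor_sites, "class", te_only = TRUE),
        family_te = summarize_taxonomy(anchor_sites, "family", te_only = TRUE),
        subfamily_te = summarize_taxonomy(anchor_sites, "subfamily",
                                          te_only = TRUE)),
      functions = functions)
    if (n_shuffles > 0)
      res$species[[sp]]$shuffle_null <-
        shuffle_null(anchor_sites, d$repeats, d$assembly,
                     n_shuffles = max(100, n_shuffles),
                     seed = (config$seed %||% 1) + 100)
  }

  if (!is.null(config$chains) && length(sp_names) == 2) {
    ch_ab <- read_chain(config$chains$a_to_b)
    ch_ba <- read_chain(config$chains$b_to_a)
    A <- sp_names[1]; B <- sp_names[2]
    res$orthology <- list()
    res$orthology[[paste0(A, "_vs_", B)]] <- classify_loops_orthology(
      data[[A]]$loops, ch_ab, data[[B]]$loops, thr$min_match, thr$cap_bp)
    res$orthology[[paste0(B, "_vs_", A)]] <- classify_loops_orthology(
      data[[B]]$loops, ch_ba, data[[A]]$loops, thr$min_match, thr$cap_bp)
    bm_a <- res$species[[A]]$boundary_sites
    bm_b <- res$species[[B]]$boundary_sites
    bm_a$id <- bm_a$structure_id; bm_b$id <- bm_b$structure_id
    res$orthology$boundaries <- classify_boundaries_orthology(
      bm_a, ch_ab, bm_b, thr$min_match, thr$cap_bp)
    res$cross_tab <- cross_tabulate(
      res$species[[A]]$loop_classifications,
      res$orthology[[paste0(A, "_vs_", B)]])
    gh <- if (!is.null(config$genehancer) && file.exists(config$genehancer))
      utils::read.table(config$genehancer, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE) else NULL
    res$candidates <- select_crispr_candidates(
      data[[A]]$loops, res$species[[A]]$anchor_sites,
      res$orthology[[paste0(A, "_vs_", B)]], res$species[[A]]$functions,
      data[[A]]$ctcf_peaks, data[[A]]$p300_peaks, gh,
      thr$ctcf_exclusion_window)
  } else {
    message("orthology stage skipped: no chains configured")
  }

  if (!is.null(config$contacts)) {
    cc <- config$contacts
    wt <- read_contact_coo(cc$wt, cc$chrom, cc$start, cc$end, cc$bin_size)
    ko <- read_contact_coo(cc$ko, cc$chrom, cc$start, cc$end, cc$bin_size)
    kr <- kr_balance(wt)
    lr <- function(cm) long_range_fraction(cm, cc$roi, cc$partition_a,
                                           cc$partition_b, thr$min_long_range)
    cand_loop <- NULL
    if (!is.null(res$candidates)) {
      ok <- res$candidates$loop_id[which(res$candidates$passed)]
      if (length(ok) > 0) {
        lpA <- data[[sp_names[1]]]$loops
        cand_loop <- lpA[lpA$id == ok[1], , drop = FALSE]
      }
    }
    res$contacts <- list(
      wt = wt, ko = ko, kr = kr,
      long_range_wt = lr(wt), long_range_ko = lr(ko),
      focal_wt = if (!is.null(cand_loop)) focal_enrichment(wt, cand_loop) else NULL,
      focal_ko = if (!is.null(cand_loop)) focal_enrichment(ko, cand_loop) else NULL,
      virtual_4c_wt = if (!is.null(cand_loop))
        virtual_4c(wt, list(chrom = cand_loop$chrom,
                            start = cand_loop$start2,
                            end = cand_loop$end2)) else NULL)
  } else {
    message("contact stage skipped: no matrices configured")
  }

  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

#' Write the pipeline's TSV report bundle
#' @param res result of [run_pipeline()]
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(package = sprintf("teloop %s",
                             as.character(utils::packageVersion("teloop"))),
           config_md5 = config_hash(res$config),
           thresholds = paste(names(res$thresholds), unlist(res$thresholds),
                              sep = "=", collapse = ";"))
  for (sp in names(res$species)) {
    s <- res$species[[sp]]
    write_tsv_report(s$sites, file.path(out_dir, sprintf("sites_%s.tsv", sp)), hdr)
    write_tsv_report(s$loop_classifications,
                     file.path(out_dir, sprintf("loop_classifications_%s.tsv", sp)), hdr)
    write_tsv_report(s$tad_classifications,
                     file.path(out_dir, sprintf("tad_classifications_%s.tsv", sp)), hdr)
    write_tsv_report(s$functions,
                     file.path(out_dir, sprintf("loop_functions_%s.tsv", sp)), hdr)
    for (nm in names(s$taxonomy))
      write_tsv_report(s$taxonomy[[nm]],
                       file.path(out_dir, sprintf("taxonomy_%s_%s.tsv", nm, sp)), hdr)
    fr <- s$re_fraction_anchors
    write_tsv_report(
      data.frame(metric = c("re_fraction_anchors_pct", "re_fraction_boundaries_pct"),
                 value = c(as.numeric(fr), as.numeric(s$re_fraction_boundaries)),
                 numerator = c(attr(fr, "numerator"),
                               attr(s$re_fraction_boundaries, "numerator")),
                 denominator = c(attr(fr, "denominator"),
                                 attr(s$re_fraction_boundaries, "denominator"))),
      file.path(out_dir, sprintf("re_fraction_%s.tsv", sp)), hdr)
  }
  for (nm in names(res$orthology))
    write_tsv_report(res$orthology[[nm]],
                     file.path(out_dir, sprintf("orthology_%s.tsv", nm)), hdr)
  if (!is.null(res$cross_tab)) {
    write_tsv_report(res$cross_tab$table, file.path(out_dir, "cross_tab.tsv"), hdr)
    write_tsv_report(res$cross_tab$subfamily,
                     file.path(out_dir, "cross_tab_subfamily.tsv"), hdr)
  }
  if (!is.null(res$candidates))
    write_tsv_report(res$candidates, file.path(out_dir, "candidates.tsv"), hdr)
  if (!is.null(res$contacts)) {
    lrw <- res$contacts$long_range_wt; lrk <- res$contacts$long_range_ko
    write_tsv_report(
      data.frame(condition = c("WT", "KO"),
                 intra_a_pct = c(lrw$intra_a_pct, lrk$intra_a_pct),
                 inter_ab_pct = c(lrw$inter_ab_pct, lrk$inter_ab_pct),
                 focal_enrichment = c(res$contacts$focal_wt %||% NA,
                                      res$contacts$focal_ko %||% NA)),
      file.path(out_dir, "contact_report.tsv"),
      c(hdr, region = sprintf("%s:%d-%d (partitions %s / %s)",
                              lrw$region_of_interest[1] %||% NA,
                              0, 0, paste(lrw$partition_a, collapse = "-"),
                              paste(lrw$partition_b, collapse = "-"))))
  }
  invisible(out_dir)
}
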