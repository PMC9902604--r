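# Deterministic two-species synthetic dataset with planted ground truth.
#
# Species B is derived from species A by one 20 kb deletion and one 30 kb
# insertion per chromosome, described exactly by a chain file. Each
# chromosome carries three loop zones: a conserved zone (loops planted at
# identical coordinates in both species), an A-specific zone and a
# B-specific zone (loops present in one species only, in aligned sequence
# so they lift but find no partner). CTCF motifs are planted as exact
# consensus at anchor and TAD-boundary positions; a planted fraction of
# them is embedded inside a TE with full-motif overlap. ChromHMM-like
# state tracks, ChIP peaks, a GeneHancer-style pair list and Poisson
# contact maps with distance decay, TAD blocks and focal loop peaks
# complete the dataset. Everything is reproducible from the config seed.

SIM_CONSENSUS <- "CCACCAGGTGGCAGCATTA"   # fixed 19-mer, non-palindromic

# slot pairing used to turn 30 anchor slots into 15 loops of varied span
SIM_PAIRING <- list(c(0, 3), c(1, 5), c(2, 8), c(4, 9), c(6, 12), c(7, 14),
                    c(10, 17), c(11, 19), c(13, 21), c(15, 22), c(16, 24),
                    c(18, 26), c(20, 27), c(23, 28), c(25, 29))

SIM_TAXA <- data.frame(
  class_name = c("SINE", "SINE", "SINE", "LINE", "LINE", "LINE",
                 "LTR", "LTR", "LTR", "DNA"),
  family = c("Alu", "Alu", "MIR", "L1", "L1", "L2",
             "ERVL-MaLR", "ERV1", "ERVK", "hAT-Charlie"),
  subfamily = c("AluY", "AluSx", "MIRb", "L1MC1", "L1PA3", "L2a",
                "MLT1H1", "MER52C", "LTR13", "MER20"),
  weight = c(0.15, 0.10, 0.15, 0.10, 0.10, 0.10, 0.10, 0.05, 0.05, 0.10),
  stringsAsFactors = FALSE)

#' Configuration for the synthetic two-species dataset
#'
#' Defaults define the study conditions: 2 chromosomes of 2 Mb per species,
#' 5 kb bins, 60 loops and 12 TADs per species, ~200 TEs per species, 30%
#' of anchor CTCF sites RE-derived, 50% of loops conserved across species,
#' 40% of loops enhancer-promoter and 10% repressive.
#'
#' @param seed RNG seed governing every random choice
#' @param n_chromosomes number of chromosomes per species
#' @param chrom_length chromosome length in bp (species A)
#' @param bin_size contact-map bin size in bp
#' @param re_derived_fraction fraction of loop-anchor (and boundary) CTCF
#'   sites embedded in a TE with full-motif overlap
#' @param ep_fraction fraction of loops planted as enhancer-promoter
#' @param repressive_fraction fraction of loops planted as repressive
#' @param n_te total TE copies per species (anchor TEs + lineage-block TEs
#'   + background decoys)
#' @param anchor_width loop anchor / call resolution in bp
#' @param te_length decoy/anchor TE length in bp
#' @param contact_scale,decay_alpha,decay_d0 contact model: mean(i,j) =
#'   scale * (1 + d/d0)^(-alpha) * tad_factor * loop_factor
#' @param tad_factor within-TAD contact boost
#' @param loop_factor loop-pixel contact boost (3x3 neighborhood)
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1, n_chromosomes = 2, chrom_length = 2e6,
                       bin_size = 5000, re_derived_fraction = 0.3,
                       ep_fraction = 0.4, repressive_fraction = 0.1,
                       n_te = 200, anchor_width = 5000, te_length = 400,
                       contact_scale = 50, decay_alpha = 1,
                       decay_d0 = 20000, tad_factor = 3, loop_factor = 4) {
  stopifnot(chrom_length >= 2e6, n_chromosomes >= 1,
            re_derived_fraction >= 0, re_derived_fraction <= 1,
            ep_fraction + repressive_fraction <= 1,
            chrom_length %% bin_size == 0)
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, bin_size = bin_size,
                 re_derived_fraction = re_derived_fraction,
                 ep_fraction = ep_fraction,
                 repressive_fraction = repressive_fraction,
                 n_te = n_te, anchor_width = anchor_width,
                 te_length = te_length, contact_scale = contact_scale,
                 decay_alpha = decay_alpha, decay_d0 = decay_d0,
                 tad_factor = tad_factor, loop_factor = loop_factor,
                 motif_width = nchar(SIM_CONSENSUS)),
            class = "sim_config")
}

# Fixed per-chromosome geometry (coordinates in species A unless noted).
sim_layout <- function(config) {
  snap <- function(x) round(x / 5000) * 5000
  cons_slots <- 60000 + 24000 * (0:29)
  specA_slots <- 840000 + 19000 * (0:29)
  specB_slots <- 1430000 + 19000 * (0:29)      # B coordinates
  list(
    cons_slots = cons_slots,
    specA_slots = specA_slots,
    specB_slots = specB_slots,
    del_start = 800000, del_len = 20000,        # A-only block
    ins_point_a = 1410000, ins_len = 30000,     # B gains 30 kb here
    ins_start_b = 1390000,
    cons_bounds = snap(cons_slots[c(11, 15, 19, 23)] + 12000),
    specA_bounds = snap(specA_slots[c(7, 12, 17, 22)] + 12000),
    specB_bounds = snap(specB_slots[c(7, 12, 17, 22)] + 12000),  # B coords
    candidate_pair_index = 7,                   # pairing entry c(10, 17)
    motif_offset = 2000                         # motif start within anchor
  )
}

#' Generate the two related genomes, their assemblies and the chain files
#'
#' Species B is species A with, per chromosome, a 20 kb deletion and a
#' 30 kb insertion; the returned chains describe the correspondence
#' exactly in both directions.
#'
#' @param config a `sim_config`
#' @return list with assemblies (A/B), genome_chars (per-species list of
#'   per-chromosome character vectors), chains (a_to_b / b_to_a)
#' @export
generate_genome_pair <- function(config) {
  lay <- sim_layout(config)
  L <- config$chrom_length
  LB <- L - lay$del_len + lay$ins_len
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genomes <- list(A = list(), B = list())
  chains_ab <- list()
  with_seed(config$seed + 1, {
    for (ci in seq_along(chroms)) {
      a <- sample(BASES, L, replace = TRUE)
      ins <- sample(BASES, lay$ins_len, replace = TRUE)
      b <- c(a[seq_len(lay$del_start)],
             a[(lay$del_start + lay$del_len + 1):lay$ins_point_a],
             ins,
             a[(lay$ins_point_a + 1):L])
      stopifnot(length(b) == LB)
      genomes$A[[chroms[ci]]] <- a
      genomes$B[[chroms[ci]]] <- b
      blocks <- rbind(c(lay$del_start, lay$del_len, 0),
                      c(lay$ins_point_a - lay$del_start - lay$del_len, 0,
                        lay$ins_len),
                      c(L - lay$ins_point_a, 0, 0))
      colnames(blocks) <- c("size", "source_gap", "target_gap")
      chains_ab[[ci]] <- list(
        score = 1e6 - ci, id = sprintf("%s_aToB", chroms[ci]),
        source = list(chrom = chroms[ci], size = L, strand = "+",
                      start = 0, end = L),
        target = list(chrom = chroms[ci], size = LB, strand = "+",
                      start = 0, end = LB),
        blocks = blocks)
    }
  })
  list(assemblies = list(
         A = genome_assembly("simA", stats::setNames(rep(L, length(chroms)), chroms)),
         B = genome_assembly("simB", stats::setNames(rep(LB, length(chroms)), chroms))),
       genome_chars = genomes,
       chains = list(a_to_b = chains_ab,
                     b_to_a = lapply(chains_ab, chain_invert)))
}

# Build the structural plan: anchor slots paired into loops, TAD
# boundaries, and the per-site motif table for both species.
sim_plan_structures <- function(config) {
  lay <- sim_layout(config)
  W <- config$motif_width
  aw <- config$anchor_width
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cand_slot <- lay$specA_slots[SIM_PAIRING[[lay$candidate_pair_index]][2] + 1]
  cand_motif <- cand_slot + lay$motif_offset
  cand_strand <- if (((cand_slot / 1000) %% 2) == 0) "+" else "-"
  mk_loops <- function(slots, chrom, category) {
    do.call(rbind, lapply(seq_along(SIM_PAIRING), function(k) {
      p <- SIM_PAIRING[[k]]
      a1 <- slots[p[1] + 1]; a2 <- slots[p[2] + 1]
      data.frame(chrom = chrom, start1 = a1, end1 = a1 + aw,
                 start2 = a2, end2 = a2 + aw, category = category,
                 pair_index = k, stringsAsFactors = FALSE)
    }))
  }
  loops <- list(A = NULL, B = NULL)
  bounds <- list(A = NULL, B = NULL)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    cons <- mk_loops(lay$cons_slots, ch, "conserved")
    specA <- mk_loops(lay$specA_slots, ch, "specific")
    specB <- mk_loops(lay$specB_slots, ch, "specific")
    loops$A <- rbind(loops$A, cons, specA)
    loops$B <- rbind(loops$B, cons, specB)
    sb_a <- lay$specA_bounds
    if (ci == 1) {
      # candidate anchor motif doubles as a TAD boundary on chr1
      sb_a <- c(sb_a[1:2], cand_motif, cand_motif + 105000)
    }
    bounds$A <- rbind(bounds$A,
                      data.frame(chrom = ch, point = c(lay$cons_bounds, sb_a),
                                 category = rep(c("conserved", "specific"),
                                                each = 4),
                                 stringsAsFactors = FALSE))
    bounds$B <- rbind(bounds$B,
                      data.frame(chrom = ch,
                                 point = c(lay$cons_bounds, lay$specB_bounds),
                                 category = rep(c("conserved", "specific"),
                                                each = 4),
                                 stringsAsFactors = FALSE))
  }
  for (sp in c("A", "B")) {
    loops[[sp]]$id <- loop_id_from_coords(loops[[sp]]$chrom, loops[[sp]]$start1,
                                          loops[[sp]]$end1, loops[[sp]]$start2,
                                          loops[[sp]]$end2)
    bounds[[sp]]$id <- sprintf("tadb_%s_%d", bounds[[sp]]$chrom,
                               as.integer(bounds[[sp]]$point))
  }
  # per-side motif sites for loops; strand alternates with slot parity
  mk_sites <- function(lp) {
    out <- NULL
    for (side in 1:2) {
      st <- if (side == 1) lp$start1 else lp$start2
      m <- st + lay$motif_offset
      out <- rbind(out, data.frame(
        structure_id = lp$id, side = side, role = "loop_anchor",
        chrom = lp$chrom, start = m, end = m + W,
        strand = ifelse(((st / 1000) %% 2) == 0, "+", "-"),
        category = lp$category, stringsAsFactors = FALSE))
    }
    out
  }
  sites <- list(A = mk_sites(loops$A), B = mk_sites(loops$B))
  for (sp in c("A", "B")) {
    b <- bounds[[sp]]
    # on chr1 of species A one boundary IS the candidate anchor motif
    cand_b <- sp == "A" & b$chrom == chroms[1] & b$point == cand_motif
    bsites <- data.frame(
      structure_id = b$id, side = 1, role = "tad_boundary",
      chrom = b$chrom, start = ifelse(cand_b, b$point, b$point - 9),
      end = ifelse(cand_b, b$point + W, b$point - 9 + W),
      strand = ifelse(cand_b, cand_strand, "+"),
      category = b$category, stringsAsFactors = FALSE)
    sites[[sp]] <- rbind(sites[[sp]], bsites)
  }
  list(loops = loops, bounds = bounds, sites = sites, layout = lay)
}

# Decide which sites are RE-derived (exactly the planted fraction of loop
# anchor sites per species; conserved sites share status across species),
# assign repeat taxonomy, and plant TEs + motifs into the sequences.
sim_assign_and_plant <- function(pair, plan, config) {
  W <- config$motif_width
  lay <- plan$layout
  cons_chars <- strsplit(SIM_CONSENSUS, "")[[1]]
  rc_chars <- strsplit(revcomp_string(SIM_CONSENSUS), "")[[1]]

  candidate_loop_id <- NULL
  la <- plan$loops$A
  cand <- la[la$chrom == "chr1" & la$category == "specific" &
               la$pair_index == lay$candidate_pair_index, ]
  candidate_loop_id <- cand$id

  sites <- plan$sites
  pick_re <- function(sp, inherit = NULL) {
    s <- sites[[sp]]
    la_idx <- which(s$role == "loop_anchor")
    n_re <- round(config$re_derived_fraction * length(la_idx))
    s$origin_truth <- "non_RE"
    if (!is.null(inherit)) {
      key <- paste(s$chrom, s$start, s$strand)
      s$origin_truth[key %in% inherit] <- "RE_derived"
      n_have <- sum(s$origin_truth[la_idx] == "RE_derived")
      pool <- la_idx[s$category[la_idx] == "specific" &
                       s$origin_truth[la_idx] != "RE_derived"]
      extra <- sample(pool, n_re - n_have)
      s$origin_truth[extra] <- "RE_derived"
    } else {
      chosen <- sample(la_idx, n_re)
      cand_idx <- which(s$structure_id == candidate_loop_id & s$side == 2)
      if (n_re > 0 && !(cand_idx %in% chosen)) {
        drop <- chosen[!(chosen %in% cand_idx)][1]
        chosen <- c(setdiff(chosen, drop), cand_idx)
      }
      s$origin_truth[chosen] <- "RE_derived"
    }
    # boundary sites: planted fraction too; the candidate-motif boundary
    # shares coordinates (and status) with the candidate anchor site
    tb_idx <- which(s$role == "tad_boundary")
    key_all <- paste(s$chrom, s$start, s$strand)
    shared <- tb_idx[key_all[tb_idx] %in%
                       key_all[la_idx][s$origin_truth[la_idx] == "RE_derived"]]
    s$origin_truth[shared] <- "RE_derived"
    n_re_b <- round(config$re_derived_fraction * length(tb_idx))
    if (!is.null(inherit)) {
      n_have <- sum(s$origin_truth[tb_idx] == "RE_derived")
      pool <- tb_idx[s$category[tb_idx] == "specific" &
                       s$origin_truth[tb_idx] != "RE_derived"]
    } else {
      n_have <- length(shared)
      pool <- setdiff(tb_idx, shared)
    }
    if (n_re_b > n_have) {
      extra <- sample(pool, n_re_b - n_have)
      s$origin_truth[extra] <- "RE_derived"
    }
    s
  }
  with_seed(config$seed + 2, {
    sites$A <- pick_re("A")
    sa <- sites$A
    cons_re_keys <- paste(sa$chrom, sa$start, sa$strand)[
      sa$category == "conserved" & sa$origin_truth == "RE_derived"]
    sites$B <- pick_re("B", inherit = cons_re_keys)
  })

  # taxonomy for RE sites: seeded draw; the candidate site is L1MC1 and two
  # non-candidate RE anchor sites per species are simple repeats (REs that
  # are not TEs)
  assign_taxa <- function(s, sp) {
    re_idx <- which(s$origin_truth == "RE_derived")
    s$repeat_class <- NA_character_
    s$repeat_family <- NA_character_
    s$repeat_subfamily <- NA_character_
    draw <- sample(nrow(SIM_TAXA), length(re_idx), replace = TRUE,
                   prob = SIM_TAXA$weight)
    s$repeat_class[re_idx] <- SIM_TAXA$class_name[draw]
    s$repeat_family[re_idx] <- SIM_TAXA$family[draw]
    s$repeat_subfamily[re_idx] <- SIM_TAXA$subfamily[draw]
    cand_idx <- re_idx[s$structure_id[re_idx] %in% candidate_loop_id &
                         s$side[re_idx] == 2]
    simple <- setdiff(re_idx[s$role[re_idx] == "loop_anchor"], cand_idx)
    simple <- utils::head(simple[order(s$chrom[simple], s$start[simple])], 2)
    s$repeat_class[simple] <- "Simple_repeat"
    s$repeat_family[simple] <- "Simple_repeat"
    s$repeat_subfamily[simple] <- "(TA)n"
    if (length(cand_idx) > 0) {
      s$repeat_class[cand_idx] <- "LINE"
      s$repeat_family[cand_idx] <- "L1"
      s$repeat_subfamily[cand_idx] <- "L1MC1"
    }
    # sites sharing coordinates (the candidate anchor doubling as a TAD
    # boundary) share one repeat copy and therefore one taxonomy
    key <- paste(s$chrom, s$start, s$strand)
    first <- match(key, key)
    for (col in c("repeat_class", "repeat_family", "repeat_subfamily"))
      s[[col]] <- s[[col]][first]
    s
  }
  with_seed(config$seed + 3, {
    sites$A <- assign_taxa(sites$A, "A")
    sites$B <- assign_taxa(sites$B, "B")
    sb <- sites$B
    key_b <- paste(sb$chrom, sb$start, sb$strand)
    sa <- sites$A
    key_a <- paste(sa$chrom, sa$start, sa$strand)
    shared <- match(key_b, key_a)
    take <- !is.na(shared) & sb$origin_truth == "RE_derived"
    for (col in c("repeat_class", "repeat_family", "repeat_subfamily"))
      sites$B[[col]][take] <- sa[[col]][shared[take]]
  })

  # plant motifs into sequences and build the repeat tables
  genomes <- pair$genome_chars
  plant <- function(sp) {
    s <- dedupe_sites(sites[[sp]])
    for (i in seq_len(nrow(s))) {
      chars <- if (s$strand[i] == "+") cons_chars else rc_chars
      genomes[[sp]][[s$chrom[i]]][(s$start[i] + 1):(s$start[i] + W)] <<- chars
    }
    s
  }
  uA <- plant("A"); uB <- plant("B")
  # species B shares the conserved zone sequence with A, but B's sequence
  # was derived before planting; replant everything (conserved coordinates
  # are identical in both species so the motifs coincide)
  te_from_sites <- function(u) {
    re <- u[u$origin_truth == "RE_derived", , drop = FALSE]
    if (nrow(re) == 0)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        subfamily = character(), family = character(),
                        class_name = character(), score = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(chrom = re$chrom, start = re$start - 150,
               end = re$start - 150 + config$te_length,
               strand = re$strand, subfamily = re$repeat_subfamily,
               family = re$repeat_family, class_name = re$repeat_class,
               score = 1000, stringsAsFactors = FALSE)
  }
  reps <- list(A = te_from_sites(uA), B = te_from_sites(uB))
  # lineage-specific TEs inside each species' unique blocks
  lay <- plan$layout
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  lineage_taxa <- SIM_TAXA[SIM_TAXA$subfamily %in% c("AluY", "L1PA3", "MER20"), ]
  for (ch in chroms) {
    offs <- c(2000, 8000, 14000)
    reps$A <- rbind(reps$A, data.frame(
      chrom = ch, start = lay$del_start + offs,
      end = lay$del_start + offs + config$te_length, strand = "+",
      subfamily = lineage_taxa$subfamily, family = lineage_taxa$family,
      class_name = lineage_taxa$class_name, score = 1000,
      stringsAsFactors = FALSE))
    reps$B <- rbind(reps$B, data.frame(
      chrom = ch, start = lay$ins_start_b + offs,
      end = lay$ins_start_b + offs + config$te_length, strand = "+",
      subfamily = lineage_taxa$subfamily, family = lineage_taxa$family,
      class_name = lineage_taxa$class_name, score = 1000,
      stringsAsFactors = FALSE))
  }
  # background decoy TEs, kept clear of every planted motif
  add_decoys <- function(sp, seed_off) {
    u <- dedupe_sites(sites[[sp]])
    asm <- pair$assemblies[[sp]]
    n_decoy <- max(0, config$n_te - nrow(reps[[sp]]))
    placed <- reps[[sp]][, c("chrom", "start", "end")]
    out <- NULL
    with_seed(config$seed + seed_off, {
      taxa_draw <- sample(nrow(SIM_TAXA), n_decoy, replace = TRUE,
                          prob = SIM_TAXA$weight)
      k <- 0; tries <- 0
      while (k < n_decoy && tries < n_decoy * 200) {
        tries <- tries + 1
        ch <- sample(names(asm$chrom_sizes), 1)
        st <- floor(stats::runif(1, 0,
                                 asm$chrom_sizes[[ch]] - config$te_length))
        en <- st + config$te_length
        msk <- u$chrom == ch
        if (any(interval_gap_bp(st, en, u$start[msk], u$end[msk]) < 500))
          next
        pk <- placed$chrom == ch
        if (any(interval_gap_bp(st, en, placed$start[pk], placed$end[pk]) < 100))
          next
        k <- k + 1
        tx <- SIM_TAXA[taxa_draw[k], ]
        row <- data.frame(chrom = ch, start = st, end = en, strand = "+",
                          subfamily = tx$subfamily, family = tx$family,
                          class_name = tx$class_name, score = 1000,
                          stringsAsFactors = FALSE)
        out <- rbind(out, row)
        placed <- rbind(placed, row[, c("chrom", "start", "end")])
      }
      if (k < n_decoy)
        stop_fmt("TE placement failed after max rejections; lower n_te or density")
    })
    out
  }
  reps$A <- rbind(reps$A, add_decoys("A", 4))
  reps$B <- rbind(reps$B, add_decoys("B", 5))
  for (sp in c("A", "B")) {
    reps[[sp]] <- reps[[sp]][order(reps[[sp]]$chrom, reps[[sp]]$start), ]
    rownames(reps[[sp]]) <- NULL
  }
  list(sites = sites, repeats = reps, genome_chars = genomes,
       candidate_loop_id = candidate_loop_id)
}

#' @rdname generate_synthetic_dataset
#' @param pair output of [generate_genome_pair()]
#' @param config a `sim_config`
#' @export
plant_tes_and_motifs <- function(pair, config) {
  plan <- sim_plan_structures(config)
  planted <- sim_assign_and_plant(pair, plan, config)
  c(pair[c("assemblies", "chains")], planted["genome_chars"], planted["sites"],
    list(repeats = planted$repeats, plan = plan,
         candidate_loop_id = planted$candidate_loop_id))
}

# Assign function labels, plant ChromHMM states / ChIP peaks / p300 /
# GeneHancer evidence, and finalize loop & TAD tables with ground truth.
sim_states_and_peaks <- function(ds, config) {
  W <- config$motif_width
  lay <- ds$plan$layout
  loops <- ds$plan$loops
  bounds <- ds$plan$bounds
  ep_states <- c("EnhA1", "Enh", "EnhG")
  out_states <- list(); out_truth <- list()
  for (sp in c("A", "B")) {
    lp <- loops[[sp]]
    n <- nrow(lp)
    n_ep <- round(config$ep_fraction * n)
    n_rep <- round(config$repressive_fraction * n)
    with_seed(config$seed + ifelse(sp == "A", 6, 7), {
      perm <- sample(n)
      cand_row <- which(lp$id == ds$candidate_loop_id)
      if (sp == "A" && length(cand_row) == 1)
        perm <- c(cand_row, setdiff(perm, cand_row))  # candidate is always E-P
      ep_idx <- perm[seq_len(n_ep)]
      rep_idx <- perm[n_ep + seq_len(n_rep)]
    })
    lp$function_truth <- "unannotated"
    lp$function_truth[ep_idx] <- "enhancer_promoter"
    lp$function_truth[rep_idx] <- "repressive"
    segs <- NULL
    lp$ep_subclass_truth <- "none"
    for (k in seq_len(n)) {
      if (lp$function_truth[k] == "unannotated") next
      a1 <- lp$start1[k]; a2 <- lp$start2[k]
      prom_state <- if (k %% 3 == 0) "TssAFlnk" else "TssA"
      if (sp == "A" && lp$id[k] == ds$candidate_loop_id) prom_state <- "TssA"
      prom_seg <- if (lp$category[k] == "conserved")
        c(a1 - 8600, a1 - 8000) else c(a1 + 200, a1 + 800)
      opp_state <- if (lp$function_truth[k] == "repressive") "ReprPC"
      else if (k %% 2 == 0) "EnhA1" else ep_states[2 + (k %% 4 == 1)]
      if (sp == "A" && lp$id[k] == ds$candidate_loop_id) opp_state <- "EnhA1"
      segs <- rbind(segs,
                    data.frame(chrom = lp$chrom[k], start = prom_seg[1],
                               end = prom_seg[2], state = prom_state,
                               stringsAsFactors = FALSE),
                    data.frame(chrom = lp$chrom[k], start = a2 + 1000,
                               end = a2 + 1600, state = opp_state,
                               stringsAsFactors = FALSE))
      if (lp$function_truth[k] == "enhancer_promoter")
        lp$ep_subclass_truth[k] <- sprintf(
          "%s_enh_%s_prom",
          if (opp_state == "EnhA1") "strong" else "weak",
          if (prom_state == "TssA") "active" else "weak")
    }
    # fill gaps with a quiescent state so segments tile without overlap
    asm <- ds$assemblies[[sp]]
    filled <- NULL
    for (ch in names(asm$chrom_sizes)) {
      s <- segs[segs$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      pos <- 0
      for (i in seq_len(nrow(s))) {
        if (s$start[i] > pos)
          filled <- rbind(filled, data.frame(chrom = ch, start = pos,
                                             end = s$start[i], state = "Quies",
                                             stringsAsFactors = FALSE))
        filled <- rbind(filled, s[i, ])
        pos <- s$end[i]
      }
      if (pos < asm$chrom_sizes[[ch]])
        filled <- rbind(filled, data.frame(chrom = ch, start = pos,
                                           end = asm$chrom_sizes[[ch]],
                                           state = "Quies",
                                           stringsAsFactors = FALSE))
    }
    rownames(filled) <- NULL
    out_states[[sp]] <- filled
    out_truth[[sp]] <- lp
  }
  # CTCF ChIP peaks over every planted motif
  peaks <- list(ctcf = list(), p300 = list())
  for (sp in c("A", "B")) {
    u <- dedupe_sites(ds$sites[[sp]])
    u <- u[order(u$chrom, u$start), ]
    peaks$ctcf[[sp]] <- data.frame(
      chrom = u$chrom, start = u$start - 190, end = u$start + W + 191,
      name = sprintf("ctcf_%s_%d", sp, seq_len(nrow(u))), score = 1000,
      strand = ".", signal = 10, pvalue = -1, qvalue = -1,
      peak = 190 + floor(W / 2), label = "CTCF", stringsAsFactors = FALSE)
  }
  # p300: block every lineage-specific, RE-derived, functional loop except
  # the engineered candidate (their RE motifs overlap a p300 peak), plus
  # one benign distal peak per chromosome
  for (sp in c("A", "B")) {
    lp <- out_truth[[sp]]
    s <- ds$sites[[sp]]
    blocked <- lp$id[lp$category == "specific" &
                       lp$function_truth != "unannotated" &
                       lp$id != (ds$candidate_loop_id %||% "")]
    bm <- s[s$structure_id %in% blocked & s$origin_truth == "RE_derived" &
              s$role == "loop_anchor", , drop = FALSE]
    p3 <- data.frame(chrom = bm$chrom, start = bm$start - 30,
                     end = bm$end + 30, stringsAsFactors = FALSE)
    chroms <- names(ds$assemblies[[sp]]$chrom_sizes)
    p3 <- rbind(p3, data.frame(chrom = chroms, start = 10000, end = 10300,
                               stringsAsFactors = FALSE))
    p3 <- p3[order(p3$chrom, p3$start), ]
    peaks$p300[[sp]] <- data.frame(
      chrom = p3$chrom, start = p3$start, end = p3$end,
      name = sprintf("p300_%s_%d", sp, seq_len(nrow(p3))), score = 500,
      strand = ".", signal = 5, pvalue = -1, qvalue = -1,
      peak = floor((p3$end - p3$start) / 2), label = "p300",
      stringsAsFactors = FALSE)
  }
  # GeneHancer-style support for the candidate loop
  cand <- out_truth$A[out_truth$A$id == ds$candidate_loop_id, ]
  genehancer <- data.frame(chrom = cand$chrom,
                           enh_start = cand$start2 + 1000,
                           enh_end = cand$start2 + 1600,
                           prom_start = cand$start1 + 200,
                           prom_end = cand$start1 + 800)
  list(chromhmm = out_states, loop_truth = out_truth, peaks = peaks,
       genehancer = genehancer)
}

#' @rdname generate_synthetic_dataset
#' @param ds dataset under construction (output of [plant_tes_and_motifs()])
#' @export
generate_structures_and_states <- function(ds, config) {
  sts <- sim_states_and_peaks(ds, config)
  loops <- list(); truth_loops <- list()
  for (sp in c("A", "B")) {
    lt <- sts$loop_truth[[sp]]
    re_by_loop <- tapply(ds$sites[[sp]]$origin_truth == "RE_derived" &
                           ds$sites[[sp]]$role == "loop_anchor",
                         ds$sites[[sp]]$structure_id, any)
    lt$origin_truth <- ifelse(unname(re_by_loop[lt$id]), "RE_derived",
                              "non_RE_derived")
    lt$orthology_truth <- ifelse(lt$category == "conserved", "conserved",
                                 "lineage_specific")
    lt$is_candidate <- lt$id == (ds$candidate_loop_id %||% "")
    loops[[sp]] <- data.frame(id = lt$id, chrom = lt$chrom,
                              start1 = lt$start1, end1 = lt$end1,
                              start2 = lt$start2, end2 = lt$end2,
                              resolution = config$anchor_width,
                              stringsAsFactors = FALSE)
    truth_loops[[sp]] <- lt
  }
  tads <- list(); truth_bounds <- list()
  for (sp in c("A", "B")) {
    b <- ds$plan$bounds[[sp]]
    td <- NULL
    for (ch in unique(b$chrom)) {
      for (cat in c("conserved", "specific")) {
        pts <- sort(b$point[b$chrom == ch & b$category == cat])
        if (length(pts) >= 2)
          td <- rbind(td, data.frame(chrom = ch, start = pts[-length(pts)],
                                     end = pts[-1], stringsAsFactors = FALSE))
      }
    }
    td$name <- sprintf("tad_%s_%d", td$chrom, as.integer(td$start))
    tads[[sp]] <- td
    b$conserved_truth <- b$category == "conserved"
    truth_bounds[[sp]] <- b
  }
  c(ds[c("assemblies", "chains", "genome_chars", "sites", "repeats",
         "plan", "candidate_loop_id")],
    list(loops = loops, tads = tads, chromhmm = sts$chromhmm,
         peaks = sts$peaks, genehancer = sts$genehancer,
         truth = list(loops = truth_loops, boundaries = truth_bounds)))
}

#' Simulate a binned contact matrix with planted TADs and loops
#'
#' mean(i,j) = scale * (1 + d_ij/d0)^(-alpha) * tad_factor(i,j) *
#' loop_factor(i,j); counts are Poisson draws symmetrized over the upper
#' triangle. `tad_boundaries` partition the region into blocks whose
#' within-block pairs are boosted by `tad_factor`; each loop pixel's 3x3
#' neighborhood is boosted by `loop_factor`.
#'
#' @param chrom,start,end region simulated
#' @param tad_boundaries boundary positions in bp (within the region)
#' @param loop_pixels data.frame with columns i, j (1-based bin indices)
#' @param config a `sim_config` (contact model parameters)
#' @param seed RNG seed for the Poisson draws
#' @return a `contact_matrix`
#' @export
simulate_contact_matrix <- function(chrom, start, end, tad_boundaries,
                                    loop_pixels, config, seed) {
  bs <- config$bin_size
  nb <- (end - start) / bs
  stopifnot(nb == round(nb))
  D <- abs(outer(seq_len(nb), seq_len(nb), "-")) * bs
  base <- config$contact_scale * (1 + D / config$decay_d0)^(-config$decay_alpha)
  mids <- start + (seq_len(nb) - 0.5) * bs
  seg <- findInterval(mids, sort(tad_boundaries))
  tadF <- ifelse(outer(seg, seg, "=="), config$tad_factor, 1)
  loopF <- matrix(1, nb, nb)
  if (!is.null(loop_pixels) && nrow(loop_pixels) > 0) {
    for (k in seq_len(nrow(loop_pixels))) {
      ii <- max(1, loop_pixels$i[k] - 1):min(nb, loop_pixels$i[k] + 1)
      jj <- max(1, loop_pixels$j[k] - 1):min(nb, loop_pixels$j[k] + 1)
      loopF[ii, jj] <- config$loop_factor
      loopF[jj, ii] <- config$loop_factor
    }
  }
  mu <- base * tadF * loopF
  cnt <- matrix(0, nb, nb)
  up <- upper.tri(mu, diag = TRUE)
  with_seed(seed, {
    cnt[up] <- stats::rpois(sum(up), mu[up])
  })
  cnt <- cnt + t(cnt) - diag(diag(cnt))
  contact_matrix(cnt, chrom, start, bs)
}

#' Simulate the wild-type / knockout contact-map pair
#'
#' The WT map carries every planted TAD boundary and loop pixel in the
#' region; the KO map removes the candidate anchor's loop pixel and its TAD
#' boundary (factors reset to 1), emulating deletion of the TE-derived
#' anchor.
#'
#' @param ds a generated dataset ([generate_synthetic_dataset()])
#' @param seed RNG seed for the Poisson noise
#' @return list(wt, ko) of `contact_matrix`, plus the region/partition spec
#' @export
simulate_contact_pair <- function(ds, seed = ds$config$seed + 10) {
  spec <- ds$contact_spec
  wt <- simulate_contact_matrix(spec$chrom, spec$start, spec$end,
                                spec$tad_boundaries, spec$loop_pixels,
                                ds$config, seed)
  ko <- simulate_contact_matrix(spec$chrom, spec$start, spec$end,
                                setdiff(spec$tad_boundaries, spec$ablated_boundary),
                                spec$loop_pixels[!spec$loop_pixels$candidate, ,
                                                 drop = FALSE],
                                ds$config, seed + 1)
  list(wt = wt, ko = ko, spec = spec)
}

#' Generate the full synthetic two-species dataset
#'
#' Runs genome/chain generation, TE + motif planting, structure/state/peak
#' generation and wild-type/knockout contact-map simulation; collects
#' planted ground truth for every stage.
#'
#' @param config a [sim_config()]
#' @return a list of class `sim_dataset`; see the package vignette for the
#'   component inventory
#' @export
generate_synthetic_dataset <- function(config = sim_config()) {
  pair <- generate_genome_pair(config)
  ds <- plant_tes_and_motifs(pair, config)
  ds <- generate_structures_and_states(ds, config)
  ds$config <- config
  lay <- ds$plan$layout
  # contact region: the chr1 A-specific zone
  start <- 840000; end <- 1440000
  bs <- config$bin_size
  lp <- ds$truth$loops$A
  reg <- lp[lp$chrom == "chr1" & lp$category == "specific", ]
  px <- data.frame(
    i = floor((interval_midpoint(reg$start1, reg$end1) - start) / bs) + 1,
    j = floor((interval_midpoint(reg$start2, reg$end2) - start) / bs) + 1,
    candidate = reg$is_candidate)
  bounds <- ds$plan$bounds$A
  tb <- bounds$point[bounds$chrom == "chr1" & bounds$category == "specific"]
  cand_site <- ds$sites$A[ds$sites$A$structure_id == ds$candidate_loop_id &
                            ds$sites$A$side == 2, ]
  ablated <- tb[abs(tb - cand_site$start) < 2500]
  ds$contact_spec <- list(chrom = "chr1", start = start, end = end,
                          tad_boundaries = tb, loop_pixels = px,
                          ablated_boundary = ablated,
                          partition_a = c(sort(tb)[2], ablated),
                          partition_b = c(ablated, sort(tb)[4]),
                          roi = c(sort(tb)[2], sort(tb)[4]))
  mats <- simulate_contact_pair(ds)
  ds$matrices <- mats[c("wt", "ko")]
  ds$genomes <- lapply(ds$genome_chars, function(g)
    vapply(g, paste, character(1), collapse = ""))
  ds$genome_chars <- NULL
  ds$pwm <- sim_pwm()
  ds$config <- config
  # construction self-check: every planted motif must sit in the sequence
  for (sp in c("A", "B")) {
    u <- dedupe_sites(ds$sites[[sp]])
    for (i in seq_len(nrow(u))) {
      seq <- substr(ds$genomes[[sp]][[u$chrom[i]]], u$start[i] + 1, u$end[i])
      want <- if (u$strand[i] == "+") SIM_CONSENSUS else revcomp_string(SIM_CONSENSUS)
      if (seq != want)
        stop_fmt("planted motif mismatch at %s:%d (%s)", u$chrom[i],
                 u$start[i], sp)
    }
  }
  class(ds) <- "sim_dataset"
  ds
}

#' The sharp consensus PWM used by the generator
#'
#' Probability 0.997 on the consensus base at every position; one mismatch
#' costs ~10 bits, so at the 80% scanning threshold only exact consensus
#' matches score as hits.
#' @return a `pwm`
#' @export
sim_pwm <- function() {
  chars <- strsplit(SIM_CONSENSUS, "")[[1]]
  probs <- matrix(0.001, 4, length(chars), dimnames = list(BASES, NULL))
  probs[cbind(match(chars, BASES), seq_along(chars))] <- 0.997
  pwm(probs, pseudocount = 0)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> seed %d: %d+%d loops, %d+%d TADs, %d+%d TEs\n",
              x$config$seed, nrow(x$loops$A), nrow(x$loops$B),
              nrow(x$tads$A), nrow(x$tads$B),
              nrow(x$repeats$A), nrow(x$repeats$B)))
  invisible(x)
}

#' Write a generated dataset to disk in the pipeline's input formats
#'
#' Emits FASTA genomes, chrom.sizes, BEDPE loops, BED TADs, RepeatMasker
#' .out, narrowPeak CTCF/p300, ChromHMM BED, UCSC chains, the PWM, COO
#' contact matrices, ground-truth TSVs and a YAML manifest echoing the
#' config. Output is byte-identical for identical configs.
#'
#' @param ds a `sim_dataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  for (sp in c("A", "B")) {
    write_fasta_genome(ds$genomes[[sp]], p(sprintf("genome_%s.fa", sp)))
    write_chrom_sizes(ds$assemblies[[sp]], p(sprintf("%s.chrom.sizes", sp)))
    write_bedpe_loops(ds$loops[[sp]], p(sprintf("loops_%s.bedpe", sp)), ids = FALSE)
    write_bed(ds$tads[[sp]], p(sprintf("tads_%s.bed", sp)), "name")
    write_repeatmasker_out(ds$repeats[[sp]], p(sprintf("rmsk_%s.out", sp)))
    write_narrowpeak(ds$peaks$ctcf[[sp]], p(sprintf("ctcf_%s.narrowPeak", sp)))
    write_narrowpeak(ds$peaks$p300[[sp]], p(sprintf("p300_%s.narrowPeak", sp)))
    write_bed(ds$chromhmm[[sp]], p(sprintf("chromhmm_%s.bed", sp)), "state")
    write_tsv_report(ds$truth$loops[[sp]],
                     p("ground_truth", sprintf("loops_%s.tsv", sp)))
    write_tsv_report(ds$truth$boundaries[[sp]],
                     p("ground_truth", sprintf("boundaries_%s.tsv", sp)))
    write_tsv_report(ds$sites[[sp]],
                     p("ground_truth", sprintf("sites_%s.tsv", sp)))
  }
  write_chain(ds$chains$a_to_b, p("aToB.chain"))
  write_chain(ds$chains$b_to_a, p("bToA.chain"))
  write_jaspar_pwm(ds$pwm, p("ctcf_pwm.jaspar"), "sim_CTCF")
  utils::write.table(ds$genehancer, p("genehancer_A.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_contact_coo(ds$matrices$wt, p("contacts_wt.coo.tsv"))
  write_contact_coo(ds$matrices$ko, p("contacts_ko.coo.tsv"))
  manifest <- list(
    generator = "teloop synthetic dataset",
    config = unclass(ds$config),
    contact_region = ds$contact_spec[c("chrom", "start", "end")],
    partitions = list(a = ds$contact_spec$partition_a,
                      b = ds$contact_spec$partition_b),
    candidate_loop = ds$candidate_loop_id)
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(dir)
}
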