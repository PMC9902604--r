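# Loop and TAD-boundary conservation calls and the origin-by-orthology
# cross-tabulation.

mk_loop <- function(id, chrom, a1, a2, w = 5000) {
  data.frame(id = id, chrom = chrom, start1 = a1, end1 = a1 + w,
             start2 = a2, end2 = a2 + w, stringsAsFactors = FALSE)
}
mapped <- function(chrom, start, end) {
  list(status = "mapped", mapped_fraction = 1,
       target = list(chrom = chrom, start = start, end = end, strand = "+"))
}

test_that("conservation threshold is min(half loop span, 50 kb)", {
  # 60 kb loop -> t = 30 kb; anchors 10 kb and 25 kb away qualify
  src <- mk_loop("s", "chr1", 0, 55000)     # span end2 - start1 = 60 kb
  tgt <- mk_loop("t", "chr1", 10000, 80000)
  lab <- loop_is_conserved(src, mapped("chr1", 0, 5000),
                           mapped("chr1", 55000, 60000), tgt)
  expect_equal(lab$label, "conserved")
  expect_equal(lab$matched_target_id, "t")
  # 200 kb loop -> t capped at 50 kb; one anchor 60 kb away fails
  src2 <- mk_loop("s2", "chr1", 0, 195000)
  tgt2 <- mk_loop("t2", "chr1", 60000, 200000)
  lab2 <- loop_is_conserved(src2, mapped("chr1", 0, 5000),
                            mapped("chr1", 195000, 200000), tgt2)
  expect_equal(lab2$label, "lineage_specific")
})

test_that("the 50 kb cap is exercised at value and value +/- 1", {
  src <- mk_loop("s", "chr1", 0, 995000)    # t = 50 kb exactly (span 1 Mb)
  for (d in c(-1, 0, 1)) {
    tgt <- mk_loop("t", "chr1", 50000 + d, 1045000 + d)
    lab <- loop_is_conserved(src, mapped("chr1", 0, 5000),
                             mapped("chr1", 995000, 1000000), tgt)
    expect_equal(lab$label,
                 if (d <= 0) "conserved" else "lineage_specific",
                 info = sprintf("offset %d", d))
  }
})

test_that("unliftable anchors and anchor-order flips are handled", {
  src <- mk_loop("s", "chr1", 0, 55000)
  tgt <- mk_loop("t", "chr1", 0, 55000)
  lab <- loop_is_conserved(src, list(status = "unmapped_low_match",
                                     target = NULL, mapped_fraction = 0.05),
                           mapped("chr1", 55000, 60000), tgt)
  expect_equal(lab$label, "unliftable")
  # lifted anchors arriving in reversed order are re-ordered before matching
  lab2 <- loop_is_conserved(src, mapped("chr1", 55000, 60000),
                            mapped("chr1", 0, 5000), tgt)
  expect_equal(lab2$label, "conserved")
  expect_equal(lab2$distance_bp, 0)
})

test_that("identity chains make every structure conserved at distance 0", {
  ds <- default_dataset()
  loops <- ds$loops$A
  ident <- lapply(names(ds$assemblies$A$chrom_sizes), function(ch)
    make_chain(list(c(ds$assemblies$A$chrom_sizes[[ch]], 0, 0)),
               s_chrom = ch, t_chrom = ch, id = ch))
  orth <- classify_loops_orthology(loops, ident, loops)
  expect_true(all(orth$label == "conserved"))
  expect_true(all(orth$distance_bp == 0))
  expect_equal(orth$matched_target_id, loops$id)
})

test_that("boundary conservation uses the 50 kb rule on lifted motifs", {
  tgt <- data.frame(id = "tb", chrom = "chr1", start = 100000, end = 100019)
  ident <- list(make_chain(list(c(1e6, 0, 0))))
  for (d in c(49999, 50000, 50001)) {
    src <- data.frame(id = "b", chrom = "chr1", start = 100000 + d,
                      end = 100019 + d)
    lab <- classify_boundaries_orthology(src, ident, tgt)
    expect_equal(lab$label,
                 if (d <= 50000) "conserved" else "lineage_specific",
                 info = sprintf("d=%d", d))
  }
  # unliftable motifs are labelled as such
  gap_chain <- list(make_chain(list(c(100, 1e6, 0), c(100, 0, 0))))
  src <- data.frame(id = "b", chrom = "chr1", start = 500000, end = 500019)
  expect_equal(classify_boundaries_orthology(src, gap_chain, tgt)$label,
               "unliftable")
})

test_that("conserved calls are monotone in the distance threshold", {
  set.seed(23)
  ident <- list(make_chain(list(c(1e6, 0, 0))))
  src <- do.call(rbind, lapply(1:20, function(i)
    mk_loop(paste0("s", i), "chr1", sample(0:400000, 1),
            sample(500000:900000, 1))))
  tgt <- do.call(rbind, lapply(1:20, function(i)
    mk_loop(paste0("t", i), "chr1", sample(0:400000, 1),
            sample(500000:900000, 1))))
  caps <- c(1000, 5000, 20000, 50000, 200000)
  n_cons <- vapply(caps, function(cap) {
    sum(classify_loops_orthology(src, ident, tgt, cap_bp = cap)$label ==
          "conserved")
  }, numeric(1))
  expect_true(all(diff(n_cons) >= 0))
})

test_that("cross-tabulation counts, percents and orphan errors", {
  origins <- data.frame(structure_id = paste0("l", 1:10),
                        label = c(rep("RE_derived", 4), rep("non_RE_derived", 6)),
                        te_only = c(rep(TRUE, 4), rep(FALSE, 6)),
                        repeat_subfamily = c("L1MC1", "AluY", "L1MC1", "MIRb",
                                             rep(NA, 6)))
  orth <- data.frame(structure_id = paste0("l", 1:10),
                     label = rep(c("lineage_specific", "conserved"),
                                 c(4, 6)),
                     matched_target_id = NA, distance_bp = NA)
  # 4 lineage-specific of which 1 TE-derived (l1..l4: first is TE-derived...)
  origins$label[2:4] <- "non_RE_derived"; origins$te_only[2:4] <- FALSE
  ct <- cross_tabulate(origins, orth)
  tab <- ct$table
  cell <- tab$count[tab$origin == "TE_derived" &
                      tab$orthology == "lineage_specific"]
  expect_equal(cell, 1)
  expect_equal(tab$percent_of_column[tab$origin == "TE_derived" &
                                       tab$orthology == "lineage_specific"], 25)
  # percents within each orthology column sum to 100
  for (k in unique(tab$orthology))
    expect_equal(sum(tab$percent_of_column[tab$orthology == k]), 100)
  # all conserved: specific column all zeros
  orth2 <- orth; orth2$label <- "conserved"
  ct2 <- cross_tabulate(origins, orth2)
  expect_true(all(ct2$table$count[ct2$table$orthology == "lineage_specific"] == 0))
  expect_error(cross_tabulate(origins[-1, ], orth), "l1")
})
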