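# ChromHMM-based loop function attribution, E-P strength subclasses and
# the CRISPR candidate filters.

fn_loop <- function(a1 = 100000, a2 = 300000, w = 5000, id = "L") {
  data.frame(id = id, chrom = "chr1", start1 = a1, end1 = a1 + w,
             start2 = a2, end2 = a2 + w, stringsAsFactors = FALSE)
}
seg <- function(start, end, state) {
  data.frame(chrom = "chr1", start = start, end = end, state = state,
             stringsAsFactors = FALSE)
}

test_that("promoter + enhancer / repressor patterns label loops", {
  lp <- fn_loop()
  # TssA 8 kb from anchor1, Enh overlapping anchor2 -> E-P, promoter at 1
  track <- rbind(seg(91400, 92000, "TssA"), seg(301000, 301600, "Enh"))
  got <- attribute_loop_function(lp, track)
  expect_equal(got$label, "enhancer_promoter")
  expect_equal(got$promoter_anchor, 1L)
  # polycomb at the opposite anchor -> repressive
  track2 <- rbind(seg(91400, 92000, "TssA"), seg(301000, 301600, "ReprPC"))
  expect_equal(attribute_loop_function(lp, track2)$label, "repressive")
  # TssA 12 kb away and nothing else -> unannotated
  track3 <- seg(83000, 88000, "TssA")
  expect_equal(attribute_loop_function(lp, track3)$label, "unannotated")
  # enhancer + repressor both present resolve to E-P with a flag
  track4 <- rbind(seg(91400, 92000, "TssA"), seg(301000, 301600, "Enh"),
                  seg(302000, 302600, "ReprPC"))
  got4 <- attribute_loop_function(lp, track4)
  expect_equal(got4$label, "enhancer_promoter")
  expect_true(got4$ep_repr_conflict)
})

test_that("the 10 kb window is inclusive and exercised at value +/- 1", {
  lp <- fn_loop()
  enh <- seg(301000, 301600, "Enh")
  for (d in c(9999, 10000, 10001)) {
    track <- rbind(seg(100000 - d - 600, 100000 - d, "TssA"), enh)
    got <- attribute_loop_function(lp, track)
    expect_equal(got$label,
                 if (d <= 10000) "enhancer_promoter" else "unannotated",
                 info = sprintf("gap %d", d))
  }
})

test_that("function labels are symmetric under anchor swap", {
  track <- rbind(seg(91400, 92000, "TssA"), seg(301000, 301600, "Enh"))
  lp <- fn_loop()
  swapped <- lp
  swapped[c("start1", "end1", "start2", "end2")] <-
    lp[c("start2", "end2", "start1", "end1")]
  a <- attribute_loop_function(lp, track)
  b <- attribute_loop_function(swapped, track)
  expect_equal(a$label, b$label)
  expect_equal(a$promoter_anchor, 3L - b$promoter_anchor)
})

test_that("unknown state labels are ignored with a warning", {
  lp <- fn_loop()
  track <- rbind(seg(91400, 92000, "TssA"), seg(301000, 301600, "Enh"),
                 seg(200000, 201000, "MadeUpState"))
  expect_warning(got <- attribute_loop_function(lp, track), "MadeUpState")
  expect_equal(got$label, "enhancer_promoter")
})

test_that("E-P subclasses follow the strength map", {
  lp <- fn_loop()
  cases <- list(
    list(enh = "EnhA1", prom = "TssA", want = "strong_enh_active_prom"),
    list(enh = "Enh", prom = "TssAFlnk", want = "weak_enh_weak_prom"),
    list(enh = "EnhA2", prom = "TssAFlnk", want = "strong_enh_weak_prom"),
    list(enh = "EnhG", prom = "TssA", want = "weak_enh_active_prom"))
  for (cs in cases) {
    track <- rbind(seg(91400, 92000, cs$prom), seg(301000, 301600, cs$enh))
    fn <- attribute_loop_function(lp, track)
    expect_equal(subclassify_ep(lp, fn, track), cs$want)
  }
  # repressive loops have no E-P subclass
  track <- rbind(seg(91400, 92000, "TssA"), seg(301000, 301600, "ReprPC"))
  fn <- attribute_loop_function(lp, track)
  expect_equal(subclassify_ep(lp, fn, track), "none")
})

test_that("candidate filters fire in order with a telescoping audit", {
  res <- default_pipeline()
  ds <- default_dataset()
  cand <- res$candidates
  expect_equal(nrow(cand), nrow(ds$loops$A))
  expect_equal(sum(cand$passed), 1)
  expect_equal(cand$loop_id[cand$passed], ds$candidate_loop_id)
  # audit counts telescope: every loop either passed or failed at one filter
  expect_equal(sum(cand$passed) + sum(!is.na(cand$failed_at)), nrow(cand))
  expect_equal(cand$rank[cand$passed], 1L)
  expect_true(cand$genehancer_support[cand$passed])
})

test_that("the 15 kb CTCF exclusion window rejects crowded anchors", {
  lp <- fn_loop(id = "L1")
  sites <- data.frame(structure_id = "L1", side = 2, chrom = "chr1",
                      start = 302000, end = 302019, strand = "+",
                      score = 10, origin = "RE_derived")
  orth <- data.frame(structure_id = "L1", label = "lineage_specific")
  fns <- data.frame(loop_id = "L1", label = "enhancer_promoter")
  own <- data.frame(chrom = "chr1", start = 301900, end = 302200)
  p300 <- data.frame(chrom = "chr1", start = 1, end = 2)
  for (d in c(14999, 15000, 15001)) {
    peaks <- rbind(own, data.frame(chrom = "chr1", start = 305000 + d,
                                   end = 305400 + d))
    got <- select_crispr_candidates(lp, sites, orth, fns, peaks, p300)
    # second peak gap from anchor end (305000) is exactly d
    expect_equal(got$passed, d > 15000, info = sprintf("d=%d", d))
    if (d <= 15000) expect_equal(got$failed_at, 3L)
  }
  # motif overlapping a p300 peak by 1 bp fails filter 4
  p300_hit <- data.frame(chrom = "chr1", start = 302018, end = 302100)
  got <- select_crispr_candidates(lp, sites, orth, fns, own, p300_hit)
  expect_false(got$passed)
  expect_equal(got$failed_at, 4L)
  p300_miss <- data.frame(chrom = "chr1", start = 302019, end = 302100)
  expect_true(select_crispr_candidates(lp, sites, orth, fns, own,
                                       p300_miss)$passed)
})

test_that("planted E-P loops are recovered exactly on the synthetic track", {
  res <- default_pipeline()
  ds <- default_dataset()
  for (sp in c("A", "B")) {
    fns <- res$species[[sp]]$functions
    truth <- ds$truth$loops[[sp]]
    m <- match(fns$loop_id, truth$id)
    expect_equal(fns$label, truth$function_truth[m])
    ep <- fns$label == "enhancer_promoter"
    expect_equal(fns$ep_subclass[ep], truth$ep_subclass_truth[m][ep])
  }
})
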