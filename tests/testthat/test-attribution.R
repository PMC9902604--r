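# The 10 bp overlap rule, structure labels, taxonomy summaries, pooled
# fractions and the chromosome-preserving shuffle null.

test_that("the 10 bp overlap rule is inclusive at its boundary", {
  reps <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                    strand = "+", subfamily = "L1MC1",
                                    family = "L1", class_name = "LINE",
                                    score = 0)
  motif <- list(chrom = "chr1", start = 1000, end = 1019)
  # 19 bp motif [1000,1019) vs repeat [1005,1200): overlap 14 >= 10
  expect_equal(classify_ctcf_origin(motif, reps(1005, 1200))$origin,
               "RE_derived")
  # overlap exactly 9 -> non_RE; exactly 10 -> RE_derived; 11 -> RE_derived
  expect_equal(classify_ctcf_origin(motif, reps(1010, 1200))$origin, "non_RE")
  expect_equal(classify_ctcf_origin(motif, reps(1009, 1200))$origin,
               "RE_derived")
  expect_equal(classify_ctcf_origin(motif, reps(1008, 1200))$origin,
               "RE_derived")
  expect_equal(classify_ctcf_origin(motif, reps(1010, 1200))$overlap_bp, 9)
})

test_that("a motif overlapping two repeats is attributed to the larger", {
  motif <- list(chrom = "chr1", start = 1000, end = 1019)
  reps <- data.frame(chrom = "chr1", start = c(1005, 995), end = c(1200, 1005),
                     strand = "+", subfamily = c("L1MC1", "AluY"),
                     family = c("L1", "Alu"), class_name = c("LINE", "SINE"),
                     score = 0)
  got <- classify_ctcf_origin(motif, reps)
  expect_equal(got$repeat_subfamily, "L1MC1")   # 14 bp beats 5 bp
  expect_equal(got$overlap_bp, 14)
})

test_that("origin classification matches the brute-force oracle", {
  set.seed(19)
  for (rep in 1:300) {
    reps <- random_repeats(sample(1:25, 1))
    st <- sample.int(10000, 1)
    motif <- list(chrom = "chr1", start = st, end = st + 19)
    got <- classify_ctcf_origin(motif, reps)
    want <- overlap_oracle(motif, reps)
    expect_identical(got$origin, want$origin)
    expect_equal(got$overlap_bp, want$overlap)
    if (want$origin == "RE_derived")
      expect_identical(got$repeat_subfamily, want$subfamily)
  }
})

test_that("TAD borders standardize to +/-5 kb windows with edge clipping", {
  asm <- genome_assembly("toy", c(chr1 = 200000))
  w <- standardize_tad_boundary(100000, "chr1", asm)
  expect_equal(c(w$window_start, w$window_end), c(95000, 105000))
  expect_equal(standardize_tad_boundary(2000, "chr1", asm)$window_start, 0)
  expect_equal(standardize_tad_boundary(2000, "chr1", asm)$window_end, 7000)
  w <- standardize_tad_boundary(199000, "chr1", asm)
  expect_equal(w$window_end, 200000)
  expect_error(standardize_tad_boundary(300000, "chr1", asm), "outside")
})

test_that("structure labels follow the anchor-CTCF dichotomy", {
  re_site <- data.frame(origin = "RE_derived", repeat_subfamily = "L1MC1",
                        repeat_family = "L1", repeat_class = "LINE")
  non_site <- data.frame(origin = "non_RE", repeat_subfamily = NA,
                         repeat_family = NA, repeat_class = NA)
  expect_equal(classify_structure("l1", "loop", list(re_site, NULL))$label,
               "RE_derived")
  expect_equal(classify_structure("l2", "loop", list(non_site, non_site))$label,
               "non_RE_derived")
  expect_equal(classify_structure("l3", "loop", list(non_site, NULL))$label,
               "excluded")
  simple <- data.frame(origin = "RE_derived", repeat_subfamily = "(TA)n",
                       repeat_family = "Simple_repeat",
                       repeat_class = "Simple_repeat")
  expect_true(classify_structure("l4", "loop", list(re_site, NULL))$te_only)
  expect_false(classify_structure("l5", "loop", list(simple, NULL))$te_only)
  # "DNA?" variants still count as TEs
  q <- re_site; q$repeat_class <- "DNA?"
  expect_true(classify_structure("l6", "loop", list(q, NULL))$te_only)
})

test_that("label accounting partitions every structure", {
  res <- default_pipeline()
  for (sp in c("A", "B")) {
    cls <- res$species[[sp]]$loop_classifications
    expect_equal(sum(cls$label %in% c("RE_derived", "non_RE_derived",
                                      "excluded")), nrow(cls))
    ds <- default_dataset()
    expect_equal(nrow(cls), nrow(ds$loops[[sp]]))
  }
})

test_that("taxonomy summaries count unique sites and sum to 100 percent", {
  sites <- data.frame(
    chrom = "chr1", start = c(100, 200, 300, 400, 100), end = c(119, 219, 319, 419, 119),
    strand = "+", origin = "RE_derived",
    repeat_class = c("SINE", "SINE", "SINE", "LTR", "SINE"),
    repeat_family = c("Alu", "Alu", "MIR", "ERV1", "Alu"),
    repeat_subfamily = c("AluY", "AluSx", "MIRb", "MER52C", "AluY"))
  s <- summarize_taxonomy(sites, "class")
  # duplicate coordinates collapse: 4 unique sites, 3 SINE + 1 LTR
  expect_equal(attr(s, "denominator"), 4)
  expect_equal(s$percent[s$name == "SINE"], 75)
  expect_equal(s$percent[s$name == "LTR"], 25)
  expect_equal(sum(s$percent), 100, tolerance = 1e-6)
  one <- summarize_taxonomy(sites[4, ], "subfamily")
  expect_equal(one$percent, 100)
  # family percents re-aggregated by class equal the class summary
  fam <- summarize_taxonomy(sites, "family")
  cls_from_fam <- tapply(fam$percent,
                         c(Alu = "SINE", MIR = "SINE", ERV1 = "LTR")[fam$name],
                         sum)
  expect_equal(as.vector(cls_from_fam[s$name]), s$percent)
  expect_warning(empty <- summarize_taxonomy(sites[0, ], "class"),
                 "no qualifying")
  expect_equal(attr(empty, "denominator"), 0)
})

test_that("re_fraction pools as summed counts, not mean of percents", {
  mk <- function(n_re, n) data.frame(
    chrom = "chr1", start = seq_len(n) * 100, end = seq_len(n) * 100 + 19,
    strand = "+", origin = rep(c("RE_derived", "non_RE"), c(n_re, n - n_re)))
  expect_equal(as.numeric(re_fraction(mk(3, 20))), 15)
  pooled <- re_fraction_pooled(list(mk(1, 10), mk(3, 10)))
  expect_equal(as.numeric(pooled), 20)   # (1+3)/(10+10)
  expect_equal(attr(pooled, "numerator"), 4)
  expect_equal(attr(pooled, "denominator"), 20)
  pooled2 <- re_fraction_pooled(list(mk(1, 10), mk(9, 30)))
  expect_equal(as.numeric(pooled2), 25)  # 10/40, not mean(10%, 30%) = 20%
})

test_that("shuffle null is seeded, bounded and analytically calibrated", {
  asm <- genome_assembly("toy", c(chr1 = 1e6))
  # repeats tile 50% of the chromosome in 500 bp blocks
  reps <- data.frame(chrom = "chr1", start = seq(0, 1e6 - 1000, by = 1000),
                     end = seq(0, 1e6 - 1000, by = 1000) + 500,
                     strand = "+", subfamily = "AluY", family = "Alu",
                     class_name = "SINE", score = 0)
  sites <- data.frame(chrom = "chr1", start = seq(100, 99100, by = 1000),
                      end = seq(100, 99100, by = 1000) + 19, strand = "+",
                      origin = "RE_derived")
  out <- shuffle_null(sites, reps, asm, n_shuffles = 1000, seed = 5)
  # exact placement probability by enumerating starts over one 1000 bp period
  qualifies <- vapply(0:999, function(s) {
    ov1 <- max(0, min(s + 19, 500) - max(s, 0))
    ov2 <- max(0, min(s + 19, 1500) - max(s, 1000))
    max(ov1, ov2) >= 10
  }, logical(1))
  p_hit <- mean(qualifies)
  se <- sqrt(p_hit * (1 - p_hit) / nrow(sites)) / sqrt(1000) * 100
  expect_lt(abs(mean(out$null) - 100 * p_hit), 3 * max(se, 0.05))
  # determinism and full-coverage degenerate case
  out2 <- shuffle_null(sites, reps, asm, n_shuffles = 1000, seed = 5)
  expect_identical(out$null, out2$null)
  all_re <- reps[1, ]; all_re$start <- 0; all_re$end <- 1e6
  out3 <- shuffle_null(sites, all_re, asm, n_shuffles = 100, seed = 1)
  expect_true(all(out3$null == 100))
  big <- sites[1, ]; big$end <- big$start + 2e6
  expect_error(shuffle_null(big, reps, asm, n_shuffles = 100, seed = 1),
               "longer than")
})
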