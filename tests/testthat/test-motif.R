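# PWM log-odds scoring, region scanning and ChIP-gated anchor assignment.

test_that("consensus scoring has the closed-form value and N scores zero", {
  p <- consensus_pwm("ACGT", p = 1, pseudocount = 0.01)
  # prob 1.0 on the consensus base, uniform background: with pseudocount pc
  # the consensus score is 4 * log2((1 + 0.25 pc) / ((1 + pc) * 0.25))
  pc <- 0.01
  expect_equal(log_odds_score("ACGT", p),
               4 * log2((1 + 0.25 * pc) / ((1 + pc) * 0.25)))
  # pc -> 0 limit is 4 * log2(4) = 8 bits
  p0 <- consensus_pwm("ACGT", p = 0.9999999999, pseudocount = 0)
  expect_equal(log_odds_score("ACGT", p0), 4 * log2(4), tolerance = 1e-8)
  expect_equal(log_odds_score("NNNN", p), 0)
  expect_error(log_odds_score("ACGTA", p), "width")
})

test_that("scores equal an independently coded per-position sum", {
  set.seed(7)
  for (rep in 1:50) {
    probs <- matrix(stats::rexp(40), 4, 10)
    probs <- sweep(probs, 2, colSums(probs), "/")
    rownames(probs) <- c("A", "C", "G", "T")
    pw <- pwm(probs, pseudocount = 0.05)
    win <- paste(sample(c("A", "C", "G", "T", "N"), 10, TRUE), collapse = "")
    chars <- strsplit(win, "")[[1]]
    manual <- 0
    for (i in 1:10) {
      b <- chars[i]
      manual <- manual + if (b == "N") 0 else
        log2((probs[b, i] + 0.05 * 0.25) / (1.05 * 0.25))
    }
    expect_equal(log_odds_score(win, pw), unname(manual), tolerance = 1e-12)
  }
})

test_that("minus-strand scoring uses the reverse complement", {
  pw <- consensus_pwm("CCGATTACG")
  rc <- "CGTAATCGG"
  expect_equal(log_odds_score(rc, pw, strand = "-"),
               log_odds_score("CCGATTACG", pw, strand = "+"))
})

test_that("scan_region recovers planted motifs with strand and position", {
  set.seed(11)
  cons <- "CCGATTACGGTAACCGTAA"
  pw <- consensus_pwm(cons)
  bg <- sample(c("A", "C", "G", "T"), 5000, TRUE)
  rc <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cons))), "")[[1]]
  bg[1001:1019] <- rc                       # minus-strand plant
  bg[3001:3019] <- strsplit(cons, "")[[1]]  # plus-strand plant
  genome <- c(chr1 = paste(bg, collapse = ""))
  hits <- scan_region("chr1", 0, 5000, genome, pw,
                      min_score = 0.8 * pwm_max_score(pw))
  expect_equal(nrow(hits), 2)
  expect_equal(sort(hits$start), c(1000, 3000))
  expect_equal(hits$strand[hits$start == 1000], "-")
  expect_equal(hits$strand[hits$start == 3000], "+")
  # cross-check with exact string matching
  mp <- Biostrings::matchPattern(cons, Biostrings::DNAString(genome[["chr1"]]))
  expect_equal(Biostrings::start(mp) - 1, 3000)
})

test_that("scan thresholds, ordering and errors behave as specified", {
  pw <- consensus_pwm("CCGATTAC")
  genome <- c(chr1 = paste(rep("CCGATTAC", 8), collapse = ""))
  # min_score above the maximum achievable: empty result
  expect_equal(nrow(scan_region("chr1", 0, 64, genome, pw,
                                min_score = pwm_max_score(pw) + 1)), 0)
  # identical planted motifs: score ties broken by ascending position
  hits <- scan_region("chr1", 0, 64, genome, pw,
                      min_score = pwm_max_score(pw) - 1e-9)
  expect_true(all(diff(hits$start[hits$score == max(hits$score)]) > 0))
  expect_error(scan_region("chr1", 0, 100, genome, pw), "outside")
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(3)
  pw <- consensus_pwm("CCGATTACG", p = 0.9)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_region("chr1", 0, 600, c(chr1 = seq), pw,
                    min_score = 0.3 * pwm_max_score(pw))
  h2 <- scan_region("chr1", 0, 600, c(chr1 = rc), pw,
                    min_score = 0.3 * pwm_max_score(pw))
  expect_equal(nrow(h1), nrow(h2))
  # a hit at [s, e) on + maps to [L-e, L-s) on the opposite strand
  k1 <- paste(600 - h1$end, ifelse(h1$strand == "+", "-", "+"),
              round(h1$score, 9))
  k2 <- paste(h2$start, h2$strand, round(h2$score, 9))
  expect_setequal(k1, k2)
})

test_that("the bundled default CTCF matrix loads as a valid 19-column pwm", {
  pw <- default_ctcf_pwm()
  expect_s3_class(pw, "pwm")
  expect_equal(pw$width, 19)
  expect_true(all(abs(colSums(pw$probs) - 1) < 1e-9))
  expect_gt(pwm_max_score(pw), 0)
})

test_that("anchor CTCF assignment is peak-gated with deterministic ties", {
  anchor <- list(chrom = "chr1", start = 1000, end = 6000)
  hits <- data.frame(chrom = "chr1", start = c(2000, 4000), end = c(2019, 4019),
                     strand = "+", score = c(12.1, 14.0))
  peaks <- data.frame(chrom = "chr1", start = 1950, end = 2100)
  # the higher-scoring hit lies outside any peak: the in-peak hit wins
  got <- assign_anchor_ctcf(anchor, hits, peaks)
  expect_equal(got$score, 12.1)
  # no peak at all: no site
  expect_null(assign_anchor_ctcf(anchor, hits, peaks[0, ]))
  # equal-score in-peak hits: leftmost
  hits2 <- data.frame(chrom = "chr1", start = c(3000, 2000),
                      end = c(3019, 2019), strand = "+", score = c(9, 9))
  peaks2 <- data.frame(chrom = "chr1", start = 0, end = 6000)
  expect_equal(assign_anchor_ctcf(anchor, hits2, peaks2)$start, 2000)
})
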