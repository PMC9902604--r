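# KR balancing, expected/O-E transforms, long-range interaction fractions,
# virtual 4C and focal enrichment.

rand_sym <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.1, 5), n, n)
  (m + t(m)) / 2
}

test_that("KR balancing matches the closed-form 2x2 solution", {
  cm <- contact_matrix(matrix(c(2, 1, 1, 2), 2), "chr1", 0, 1000)
  out <- kr_balance(cm, tol = 1e-10)
  # symmetric with equal diagonal: already balanced, d1 = d2
  expect_equal(out$scaling[1] / out$scaling[2], 1, tolerance = 1e-8)
  expect_equal(rowSums(out$matrix$counts)[1], rowSums(out$matrix$counts)[2],
               tolerance = 1e-8)
  # general symmetric 2x2 [[a,b],[b,c]]: d1/d2 = sqrt(c/a)
  cm2 <- contact_matrix(matrix(c(4, 1, 1, 1), 2), "chr1", 0, 1000)
  out2 <- kr_balance(cm2, tol = 1e-12)
  expect_equal(out2$scaling[1] / out2$scaling[2], sqrt(1 / 4),
               tolerance = 1e-8)
})

test_that("balanced row sums have coefficient of variation < 1e-6", {
  for (seed in 1:3) {
    cm <- contact_matrix(rand_sym(200, seed), "chr1", 0, 5000 * 200, "raw")
    out <- kr_balance(cm, tol = 1e-8)
    rs <- rowSums(out$matrix$counts)
    expect_lt(stats::sd(rs) / mean(rs), 1e-6)
    expect_lt(max(abs(out$matrix$counts - t(out$matrix$counts))), 1e-9)
  }
})

test_that("KR masks zero rows and fixes already-balanced matrices", {
  m <- rand_sym(20, 4)
  m[5, ] <- 0; m[, 5] <- 0
  out <- kr_balance(contact_matrix(m, "chr1", 0, 1000))
  expect_true(all(out$matrix$counts[5, ] == 0))
  expect_true(is.na(out$scaling[5]))
  rs <- rowSums(out$matrix$counts)[-5]
  expect_lt(stats::sd(rs) / mean(rs), 1e-6)
  # a doubly-balanced matrix yields a constant scaling vector
  bal <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  out2 <- kr_balance(contact_matrix(bal, "chr1", 0, 1000), tol = 1e-12)
  expect_equal(out2$scaling[1], out2$scaling[2], tolerance = 1e-8)
})

test_that("expected-by-distance equals the per-diagonal mean oracle", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    cm <- contact_matrix(rand_sym(n, rep + 100), "chr1", 0, 1000)
    got <- expected_by_distance(cm)
    for (d in 0:(n - 1)) {
      vals <- c()
      for (i in seq_len(n)) for (j in seq_len(n))
        if (abs(i - j) == d) vals <- c(vals, cm$counts[i, j])
      expect_equal(got[d + 1], mean(vals), tolerance = 1e-9)
    }
  }
})

test_that("O/E of a constant matrix is 1 and the transform is idempotent", {
  cm <- contact_matrix(matrix(3.7, 10, 10), "chr1", 0, 10000)
  oe <- oe_transform(cm)
  expect_true(all(abs(oe$counts - 1) < 1e-12))
  cm2 <- contact_matrix(rand_sym(15, 6), "chr1", 0, 15000)
  once <- oe_transform(cm2)
  twice <- oe_transform(once)
  expect_lt(max(abs(once$counts - twice$counts)), 1e-12)
})

test_that("long-range fractions match exhaustive pair enumeration", {
  set.seed(13)
  for (rep in 1:50) {
    nb <- 8; bs <- 10000
    cm <- contact_matrix(rand_sym(nb, rep + 500), "chr1", 0, bs)
    roi <- c(0, 80000); pa <- c(0, 40000); pb <- c(40000, 80000)
    got <- long_range_fraction(cm, roi, pa, pb, min_distance = 30000)
    denom <- intra <- inter <- 0
    for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
      mid_i <- (i - 0.5) * bs; mid_j <- (j - 0.5) * bs
      if ((j - i) * bs <= 30000) next
      denom <- denom + cm$counts[i, j]
      in_a <- c(mid_i, mid_j) >= pa[1] & c(mid_i, mid_j) < pa[2]
      in_b <- c(mid_i, mid_j) >= pb[1] & c(mid_i, mid_j) < pb[2]
      if (all(in_a)) intra <- intra + cm$counts[i, j]
      if (sum(in_a) == 1 && sum(in_b) == 1) inter <- inter + cm$counts[i, j]
    }
    expect_equal(got$intra_a_pct, 100 * intra / denom, tolerance = 1e-9)
    expect_equal(got$inter_ab_pct, 100 * inter / denom, tolerance = 1e-9)
    # invariance to global rescaling
    cm10 <- contact_matrix(cm$counts * 10, "chr1", 0, bs)
    got10 <- long_range_fraction(cm10, roi, pa, pb, min_distance = 30000)
    expect_equal(got10$intra_a_pct, got$intra_a_pct, tolerance = 1e-9)
  }
})

test_that("empty long-range mass is flagged undefined", {
  cm <- contact_matrix(diag(4) * 5, "chr1", 0, 5000)
  expect_warning(
    got <- long_range_fraction(cm, c(0, 20000), c(0, 10000), c(10000, 20000),
                               min_distance = 30000),
    "no contact mass")
  expect_true(got$undefined)
  expect_true(is.na(got$intra_a_pct))
})

test_that("virtual 4C profiles average anchor rows and conserve mass", {
  m <- rand_sym(12, 21)
  cm <- contact_matrix(m, "chr1", 0, 5000)
  # single-bin anchor: the profile is that matrix row
  p1 <- virtual_4c(cm, list(chrom = "chr1", start = 10000, end = 15000))
  expect_equal(p1$value, m[3, ])
  # two-bin anchor: elementwise mean of the two rows
  p2 <- virtual_4c(cm, list(chrom = "chr1", start = 10000, end = 20000))
  expect_equal(p2$value, colMeans(m[3:4, ]))
  # smoothing preserves interior mass
  p3 <- virtual_4c(cm, list(chrom = "chr1", start = 10000, end = 15000),
                   smooth_bins = 2)
  inner <- 3:10
  expect_equal(sum(p3$value[inner]),
               sum(stats::filter(m[3, ], rep(1/5, 5), sides = 2)[inner]),
               tolerance = 1e-9)
  expect_error(virtual_4c(cm, list(chrom = "chr1", start = 100000,
                                   end = 101000)), "outside")
})

test_that("focal enrichment detects planted loops and their loss", {
  ds <- default_dataset()
  cand <- ds$truth$loops$A[ds$truth$loops$A$is_candidate, ]
  fe_wt <- focal_enrichment(ds$matrices$wt, cand)
  fe_ko <- focal_enrichment(ds$matrices$ko, cand)
  expect_gte(fe_wt, 2)                    # planted 4x enrichment
  expect_gt(fe_wt, 2 * fe_ko)
  expect_gte(fe_ko, 0.8)
  expect_lte(fe_ko, 1.25)
  # uniform O/E matrix scores exactly 1
  u <- contact_matrix(matrix(1, 30, 30), "chr1", 0, 5000, "OE")
  lp <- data.frame(chrom = "chr1", start1 = 50000, end1 = 55000,
                   start2 = 100000, end2 = 105000)
  expect_equal(focal_enrichment(u, lp), 1)
  edge <- data.frame(chrom = "chr1", start1 = 0, end1 = 5000,
                     start2 = 100000, end2 = 105000)
  expect_error(focal_enrichment(u, edge), "edge")
})
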