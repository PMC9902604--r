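# Contact-matrix computations: KR balancing, expected-by-distance and O/E,
# long-range intra/inter-domain interaction fractions, virtual 4C, and a
# simplified focal-enrichment score for loop pixels.

#' Construct a binned contact matrix over one region
#'
#' @param counts symmetric nonnegative numeric matrix (bins x bins)
#' @param chrom chromosome name
#' @param start region start in bp (0-based); the region covers
#'   `nrow(counts)` bins of `bin_size` bp
#' @param bin_size bin size in bp
#' @param normalization "raw", "KR" or "OE"
#' @return an object of class `contact_matrix`
#' @export
contact_matrix <- function(counts, chrom, start, bin_size,
                           normalization = "raw") {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop_fmt("contact matrix must be square")
  if (max(abs(counts - t(counts))) > 1e-9)
    stop_fmt("contact matrix must be symmetric within 1e-9")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_fmt("contact matrix entries must be finite and >= 0")
  structure(list(counts = counts, chrom = chrom, start = start,
                 end = start + nrow(counts) * bin_size,
                 bin_size = bin_size, normalization = normalization),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s:%d-%d, %d bins of %d bp, %s\n",
              x$chrom, x$start, x$end, nrow(x$counts), x$bin_size,
              x$normalization))
  invisible(x)
}

n_bins <- function(cm) nrow(cm$counts)
bin_mids <- function(cm) cm$start + (seq_len(n_bins(cm)) - 0.5) * cm$bin_size

#' Read a contact matrix from 3-column COO text
#'
#' Columns: bin1_start, bin2_start, count (bin starts in bp, upper triangle
#' or full; the matrix is symmetrized).
#' @param path file path
#' @param chrom,start,end region covered
#' @param bin_size bin size in bp
#' @return a `contact_matrix`
#' @export
read_contact_coo <- function(path, chrom, start, end, bin_size) {
  nb <- ceiling((end - start) / bin_size)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("bin1", "bin2", "count"))
  i <- (df$bin1 - start) / bin_size + 1
  j <- (df$bin2 - start) / bin_size + 1
  if (any(i != floor(i)) || any(j != floor(j)))
    stop_fmt("%s: bin starts not aligned to bin size %d", path, bin_size)
  if (any(i < 1 | i > nb | j < 1 | j > nb))
    stop_fmt("%s: bins outside region", path)
  m <- matrix(0, nb, nb)
  m[cbind(i, j)] <- df$count
  m[cbind(j, i)] <- df$count
  contact_matrix(m, chrom, start, bin_size)
}

#' Write a contact matrix as upper-triangle COO text
#' @param cm a `contact_matrix`
#' @param path output path
#' @export
write_contact_coo <- function(cm, path) {
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(bin1 = cm$start + (idx[, 1] - 1) * cm$bin_size,
                   bin2 = cm$start + (idx[, 2] - 1) * cm$bin_size,
                   count = cm$counts[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense whitespace-separated contact matrix
#' @param path file path
#' @param chrom,start region covered
#' @param bin_size bin size in bp
#' @return a `contact_matrix`
#' @export
read_contact_dense <- function(path, chrom, start, bin_size) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  contact_matrix(m, chrom, start, bin_size)
}

#' Knight-Ruiz balancing of a symmetric contact matrix
#'
#' Finds a diagonal scaling D so that B = D A D has equal row sums over the
#' unmasked bins (all-zero rows are masked and stay zero). Uses the
#' symmetric fixed-point iteration x <- sqrt(x / (A x)), the diagonal-
#' scaling iteration the Knight-Ruiz algorithm accelerates; the balanced
#' matrix is rescaled so its unmasked row sums equal the mean unmasked raw
#' row sum.
#'
#' @param cm a `contact_matrix` (raw counts)
#' @param tol convergence tolerance on the row-sum coefficient of variation
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual
#' @return list(matrix = balanced `contact_matrix`, scaling = per-bin
#'   scaling vector (NA at masked bins), iterations, residual)
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 5000) {
  A <- cm$counts
  keep <- rowSums(A) > 0
  if (!any(keep)) stop_fmt("kr_balance: all rows are zero")
  M <- A[keep, keep, drop = FALSE]
  x <- rep(1, nrow(M))
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- as.vector(M %*% x) * x
    m <- mean(r)
    resid <- sqrt(mean((r / m - 1)^2))
    if (resid < tol) break
    x <- sqrt(x / as.vector(M %*% x))
  }
  if (resid >= tol)
    stop_fmt("kr_balance: no convergence in %d iterations (residual %.3g)",
             max_iter, resid)
  target <- mean(rowSums(A)[keep])
  r <- as.vector(M %*% x) * x
  x <- x * sqrt(target / mean(r))
  B <- A
  B[keep, keep] <- M * tcrossprod(x)
  scaling <- rep(NA_real_, nrow(A))
  scaling[keep] <- x
  out <- contact_matrix(B, cm$chrom, cm$start, cm$bin_size, "KR")
  list(matrix = out, scaling = scaling, iterations = it, residual = resid)
}

#' Mean contact count per bin distance
#'
#' expected(d) = mean of counts over all bin pairs at bin-distance d within
#' the matrix region.
#' @param cm a `contact_matrix`
#' @return numeric vector of length `n_bins`, element d+1 holding the
#'   expected count at bin distance d
#' @export
expected_by_distance <- function(cm) {
  A <- cm$counts
  d <- abs(row(A) - col(A))
  as.numeric(tapply(A, d, mean))
}

#' Observed/expected transform
#'
#' Divides each entry by the mean count at its bin distance; 0/0 maps to 0.
#' @param cm a `contact_matrix`
#' @return a `contact_matrix` with normalization "OE"
#' @export
oe_transform <- function(cm) {
  A <- cm$counts
  ex <- expected_by_distance(cm)
  E <- matrix(ex[abs(row(A) - col(A)) + 1], nrow(A), ncol(A))
  OE <- ifelse(E > 0, A / E, 0)
  contact_matrix(OE, cm$chrom, cm$start, cm$bin_size, "OE")
}

in_partition <- function(mids, part) mids >= part[1] & mids < part[2]

#' Long-range intra/inter-partition interaction fractions
#'
#' Among bin pairs (upper triangle) whose genomic distance exceeds
#' `min_distance` and whose bins both lie inside the region of interest,
#' reports the percent of contact mass with both bins in partition A
#' (intra) and with one bin in each partition (inter). Bin membership is by
#' bin midpoint. Invariant to global rescaling of the matrix.
#'
#' @param cm a `contact_matrix`
#' @param region_of_interest numeric length-2 (start, end) in bp
#' @param partition_a,partition_b numeric length-2 (start, end) in bp
#' @param min_distance minimum genomic distance in bp (default 30000,
#'   i.e. >30 kb interactions)
#' @return list with intra_a_pct, inter_ab_pct, denominator_mass,
#'   undefined flag and the inputs echoed
#' @export
long_range_fraction <- function(cm, region_of_interest, partition_a,
                                partition_b, min_distance = 30000) {
  mids <- bin_mids(cm)
  roi <- in_partition(mids, region_of_interest)
  a <- in_partition(mids, partition_a)
  b <- in_partition(mids, partition_b)
  A <- cm$counts
  nb <- n_bins(cm)
  ij <- which(upper.tri(A, diag = FALSE), arr.ind = TRUE)
  dist <- (ij[, 2] - ij[, 1]) * cm$bin_size
  keep <- dist > min_distance & roi[ij[, 1]] & roi[ij[, 2]]
  mass <- A[ij[keep, , drop = FALSE]]
  denom <- sum(mass)
  if (denom <= 0) {
    warn_fmt("long_range_fraction: no contact mass beyond %d bp in region",
             min_distance)
    return(list(intra_a_pct = NA_real_, inter_ab_pct = NA_real_,
                denominator_mass = 0, undefined = TRUE,
                region_of_interest = region_of_interest,
                partition_a = partition_a, partition_b = partition_b,
                min_distance = min_distance))
  }
  i <- ij[keep, 1]; j <- ij[keep, 2]
  intra <- sum(mass[a[i] & a[j]])
  inter <- sum(mass[(a[i] & b[j]) | (b[i] & a[j])])
  list(intra_a_pct = 100 * intra / denom,
       inter_ab_pct = 100 * inter / denom,
       denominator_mass = denom, undefined = FALSE,
       region_of_interest = region_of_interest,
       partition_a = partition_a, partition_b = partition_b,
       min_distance = min_distance)
}

#' Virtual 4C profile anchored at an interval
#'
#' The profile is the mean of the anchor bins' matrix rows, optionally
#' smoothed with a centered moving average of width 2*smooth_bins+1 (edge
#' bins keep their unsmoothed values).
#'
#' @param cm a `contact_matrix`
#' @param anchor list/one-row data.frame with chrom, start, end
#' @param smooth_bins half-width of the moving average (0 = none)
#' @return data.frame bin_start, value
#' @export
virtual_4c <- function(cm, anchor, smooth_bins = 0) {
  if (!identical(anchor$chrom, cm$chrom) ||
      anchor$start < cm$start || anchor$end > cm$end)
    stop_fmt("virtual_4c: anchor outside matrix region")
  starts <- cm$start + (seq_len(n_bins(cm)) - 1) * cm$bin_size
  rows <- which(interval_overlap_bp(anchor$start, anchor$end,
                                    starts, starts + cm$bin_size) > 0)
  prof <- colMeans(cm$counts[rows, , drop = FALSE])
  if (smooth_bins > 0) {
    k <- 2 * smooth_bins + 1
    sm <- as.numeric(stats::filter(prof, rep(1 / k, k), sides = 2))
    prof <- ifelse(is.na(sm), prof, sm)
  }
  data.frame(bin_start = starts, value = prof)
}

#' Focal enrichment of a loop pixel over its local background
#'
#' Ratio of the mean O/E value in the (2*peak_radius+1)^2 peak neighborhood
#' of the loop pixel to the mean O/E value in the surrounding donut annulus
#' (peak square excluded). A simplified validation score for planted or
#' called loops; not a loop caller.
#'
#' @param cm a `contact_matrix` (transformed to O/E unless already "OE")
#' @param loop one-row loop data.frame
#' @param peak_radius_bins peak half-width in bins (default 1)
#' @param donut_radius_bins donut half-width in bins (default 5)
#' @return numeric ratio
#' @export
focal_enrichment <- function(cm, loop, peak_radius_bins = 1,
                             donut_radius_bins = 5) {
  if (cm$normalization != "OE") cm <- oe_transform(cm)
  i <- floor((interval_midpoint(loop$start1, loop$end1) - cm$start) / cm$bin_size) + 1
  j <- floor((interval_midpoint(loop$start2, loop$end2) - cm$start) / cm$bin_size) + 1
  nb <- n_bins(cm)
  R <- donut_radius_bins
  if (i - R < 1 || j - R < 1 || i + R > nb || j + R > nb)
    stop_fmt("focal_enrichment: loop pixel within %d bins of the matrix edge", R)
  r <- peak_radius_bins
  peak <- cm$counts[(i - r):(i + r), (j - r):(j + r)]
  box <- cm$counts[(i - R):(i + R), (j - R):(j + R)]
  donut_mass <- sum(box) - sum(peak)
  donut_n <- length(box) - length(peak)
  mean(peak) / (donut_mass / donut_n)
}
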