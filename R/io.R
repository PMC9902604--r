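# Readers and writers for the external formats the pipeline touches.
# Everything surfaced to the rest of the package is 0-based half-open;
# 1-based formats (RepeatMasker .out) are converted at this boundary.

read_nonblank_lines <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], lineno = which(keep))
}

#' Read chromatin loops from a BEDPE file
#'
#' Expects >= 6 tab-separated columns (chrom1, start1, end1, chrom2, start2,
#' end2) in BED convention; an optional 7th column supplies loop ids,
#' otherwise ids are synthesized from anchor coordinates. Anchors are put in
#' genome order, inter-chromosomal rows are skipped with one warning, and
#' exact duplicate anchor pairs are dropped.
#'
#' @param path BEDPE file path
#' @param assembly optional `genome_assembly` to validate chromosomes against
#' @return data.frame with columns id, chrom, start1, end1, start2, end2,
#'   resolution (anchor width in bp)
#' @export
read_bedpe_loops <- function(path, assembly = NULL) {
  src <- read_nonblank_lines(path)
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  rows <- vector("list", length(fields))
  n_inter <- 0L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6)
      stop_fmt("malformed BEDPE row at line %d of %s: fewer than 6 columns",
               src$lineno[i], path)
    num <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    if (any(is.na(num)))
      stop_fmt("malformed BEDPE row at line %d of %s: non-numeric coordinate",
               src$lineno[i], path)
    if (f[1] != f[4]) { n_inter <- n_inter + 1L; next }
    a <- c(num[1], num[2]); b <- c(num[3], num[4])
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) { tmp <- a; a <- b; b <- tmp }
    id <- if (length(f) >= 7 && nzchar(f[7])) f[7] else
      loop_id_from_coords(f[1], a[1], a[2], b[1], b[2])
    rows[[i]] <- data.frame(id = id, chrom = f[1],
                            start1 = a[1], end1 = a[2],
                            start2 = b[1], end2 = b[2],
                            stringsAsFactors = FALSE)
  }
  if (n_inter > 0)
    warn_fmt("%s: skipped %d inter-chromosomal loop row(s)", path, n_inter)
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df))
    df <- data.frame(id = character(), chrom = character(), start1 = numeric(),
                     end1 = numeric(), start2 = numeric(), end2 = numeric(),
                     stringsAsFactors = FALSE)
  if (!is.null(assembly) && nrow(df) > 0) {
    validate_intervals(data.frame(chrom = df$chrom, start = df$start1, end = df$end1),
                       assembly, "loop anchor1")
    validate_intervals(data.frame(chrom = df$chrom, start = df$start2, end = df$end2),
                       assembly, "loop anchor2")
  }
  if (nrow(df) > 0) {
    key <- paste(df$chrom, df$start1, df$end1, df$start2, df$end2)
    dup <- duplicated(key)
    if (any(dup)) {
      warn_fmt("%s: dropped %d duplicate loop row(s)", path, sum(dup))
      df <- df[!dup, , drop = FALSE]
    }
    df$resolution <- pmax(df$end1 - df$start1, df$end2 - df$start2)
    # flag (do not drop) near-duplicates within one resolution unit
    res <- df$resolution
    near <- rep(FALSE, nrow(df))
    ord <- order(df$chrom, df$start1)
    for (k in seq_along(ord)[-1]) {
      i <- ord[k]; j <- ord[k - 1]
      if (df$chrom[i] == df$chrom[j] &&
          abs(df$start1[i] - df$start1[j]) <= res[i] &&
          abs(df$start2[i] - df$start2[j]) <= res[i] &&
          !(df$start1[i] == df$start1[j] && df$start2[i] == df$start2[j]))
        near[i] <- TRUE
    }
    df$near_duplicate <- near
  } else {
    df$resolution <- numeric()
    df$near_duplicate <- logical()
  }
  rownames(df) <- NULL
  df
}

#' Write loops to BEDPE
#' @param loops loop data.frame as returned by [read_bedpe_loops()]
#' @param path output path
#' @param ids write the id as a 7th column
#' @export
write_bedpe_loops <- function(loops, path, ids = TRUE) {
  out <- data.frame(loops$chrom, as.integer(loops$start1), as.integer(loops$end1),
                    loops$chrom, as.integer(loops$start2), as.integer(loops$end2))
  if (ids) out$id <- loops$id
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 file
#' @param path file path
#' @param assembly optional assembly for validation
#' @return data.frame with chrom, start, end and, when present, name
#' @export
read_bed <- function(path, assembly = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  validate_intervals(df, assembly, "BED")
  df[, seq_len(min(ncol(df), 4)), drop = FALSE]
}

#' Write intervals to BED
#' @export
#' @param df data.frame with chrom/start/end and optional extra columns
#' @param path output path
#' @param extra_cols names of columns to append after the first three
write_bed <- function(df, path, extra_cols = character()) {
  out <- data.frame(df$chrom, as.integer(df$start), as.integer(df$end))
  for (cn in extra_cols) out[[cn]] <- df[[cn]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#' @param path file path
#' @param label peak-set label (e.g. "CTCF", "p300")
#' @param assembly optional assembly for validation
#' @return data.frame chrom, start, end, name, score, strand, signal,
#'   pvalue, qvalue, peak, label
#' @export
read_narrowpeak <- function(path, label = "peaks", assembly = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 10)
    stop_fmt("%s: narrowPeak requires 10 columns, found %d", path, ncol(df))
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signal", "pvalue", "qvalue", "peak")
  if (any(!is.finite(df$score)))
    stop_fmt("%s: non-finite peak scores", path)
  validate_intervals(df, assembly, "narrowPeak")
  df$label <- label
  df
}

#' Write a narrowPeak file
#' @param peaks data.frame as from [read_narrowpeak()]
#' @param path output path
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                    peaks$name %||% ".", peaks$score, peaks$strand %||% ".",
                    peaks$signal %||% 0, peaks$pvalue %||% -1,
                    peaks$qvalue %||% -1, peaks$peak %||% -1)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ChromHMM segmentation (BED4, state label in column 4)
#'
#' Segments on one chromosome must be non-overlapping.
#' @param path file path
#' @param assembly optional assembly for validation
#' @return data.frame chrom, start, end, state
#' @export
read_chromhmm_bed <- function(path, assembly = NULL) {
  df <- read_bed(path, assembly)
  if (ncol(df) < 4)
    stop_fmt("%s: ChromHMM BED requires a state label in column 4", path)
  names(df)[4] <- "state"
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop_fmt("%s: overlapping ChromHMM segments on %s", path, ch)
  }
  df
}

#' Read RepeatMasker .out annotations
#'
#' Standard layout: 3 header lines, whitespace-separated columns, 1-based
#' inclusive query coordinates. Coordinates are converted to 0-based
#' half-open; the class/family column is split on "/" (family falls back to
#' the class when there is no "/").
#'
#' @param path .out file path
#' @param assembly optional assembly for validation
#' @return data.frame chrom, start, end, strand, subfamily, family,
#'   class_name, score
#' @export
read_repeatmasker_out <- function(path, assembly = NULL) {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-seq_len(3)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), subfamily = character(),
                      family = character(), class_name = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n <- length(fields)
  out <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    strand = character(n), subfamily = character(n),
                    family = character(n), class_name = character(n),
                    score = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 11)
      stop_fmt("malformed RepeatMasker row at data line %d of %s", i, path)
    begin <- suppressWarnings(as.numeric(f[6]))
    end <- suppressWarnings(as.numeric(f[7]))
    if (is.na(begin) || is.na(end))
      stop_fmt("non-numeric coordinates at data line %d of %s", i, path)
    taxo <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    cls <- taxo[1]
    fam <- if (length(taxo) >= 2) taxo[2] else cls
    if (length(taxo) == 0 || !nzchar(cls)) {
      warn_fmt("%s: unsplittable class/family '%s' at data line %d", path, f[11], i)
      cls <- f[11]; fam <- f[11]
    }
    out$chrom[i] <- f[5]
    out$start[i] <- begin - 1   # 1-based inclusive -> 0-based half-open
    out$end[i] <- end
    out$strand[i] <- if (f[9] %in% c("C", "-")) "-" else "+"
    out$subfamily[i] <- f[10]
    out$family[i] <- fam
    out$class_name[i] <- cls
    out$score[i] <- suppressWarnings(as.numeric(f[1]))
  }
  validate_intervals(out, assembly, "RepeatMasker")
  out
}

#' Write RepeatMasker-style .out annotations (round-trip format)
#' @param repeats data.frame as from [read_repeatmasker_out()]
#' @param path output path
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query          matching  repeat           position in repeat",
    "score   div. del. ins.  sequence  begin end        (left)    repeat    class/family   begin  end    (left)  ID",
    "")
  classfam <- ifelse(repeats$family == repeats$class_name,
                     repeats$class_name,
                     paste0(repeats$class_name, "/", repeats$family))
  body <- sprintf("%5d %6.1f %4.1f %4.1f  %s %10d %10d (%d) %s %s %s %6d %6d (%d) %6d",
                  as.integer(repeats$score %||% 1000), 10.0, 0.0, 0.0,
                  repeats$chrom,
                  as.integer(repeats$start + 1), as.integer(repeats$end), 0L,
                  ifelse(repeats$strand == "-", "C", "+"),
                  repeats$subfamily, classfam,
                  1L, as.integer(repeats$end - repeats$start), 0L,
                  seq_len(nrow(repeats)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector of sequences
#' @param path FASTA path
#' @return named character vector (one element per chromosome, upper case)
#' @export
read_fasta_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a named character vector of sequences to FASTA
#' @param genome named character vector of sequences
#' @param path output path
#' @export
write_fasta_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Write a TSV report with a provenance header
#' @param df data.frame to write
#' @param path output path
#' @param header named character vector written as "# key: value" lines
#' @export
write_tsv_report <- function(df, path, header = character()) {
  con <- file(path, open = "w")
  on.exit(close(con), add = TRUE)
  if (length(header) > 0)
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#' @param path file path
#' @return data.frame (header comment lines are skipped)
#' @export
read_tsv_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
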