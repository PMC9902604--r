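#' Genome assembly descriptor
#'
#' Lightweight container pairing an assembly name with its chromosome sizes.
#' All interval validation in the package is performed against one of these.
#'
#' @param name single assembly identifier (e.g. "simA")
#' @param chrom_sizes named numeric vector of chromosome lengths in bp
#' @return an object of class `genome_assembly`
#' @export
genome_assembly <- function(name, chrom_sizes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_fmt("assembly name must be a single non-empty string")
  sizes <- as.numeric(chrom_sizes)
  names(sizes) <- names(chrom_sizes)
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop_fmt("chrom_sizes must be a named vector")
  if (anyDuplicated(names(sizes)))
    stop_fmt("duplicate chromosome names in assembly '%s'", name)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop_fmt("chromosome lengths must be positive and finite")
  structure(list(name = name, chrom_sizes = sizes), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d chromosome(s), %.3g bp total\n",
              x$name, length(x$chrom_sizes), sum(x$chrom_sizes)))
  invisible(x)
}

#' Length of one chromosome, erroring on unknown names
#' @param assembly a `genome_assembly`
#' @param chrom chromosome name(s)
#' @return numeric length(s) in bp
#' @export
chrom_length <- function(assembly, chrom) {
  unknown <- setdiff(unique(chrom), names(assembly$chrom_sizes))
  if (length(unknown) > 0)
    stop_fmt("unknown chromosome(s) in assembly '%s': %s",
             assembly$name, paste(unknown, collapse = ", "))
  unname(assembly$chrom_sizes[chrom])
}

#' Read a UCSC-style chrom.sizes file (two-column TSV)
#' @param path file path
#' @param name assembly name to attach
#' @return a `genome_assembly`
#' @export
read_chrom_sizes <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  genome_assembly(name, stats::setNames(df$size, df$chrom))
}

#' Write a chrom.sizes file
#' @param assembly a `genome_assembly`
#' @param path output path
#' @export
write_chrom_sizes <- function(assembly, path) {
  df <- data.frame(chrom = names(assembly$chrom_sizes),
                   size = as.integer(assembly$chrom_sizes))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Validate a data.frame of intervals (columns chrom/start/end) against an
# assembly; errors name the offending chromosome or row.
validate_intervals <- function(df, assembly = NULL, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0)
    stop_fmt("%s rows with start >= end or negative start (first at row %d)",
             what, bad[1])
  if (!is.null(assembly)) {
    len <- chrom_length(assembly, df$chrom)
    over <- which(df$end > len)
    if (length(over) > 0)
      stop_fmt("%s rows extend past chromosome end (first at row %d)",
               what, over[1])
  }
  invisible(df)
}
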