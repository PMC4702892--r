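#' Genome assembly: ordered chromosomes with lengths
#'
#' A `genome_assembly` is the coordinate universe for every interval and for
#' breakpoint randomization: an ordered set of chromosome names with strictly
#' positive lengths in bases. All coordinates in this package are 0-based,
#' half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in bases (must be
#'   strictly positive; stored as double so multi-gigabase genomes are safe).
#' @return An object of class `genome_assembly`.
#' @examples
#' g <- genome_assembly(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_size(g)
#' @export
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) {
    stop("a genome assembly needs at least one chromosome", call. = FALSE)
  }
  if (length(chrom) != length(length)) {
    stop("'chrom' and 'length' must have equal length", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    dup <- unique(chrom[duplicated(chrom)])
    stop("duplicate chromosome name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(chrom = chrom, length = stats::setNames(length, chrom)),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("Genome assembly:", length(x$chrom), "chromosome(s),",
      format(genome_size(x), big.mark = ","), "bp total\n")
  n <- min(length(x$chrom), 8L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-8s %12s\n", x$chrom[i],
                format(x$length[[i]], big.mark = ",")))
  }
  if (length(x$chrom) > n) cat("  ...\n")
  invisible(x)
}

#' Total genome length in bases
#' @param genome A [genome_assembly()].
#' @return Numeric scalar, the sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  sum(genome$length)
}

#' Chromosome length lookup
#' @param genome A [genome_assembly()].
#' @param chrom Character vector of chromosome names.
#' @return Numeric vector of lengths; errors if a name is absent.
#' @export
chrom_length <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_assembly"))
  miss <- setdiff(unique(chrom), genome$chrom)
  if (length(miss)) {
    stop("chromosome(s) not in genome: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unname(genome$length[chrom])
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-delimited columns: chromosome name and length in bases.
#' File order is preserved (it fixes the chromosome order of the assembly).
#'
#' @param path Path to a chrom.sizes file.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("empty chrom.sizes file: ", path, call. = FALSE)
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- line_no[which(nf != 2L)[1L]]
    stop(sprintf("malformed chrom.sizes line %d in %s (need 2 fields)",
                 bad, path), call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len)) {
    bad <- line_no[which(is.na(len))[1L]]
    stop(sprintf("non-numeric length at chrom.sizes line %d in %s", bad, path),
         call. = FALSE)
  }
  if (any(len <= 0)) {
    bad <- line_no[which(len <= 0)[1L]]
    stop(sprintf("non-positive length at chrom.sizes line %d in %s", bad, path),
         call. = FALSE)
  }
  genome_assembly(chrom, len)
}

#' Write a chrom.sizes file
#' @param genome A [genome_assembly()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_assembly"))
  writeLines(paste(genome$chrom, format_pos(unname(genome$length)),
                   sep = "\t"), path)
  invisible(path)
}

# integer-valued doubles -> exact decimal text (no scientific notation)
format_pos <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
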