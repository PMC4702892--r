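#' Recognised structural-alteration event types
#'
#' Closed set of event-type tokens: deletion, insertion, inversion, tandem
#' duplication, intra-/inter-chromosomal translocation, and complex
#' (combination) events.
#' @return Character vector of the accepted tokens.
#' @export
event_types <- function() {
  c("DEL", "INS", "INV", "TDUP", "TRA_INTRA", "TRA_INTER", "COMPLEX")
}

# event classes whose two breakpoints live on the same chromosome
intra_event_types <- function() c("DEL", "INV", "TDUP", "TRA_INTRA", "COMPLEX")

#' Construct and validate a table of alteration records
#'
#' One row per genomic alteration (GA): the primary breakpoint (`chrom`,
#' `pos`), an optional mate breakpoint (`mate_chrom`, `mate_pos`; `NA` when
#' absent), the event type, and the read support behind the call. `size` is
#' derived as `|mate_pos - pos|` for same-chromosome pairs and is `NA`
#' (undefined) otherwise; inter-chromosomal events are therefore never
#' compared against a size threshold.
#'
#' @param df A data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `event_type`, `discordant_pairs`, `softclip_reads`, `mate_chrom`,
#'   `mate_pos`. Missing support columns default to 0 (so unfiltered input is
#'   visibly rejected by the support filter rather than silently passing).
#' @param genome A [genome_assembly()] the coordinates are validated against.
#' @return The validated data.frame with a recomputed `size` column.
#' @export
alteration_records <- function(df, genome) {
  stopifnot(is.data.frame(df), inherits(genome, "genome_assembly"))
  need <- c("sample_id", "chrom", "pos", "event_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing record column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$discordant_pairs)) df$discordant_pairs <- 0
  if (is.null(df$softclip_reads)) df$softclip_reads <- 0
  if (is.null(df$mate_chrom)) df$mate_chrom <- NA_character_
  if (is.null(df$mate_pos)) df$mate_pos <- NA_real_
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$event_type <- as.character(df$event_type)
  df$mate_chrom <- as.character(df$mate_chrom)
  df$mate_pos <- as.numeric(df$mate_pos)
  df$discordant_pairs <- as.numeric(df$discordant_pairs)
  df$softclip_reads <- as.numeric(df$softclip_reads)

  if (nrow(df)) {
    bad <- !df$event_type %in% event_types()
    if (any(bad)) {
      stop("unknown event type '", df$event_type[which(bad)[1L]],
           "'; accepted tokens: ", paste(event_types(), collapse = ", "),
           call. = FALSE)
    }
    check_locus(df$chrom, df$pos, genome, what = "breakpoint")
    has_mate <- !is.na(df$mate_chrom)
    if (any(has_mate)) {
      if (anyNA(df$mate_pos[has_mate])) {
        stop("mate chromosome given without mate position", call. = FALSE)
      }
      check_locus(df$mate_chrom[has_mate], df$mate_pos[has_mate], genome,
                  what = "mate breakpoint")
    }
    if (any(df$discordant_pairs < 0) || any(df$softclip_reads < 0)) {
      stop("read-support counts must be non-negative", call. = FALSE)
    }
  }
  same <- !is.na(df$mate_chrom) & df$mate_chrom == df$chrom
  df$size <- ifelse(same, abs(df$mate_pos - df$pos), NA_real_)
  keep <- c("sample_id", "chrom", "pos", "event_type", "discordant_pairs",
            "softclip_reads", "mate_chrom", "mate_pos", "size")
  df <- df[, keep]
  rownames(df) <- NULL
  df
}

check_locus <- function(chrom, pos, genome, what = "breakpoint") {
  miss <- setdiff(unique(chrom), genome$chrom)
  if (length(miss)) {
    stop(what, " on chromosome(s) absent from genome: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  len <- chrom_length(genome, chrom)
  bad <- is.na(pos) | pos < 0 | pos >= len
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s position out of range: %s:%s (chromosome length %s)",
                 what, chrom[i], format_pos(pos[i]), format_pos(len[i])),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a per-sample breakpoint profile in the package's BED dialect
#'
#' Tab-separated columns: `chrom`, `start`, `end` (= start + 1 for point
#' breakpoints), event-type token, discordant-pair count, soft-clip read
#' count, and mate locus as `"chrom:pos"` or `"."`. Columns beyond the first
#' four are optional; absent support counts parse as 0. Lines starting with
#' `#` or `track` are ignored.
#'
#' @param path Path to the profile file.
#' @param genome A [genome_assembly()] used for validation.
#' @param sample_id Sample identity; defaults to the file name stem
#'   (one file per sample).
#' @return A validated alteration-record data.frame (see
#'   [alteration_records()]).
#' @export
read_profile <- function(path, genome, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*(#|track\\b)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(alteration_records(empty_records(), genome))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L)) {
    bad <- line_no[which(nf < 4L)[1L]]
    stop(sprintf("malformed profile line %d in %s (need >= 4 tab-separated fields)",
                 bad, path), call. = FALSE)
  }
  field <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else default, "")
  }
  start <- suppressWarnings(as.numeric(field(2L, NA)))
  end <- suppressWarnings(as.numeric(field(3L, NA)))
  if (anyNA(start) || anyNA(end)) {
    bad <- line_no[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("non-numeric coordinate at profile line %d in %s", bad, path),
         call. = FALSE)
  }
  if (any(end != start + 1)) {
    bad <- line_no[which(end != start + 1)[1L]]
    stop(sprintf("profile line %d in %s: breakpoints are single-base (end must equal start + 1)",
                 bad, path), call. = FALSE)
  }
  mate <- field(7L, ".")
  mate[mate == "" | mate == "."] <- NA_character_
  mate_chrom <- rep(NA_character_, length(mate))
  mate_pos <- rep(NA_real_, length(mate))
  has <- !is.na(mate)
  if (any(has)) {
    m <- regmatches(mate[has], regexec("^(.+):([0-9]+)$", mate[has]))
    ok <- lengths(m) == 3L
    if (any(!ok)) {
      bad <- line_no[has][which(!ok)[1L]]
      stop(sprintf("profile line %d in %s: mate locus must be 'chrom:pos' or '.'",
                   bad, path), call. = FALSE)
    }
    mate_chrom[has] <- vapply(m, `[[`, "", 2L)
    mate_pos[has] <- as.numeric(vapply(m, `[[`, "", 3L))
  }
  sup <- function(i) {
    v <- field(i, "0")
    v[v == "" | v == "."] <- "0"
    x <- suppressWarnings(as.numeric(v))
    if (anyNA(x)) {
      bad <- line_no[which(is.na(x))[1L]]
      stop(sprintf("non-numeric support count at profile line %d in %s",
                   bad, path), call. = FALSE)
    }
    x
  }
  df <- data.frame(
    sample_id = sample_id,
    chrom = field(1L, NA),
    pos = start,
    event_type = field(4L, NA),
    discordant_pairs = sup(5L),
    softclip_reads = sup(6L),
    mate_chrom = mate_chrom,
    mate_pos = mate_pos,
    stringsAsFactors = FALSE
  )
  alteration_records(df, genome)
}

empty_records <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = numeric(),
             event_type = character(), discordant_pairs = numeric(),
             softclip_reads = numeric(), mate_chrom = character(),
             mate_pos = numeric(), stringsAsFactors = FALSE)
}

#' Write alteration records in the profile BED dialect
#'
#' Inverse of [read_profile()]: a round trip through
#' `write_profile()`/[read_profile()] is lossless for every field.
#'
#' @param records Alteration-record data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(records, path) {
  mate <- ifelse(is.na(records$mate_chrom), ".",
                 paste0(records$mate_chrom, ":", format_pos(records$mate_pos)))
  lines <- paste(records$chrom,
                 format_pos(records$pos),
                 format_pos(records$pos + 1),
                 records$event_type,
                 format_pos(records$discordant_pairs),
                 format_pos(records$softclip_reads),
                 mate,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Expand alteration records into single-base breakpoints
#'
#' Each record contributes its primary breakpoint; when `expand_mates` is
#' `TRUE` (default) a record with a defined mate locus contributes that
#' second breakpoint too, so an intra-chromosomal GA yields two breakpoints
#' and an inter-chromosomal translocation yields one per chromosome side.
#'
#' @param records Alteration-record data.frame.
#' @param expand_mates Include mate loci as breakpoints of their own?
#' @return Data.frame with columns `sample_id`, `chrom`, `pos`, `event_type`.
#' @export
profile_breakpoints <- function(records, expand_mates = TRUE) {
  bp <- records[, c("sample_id", "chrom", "pos", "event_type")]
  if (expand_mates) {
    has <- !is.na(records$mate_chrom)
    if (any(has)) {
      mates <- data.frame(sample_id = records$sample_id[has],
                          chrom = records$mate_chrom[has],
                          pos = records$mate_pos[has],
                          event_type = records$event_type[has],
                          stringsAsFactors = FALSE)
      bp <- rbind(bp, mates)
    }
  }
  rownames(bp) <- NULL
  bp
}

#' Construct a per-sample breakpoint profile
#'
#' The unit the hotspot test counts over: all (filtered) breakpoints of one
#' sample, tagged with a cancer-type label.
#'
#' @param sample_id Sample identifier; every breakpoint must carry it.
#' @param breakpoints Data.frame with columns `chrom`, `pos` and optionally
#'   `event_type` (and `sample_id`, checked against `sample_id`).
#' @param cancer_type Group label (default `"unknown"`).
#' @param genome Optional [genome_assembly()]; if given, loci are validated.
#' @return An object of class `breakpoint_profile`.
#' @export
breakpoint_profile <- function(sample_id, breakpoints, cancer_type = "unknown",
                               genome = NULL) {
  stopifnot(is.data.frame(breakpoints))
  if (!all(c("chrom", "pos") %in% names(breakpoints))) {
    stop("breakpoints need 'chrom' and 'pos' columns", call. = FALSE)
  }
  if (!is.null(breakpoints$sample_id) &&
      nrow(breakpoints) && !all(breakpoints$sample_id == sample_id)) {
    stop("all breakpoints must carry the profile's sample_id", call. = FALSE)
  }
  breakpoints$sample_id <- rep(as.character(sample_id),
                               length.out = max(nrow(breakpoints), 0L))
  if (is.null(breakpoints$event_type)) {
    breakpoints$event_type <- rep(NA_character_, nrow(breakpoints))
  }
  breakpoints$chrom <- as.character(breakpoints$chrom)
  breakpoints$pos <- as.numeric(breakpoints$pos)
  if (!is.null(genome) && nrow(breakpoints)) {
    check_locus(breakpoints$chrom, breakpoints$pos, genome)
  }
  cols <- c("sample_id", "chrom", "pos", "event_type")
  structure(list(sample_id = as.character(sample_id),
                 cancer_type = as.character(cancer_type),
                 breakpoints = breakpoints[, cols]),
            class = "breakpoint_profile")
}

#' @export
print.breakpoint_profile <- function(x, ...) {
  cat(sprintf("Breakpoint profile '%s' (%s): %d breakpoint(s)\n",
              x$sample_id, x$cancer_type, nrow(x$breakpoints)))
  invisible(x)
}

# bind breakpoints of a list of profiles into one table; sample ids must be
# unique across profiles
bind_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id across profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  do.call(rbind, lapply(profiles, function(p) p$breakpoints))
}

#' Read a directory (or files) of breakpoint profiles
#'
#' @param paths A directory containing profile files, or a character vector
#'   of file paths. Cancer-type labels default to the part of the file stem
#'   before the first underscore when one is present (e.g. `GBM_profile1.bed`
#'   is labelled `GBM`), else `"unknown"`.
#' @param genome A [genome_assembly()].
#' @param expand_mates Passed to [profile_breakpoints()].
#' @param pattern File-name filter applied when `paths` is a directory
#'   (default: `.bed` files).
#' @return List of [breakpoint_profile()] objects, one per file.
#' @export
read_profile_dir <- function(paths, genome, expand_mates = TRUE,
                             pattern = "\\.bed$") {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = pattern, full.names = TRUE)
    paths <- paths[!dir.exists(paths)]
  }
  if (length(paths) == 0L) stop("no profile files found", call. = FALSE)
  lapply(paths, function(p) {
    stem <- sub("\\.[^.]*$", "", basename(p))
    ct <- if (grepl("_", stem)) sub("_.*$", "", stem) else "unknown"
    rec <- read_profile(p, genome, sample_id = stem)
    breakpoint_profile(stem, profile_breakpoints(rec, expand_mates),
                       cancer_type = ct, genome = genome)
  })
}

#' Read a plain 3-column BED blacklist
#'
#' Intervals (e.g. Database-of-Genomic-Variants-style population variants)
#' whose contained breakpoints are removed by [subtract_blacklist()].
#'
#' @param path Path to a BED file (first three columns used; `#`/`track`
#'   lines ignored).
#' @param genome Optional [genome_assembly()]; if given, intervals are
#'   clipped-validated against it.
#' @return Data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_blacklist <- function(path, genome = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*(#|track\\b)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 3L)) {
    stop("malformed blacklist BED line (need >= 3 fields) in ", path,
         call. = FALSE)
  }
  df <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                   start = as.numeric(vapply(parts, `[[`, "", 2L)),
                   end = as.numeric(vapply(parts, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$start) | is.na(df$end) | df$start < 0 | df$end <= df$start)) {
    stop("invalid blacklist interval (need 0 <= start < end) in ", path,
         call. = FALSE)
  }
  if (!is.null(genome)) {
    miss <- setdiff(unique(df$chrom), genome$chrom)
    if (length(miss)) {
      stop("blacklist chromosome(s) absent from genome: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write scored bins / hotspots as a results TSV
#'
#' Header columns: `chrom`, `start`, `end`, `score`, `p`, `q` (plus any
#' further columns present, e.g. `tested`).
#'
#' @param bins Data.frame of segment bins or hotspots.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(bins, path) {
  out <- bins
  if (!is.null(out$p_value)) names(out)[names(out) == "p_value"] <- "p"
  if (!is.null(out$q_value)) names(out)[names(out) == "q_value"] <- "q"
  lead <- intersect(c("chrom", "start", "end", "score", "p", "q"), names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  for (col in c("start", "end")) out[[col]] <- format_pos(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a profile as display BED rectangles
#'
#' Each breakpoint is rendered as the interval
#' `[pos - flank, pos + flank + 1)` clipped to chromosome bounds, matching
#' the browser convention of drawing a ~20 Kb bar centred at the breakpoint
#' for the default 10 Kb flank.
#'
#' @param profile A [breakpoint_profile()].
#' @param flank Flank in bases on each side (>= 0).
#' @param genome A [genome_assembly()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_display_bed <- function(profile, flank, genome, path) {
  stopifnot(inherits(profile, "breakpoint_profile"), flank >= 0)
  bp <- profile$breakpoints
  reg <- extend_breakpoints(bp, flank, genome)
  name <- ifelse(is.na(bp$event_type), profile$sample_id,
                 paste0(profile$sample_id, ":", bp$event_type))
  lines <- paste(reg$chrom, format_pos(reg$start), format_pos(reg$end), name,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
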