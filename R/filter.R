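#' Filtering thresholds for high-confidence somatic alterations
#'
#' Defaults follow the standard high-confidence cascade: calls supported by
#' at least two discordant read pairs and two soft-clipped reads, events no
#' larger than 10 Mb, germline subtraction with 100 bp positional tolerance,
#' and blacklist removal by breakpoint containment.
#'
#' @param min_discordant Minimum discordant-pair support (default 2).
#' @param min_softclip Minimum soft-clipped-read support (default 2).
#' @param max_size Maximum event size in bases; events strictly larger are
#'   removed (default 10,000,000; events of exactly `max_size` survive).
#' @param germline_tolerance Per-breakpoint matching tolerance in bases for
#'   germline subtraction (default 100).
#' @param blacklist_mode Blacklist semantics; only `"breakpoint_in_region"`
#'   (removal when a breakpoint falls inside a blacklist interval) is
#'   implemented.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_discordant = 2, min_softclip = 2,
                          max_size = 1e7, germline_tolerance = 100,
                          blacklist_mode = "breakpoint_in_region") {
  blacklist_mode <- match.arg(blacklist_mode, "breakpoint_in_region")
  if (min_discordant < 0 || min_softclip < 0 || max_size < 0 ||
      germline_tolerance < 0) {
    stop("all filter thresholds must be non-negative", call. = FALSE)
  }
  structure(list(min_discordant = min_discordant, min_softclip = min_softclip,
                 max_size = max_size, germline_tolerance = germline_tolerance,
                 blacklist_mode = blacklist_mode),
            class = "filter_config")
}

#' Keep records with sufficient read support
#'
#' A record survives iff `discordant_pairs >= min_discordant` AND
#' `softclip_reads >= min_softclip`. Input order is preserved; records are
#' never modified, only selected.
#'
#' @param records Alteration-record data.frame.
#' @param cfg A [filter_config()].
#' @return The surviving records.
#' @export
filter_support <- function(records, cfg = filter_config()) {
  keep <- records$discordant_pairs >= cfg$min_discordant &
    records$softclip_reads >= cfg$min_softclip
  records[keep, , drop = FALSE]
}

#' Remove oversized events
#'
#' Intra-chromosomal records with `size > max_size` are removed ("more than"
#' is strict: a record of exactly `max_size` survives). Records with
#' undefined size — inter-chromosomal translocations and single-breakpoint
#' events — are always kept.
#'
#' @inheritParams filter_support
#' @return The surviving records.
#' @export
filter_size <- function(records, cfg = filter_config()) {
  keep <- is.na(records$size) | records$size <= cfg$max_size
  records[keep, , drop = FALSE]
}

#' Subtract germline alterations seen in normal genomes
#'
#' A cancer record is removed iff some normal record has the same event type
#' and every defined breakpoint of the cancer record lies within
#' `germline_tolerance` bases of the corresponding normal breakpoint on the
#' same chromosome (primary matched to primary, mate to mate; the mate must
#' be defined on both sides or on neither). Normals from several genomes are
#' pooled: pass their union.
#'
#' @param cancer_records Cancer alteration-record data.frame.
#' @param normal_records Pooled normal alteration-record data.frame
#'   (validated against the same genome).
#' @param cfg A [filter_config()].
#' @return The somatic survivors, in input order.
#' @export
subtract_germline <- function(cancer_records, normal_records,
                              cfg = filter_config()) {
  if (nrow(cancer_records) == 0L || nrow(normal_records) == 0L) {
    return(cancer_records)
  }
  tol <- cfg$germline_tolerance
  key <- function(r) paste(r$event_type, r$chrom,
                           ifelse(is.na(r$mate_chrom), ".", r$mate_chrom))
  nkey <- key(normal_records)
  ckey <- key(cancer_records)
  nsplit <- split(seq_len(nrow(normal_records)), nkey)
  drop <- logical(nrow(cancer_records))
  for (i in seq_len(nrow(cancer_records))) {
    cand <- nsplit[[ckey[i]]]
    if (is.null(cand)) next
    ok <- abs(normal_records$pos[cand] - cancer_records$pos[i]) <= tol
    cm <- cancer_records$mate_pos[i]
    if (!is.na(cm)) {
      ok <- ok & abs(normal_records$mate_pos[cand] - cm) <= tol
    }
    drop[i] <- any(ok)
  }
  cancer_records[!drop, , drop = FALSE]
}

#' Remove records whose breakpoints fall in blacklist intervals
#'
#' A record is removed iff any of its defined breakpoints (primary or mate)
#' lies inside any blacklist interval, with half-open containment
#' (`start <= pos < end`). Typical blacklists are population-variant
#' catalogues such as the Database of Genomic Variants.
#'
#' @param records Alteration-record data.frame.
#' @param blacklist Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_blacklist()].
#' @return The surviving records, in input order.
#' @export
subtract_blacklist <- function(records, blacklist) {
  if (nrow(records) == 0L || is.null(blacklist) || nrow(blacklist) == 0L) {
    return(records)
  }
  hit1 <- pos_in_intervals(records$chrom, records$pos, blacklist)
  has <- !is.na(records$mate_chrom)
  hit2 <- logical(nrow(records))
  if (any(has)) {
    hit2[has] <- pos_in_intervals(records$mate_chrom[has],
                                  records$mate_pos[has], blacklist)
  }
  records[!(hit1 | hit2), , drop = FALSE]
}

# half-open containment of positions in a set of (possibly overlapping)
# intervals, per chromosome via sorted merged intervals + findInterval
pos_in_intervals <- function(chrom, pos, intervals) {
  hit <- logical(length(pos))
  merged <- merge_intervals(intervals)
  for (cn in unique(chrom)) {
    iv <- merged[merged$chrom == cn, , drop = FALSE]
    if (nrow(iv) == 0L) next
    sel <- chrom == cn
    # merged intervals are disjoint & sorted: pos in some [start, end) iff
    # the last start <= pos belongs to an interval whose end > pos
    idx <- findInterval(pos[sel], iv$start)
    inside <- idx >= 1L & pos[sel] < iv$end[pmax(idx, 1L)]
    hit[sel] <- inside
  }
  hit
}

# union of possibly-overlapping half-open intervals, sorted
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals)
  out <- lapply(split(intervals, intervals$chrom), function(iv) {
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    s <- iv$start; e <- iv$end
    ms <- s[1L]; me <- e[1L]; rs <- numeric(); re <- numeric()
    for (i in seq_along(s)[-1L]) {
      if (s[i] > me) {          # half-open: book-ended intervals stay merged
        rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i]
      } else {
        me <- max(me, e[i])
      }
    }
    data.frame(chrom = iv$chrom[1L], start = c(rs, ms), end = c(re, me),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full somatic filter cascade
#'
#' Applies, in order: read-support filter, size filter, germline subtraction
#' (when normals are given), blacklist subtraction (when a blacklist is
#' given). Each stage only selects records, so the cascade is idempotent and
#' survivor counts are monotone non-increasing in every threshold.
#'
#' @param records Cancer alteration-record data.frame.
#' @param cfg A [filter_config()].
#' @param normal_records Optional pooled normal records.
#' @param blacklist Optional blacklist interval data.frame.
#' @param verbose Log per-stage survivor counts to stderr?
#' @return The surviving somatic records.
#' @export
filter_records <- function(records, cfg = filter_config(),
                           normal_records = NULL, blacklist = NULL,
                           verbose = FALSE) {
  log1 <- function(stage, n) {
    if (verbose) message(sprintf("  %-10s %d record(s) remain", stage, n))
  }
  log1("input", nrow(records))
  records <- filter_support(records, cfg); log1("support", nrow(records))
  records <- filter_size(records, cfg); log1("size", nrow(records))
  if (!is.null(normal_records)) {
    records <- subtract_germline(records, normal_records, cfg)
    log1("germline", nrow(records))
  }
  if (!is.null(blacklist)) {
    records <- subtract_blacklist(records, blacklist)
    log1("blacklist", nrow(records))
  }
  records
}
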