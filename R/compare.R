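#' Count query breakpoints inside a set of intervals
#'
#' Number of query breakpoints whose position lies inside at least one
#' interval (half-open containment, `start <= pos < end`); each breakpoint
#' counts at most once however many intervals cover it. Intervals may
#' overlap.
#'
#' @param query A [breakpoint_profile()].
#' @param intervals Data.frame with `chrom`, `start`, `end`
#'   (e.g. a hotspot BED read with [read_blacklist()]).
#' @return Integer count, between 0 and the number of query breakpoints.
#' @export
overlap_with_intervals <- function(query, intervals) {
  stopifnot(inherits(query, "breakpoint_profile"))
  bp <- query$breakpoints
  if (nrow(bp) == 0L || nrow(intervals) == 0L) return(0L)
  sum(pos_in_intervals(bp$chrom, bp$pos, intervals))
}

#' Count query breakpoints near another profile's breakpoints
#'
#' A query breakpoint counts iff some target breakpoint on the same
#' chromosome lies within `window` bases of it (absolute distance
#' `<= window`); each query breakpoint counts at most once. Counting is
#' directional — query against target — and is monotone non-decreasing in
#' `window`.
#'
#' @param query,target [breakpoint_profile()] objects.
#' @param window Proximity window in bases (>= 0; default 10,000, matching
#'   the hotspot flank so two breakpoints "overlap" when their ~20 Kb
#'   rendered windows share the centre-to-centre distance).
#' @return Integer count.
#' @export
overlap_with_profile <- function(query, target, window = 1e4) {
  stopifnot(inherits(query, "breakpoint_profile"),
            inherits(target, "breakpoint_profile"), window >= 0)
  qb <- query$breakpoints
  tb <- target$breakpoints
  if (nrow(qb) == 0L || nrow(tb) == 0L) return(0L)
  n <- 0L
  for (cn in unique(qb$chrom)) {
    tp <- sort(tb$pos[tb$chrom == cn])
    if (length(tp) == 0L) next
    qp <- qb$pos[qb$chrom == cn]
    # nearest target position via the sorted insertion point
    i <- findInterval(qp, tp)
    d_left <- ifelse(i >= 1L, qp - tp[pmax(i, 1L)], Inf)
    d_right <- ifelse(i < length(tp), tp[pmin(i + 1L, length(tp))] - qp, Inf)
    n <- n + sum(pmin(d_left, d_right) <= window)
  }
  n
}

#' Compare a query profile against hotspot sets and stored profiles
#'
#' One report row per target: hotspot sets are counted by interval
#' containment ([overlap_with_intervals()]), profiles by breakpoint
#' proximity within `window` ([overlap_with_profile()]). Rows are sorted by
#' descending overlap count with a stable tie-break on target label — the
#' tabular equivalent of the sortable bar-plot view.
#'
#' @param query A [breakpoint_profile()].
#' @param hotspot_sets Named list of interval data.frames (may be empty).
#' @param profiles Named list of [breakpoint_profile()] objects (may be
#'   empty). Labels must be unique across both lists.
#' @param window Proximity window for profile targets, in bases.
#' @return Data.frame of class `overlap_report` with columns `target_id`,
#'   `target_kind` (`"hotspot_set"` or `"profile"`), `n_query_overlapping`;
#'   attributes `query_id`, `window`, `n_query`.
#' @export
compare_all <- function(query, hotspot_sets = list(), profiles = list(),
                        window = 1e4) {
  stopifnot(inherits(query, "breakpoint_profile"))
  labels <- c(names(hotspot_sets), names(profiles))
  if (length(labels) && (is.null(labels) || any(!nzchar(labels)))) {
    stop("all hotspot sets and profiles must be named", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate target label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- data.frame(
    target_id = labels,
    target_kind = c(rep("hotspot_set", length(hotspot_sets)),
                    rep("profile", length(profiles))),
    n_query_overlapping = c(
      vapply(hotspot_sets, function(iv)
        as.integer(overlap_with_intervals(query, iv)), 0L),
      vapply(profiles, function(p)
        as.integer(overlap_with_profile(query, p, window)), 0L)),
    stringsAsFactors = FALSE
  )
  rows <- rows[order(-rows$n_query_overlapping, rows$target_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, query_id = query$sample_id, window = window,
            n_query = nrow(query$breakpoints),
            class = c("overlap_report", "data.frame"))
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap report for query '%s' (%d breakpoints, window %s bp)\n",
              attr(x, "query_id"), attr(x, "n_query"),
              format_pos(attr(x, "window"))))
  print.data.frame(x, ...)
  invisible(x)
}
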