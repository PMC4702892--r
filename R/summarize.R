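#' Summarise breakpoint profiles by cancer type
#'
#' Per cancer-type group: number of samples, total breakpoints, and
#' breakpoints per genome as FLOOR(total / samples); plus a `Total` row with
#' the grand sums and floor of the overall mean. This reproduces the usual
#' cohort summary table arithmetic.
#'
#' @param profiles List of [breakpoint_profile()] objects.
#' @return Data.frame with columns `cancer_type`, `n_samples`,
#'   `n_breakpoints`, `breakpoints_per_genome`; empty for empty input.
#' @export
summarize_profiles <- function(profiles) {
  if (length(profiles) == 0L) {
    return(data.frame(cancer_type = character(), n_samples = integer(),
                      n_breakpoints = numeric(),
                      breakpoints_per_genome = numeric()))
  }
  df <- data.frame(
    cancer_type = vapply(profiles, function(p) p$cancer_type, ""),
    n_samples = 1L,
    n_breakpoints = vapply(profiles, function(p) nrow(p$breakpoints), 0),
    stringsAsFactors = FALSE
  )
  summarize_breakpoint_counts(df)
}

#' Summarise per-group sample and breakpoint counts
#'
#' Core arithmetic behind [summarize_profiles()], usable directly on a table
#' of published cohort counts: rows are aggregated by `cancer_type`, the
#' per-genome average is floor division, and a `Total` row holds the grand
#' sums and the floored overall average.
#'
#' @param counts Data.frame with columns `cancer_type`, `n_samples`,
#'   `n_breakpoints` (one or more rows per group).
#' @return Data.frame as in [summarize_profiles()], groups in first-seen
#'   order, `Total` row last. Groups with zero samples are omitted with a
#'   warning.
#' @export
summarize_breakpoint_counts <- function(counts) {
  stopifnot(all(c("cancer_type", "n_samples", "n_breakpoints") %in%
                  names(counts)))
  if (nrow(counts) == 0L) {
    return(data.frame(cancer_type = character(), n_samples = integer(),
                      n_breakpoints = numeric(),
                      breakpoints_per_genome = numeric()))
  }
  groups <- unique(counts$cancer_type)
  ns <- vapply(groups, function(g)
    sum(counts$n_samples[counts$cancer_type == g]), 0)
  nb <- vapply(groups, function(g)
    sum(counts$n_breakpoints[counts$cancer_type == g]), 0)
  empty <- ns == 0
  if (any(empty)) {
    warning("omitting group(s) with zero samples: ",
            paste(groups[empty], collapse = ", "), call. = FALSE)
    groups <- groups[!empty]; ns <- ns[!empty]; nb <- nb[!empty]
  }
  out <- data.frame(cancer_type = c(groups, "Total"),
                    n_samples = c(ns, sum(ns)),
                    n_breakpoints = c(nb, sum(nb)),
                    stringsAsFactors = FALSE)
  out$breakpoints_per_genome <- floor(out$n_breakpoints / out$n_samples)
  rownames(out) <- NULL
  out
}

#' Summarise per-group hotspot counts
#'
#' Aggregates a table of per-cancer hotspot counts (and, optionally, the
#' genomic span they cover) and appends a `Total` row with the sums.
#'
#' @param counts Data.frame with columns `cancer_type`, `n_hotspots`, and
#'   optionally `span_mb` (total hotspot length in Mb).
#' @return The input aggregated by group with a `Total` row appended.
#' @export
summarize_hotspot_counts <- function(counts) {
  stopifnot(all(c("cancer_type", "n_hotspots") %in% names(counts)))
  if (nrow(counts) == 0L) return(counts)
  groups <- unique(counts$cancer_type)
  nh <- vapply(groups, function(g)
    sum(counts$n_hotspots[counts$cancer_type == g]), 0)
  out <- data.frame(cancer_type = c(groups, "Total"),
                    n_hotspots = c(nh, sum(nh)),
                    stringsAsFactors = FALSE)
  if (!is.null(counts$span_mb)) {
    sp <- vapply(groups, function(g)
      sum(counts$span_mb[counts$cancer_type == g]), 0)
    out$span_mb <- c(sp, sum(sp))
  }
  rownames(out) <- NULL
  out
}
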