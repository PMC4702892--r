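#' @export
print.hotspot_result <- function(x, ...) {
  cat("Breakpoint hotspot analysis\n")
  cat(sprintf("  samples: %d   breakpoints: %d   flank: %s bp\n",
              x$n_samples, x$n_breakpoints, format_pos(x$config$flank)))
  cat(sprintf("  bins: %d (tested: %d)   permutations: %d   correction: %s\n",
              nrow(x$bins), sum(x$bins$tested), x$config$n_perm,
              toupper(x$config$correction)))
  cat(sprintf("  hotspots at adjusted p < %g: %d\n", x$config$alpha,
              nrow(x$hotspots)))
  if (nrow(x$hotspots)) {
    show <- utils::head(x$hotspots[order(x$hotspots$q_value,
                                         -x$hotspots$score), ], 5L)
    cat("  top hotspots:\n")
    for (i in seq_len(nrow(show))) {
      cat(sprintf("    %s:%s-%s  score %d  q = %.3g\n", show$chrom[i],
                  format_pos(show$start[i]), format_pos(show$end[i]),
                  show$score[i], show$q_value[i]))
    }
  }
  invisible(x)
}

#' Summarise a hotspot analysis
#'
#' @param object A `hotspot_result` from [call_hotspots()].
#' @param ... Unused.
#' @return A list of class `summary.hotspot_result` with per-chromosome
#'   hotspot counts, total hotspot span, and the score distribution of the
#'   tested bins.
#' @export
summary.hotspot_result <- function(object, ...) {
  h <- object$hotspots
  per_chrom <- if (nrow(h)) {
    agg <- stats::aggregate(cbind(n = rep(1L, nrow(h)),
                                  span = h$end - h$start),
                            by = list(chrom = h$chrom), FUN = sum)
    agg[order(match(agg$chrom, object$genome$chrom)), ]
  } else {
    data.frame(chrom = character(), n = integer(), span = numeric())
  }
  structure(list(config = object$config,
                 n_samples = object$n_samples,
                 n_breakpoints = object$n_breakpoints,
                 n_bins = nrow(object$bins),
                 n_tested = sum(object$bins$tested),
                 n_hotspots = nrow(h),
                 hotspot_span = sum(h$end - h$start),
                 per_chromosome = per_chrom,
                 score_table = table(object$bins$score[object$bins$tested])),
            class = "summary.hotspot_result")
}

#' @export
print.summary.hotspot_result <- function(x, ...) {
  cat(sprintf("Hotspot analysis of %d samples (%d breakpoints)\n",
              x$n_samples, x$n_breakpoints))
  cat(sprintf("  %d bins (%d tested), %d permutations, %s, alpha %g\n",
              x$n_bins, x$n_tested, x$config$n_perm,
              toupper(x$config$correction), x$config$alpha))
  cat(sprintf("  %d hotspot(s) spanning %s bp\n", x$n_hotspots,
              format(x$hotspot_span, big.mark = ",")))
  if (nrow(x$per_chromosome)) {
    cat("  per chromosome:\n")
    for (i in seq_len(nrow(x$per_chromosome))) {
      cat(sprintf("    %-8s %4d hotspot(s)  %12s bp\n",
                  x$per_chromosome$chrom[i], x$per_chromosome$n[i],
                  format(x$per_chromosome$span[i], big.mark = ",")))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.hotspot_result <- function(x, row.names = NULL, optional = FALSE,
                                         which = c("hotspots", "bins"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Plot bin scores and hotspot calls along the genome
#'
#' Draws per-bin enrichment scores (distinct-sample counts) against a
#' genome-wide concatenated coordinate, one panel strip per chromosome
#' boundary, highlighting the significant hotspot bins.
#'
#' @param x A `hotspot_result`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.hotspot_result <- function(x, ...) {
  bins <- x$bins
  g <- x$genome
  off <- c(0, cumsum(unname(g$length)))[seq_along(g$chrom)]
  names(off) <- g$chrom
  mid <- off[bins$chrom] + (bins$start + bins$end) / 2
  graphics::plot(mid, bins$score, type = "h", col = "grey60",
                 xlab = "genome position (concatenated)",
                 ylab = "enrichment score (distinct samples)",
                 xlim = c(0, genome_size(g)), ...)
  graphics::abline(v = cumsum(unname(g$length)), col = "grey85", lty = 3)
  sig <- bins$tested & !is.na(bins$q_value) & bins$q_value < x$config$alpha
  if (any(sig)) {
    graphics::points(mid[sig], bins$score[sig], col = "firebrick", pch = 16,
                     cex = 0.6)
  }
  invisible(x)
}
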