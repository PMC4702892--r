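#' Extend breakpoints into flanking windows
#'
#' Each single-base breakpoint becomes the half-open interval
#' `[pos - flank, pos + flank + 1)`, clipped to `[0, chromosome length)`.
#' With the default 10 Kb flank this is the ~20 Kb window centred at the
#' breakpoint that the hotspot test counts overlaps over.
#'
#' @param breakpoints Data.frame with `chrom`, `pos` and (optionally)
#'   `sample_id`, e.g. a profile's `$breakpoints`.
#' @param flank Bases added on each side (>= 0; default 10,000).
#' @param genome A [genome_assembly()].
#' @return Data.frame with `chrom`, `start`, `end`, `sample_id`.
#' @export
extend_breakpoints <- function(breakpoints, flank = 1e4, genome) {
  stopifnot(flank >= 0, inherits(genome, "genome_assembly"))
  if (nrow(breakpoints) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  len <- chrom_length(genome, breakpoints$chrom)
  data.frame(chrom = breakpoints$chrom,
             start = pmax(breakpoints$pos - flank, 0),
             end = pmin(breakpoints$pos + flank + 1, len),
             sample_id = if (is.null(breakpoints$sample_id))
               NA_character_ else breakpoints$sample_id,
             stringsAsFactors = FALSE)
}

#' Segment the genome at extended-region boundaries and score the bins
#'
#' Per chromosome, the sorted distinct starts and ends of all samples'
#' extended regions define bin boundaries; consecutive boundaries form
#' non-overlapping half-open bins of unequal size. Bins covered by no region
#' are dropped. Each remaining bin's enrichment score is the number of
#' DISTINCT samples with at least one region overlapping the bin (a sample
#' contributing two overlapping regions still counts once); per-base
#' distinct-sample coverage is constant within a bin and equals that score.
#'
#' @param regions Extended regions from [extend_breakpoints()] for all
#'   samples (column `sample_id` required).
#' @param genome A [genome_assembly()]; fixes chromosome output order.
#' @param min_samples_tested Bins with score below this do not enter testing
#'   (`tested = FALSE`); default 2, i.e. only bins hit by more than one
#'   sample form the multiple-testing family.
#' @return Data.frame with `chrom`, `start`, `end`, `score`, `tested`,
#'   sorted by genome chromosome order then start; bins on a chromosome are
#'   non-overlapping.
#' @export
segment_by_boundaries <- function(regions, genome, min_samples_tested = 2) {
  stopifnot(inherits(genome, "genome_assembly"))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      score = integer(), tested = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(empty)
  if (anyNA(regions$sample_id)) {
    stop("regions must carry sample_id for distinct-sample scoring",
         call. = FALSE)
  }
  codes <- match(regions$sample_id, unique(regions$sample_id))
  ns <- max(codes)
  out <- vector("list", length(genome$chrom))
  for (ci in seq_along(genome$chrom)) {
    sel <- regions$chrom == genome$chrom[ci]
    if (!any(sel)) next
    s <- regions$start[sel]; e <- regions$end[sel]; cd <- codes[sel]
    b <- sort(unique(c(s, e)))
    lo <- findInterval(s, b)        # s is a boundary: index of its bin
    hi <- findInterval(e, b) - 1L   # last bin strictly before e
    nbins <- hi - lo + 1L
    bin_idx <- sequence(nbins, from = lo)
    samp <- rep(cd, nbins)
    key <- unique(bin_idx * (ns + 1) + samp)
    score <- tabulate(key %/% (ns + 1), nbins = length(b) - 1L)
    keep <- score > 0L
    out[[ci]] <- data.frame(chrom = genome$chrom[ci],
                            start = b[-length(b)][keep],
                            end = b[-1L][keep],
                            score = score[keep],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res$tested <- res$score >= min_samples_tested
  res
}

#' Relocate breakpoints uniformly over the genome
#'
#' The randomization step of the permutation null: every breakpoint keeps
#' its sample identity and event-type label but is moved independently to a
#' uniform random genome position — chromosome drawn with probability
#' proportional to its length, position uniform on that chromosome (with
#' `within_chromosome = TRUE` the chromosome is kept and only the position
#' is redrawn). Per-sample breakpoint counts are conserved exactly. Uses the
#' current R random-number state; seed beforehand for reproducibility.
#'
#' @param breakpoints Data.frame with `chrom`, `pos`, `sample_id`.
#' @param genome A [genome_assembly()].
#' @param within_chromosome Keep each breakpoint's chromosome assignment?
#' @return Data.frame of the same shape with new `chrom`/`pos`.
#' @export
permute_breakpoints <- function(breakpoints, genome,
                                within_chromosome = FALSE) {
  n <- nrow(breakpoints)
  out <- breakpoints
  if (n == 0L) return(out)
  if (within_chromosome) {
    len <- chrom_length(genome, breakpoints$chrom)
  } else {
    ci <- sample.int(length(genome$chrom), n, replace = TRUE,
                     prob = genome$length)
    out$chrom <- genome$chrom[ci]
    len <- unname(genome$length[ci])
  }
  out$pos <- pmin(floor(stats::runif(n) * len), len - 1)
  out
}

# Count distinct samples per FIXED bin for a set of regions.
# bins_by_chrom: list per chromosome with numeric vectors $start, $end
# (sorted, non-overlapping) and $offset (0-based row offset into the global
# bin vector); nbin: total bins; ns: total number of distinct samples.
score_on_bins <- function(bins_by_chrom, regions, codes, nbin, ns) {
  acc_bin <- vector("list", length(bins_by_chrom))
  acc_cd <- vector("list", length(bins_by_chrom))
  k <- 0L
  for (cn in names(bins_by_chrom)) {
    bb <- bins_by_chrom[[cn]]
    sel <- which(regions$chrom == cn)
    if (length(sel) == 0L) next
    s <- regions$start[sel]; e <- regions$end[sel]
    hi <- findInterval(e - 1, bb$start)      # last bin with start < e
    lo <- findInterval(s, bb$end) + 1L       # first bin with end > s
    n_over <- hi - lo + 1L
    ok <- n_over > 0L & hi >= 1L
    if (!any(ok)) next
    k <- k + 1L
    acc_bin[[k]] <- sequence(n_over[ok], from = lo[ok] + bb$offset)
    acc_cd[[k]] <- rep(codes[sel][ok], n_over[ok])
  }
  if (k == 0L) return(integer(nbin))
  bin_idx <- unlist(acc_bin[seq_len(k)], use.names = FALSE)
  cd <- unlist(acc_cd[seq_len(k)], use.names = FALSE)
  key <- unique(bin_idx * (ns + 1) + cd)
  tabulate(key %/% (ns + 1), nbins = nbin)
}

split_bins <- function(bins) {
  res <- list()
  for (cn in unique(bins$chrom)) {
    idx <- which(bins$chrom == cn)
    res[[cn]] <- list(start = bins$start[idx], end = bins$end[idx],
                      offset = idx[1L] - 1L)
  }
  res
}

# one sub-seed per permutation, derived from the master seed, so results do
# not depend on evaluation order
permutation_seeds <- function(seed, n_perm) {
  set.seed(seed)
  sample.int(2147483646L, n_perm)
}

#' Empirical permutation p-values for scored bins
#'
#' For each of `n_perm` permutations, all samples' breakpoints are relocated
#' ([permute_breakpoints()]), re-extended by `flank`, and distinct-sample
#' scores are recomputed on the FIXED observed bins. For each tested bin the
#' upper-tail empirical p-value with pseudocount is
#' `p = (1 + #permutations with permuted score >= observed score) / (n_perm + 1)`,
#' so p-values lie in `[1/(n_perm + 1), 1]` and are never exactly zero.
#' Ties count as exceedances (conservative). Untested bins get `NA`.
#'
#' With `pooled_null = TRUE`, permuted scores of all tested bins and all
#' permutations are pooled into one genome-wide null distribution and every
#' tested bin is compared against that pool.
#'
#' @param bins Scored bins from [segment_by_boundaries()].
#' @param breakpoints Combined breakpoint table of all samples
#'   (`chrom`, `pos`, `sample_id`).
#' @param genome A [genome_assembly()].
#' @param n_perm Number of permutations (>= 1; default 10,000).
#' @param flank Flank used when extending, in bases (default 10,000).
#' @param seed Master seed for the permutation stream.
#' @param within_chromosome,pooled_null See [call_hotspots()].
#' @return `bins` with a `p_value` column added.
#' @export
empirical_pvalues <- function(bins, breakpoints, genome, n_perm = 1e4,
                              flank = 1e4, seed = 1,
                              within_chromosome = FALSE,
                              pooled_null = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  bins$p_value <- NA_real_
  ti <- which(bins$tested)
  if (length(ti) == 0L || nrow(breakpoints) == 0L) return(bins)
  tbins <- bins[ti, , drop = FALSE]
  bb <- split_bins(tbins)
  samples <- unique(breakpoints$sample_id)
  codes <- match(breakpoints$sample_id, samples)
  ns <- length(samples)
  obs <- tbins$score
  seeds <- permutation_seeds(seed, n_perm)
  if (pooled_null) {
    # accumulate the pooled null as counts per score value (scores <= ns)
    pool <- numeric(ns + 1L)   # pool[s + 1] = #(bin, perm) pairs with score s
  } else {
    exceed <- numeric(length(ti))
  }
  for (k in seq_len(n_perm)) {
    set.seed(seeds[k])
    pb <- permute_breakpoints(breakpoints, genome, within_chromosome)
    reg <- extend_breakpoints(pb, flank, genome)
    sc <- score_on_bins(bb, reg, codes, nrow(tbins), ns)
    if (pooled_null) {
      tab <- tabulate(sc + 1L, nbins = ns + 1L)
      pool <- pool + tab
    } else {
      exceed <- exceed + (sc >= obs)
    }
  }
  if (pooled_null) {
    tail_ge <- rev(cumsum(rev(pool)))   # tail_ge[s + 1] = #scores >= s
    total <- sum(pool)
    bins$p_value[ti] <- (1 + tail_ge[obs + 1L]) / (total + 1)
  } else {
    bins$p_value[ti] <- (1 + exceed) / (n_perm + 1)
  }
  bins
}

#' Multiple-testing adjustment of empirical p-values
#'
#' Benjamini-Hochberg step-up FDR adjustment (default), or plain Bonferroni.
#' The adjusted values are returned in input order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @return Numeric vector of adjusted values (q-values for `"bh"`).
#' @export
bh_adjust <- function(p_values, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni")
}

# merge book-ended significant bins (same chrom, end == next start) into
# single reported hotspots; score = max, p/q = min over members
merge_adjacent_bins <- function(bins) {
  if (nrow(bins) == 0L) {
    bins$n_bins <- integer()
    return(bins)
  }
  grp <- cumsum(c(TRUE, !(bins$chrom[-1L] == bins$chrom[-nrow(bins)] &
                            bins$start[-1L] == bins$end[-nrow(bins)])))
  out <- lapply(split(seq_len(nrow(bins)), grp), function(idx) {
    data.frame(chrom = bins$chrom[idx[1L]],
               start = bins$start[idx[1L]],
               end = bins$end[idx[length(idx)]],
               score = max(bins$score[idx]),
               p_value = min(bins$p_value[idx]),
               q_value = min(bins$q_value[idx]),
               n_bins = length(idx),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call breakpoint hotspots from a cohort of profiles
#'
#' The full recurrence analysis: extend every breakpoint by `flank` bases on
#' each side, segment the genome at all samples' region boundaries into
#' non-overlapping bins of unequal size, score each bin by the number of
#' distinct samples hitting it, compute empirical p-values against `n_perm`
#' random relocations of all breakpoints, adjust for multiple testing over
#' the tested bins, and report the bins with adjusted p-value below `alpha`
#' as hotspots (adjacent book-ended significant bins merged by default).
#'
#' @param profiles List of at least two [breakpoint_profile()] objects
#'   (recurrence across samples is what defines a hotspot, so a single
#'   profile is rejected).
#' @param genome A [genome_assembly()].
#' @param flank Extension in bases on each side of a breakpoint
#'   (default 10,000, i.e. ~20 Kb windows).
#' @param n_perm Number of breakpoint randomizations (default 10,000).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param correction `"bh"` (Benjamini-Hochberg step-up FDR, default) or
#'   `"bonferroni"`.
#' @param min_samples Minimum distinct-sample score for a bin to enter
#'   testing and the correction family (default 2).
#' @param seed Master seed; fixed seed and config make the whole call
#'   bit-reproducible.
#' @param merge Merge adjacent (book-ended) significant bins into single
#'   reported hotspots?
#' @param within_chromosome Restrict randomization to each breakpoint's own
#'   chromosome?
#' @param pooled_null Compare observed scores against the pooled genome-wide
#'   permuted-score distribution instead of per-bin nulls?
#' @return An object of class `hotspot_result` with components `hotspots`
#'   (significant bins, optionally merged), `bins` (the full scored
#'   segmentation with `p_value`/`q_value`), `config` (the permutation
#'   configuration), and `n_samples`.
#' @examples
#' g <- genome_assembly("chr1", 1e6)
#' set.seed(42)
#' profs <- lapply(1:5, function(i) {
#'   bp <- data.frame(chrom = "chr1",
#'                    pos = c(5e5 + sample(-500:500, 1),
#'                            sample.int(1e6, 3) - 1))
#'   breakpoint_profile(paste0("S", i), bp)
#' })
#' hs <- call_hotspots(profs, g, flank = 1e4, n_perm = 200, seed = 1)
#' hs
#' @export
call_hotspots <- function(profiles, genome, flank = 1e4, n_perm = 1e4,
                          alpha = 0.05, correction = c("bh", "bonferroni"),
                          min_samples = 2, seed = 1, merge = TRUE,
                          within_chromosome = FALSE, pooled_null = FALSE) {
  correction <- match.arg(correction)
  if (!is.list(profiles) || length(profiles) < 2L) {
    stop("hotspot calling needs >= 2 profiles: a hotspot is a region ",
         "recurrently hit across samples", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  bp <- bind_profiles(profiles)
  regions <- extend_breakpoints(bp, flank, genome)
  bins <- segment_by_boundaries(regions, genome,
                                min_samples_tested = min_samples)
  bins <- empirical_pvalues(bins, bp, genome, n_perm = n_perm, flank = flank,
                            seed = seed, within_chromosome = within_chromosome,
                            pooled_null = pooled_null)
  bins$q_value <- NA_real_
  ti <- which(bins$tested)
  if (length(ti)) {
    bins$q_value[ti] <- bh_adjust(bins$p_value[ti], method = correction)
  }
  sig <- bins[bins$tested & !is.na(bins$q_value) & bins$q_value < alpha, ,
              drop = FALSE]
  hot <- if (merge) merge_adjacent_bins(sig) else
    cbind(sig, n_bins = rep(1L, nrow(sig)))
  rownames(hot) <- NULL
  structure(list(
    hotspots = hot,
    bins = bins,
    config = list(flank = flank, n_perm = n_perm, alpha = alpha,
                  correction = correction, min_samples = min_samples,
                  seed = seed, merge = merge,
                  within_chromosome = within_chromosome,
                  pooled_null = pooled_null,
                  placement = if (within_chromosome)
                    "uniform_within_chromosome" else "uniform_genome"),
    n_samples = length(profiles),
    n_breakpoints = nrow(bp),
    genome = genome
  ), class = "hotspot_result")
}
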