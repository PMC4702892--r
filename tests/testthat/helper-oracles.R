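# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (per-base scans, double loops, hand-rolled
# step-up) so they stay independent of the code paths they check.

# BH step-up by hand: sort ascending, q_i = min_{j >= i} m p_(j) / j, cap 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(m * p[o] / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# distinct-sample coverage at single bases
oracle_base_score <- function(regions, chrom, base) {
  sum(!duplicated(regions$sample_id[regions$chrom == chrom &
                                      regions$start <= base &
                                      regions$end > base]))
}

# count query breakpoints inside >= 1 interval, double loop
oracle_interval_overlap <- function(bp, intervals) {
  n <- 0L
  for (i in seq_len(nrow(bp))) {
    hit <- FALSE
    for (j in seq_len(nrow(intervals))) {
      if (bp$chrom[i] == intervals$chrom[j] &&
          bp$pos[i] >= intervals$start[j] && bp$pos[i] < intervals$end[j]) {
        hit <- TRUE
        break
      }
    }
    n <- n + hit
  }
  n
}

# count query breakpoints with a same-chromosome target within +/- window
oracle_profile_overlap <- function(qbp, tbp, window) {
  n <- 0L
  for (i in seq_len(nrow(qbp))) {
    d <- abs(tbp$pos[tbp$chrom == qbp$chrom[i]] - qbp$pos[i])
    n <- n + (length(d) > 0 && min(d) <= window)
  }
  n
}

# all-pairs germline matching: same event type, every defined breakpoint
# within tolerance of the corresponding normal breakpoint
oracle_germline_match <- function(cancer, normal, tol) {
  drop <- logical(nrow(cancer))
  for (i in seq_len(nrow(cancer))) {
    for (j in seq_len(nrow(normal))) {
      if (cancer$event_type[i] != normal$event_type[j]) next
      if (cancer$chrom[i] != normal$chrom[j]) next
      if (abs(cancer$pos[i] - normal$pos[j]) > tol) next
      cm <- cancer$mate_chrom[i]; nm <- normal$mate_chrom[j]
      if (is.na(cm) != is.na(nm)) next
      if (!is.na(cm)) {
        if (cm != nm) next
        if (abs(cancer$mate_pos[i] - normal$mate_pos[j]) > tol) next
      }
      drop[i] <- TRUE
      break
    }
  }
  drop
}

# quick validated record table on a given genome
make_records <- function(genome, n, seed = NULL, sample_id = "S1",
                         support = c(0, 6)) {
  if (!is.null(seed)) set.seed(seed)
  ci <- sample.int(length(genome$chrom), n, replace = TRUE)
  len <- unname(genome$length[ci])
  pos <- floor(runif(n) * len)
  et <- sample(event_types(), n, replace = TRUE)
  mate_chrom <- ifelse(et %in% c("INS"), NA_character_, genome$chrom[ci])
  mate_pos <- ifelse(is.na(mate_chrom), NA_real_,
                     pmin(pos + sample(100:5000, n, replace = TRUE), len - 1))
  # inter-chromosomal events get a mate on the first other chromosome
  inter <- et == "TRA_INTER" & length(genome$chrom) > 1L
  if (any(inter)) {
    other <- vapply(ci[inter], function(k)
      setdiff(seq_along(genome$chrom), k)[1L], 1L)
    mate_chrom[inter] <- genome$chrom[other]
    mate_pos[inter] <- floor(runif(sum(inter)) * unname(genome$length[other]))
  }
  alteration_records(data.frame(
    sample_id = sample_id, chrom = genome$chrom[ci], pos = pos,
    event_type = et,
    discordant_pairs = sample(support[1]:support[2], n, replace = TRUE),
    softclip_reads = sample(support[1]:support[2], n, replace = TRUE),
    mate_chrom = mate_chrom, mate_pos = mate_pos,
    stringsAsFactors = FALSE), genome)
}

test_genome <- function() genome_assembly(c("chr1", "chr2"), c(1e6, 5e5))
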