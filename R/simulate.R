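#' Default toy genome for simulations
#'
#' Three chromosomes of 50, 30 and 20 Mb (100 Mb total): large enough for
#' null-calibration experiments, small enough that permutation tests run in
#' seconds.
#' @return A [genome_assembly()].
#' @export
default_toy_genome <- function() {
  genome_assembly(c("chr1", "chr2", "chr3"), c(5e7, 3e7, 2e7))
}

#' Configuration of a synthetic breakpoint-profile cohort
#'
#' Describes a cohort with a uniform background breakpoint rate and optional
#' planted recurrent hotspot loci, the ground truth for evaluating filtering
#' and hotspot calling.
#'
#' @param genome A [genome_assembly()] (default [default_toy_genome()]).
#' @param n_samples Number of samples (default 20).
#' @param background_per_sample Background events per sample, placed
#'   uniformly over the genome (chromosome proportional to length;
#'   default 50).
#' @param hotspot_loci Data.frame with columns `chrom`, `center`,
#'   `half_width`, `penetrance`: each locus adds one breakpoint within
#'   `center +/- half_width` to each sample independently with probability
#'   `penetrance`. `NULL` or zero rows means pure background.
#' @param event_type_weights Named non-negative weights over [event_types()];
#'   default is a deletion-heavy mixture typical of somatic SV catalogues.
#' @param size_range Length-2 vector, min/max event size in bases for the
#'   synthetic mate of intra-chromosomal events (default 1,000-1,000,000).
#' @param support_range Length-2 vector, min/max for discordant-pair and
#'   soft-clip read counts, drawn uniformly (default 2-20, i.e. calls that
#'   pass the default support filter).
#' @param cancer_type Group label stamped on the profiles (default `"SIM"`).
#' @param seed Master seed; fixed seed gives bit-identical cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome = default_toy_genome(), n_samples = 20,
                              background_per_sample = 50,
                              hotspot_loci = NULL,
                              event_type_weights = c(DEL = 0.30, INS = 0.10,
                                                     INV = 0.15, TDUP = 0.15,
                                                     TRA_INTRA = 0.10,
                                                     TRA_INTER = 0.10,
                                                     COMPLEX = 0.10),
                              size_range = c(1e3, 1e6),
                              support_range = c(2, 20),
                              cancer_type = "SIM", seed = 1) {
  stopifnot(inherits(genome, "genome_assembly"))
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (background_per_sample < 0) {
    stop("background_per_sample must be >= 0", call. = FALSE)
  }
  if (is.null(hotspot_loci)) {
    hotspot_loci <- data.frame(chrom = character(), center = numeric(),
                               half_width = numeric(), penetrance = numeric())
  }
  stopifnot(all(c("chrom", "center", "half_width", "penetrance") %in%
                  names(hotspot_loci)))
  if (nrow(hotspot_loci)) {
    check_locus(hotspot_loci$chrom, hotspot_loci$center, genome,
                what = "hotspot locus")
    if (any(hotspot_loci$penetrance < 0 | hotspot_loci$penetrance > 1)) {
      stop("penetrance must lie in [0, 1]", call. = FALSE)
    }
    if (any(hotspot_loci$half_width < 0)) {
      stop("half_width must be >= 0", call. = FALSE)
    }
  }
  w <- event_type_weights[event_types()]
  if (anyNA(w) || any(w < 0) || sum(w) == 0) {
    stop("event_type_weights must be non-negative over all of ",
         paste(event_types(), collapse = ", "), " and not all zero",
         call. = FALSE)
  }
  if (length(size_range) != 2L || size_range[1] > size_range[2] ||
      size_range[1] < 0) {
    stop("size_range must be a non-decreasing pair of non-negative sizes",
         call. = FALSE)
  }
  if (length(support_range) != 2L || support_range[1] > support_range[2] ||
      support_range[1] < 0) {
    stop("support_range must be a non-decreasing pair of non-negative counts",
         call. = FALSE)
  }
  structure(list(genome = genome, n_samples = n_samples,
                 background_per_sample = background_per_sample,
                 hotspot_loci = hotspot_loci,
                 event_type_weights = w, size_range = size_range,
                 support_range = support_range, cancer_type = cancer_type,
                 seed = seed),
            class = "simulation_config")
}

runif_int <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

#' Simulate a cohort of breakpoint profiles with known ground truth
#'
#' Each sample gets `background_per_sample` events placed uniformly over the
#' genome plus, for every planted locus, one event within
#' `center +/- half_width` with probability `penetrance`. Event types are
#' drawn from the configured mixture, read supports uniformly from
#' `support_range`; intra-chromosomal events carry a synthetic mate at a
#' distance drawn from `size_range` (so the size filter is exercised) and
#' inter-chromosomal translocations a mate on another chromosome. Each
#' simulated event contributes exactly one counted breakpoint (its primary
#' locus) to the returned profiles, so per-sample breakpoint counts equal
#' `background_per_sample + planted hits`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `profiles` (list of [breakpoint_profile()]), `records`
#'   (combined validated alteration-record data.frame, one row per event),
#'   and `truth` (one row per locus x sample: `locus_id`, `chrom`, `center`,
#'   `half_width`, `penetrance`, `sample_id`, `hit`, `pos`).
#' @export
simulate_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  g <- cfg$genome
  set.seed(cfg$seed)
  sample_ids <- sprintf("%s_sim%02d", cfg$cancer_type, seq_len(cfg$n_samples))
  recs <- vector("list", cfg$n_samples)
  truth <- vector("list", cfg$n_samples)
  nloci <- nrow(cfg$hotspot_loci)
  for (i in seq_len(cfg$n_samples)) {
    nb <- cfg$background_per_sample
    ci <- if (nb) sample.int(length(g$chrom), nb, replace = TRUE,
                             prob = g$length) else integer()
    chrom <- g$chrom[ci]
    pos <- if (nb) pmin(floor(stats::runif(nb) * unname(g$length[ci])),
                        unname(g$length[ci]) - 1) else numeric()
    hit <- logical(nloci)
    hpos <- rep(NA_real_, nloci)
    if (nloci) {
      hit <- stats::runif(nloci) < cfg$hotspot_loci$penetrance
      if (any(hit)) {
        hl <- cfg$hotspot_loci[hit, , drop = FALSE]
        len <- chrom_length(g, hl$chrom)
        p <- runif_int(nrow(hl), pmax(hl$center - hl$half_width, 0),
                       pmin(hl$center + hl$half_width, len - 1))
        hpos[hit] <- p
        chrom <- c(chrom, hl$chrom)
        pos <- c(pos, p)
      }
    }
    n <- length(pos)
    et <- event_types()[sample.int(length(event_types()), n, replace = TRUE,
                                   prob = cfg$event_type_weights)]
    rec <- data.frame(sample_id = rep(sample_ids[i], n),
                      chrom = chrom, pos = pos, event_type = et,
                      discordant_pairs = runif_int(n, cfg$support_range[1],
                                                   cfg$support_range[2]),
                      softclip_reads = runif_int(n, cfg$support_range[1],
                                                 cfg$support_range[2]),
                      mate_chrom = rep(NA_character_, n),
                      mate_pos = rep(NA_real_, n),
                      stringsAsFactors = FALSE)
    rec <- add_synthetic_mates(rec, g, cfg$size_range)
    recs[[i]] <- rec
    truth[[i]] <- if (nloci) data.frame(
      locus_id = seq_len(nloci),
      chrom = cfg$hotspot_loci$chrom,
      center = cfg$hotspot_loci$center,
      half_width = cfg$hotspot_loci$half_width,
      penetrance = cfg$hotspot_loci$penetrance,
      sample_id = sample_ids[i], hit = hit, pos = hpos,
      stringsAsFactors = FALSE) else NULL
  }
  records <- alteration_records(do.call(rbind, recs), g)
  profiles <- lapply(seq_len(cfg$n_samples), function(i) {
    bp <- recs[[i]][, c("sample_id", "chrom", "pos", "event_type")]
    breakpoint_profile(sample_ids[i], bp, cancer_type = cfg$cancer_type)
  })
  truth <- if (nloci) do.call(rbind, truth) else
    data.frame(locus_id = integer(), chrom = character(), center = numeric(),
               half_width = numeric(), penetrance = numeric(),
               sample_id = character(), hit = logical(), pos = numeric())
  rownames(truth) <- NULL
  list(profiles = profiles, records = records, truth = truth)
}

# give intra-chromosomal events a mate at distance from size_range (flipped
# into bounds where needed) and inter-chromosomal translocations a mate on
# another chromosome; insertions stay single-breakpoint
add_synthetic_mates <- function(rec, g, size_range) {
  n <- nrow(rec)
  if (n == 0L) return(rec)
  intra <- rec$event_type %in% intra_event_types()
  inter <- rec$event_type == "TRA_INTER"
  if (any(intra)) {
    len <- chrom_length(g, rec$chrom[intra])
    size <- pmin(runif_int(sum(intra), size_range[1], size_range[2]), len - 1)
    sign <- ifelse(stats::runif(sum(intra)) < 0.5, 1, -1)
    mate <- rec$pos[intra] + sign * size
    flip <- mate < 0 | mate >= len
    mate[flip] <- rec$pos[intra][flip] - sign[flip] * size[flip]
    mate <- pmin(pmax(mate, 0), len - 1)   # degenerate tiny chromosome guard
    rec$mate_chrom[intra] <- rec$chrom[intra]
    rec$mate_pos[intra] <- mate
  }
  if (any(inter) && length(g$chrom) > 1L) {
    for (j in which(inter)) {
      others <- which(g$chrom != rec$chrom[j])
      ci <- others[sample.int(length(others), 1L,
                              prob = g$length[others])]
      rec$mate_chrom[j] <- g$chrom[ci]
      rec$mate_pos[j] <- min(floor(stats::runif(1) * g$length[[ci]]),
                             g$length[[ci]] - 1)
    }
  }
  rec
}

#' Simulate matched cancer/normal record sets for germline subtraction
#'
#' Simulates a cancer cohort, then copies a fixed fraction of each sample's
#' records (with positional jitter of at most `jitter` bases) into a pooled
#' normal record set, labelling every cancer record somatic or germline in
#' the returned ground truth. [subtract_germline()] at a tolerance `>=
#' jitter` should then remove exactly the germline-labelled records.
#'
#' @param cfg A [simulation_config()].
#' @param shared_fraction Fraction of each sample's records duplicated into
#'   the normals, in `[0, 1]`; the duplicated count is
#'   `round(shared_fraction * n)`.
#' @param jitter Maximum absolute positional jitter in bases applied to the
#'   normal copies (default 50, within the default 100 bp matching
#'   tolerance).
#' @return List with `cancer` (records with logical `is_germline` column),
#'   `normal` (pooled normal records), and `profiles` (the cancer profiles).
#' @export
simulate_germline_pair <- function(cfg, shared_fraction, jitter = 50) {
  stopifnot(inherits(cfg, "simulation_config"),
            shared_fraction >= 0, shared_fraction <= 1, jitter >= 0)
  sim <- simulate_profiles(cfg)
  rec <- sim$records
  rec$is_germline <- FALSE
  normals <- list()
  for (sid in unique(rec$sample_id)) {
    idx <- which(rec$sample_id == sid)
    k <- round(shared_fraction * length(idx))
    if (k == 0L) next
    shared <- sort(sample(idx, k))
    rec$is_germline[shared] <- TRUE
    nm <- rec[shared, setdiff(names(rec), "is_germline"), drop = FALSE]
    nm$sample_id <- paste0(sid, "_N")
    len <- chrom_length(cfg$genome, nm$chrom)
    nm$pos <- pmin(pmax(nm$pos + runif_int(k, -jitter, jitter), 0), len - 1)
    has <- !is.na(nm$mate_chrom)
    if (any(has)) {
      mlen <- chrom_length(cfg$genome, nm$mate_chrom[has])
      nm$mate_pos[has] <- pmin(pmax(nm$mate_pos[has] +
                                      runif_int(sum(has), -jitter, jitter),
                                    0), mlen - 1)
    }
    normals[[sid]] <- nm
  }
  normal <- if (length(normals)) {
    alteration_records(do.call(rbind, normals), cfg$genome)
  } else {
    alteration_records(empty_records(), cfg$genome)
  }
  list(cancer = rec, normal = normal, profiles = sim$profiles)
}

#' Write a simulated cohort to disk
#'
#' One profile BED per sample (named `<sample_id>.bed`) plus a ground-truth
#' TSV and a chrom.sizes file for the simulated genome.
#'
#' @param sim Result of [simulate_profiles()].
#' @param genome The [genome_assembly()] used for the simulation.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(sim$records$sample_id)) {
    write_profile(sim$records[sim$records$sample_id == sid, , drop = FALSE],
                  file.path(dir, paste0(sid, ".bed")))
  }
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_chrom_sizes(genome, file.path(dir, "genome.chrom.sizes"))
  invisible(dir)
}
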