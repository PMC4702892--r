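g2 <- genome_assembly(c("chr1", "chr2"), c(1e8, 5e7))

rec_with <- function(disc, soft, size = NA, event = "DEL") {
  n <- max(length(disc), length(soft), length(size), length(event))
  disc <- rep_len(disc, n); soft <- rep_len(soft, n)
  size <- rep_len(size, n); event <- rep_len(event, n)
  alteration_records(data.frame(
    sample_id = "S1", chrom = "chr1", pos = seq_len(n) * 1000,
    event_type = event, discordant_pairs = disc, softclip_reads = soft,
    mate_chrom = ifelse(is.na(size), NA_character_, "chr1"),
    mate_pos = ifelse(is.na(size), NA_real_, seq_len(n) * 1000 + size),
    stringsAsFactors = FALSE), g2)
}

test_that("support filter keeps >=2 discordant AND >=2 soft-clip", {
  rec <- rec_with(disc = c(2, 1), soft = c(2, 5))
  out <- filter_support(rec, filter_config())
  expect_equal(out$pos, rec$pos[1])

  expect_equal(nrow(filter_support(rec, filter_config(min_discordant = 0,
                                                      min_softclip = 0))),
               nrow(rec))

  # exhaustive grid: survivors equal brute-force conjunction count
  grid <- expand.grid(d = 0:4, s = 0:4)
  rec_grid <- rec_with(disc = grid$d, soft = grid$s)
  out_grid <- filter_support(rec_grid, filter_config())
  expect_equal(nrow(out_grid), sum(grid$d >= 2 & grid$s >= 2))
  expect_equal(out_grid, rec_grid[rec_grid$discordant_pairs >= 2 &
                                    rec_grid$softclip_reads >= 2, ])
})

test_that("size filter is strict 'more than' and spares undefined sizes", {
  rec <- rec_with(disc = 5, soft = 5, size = c(10000001, 10000000))
  out <- filter_size(rec, filter_config())
  expect_equal(out$size, 10000000)

  tra <- alteration_records(data.frame(
    sample_id = "S1", chrom = "chr1", pos = 100, event_type = "TRA_INTER",
    discordant_pairs = 5, softclip_reads = 5,
    mate_chrom = "chr2", mate_pos = 2e7), g2)
  expect_equal(nrow(filter_size(tra, filter_config(max_size = 0))), 1L)

  mix <- rec_with(disc = 5, soft = 5, size = c(0, 5, NA))
  out0 <- filter_size(mix, filter_config(max_size = 0))
  expect_true(all(is.na(out0$size) | out0$size == 0))
  expect_equal(nrow(out0), 2L)
})

test_that("germline subtraction matches by event type and proximity", {
  cancer <- alteration_records(data.frame(
    sample_id = "T", chrom = "chr1", pos = 1000, event_type = "DEL",
    discordant_pairs = 5, softclip_reads = 5,
    mate_chrom = "chr1", mate_pos = 5000), g2)
  normal <- alteration_records(data.frame(
    sample_id = "N", chrom = "chr1", pos = 1050, event_type = "DEL",
    discordant_pairs = 5, softclip_reads = 5,
    mate_chrom = "chr1", mate_pos = 4990), g2)
  expect_equal(nrow(subtract_germline(cancer, normal,
                                      filter_config(germline_tolerance = 100))),
               0L)
  expect_equal(nrow(subtract_germline(cancer, normal,
                                      filter_config(germline_tolerance = 10))),
               1L)
  # different event type never matches, however close
  normal2 <- normal
  normal2$event_type <- "TDUP"
  expect_equal(nrow(subtract_germline(cancer, normal2, filter_config())), 1L)
})

test_that("germline subtraction equals the all-pairs oracle", {
  for (seed in 1:5) {
    cancer <- make_records(g2, 60, seed = seed, sample_id = "T")
    normal <- make_records(g2, 40, seed = seed + 100, sample_id = "N")
    # pull some normals onto cancer loci so matches actually occur
    normal[1:15, c("chrom", "pos", "event_type", "mate_chrom", "mate_pos")] <-
      cancer[1:15, c("chrom", "pos", "event_type", "mate_chrom", "mate_pos")]
    normal$pos[1:15] <- normal$pos[1:15] + sample(-120:120, 15, replace = TRUE)
    normal <- alteration_records(normal, g2)
    cfg <- filter_config(germline_tolerance = 100)
    out <- subtract_germline(cancer, normal, cfg)
    drop <- oracle_germline_match(cancer, normal, 100)
    expect_equal(out, cancer[!drop, ])
  }
})

test_that("blacklist removal uses half-open breakpoint containment", {
  rec <- alteration_records(data.frame(
    sample_id = "S1", chrom = "chr1", pos = c(150, 200), event_type = "INS",
    discordant_pairs = 2, softclip_reads = 2,
    mate_chrom = NA_character_, mate_pos = NA_real_), g2)
  bl <- data.frame(chrom = "chr1", start = 100, end = 200)
  out <- subtract_blacklist(rec, bl)
  expect_equal(out$pos, 200)   # end is exclusive

  expect_equal(subtract_blacklist(rec, bl[0, ]), rec)

  # mate containment also removes the record
  rec2 <- alteration_records(data.frame(
    sample_id = "S1", chrom = "chr1", pos = 5e5, event_type = "DEL",
    discordant_pairs = 2, softclip_reads = 2,
    mate_chrom = "chr1", mate_pos = 150), g2)
  expect_equal(nrow(subtract_blacklist(rec2, bl)), 0L)
})

test_that("blacklist removal equals the per-record containment oracle", {
  set.seed(42)
  for (rep in 1:5) {
    rec <- make_records(g2, 80, sample_id = "S1")
    bl <- data.frame(chrom = sample(g2$chrom, 30, replace = TRUE),
                     start = s <- sample.int(1e8 - 1e5, 30),
                     end = s + sample.int(5e4, 30))
    out <- subtract_blacklist(rec, bl)
    drop <- vapply(seq_len(nrow(rec)), function(i) {
      hit <- oracle_interval_overlap(rec[i, c("chrom", "pos")], bl) > 0
      if (!hit && !is.na(rec$mate_chrom[i])) {
        hit <- oracle_interval_overlap(
          data.frame(chrom = rec$mate_chrom[i], pos = rec$mate_pos[i]), bl) > 0
      }
      hit
    }, TRUE)
    expect_equal(out, rec[!drop, ])
  }
})

test_that("filters are monotone in their thresholds and idempotent", {
  rec <- make_records(g2, 150, seed = 3)
  n_prev <- Inf
  for (thr in c(0, 1, 2, 4, 8)) {
    n <- nrow(filter_support(rec, filter_config(min_discordant = thr,
                                                min_softclip = thr)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- -1
  for (ms in c(0, 1e3, 1e5, 1e7)) {
    n <- nrow(filter_size(rec, filter_config(max_size = ms)))
    expect_gte(n, n_prev)  # larger cap keeps at least as many
    n_prev <- n
  }
  set.seed(9)
  bl_big <- data.frame(chrom = sample(g2$chrom, 40, replace = TRUE),
                       start = s <- sample.int(1e7, 40), end = s + 2e4)
  for (k in c(0, 10, 25, 40)) {
    n <- nrow(subtract_blacklist(rec, bl_big[seq_len(k), , drop = FALSE]))
    if (k == 0) n_prev <- n
    expect_lte(n, n_prev)
    n_prev <- n
  }
  # idempotence
  cfg <- filter_config()
  expect_equal(filter_support(filter_support(rec, cfg), cfg),
               filter_support(rec, cfg))
  expect_equal(filter_size(filter_size(rec, cfg), cfg), filter_size(rec, cfg))
  expect_equal(subtract_blacklist(subtract_blacklist(rec, bl_big), bl_big),
               subtract_blacklist(rec, bl_big))
})
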