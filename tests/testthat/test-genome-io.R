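test_that("chrom.sizes parsing preserves order and validates input", {
  f <- withr::local_tempfile(lines = c("chr1\t1000000", "chr2\t500000"))
  g <- read_chrom_sizes(f)
  expect_s3_class(g, "genome_assembly")
  expect_identical(g$chrom, c("chr1", "chr2"))
  expect_equal(genome_size(g), 1500000)

  empty <- withr::local_tempfile(lines = character())
  expect_error(read_chrom_sizes(empty), "empty")

  dup <- withr::local_tempfile(lines = c("chr1\t1000", "chr1\t2000"))
  expect_error(read_chrom_sizes(dup), "duplicate")

  neg <- withr::local_tempfile(lines = c("chr1\t1000", "chr2\t0"))
  expect_error(read_chrom_sizes(neg), "line 2")

  bad <- withr::local_tempfile(lines = c("chr1\t1000", "chr2"))
  expect_error(read_chrom_sizes(bad), "line 2")
})

test_that("profile BED dialect parses a full record", {
  g <- test_genome()
  f <- withr::local_tempfile(lines = "chr1\t49999\t50000\tDEL\t5\t3\tchr1:60000")
  rec <- read_profile(f, g)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$pos, 49999)
  expect_equal(rec$event_type, "DEL")
  expect_equal(rec$discordant_pairs, 5)
  expect_equal(rec$softclip_reads, 3)
  expect_equal(rec$mate_chrom, "chr1")
  expect_equal(rec$mate_pos, 60000)
  expect_equal(rec$size, 10001)
  expect_equal(rec$sample_id, sub("\\.[^.]*$", "", basename(f)))
})

test_that("profile parsing rejects out-of-universe and malformed records", {
  g <- genome_assembly("chr1", 1e6)
  f <- withr::local_tempfile(lines = "chrUn\t100\t101\tDEL\t5\t3\t.")
  expect_error(read_profile(f, g), "chrUn")

  f2 <- withr::local_tempfile(lines = "chr1\t1000000\t1000001\tDEL\t5\t3\t.")
  expect_error(read_profile(f2, g), "out of range")

  f3 <- withr::local_tempfile(lines = "chr1\t100\t101\tBADTYPE\t5\t3\t.")
  expect_error(read_profile(f3, g), "DEL.*INS|accepted tokens")

  f4 <- withr::local_tempfile(lines = c("# comment", "track name=x"))
  expect_equal(nrow(read_profile(f4, g)), 0L)
})

test_that("missing support columns parse as zero", {
  g <- genome_assembly("chr1", 1e6)
  f <- withr::local_tempfile(lines = "chr1\t100\t101\tINS")
  rec <- read_profile(f, g)
  expect_equal(rec$discordant_pairs, 0)
  expect_equal(rec$softclip_reads, 0)
  expect_true(is.na(rec$mate_chrom))
  # zero support is visibly rejected by the default support filter
  expect_equal(nrow(filter_support(rec, filter_config())), 0L)
})

test_that("write/read round trip is lossless for all fields", {
  g <- test_genome()
  rec <- make_records(g, 40, seed = 7)
  f <- withr::local_tempfile()
  write_profile(rec, f)
  back <- read_profile(f, g, sample_id = "S1")
  expect_equal(back, rec)
})

test_that("display BED windows are centred, clipped and half-open", {
  g <- genome_assembly("chr1", 1e6)
  prof <- breakpoint_profile("S1", data.frame(chrom = "chr1",
                                              pos = c(50000, 4000, 200)))
  f <- withr::local_tempfile()
  write_display_bed(prof, 10000, g, f)
  out <- read.table(f, sep = "\t")
  expect_equal(out$V2, c(40000, 0, 0))
  expect_equal(out$V3, c(60001, 14001, 10201))

  write_display_bed(prof, 0, g, f)
  out0 <- read.table(f, sep = "\t")
  expect_equal(out0$V2, prof$breakpoints$pos)
  expect_equal(out0$V3, prof$breakpoints$pos + 1)
  # all intervals satisfy 0 <= start < end <= chromosome length
  expect_true(all(out$V2 >= 0 & out$V2 < out$V3 & out$V3 <= 1e6))
})

test_that("mate expansion yields one breakpoint per chromosome side", {
  g <- test_genome()
  rec <- alteration_records(data.frame(
    sample_id = "S1", chrom = c("chr1", "chr1", "chr1"),
    pos = c(100, 200, 300), event_type = c("DEL", "INS", "TRA_INTER"),
    discordant_pairs = 2, softclip_reads = 2,
    mate_chrom = c("chr1", NA, "chr2"), mate_pos = c(5100, NA, 900)), g)
  expect_true(is.na(rec$size[3]))   # inter-chromosomal: size undefined
  bp <- profile_breakpoints(rec)
  expect_equal(nrow(bp), 5L)        # DEL: 2, INS: 1, TRA_INTER: 2
  expect_equal(nrow(profile_breakpoints(rec, expand_mates = FALSE)), 3L)
})

test_that("results TSV carries chrom/start/end/score/p/q header", {
  bins <- data.frame(chrom = "chr1", start = 0, end = 10, score = 2L,
                     tested = TRUE, p_value = 0.01, q_value = 0.02)
  f <- withr::local_tempfile()
  write_results(bins, f)
  out <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(names(out)[1:6], c("chrom", "start", "end", "score",
                                      "p", "q"))
  expect_equal(out$q, 0.02)
})
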