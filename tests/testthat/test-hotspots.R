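toy_cohort <- function(n = 12, bg = 20, pen = 1.0, seed = 8) {
  cfg <- simulation_config(
    n_samples = n, background_per_sample = bg,
    hotspot_loci = data.frame(chrom = "chr1", center = 2.5e7,
                              half_width = 5e3, penetrance = pen),
    seed = seed)
  simulate_profiles(cfg)
}

test_that("a recurrently hit locus is reported as a hotspot", {
  sim <- toy_cohort()
  res <- call_hotspots(sim$profiles, default_toy_genome(), n_perm = 300,
                       seed = 4)
  expect_s3_class(res, "hotspot_result")
  hs <- res$hotspots
  expect_gt(nrow(hs), 0)
  planted <- hs$chrom == "chr1" & hs$start < 2.5e7 + 5e3 & hs$end > 2.5e7 - 5e3
  expect_true(any(planted))
  expect_gte(max(hs$score[planted]), 10)
  # every hotspot is a tested bin below alpha
  expect_true(all(hs$q_value < res$config$alpha))
  expect_true(all(res$bins$tested[match(
    paste(hs$chrom, hs$start), paste(res$bins$chrom, res$bins$start))]))
})

test_that("recurrence requires at least two profiles", {
  sim <- toy_cohort(n = 2)
  expect_error(call_hotspots(sim$profiles[1], default_toy_genome()),
               ">= 2 profiles")
  expect_error(call_hotspots(list(), default_toy_genome()), ">= 2 profiles")
})

test_that("hotspot calling is bit-reproducible under a fixed seed", {
  sim <- toy_cohort(n = 6, bg = 10)
  a <- call_hotspots(sim$profiles, default_toy_genome(), n_perm = 120,
                     seed = 99)
  b <- call_hotspots(sim$profiles, default_toy_genome(), n_perm = 120,
                     seed = 99)
  expect_identical(a, b)
})

test_that("p-values are bounded by the pseudocount floor and one", {
  sim <- toy_cohort(n = 6, bg = 10)
  res <- call_hotspots(sim$profiles, default_toy_genome(), n_perm = 120,
                       seed = 12)
  p <- res$bins$p_value[res$bins$tested]
  expect_true(all(p >= 1 / 121 & p <= 1))
  expect_true(all(is.na(res$bins$p_value[!res$bins$tested])))
})

test_that("merging fuses only book-ended significant bins", {
  sim <- toy_cohort()
  g <- default_toy_genome()
  merged <- call_hotspots(sim$profiles, g, n_perm = 300, seed = 4)
  unmerged <- call_hotspots(sim$profiles, g, n_perm = 300, seed = 4,
                            merge = FALSE)
  expect_identical(merged$bins, unmerged$bins)
  expect_equal(sum(merged$hotspots$n_bins), nrow(unmerged$hotspots))
  expect_gte(nrow(unmerged$hotspots), nrow(merged$hotspots))
  # merged hotspots never abut on the same chromosome
  h <- merged$hotspots
  if (nrow(h) > 1) {
    same <- h$chrom[-1] == h$chrom[-nrow(h)]
    expect_true(all(h$start[-1][same] > h$end[-nrow(h)][same]))
  }
  # total merged span equals total significant-bin span
  expect_equal(sum(h$end - h$start),
               sum(unmerged$hotspots$end - unmerged$hotspots$start))
})

test_that("Bonferroni calls are a subset of BH calls", {
  sim <- toy_cohort()
  g <- default_toy_genome()
  bh <- call_hotspots(sim$profiles, g, n_perm = 300, seed = 4, merge = FALSE)
  bf <- call_hotspots(sim$profiles, g, n_perm = 300, seed = 4, merge = FALSE,
                      correction = "bonferroni")
  expect_identical(bh$bins$p_value, bf$bins$p_value)
  key <- function(h) paste(h$chrom, h$start, h$end)
  expect_true(all(key(bf$hotspots) %in% key(bh$hotspots)))
  expect_true(all(bf$bins$q_value >= bh$bins$q_value, na.rm = TRUE))
})

test_that("the pooled null is a valid alternative scoring mode", {
  sim <- toy_cohort(n = 8, bg = 15)
  g <- default_toy_genome()
  res <- call_hotspots(sim$profiles, g, n_perm = 150, seed = 21,
                       pooled_null = TRUE)
  p <- res$bins$p_value[res$bins$tested]
  expect_true(all(p > 0 & p <= 1))
  # the planted locus is still the strongest signal
  top <- res$bins[which.min(res$bins$p_value), ]
  expect_equal(top$chrom, "chr1")
  expect_lt(abs((top$start + top$end) / 2 - 2.5e7), 2e4)
})

test_that("result methods expose the fit the way model objects do", {
  sim <- toy_cohort(n = 6, bg = 10)
  res <- call_hotspots(sim$profiles, default_toy_genome(), n_perm = 120,
                       seed = 12)
  expect_output(print(res), "Breakpoint hotspot analysis")
  s <- summary(res)
  expect_s3_class(s, "summary.hotspot_result")
  expect_output(print(s), "hotspot")
  expect_identical(as.data.frame(res), res$hotspots)
  expect_identical(as.data.frame(res, which = "bins"), res$bins)
  f <- tempfile(fileext = ".png")
  png(f); plot(res); dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
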