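test_that("generate_genome is deterministic, labels long TEs by the
           threshold, and concentrates long-TE bp pericentromerically", {
  g1 <- toy_genome(seed = 7L)
  g2 <- toy_genome(seed = 7L)
  expect_identical(g1, g2)
  expect_false(identical(g1$tes, toy_genome(seed = 8L)$tes))

  expect_true(all(g1$tes$length[g1$tes$long] > 4000))
  expect_true(all(g1$tes$length[!g1$tes$long] <= 4000))
  expect_true(any(g1$tes$long) && any(!g1$tes$long))
  expect_gte(nrow(g1$chrom_sizes), 2L)

  # long-TE bp inside the pericentromeric third exceeds bp outside
  peri_gr <- GenomicRanges::GRanges(
    g1$pericentromere$chrom,
    IRanges::IRanges(g1$pericentromere$start + 1, g1$pericentromere$end))
  long <- g1$tes[g1$tes$long, ]
  lg <- GenomicRanges::GRanges(long$chrom,
                               IRanges::IRanges(long$start + 1, long$end))
  inside <- sum(GenomicRanges::width(GenomicRanges::intersect(lg, peri_gr)))
  expect_gt(inside, sum(long$length) - inside)

  expect_error(generate_genome(genome_spec(c(c1 = 500L))), "10x bin size")
})

test_that("write_synthetic_dataset emits byte-identical files for the same
           seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mk <- function(dir) {
    g <- toy_genome(seed = 3L, mb = 0.1)
    m <- methylome_model(coverage_mean = 5,
                         cytosine_density = c(CG = 2, CHG = 2, CHH = 2))
    wt <- simulate_methylome(g, m, "wildtype", seed = 3L)
    write_synthetic_dataset(dir, g, list(wildtype = wt),
                            chip = simulate_chip(g, chip_model(window = 1000L),
                                                 seed = 3L))
  }
  f1 <- mk(d1); f2 <- mk(d2)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(unname(tools::md5sum(f1[i])),
                     unname(tools::md5sum(f2[i])),
                     label = basename(f1[i]))
  }
})

test_that("simulate_methylome: planted losses shift the mutant mean where
           and only where configured", {
  g <- toy_genome(seed = 11L, mb = 0.2)
  m <- methylome_model(mutant_delta = c(CG = 0, CHG = -0.5, CHH = -0.15),
                       coverage_mean = 20)
  wt <- simulate_methylome(g, m, "wildtype", seed = 11L)
  mut <- simulate_methylome(g, m, "mutant", seed = 11L)
  planted <- attr(mut, "planted_dmrs")
  expect_gt(nrow(planted), 0L)
  # shared cytosine map between genotypes
  expect_equal(wt$pos, mut$pos)
  expect_equal(wt$context, mut$context)

  # CHG inside planted regions: 0.7 - 0.5 = 0.2 within +/- 0.03
  mut_chg <- region_stats(mut, planted, context = "CHG")$values
  expect_lt(abs(mean(mut_chg, na.rm = TRUE) - 0.2), 0.03)
  wt_chg <- region_stats(wt, planted, context = "CHG")$values
  expect_lt(abs(mean(wt_chg, na.rm = TRUE) - 0.7), 0.03)
  # CG untouched
  mut_cg <- region_stats(mut, planted, context = "CG")$values
  expect_lt(abs(mean(mut_cg, na.rm = TRUE) - 0.85), 0.03)
})

test_that("null mutant (zero deltas) is distributionally identical to
           wild-type at the bin level", {
  g <- toy_genome(seed = 19L, mb = 0.2)
  m <- methylome_model(mutant_delta = c(CG = 0, CHG = 0, CHH = 0))
  wt <- simulate_methylome(g, m, "wildtype", seed = 19L)
  mut <- simulate_methylome(g, m, "mutant", seed = 19L)
  bins <- make_bins(g$chrom_sizes, 100L)
  a <- aggregate_bins(wt, bins, "CHG")
  b <- aggregate_bins(mut, bins, "CHG")
  ok <- !is.na(a$level) & !is.na(b$level)
  ks <- suppressWarnings(stats::ks.test(a$level[ok], b$level[ok]))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero coverage yields a well-formed all-zero table", {
  g <- toy_genome(seed = 2L, mb = 0.1)
  m <- methylome_model(coverage_mean = 0,
                       cytosine_density = c(CG = 1, CHG = 1, CHH = 1))
  tab <- simulate_methylome(g, m, "wildtype", seed = 2L)
  expect_true(all(tab$count_total == 0L))
  expect_true(all(tab$count_methylated == 0L))
  expect_gt(nrow(tab), 0L)
})

test_that("simulate_chip: noiseless reader track correlates perfectly with
           H3K9me2; default noise keeps r >= 0.8; peaks overlap the target", {
  g <- toy_genome(seed = 5L)
  clean <- simulate_chip(g, chip_model(noise_sdlog = 0), seed = 5L)
  r0 <- track_correlation(clean$tracks$agdp1, clean$tracks$h3k9me2,
                          g$chrom_sizes)
  expect_equal(r0$pearson, 1)

  noisy <- simulate_chip(g, chip_model(), seed = 5L)
  r <- track_correlation(noisy$tracks$agdp1, noisy$tracks$h3k9me2,
                         g$chrom_sizes, bin = 10000L)
  expect_gte(r$pearson, 0.8)

  # every peak overlaps the target mask by >= 1 bp
  expect_gt(nrow(noisy$peaks), 0L)
  ov <- overlap_sets(noisy$peaks, noisy$target_mask)
  expect_equal(ov$n_a_overlapping_b, nrow(noisy$peaks))
})

test_that("long-TE-binding scenario: ground-truth bound TEs are the long
           ones and their median length exceeds the all-TE median", {
  g <- toy_genome(seed = 23L)
  chip <- simulate_chip(g, chip_model(target = "long_tes"), seed = 23L)
  cb <- classify_bound_tes(g$tes, chip$peaks)
  expect_gt(cb$median_bound_length, cb$median_all_length)
  # bound set recovers predominantly long TEs
  expect_gt(mean(cb$tes$long[cb$tes$bound]), 0.9)
})
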