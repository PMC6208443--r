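cs1 <- data.frame(chrom = "chr1", length = 100000L)

test_that("per-million normalization is the unit-factor linear scaling", {
  tr <- flat_track(cs1, value = 3, total_mapped = 1e6)
  nt <- normalize_per_million(tr)
  expect_equal(nt$intervals$value, tr$intervals$value)
  tr2 <- flat_track(cs1, value = 3, total_mapped = 2e6)
  expect_equal(normalize_per_million(tr2)$intervals$value,
               tr$intervals$value / 2)
  z <- flat_track(cs1, value = 0, total_mapped = 1e6)
  expect_true(all(normalize_per_million(z)$intervals$value == 0))
  expect_error(normalize_per_million(flat_track(cs1, 1)), "total_mapped")
})

test_that("coverage_track rejects negative values and overlapping intervals", {
  expect_error(coverage_track(data.frame(chrom = "chr1", start = 0L,
                                         end = 10L, value = -1)),
               "non-negative")
  expect_error(coverage_track(data.frame(chrom = "chr1",
                                         start = c(0L, 5L),
                                         end = c(10L, 15L), value = 1)),
               "overlap")
})

test_that("metaplot of a constant track is constant; step track matches
           hand-computed bin averages", {
  tr <- flat_track(cs1, value = 2.5)
  feats <- data.frame(chrom = "chr1", start = c(10000L, 40000L),
                      end = c(16000L, 52000L), strand = c("+", "-"))
  mp <- metaplot(tr, feats, flank_bp = 2000L, body_bins = 10L,
                 flank_bins = 4L)
  expect_equal(unname(mp$mean), rep(2.5, 18), tolerance = 1e-12)

  # step track: value 1 on [0,5000), 3 on [5000,10000); feature [0,10000)
  step <- coverage_track(data.frame(chrom = "chr1",
                                    start = c(0L, 5000L),
                                    end = c(5000L, 10000L),
                                    value = c(1, 3)))
  f1 <- data.frame(chrom = "chr1", start = 0L, end = 10000L, strand = "+")
  mp1 <- metaplot(step, f1, flank_bp = 1000L, body_bins = 10L,
                  flank_bins = 2L)
  body <- mp1$mean[mp1$bin_class == "body"]
  expect_equal(unname(body), c(rep(1, 5), rep(3, 5)))
  # upstream flank has no data (before chromosome start it is missing;
  # [0,?) is the feature itself) -> upstream bins are NA
  expect_true(all(is.na(mp1$mean[mp1$bin_class == "upstream"])))
  # same feature minus strand: body profile reverses
  f1$strand <- "-"
  mp2 <- metaplot(step, f1, flank_bp = 1000L, body_bins = 10L,
                  flank_bins = 2L)
  expect_equal(unname(mp2$mean[mp2$bin_class == "body"]), rev(unname(body)))
})

test_that("metaplot row-weighted average over concatenated feature sets is
           exact; short features are stretched, not dropped", {
  set.seed(8)
  tr <- flat_track(cs1, value = runif(1000, 0, 5))
  fa <- data.frame(chrom = "chr1", start = c(10000L, 30000L),
                   end = c(14000L, 36000L), strand = "+")
  fb <- data.frame(chrom = "chr1", start = 60000L, end = 61000L,
                   strand = "+")
  args <- list(flank_bp = 2000L, body_bins = 12L, flank_bins = 4L)
  ma <- do.call(metaplot, c(list(tr, fa), args))
  mb <- do.call(metaplot, c(list(tr, fb), args))
  mab <- do.call(metaplot, c(list(tr, rbind(fa, fb)), args))
  expect_equal(mab$mean, (2 * ma$mean + 1 * mb$mean) / 3, tolerance = 1e-9)
  # a 50-bp feature still yields a full row of body bins
  tiny <- data.frame(chrom = "chr1", start = 5000L, end = 5050L,
                     strand = "+")
  mt <- do.call(metaplot, c(list(tr, tiny), args))
  expect_false(anyNA(mt$matrix[, mt$bin_class == "body"]))
})

test_that("methylation metaplot pools reads per positional bin", {
  cy <- data.table::data.table(
    chrom = "chr1", pos = c(101L, 151L, 901L), strand = "+",
    context = "CHH",
    count_methylated = c(2L, 4L, 0L), count_total = c(10L, 10L, 10L))
  feats <- data.frame(chrom = "chr1", start = 100L, end = 1100L,
                      strand = "+")
  mp <- metaplot(cy, feats, flank_bp = 100L, body_bins = 10L,
                 flank_bins = 1L, context = "CHH")
  body <- mp$mean[mp$bin_class == "body"]
  expect_equal(unname(body[1]), 6 / 20)   # both cytosines pool in bin 1
  expect_equal(unname(body[9]), 0)
  expect_true(all(is.na(body[c(2:8, 10)])))
})

test_that("region_stats computes pooled levels and quartiles", {
  cy <- data.table::data.table(
    chrom = "chr1", pos = 500L, strand = "+", context = "CG",
    count_methylated = 7L, count_total = 10L)
  regs <- data.frame(chrom = "chr1", start = c(0L, 2000L),
                     end = c(1000L, 3000L))
  rs <- region_stats(cy, regs, context = "CG")
  expect_equal(rs$values, c(0.7, NA))
  expect_equal(rs$n_missing, 1L)

  vals <- c(1, 2, 3, 4, 10)
  tr <- coverage_track(data.frame(chrom = "chr1",
                                  start = (0:4) * 100L,
                                  end = (1:5) * 100L, value = vals))
  regs2 <- data.frame(chrom = "chr1", start = (0:4) * 100L,
                      end = (1:5) * 100L)
  rs2 <- region_stats(tr, regs2)
  expect_equal(rs2$values, vals)
  expect_equal(unname(rs2$summary), unname(quantile(vals)))
})

test_that("h3_normalized_density is the ratio of length-weighted means", {
  h3 <- flat_track(cs1, value = 2)
  regs <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                     end = c(500L, 1500L))
  expect_equal(h3_normalized_density(h3, h3, regs), c(1, 1))
  mark <- flat_track(cs1, value = 4)
  expect_equal(h3_normalized_density(mark, h3, regs), c(2, 2))
})

test_that("mark_association: uniform mark gives log2 ratio 0, is invariant
           to per-million scaling, and rejects empty peaks", {
  tr <- flat_track(cs1, value = 5, total_mapped = 3e6)
  peaks <- data.frame(chrom = "chr1", start = c(1000L, 9000L),
                      end = c(2000L, 9500L))
  ctrl <- shuffle_regions(peaks, cs1, seed = 3L, n_sets = 3L)
  a1 <- mark_association(peaks, list(m = tr), ctrl)
  expect_equal(a1$log2_ratio, 0)
  a2 <- mark_association(peaks, list(m = normalize_per_million(tr)), ctrl)
  expect_equal(a2$log2_ratio, a1$log2_ratio)
  expect_error(mark_association(peaks[0, ], list(m = tr), ctrl), "empty")
})

test_that("track_correlation: self-correlation 1; strong noise kills
           association", {
  set.seed(13)
  base <- runif(1000, 1, 10)
  tr_a <- flat_track(cs1, value = base)
  expect_equal(track_correlation(tr_a, tr_a, cs1)$pearson, 1)
  noise <- flat_track(cs1, value = sample(base))
  r <- track_correlation(tr_a, noise, cs1, bin = 100L)
  expect_lt(abs(r$spearman), 0.1)
  expect_equal(r$n, 1000L)
})
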