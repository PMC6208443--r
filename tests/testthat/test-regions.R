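cs2 <- data.frame(chrom = c("chr1", "chr2"), length = c(100000L, 50000L))

test_that("overlap_sets counts membership both ways with integer rounding", {
  a <- data.frame(chrom = "chr1", start = (0:11) * 1000L,
                  end = (0:11) * 1000L + 100L)
  expect_equal(overlap_sets(a, a)$pct_a, 100)
  b <- a[1:11, ]
  b$start <- b$start + 50L   # still overlap their source
  ov <- overlap_sets(a, b)
  expect_equal(ov$n_a_overlapping_b, 11L)
  expect_equal(ov$pct_a, 100 * 11 / 12)
  expect_equal(ov$pct_a_int, 92L)
  # disjoint
  d <- data.frame(chrom = "chr2", start = 0L, end = 10L)
  expect_equal(overlap_sets(a, d)$pct_a, 0)
})

test_that("overlap_sets agrees with brute-force pairwise checking", {
  set.seed(21)
  rnd <- function(n) {
    st <- sample.int(99000L, n)
    data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
               start = st, end = st + sample(50:500, n, TRUE))
  }
  a <- rnd(200); b <- rnd(200)
  a$end <- pmin(a$end, 50000L); a <- a[a$start < a$end, ]
  b$end <- pmin(b$end, 50000L); b <- b[b$start < b$end, ]
  ov <- overlap_sets(a, b)
  brute <- sum(vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1)))
  expect_equal(ov$n_a_overlapping_b, brute)
})

test_that("annotate_composition assigns by majority bp, tie toward TE", {
  tes <- data.frame(chrom = "chr1", start = 1000L, end = 2000L)
  genes <- data.frame(chrom = "chr1", start = 5000L, end = 7000L)
  regs <- data.frame(chrom = "chr1",
                     start = c(1100L, 1940L, 9000L, 5500L),
                     end = c(1200L, 2040L, 9100L, 5600L))
  ac <- annotate_composition(regs, genes, tes, cs2)
  # fully in TE; 60 bp TE vs 40 intergenic; intergenic; gene
  expect_equal(ac$assignment, c("TE", "TE", "intergenic", "gene"))
  expect_equal(sum(ac$fractions), 1)
})

test_that("te_family_enrichment: planted placement on one family enriches
           it; uniform coverage is null; empty input is empty", {
  set.seed(4)
  tes <- data.frame(chrom = "chr1", start = (0:19) * 5000L,
                    end = (0:19) * 5000L + 2000L,
                    family = rep(c("LTR/Gypsy", "other"), each = 10))
  hit_gypsy <- tes[tes$family == "LTR/Gypsy", c("chrom", "start", "end")]
  enr <- te_family_enrichment(hit_gypsy, tes)
  expect_gt(enr$fold[enr$family == "LTR/Gypsy"], 1)
  expect_lt(enr$fold[enr$family == "other"], 1)
  expect_lt(enr$p_value[enr$family == "LTR/Gypsy"], 0.01)

  all_te <- tes[, c("chrom", "start", "end")]
  enr0 <- te_family_enrichment(all_te, tes)
  expect_equal(enr0$fold, c(1, 1))

  expect_equal(nrow(te_family_enrichment(all_te[0, ], tes)), 0L)
})

test_that("classify_bound_tes uses a strict >80% coverage rule", {
  tes <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  exactly80 <- data.frame(chrom = "chr1", start = 0L, end = 800L)
  just_over <- data.frame(chrom = "chr1", start = 0L, end = 801L)
  full <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  expect_false(classify_bound_tes(tes, exactly80)$tes$bound)
  expect_true(classify_bound_tes(tes, just_over)$tes$bound)
  expect_true(classify_bound_tes(tes, full)$tes$bound)
  # whole-genome peaks bind everything; empty peak set binds nothing
  many <- data.frame(chrom = "chr1", start = c(0L, 3000L),
                     end = c(1000L, 9000L))
  genome_wide <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  expect_equal(classify_bound_tes(many, genome_wide)$n_bound, 2L)
  expect_equal(classify_bound_tes(many, many[0, ])$n_bound, 0L)
})

test_that("shuffle_regions preserves length multisets, respects bounds and
           exclusions, and is seeded", {
  set.seed(2)
  st <- sample.int(90000L, 40)
  regs <- data.frame(chrom = "chr1", start = st,
                     end = st + sample(100:2000, 40, TRUE))
  sets <- shuffle_regions(regs, cs2, seed = 9L, n_sets = 3L)
  expect_length(sets, 3L)
  for (s in sets) {
    expect_equal(sort(s$end - s$start), sort(regs$end - regs$start))
    len <- setNames(cs2$length, cs2$chrom)
    expect_true(all(s$start >= 0 & s$end <= len[s$chrom]))
  }
  expect_identical(shuffle_regions(regs, cs2, seed = 9L, n_sets = 3L), sets)
  expect_false(identical(shuffle_regions(regs, cs2, seed = 10L)[[1]],
                         sets[[1]]))

  excl <- data.frame(chrom = "chr1", start = 0L, end = 60000L)
  se <- shuffle_regions(regs, cs2, seed = 1L, exclude = excl)[[1]]
  gr <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(se$chrom, IRanges::IRanges(se$start + 1, se$end)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 60000)))
  expect_length(gr, 0L)

  too_long <- data.frame(chrom = "chr1", start = 0L, end = 200000L)
  expect_error(shuffle_regions(too_long, cs2, seed = 1L), "longer")
})

test_that("shuffled placement matches uniform expectation against a fixed
           mask", {
  # mask of 10% of the genome: expect ~10% of region bp to fall in it
  mask <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  cs <- data.frame(chrom = "chr1", length = 100000L)
  regs <- data.frame(chrom = "chr1", start = rep(0L, 1000),
                     end = rep(100L, 1000))
  s <- shuffle_regions(regs, cs, seed = 31L)[[1]]
  # per-region overlap bp (controls may overlap each other, so no union)
  ov <- pmax(0, pmin(s$end, 10000L) - pmax(s$start, 0L))
  frac <- sum(ov) / sum(s$end - s$start)
  expect_lt(abs(frac - 0.1), 0.02)
})

test_that("chromosome_density conserves counts and localizes regions", {
  regs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(5L, 25000L, 100L),
                     end = c(105L, 25100L, 200L))
  d <- chromosome_density(regs, cs2, window = 10000L)
  expect_equal(sum(d$count), 3L)
  expect_equal(d$count[d$chrom == "chr1" & d$start == 0L], 1L)
  expect_equal(d$count[d$chrom == "chr1" & d$start == 20000L], 1L)
})
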