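# Shared fixtures built in code. Small genomes keep the default run fast;
# the acceptance tests build their own larger instances.

toy_genome <- function(seed = 7L, mb = 0.3) {
  len <- as.integer(mb * 1e6)
  generate_genome(genome_spec(c(chr1 = len, chr2 = len), seed = seed))
}

# deterministic 3-line cytosine report fixture
write_cx_fixture <- function(path,
                             lines = c("chr1\t5\t+\tCG\t3\t10",
                                       "chr1\t101\t-\tCHG\t0\t4",
                                       "chr2\t50\t+\tCHH\t2\t2")) {
  writeLines(lines, path)
  path
}

# independent Fisher oracle: enumerate the hypergeometric support and sum
# point probabilities <= observed, computed from choose() directly
fisher_oracle <- function(ma, ta, mb, tb) {
  m <- ma + mb; n <- (ta - ma) + (tb - mb); k <- ta
  lo <- max(0, k - n); hi <- min(k, m)
  denom <- choose(m + n, k)
  a <- lo:hi
  probs <- choose(m, a) * choose(n, k - a) / denom
  p_obs <- probs[ma - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# naive O(m^2) BH definition: q_i = min over j with p_j-rank >= rank_i
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(vapply(which(r >= r[i]), function(j) m * p[j] / r[j],
                      numeric(1))))
  }, numeric(1))
}

flat_track <- function(chrom_sizes, value = 1, window = 100L,
                       total_mapped = NULL) {
  wins <- make_bins(chrom_sizes, window)
  coverage_track(data.frame(chrom = wins$chrom, start = wins$start,
                            end = wins$end, value = value),
                 total_mapped = total_mapped)
}
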