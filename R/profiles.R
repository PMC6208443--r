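#' Coverage track container
#'
#' A bedGraph-semantics track: non-overlapping intervals with a numeric
#' value, plus the scalar total of mapped reads used for per-million
#' normalization. Genome positions not covered by any interval are treated
#' as missing in profile averages (and as zero signal in correlations).
#'
#' @param intervals Data frame `chrom`, `start`, `end`, `value` (BED
#'   convention coordinates).
#' @param total_mapped Total mapped reads (scalar) or NULL if unknown.
#' @param normalized Whether values are already per-million normalized.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(intervals, total_mapped = NULL,
                           normalized = FALSE) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (any(intervals$value < 0)) stop("track values must be non-negative")
  o <- order(intervals$chrom, intervals$start)
  intervals <- intervals[o, c("chrom", "start", "end", "value")]
  rownames(intervals) <- NULL
  if (nrow(intervals) > 1) {
    n <- nrow(intervals)
    same <- intervals$chrom[-1] == intervals$chrom[-n]
    if (any(same & intervals$start[-1] < intervals$end[-n])) {
      stop("track intervals overlap", call. = FALSE)  # one value per base
    }
  }
  structure(list(intervals = intervals,
                 total_mapped = total_mapped,
                 normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d intervals on %d chromosome(s)%s\n",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              if (x$normalized) " (per-million normalized)" else ""))
  invisible(x)
}

#' Per-million normalization of a coverage track
#'
#' Scales every value by `1e6 / total_mapped`, so track sums become "read
#' counts per million mapped reads".
#'
#' @param track A [coverage_track()] with a positive `total_mapped`.
#' @return The normalized track.
#' @export
normalize_per_million <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(track$total_mapped) || track$total_mapped <= 0) {
    stop("total_mapped must be a positive scalar", call. = FALSE)
  }
  out <- track
  out$intervals$value <- track$intervals$value * 1e6 / track$total_mapped
  out$normalized <- TRUE
  out
}

# value and covered RleLists for a track; positions outside any interval
# have covered = 0 and are missing for averaging purposes.
track_rles <- function(track, chrom_sizes = NULL) {
  gr <- regions_to_gr(track$intervals, chrom_sizes)
  list(value = GenomicRanges::coverage(gr, weight = track$intervals$value),
       covered = GenomicRanges::coverage(gr))
}

# Fractional-boundary binning of a per-bp vector: bin k of B covers
# [L*k/B, L*(k+1)/B). Returns per-bin means with NA-aware fractional
# weights (exact fractional-overlap weighting; short features are
# stretched rather than dropped).
bin_fractional <- function(values, n_bins) {
  L <- length(values)
  if (L == 0) return(rep(NA_real_, n_bins))
  ok <- !is.na(values)
  cv <- cumsum(ifelse(ok, values, 0))
  cm <- cumsum(as.numeric(ok))
  fint <- function(cum, per, x) {  # integral over [0, x)
    j <- floor(x)
    base <- ifelse(j >= 1, cum[pmax(pmin(j, L), 1)], 0)
    fracpart <- x - j
    add <- ifelse(j < L & fracpart > 0, per[pmax(pmin(j + 1, L), 1)] * fracpart, 0)
    base + add
  }
  cuts <- L * (0:n_bins) / n_bins
  iv <- fint(cv, ifelse(ok, values, 0), cuts)
  im <- fint(cm, as.numeric(ok), cuts)
  num <- diff(iv); den <- diff(im)
  ifelse(den > 0, num / den, NA_real_)
}

# per-bp values (with NA where uncovered) over [start - flank, end + flank)
# of a feature, already reversed for minus-strand features.
feature_profile_values <- function(rles, chrom, start, end, strand, flank_bp) {
  win_start <- start - flank_bp       # 0-based
  win_end <- end + flank_bp
  n <- win_end - win_start
  vals <- rep(NA_real_, n)
  if (chrom %in% names(rles$value)) {
    r <- rles$value[[chrom]]
    m <- rles$covered[[chrom]]
    lo <- max(win_start, 0L)
    hi <- min(win_end, length(r))
    if (hi > lo) {
      idx <- (lo + 1):hi
      v <- as.numeric(S4Vectors::window(r, lo + 1L, hi))
      cov <- as.numeric(S4Vectors::window(m, lo + 1L, hi))
      v[cov == 0] <- NA_real_
      vals[(lo - win_start + 1):(hi - win_start)] <- v
    }
  }
  if (identical(strand, "-")) vals <- rev(vals)
  vals
}

#' Scale-region metaplot with fixed-width flanks
#'
#' Averages a signal over a feature set after rescaling each feature body to
#' `body_bins` equal bins, with `flank_bins` fixed-width bins over
#' `flank_bp` bp upstream and downstream. Minus-strand features are
#' reversed so the x axis reads 5' to 3'. Bins with no data are missing and
#' excluded from the mean's denominator.
#'
#' For a [coverage_track()] signal each matrix cell is the mean track value
#' over the bin's bp. For a methylation signal (a cytosine table plus a
#' `context`) each cell is that feature's pooled methylated/total read
#' ratio in the bin, and the `mean` curve pools reads across features
#' (weighted); set `weighted = FALSE` to average per-feature levels instead.
#'
#' @param signal A `coverage_track`, or a cytosine table (then `context` is
#'   required).
#' @param features Region data frame; optional `strand` column.
#' @param flank_bp Flank width in bp (default 2000).
#' @param body_bins,flank_bins Bin counts (defaults 60 and 20).
#' @param context Cytosine context when `signal` is a cytosine table.
#' @param weighted Pool reads across features for the mean curve
#'   (methylation signal only; default TRUE).
#' @return List of class `metaplot`: `matrix` (feature x bin), `mean`,
#'   `n` (contributing features per bin), and the bin scheme.
#' @export
metaplot <- function(signal, features, flank_bp = 2000L, body_bins = 60L,
                     flank_bins = 20L, context = NULL, weighted = TRUE) {
  stopifnot(nrow(features) > 0, flank_bp >= 0, body_bins > 0, flank_bins > 0)
  n_bins <- 2L * flank_bins + body_bins
  flank_w <- flank_bp / flank_bins
  strands <- if ("strand" %in% names(features)) features$strand
             else rep("+", nrow(features))

  if (inherits(signal, "coverage_track")) {
    rles <- track_rles(signal)
    mat <- t(vapply(seq_len(nrow(features)), function(i) {
      vals <- feature_profile_values(rles, features$chrom[i],
                                     features$start[i], features$end[i],
                                     strands[i], flank_bp)
      L <- features$end[i] - features$start[i]
      up <- vals[seq_len(flank_bp)]
      body <- vals[flank_bp + seq_len(L)]
      down <- vals[flank_bp + L + seq_len(flank_bp)]
      c(bin_fractional(up, flank_bins),
        bin_fractional(body, body_bins),
        bin_fractional(down, flank_bins))
    }, numeric(n_bins)))
    n <- colSums(!is.na(mat))
    mean_curve <- ifelse(n > 0, colMeans(mat, na.rm = TRUE), NA_real_)
  } else {
    stopifnot(!is.null(context))
    cy <- data.table::as.data.table(signal)
    keep_ctx <- cy[["context"]] == context
    cy <- cy[which(keep_ctx)]
    meth <- matrix(0, nrow(features), n_bins)
    tot <- matrix(0, nrow(features), n_bins)
    if (nrow(cy)) {
      gr_cy <- GenomicRanges::GRanges(cy$chrom,
                                      IRanges::IRanges(cy$pos, width = 1))
      win <- GenomicRanges::GRanges(
        features$chrom,
        IRanges::IRanges(pmax(features$start - flank_bp + 1L, 1L),
                         features$end + flank_bp))
      hits <- GenomicRanges::findOverlaps(gr_cy, win, ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      if (length(qi)) {
        L <- features$end[si] - features$start[si]
        rel <- cy$pos[qi] - 1L - features$start[si]    # 0 at body 5' end
        flip <- strands[si] == "-"
        rel[flip] <- L[flip] - 1L - rel[flip]
        bin <- ifelse(rel < 0, floor((rel + flank_bp) / flank_w),
                ifelse(rel < L, flank_bins + floor(rel * body_bins / L),
                       flank_bins + body_bins + floor((rel - L) / flank_w)))
        keep <- bin >= 0 & bin < n_bins
        dt <- data.table::data.table(
          i = si[keep], b = as.integer(bin[keep]) + 1L,
          m = cy$count_methylated[qi][keep], t = cy$count_total[qi][keep])
        agg <- dt[, list(m = sum(m), t = sum(t)), by = c("i", "b")]
        meth[cbind(agg$i, agg$b)] <- agg$m
        tot[cbind(agg$i, agg$b)] <- agg$t
      }
    }
    mat <- ifelse(tot > 0, meth / tot, NA_real_)
    n <- colSums(tot > 0)
    if (weighted) {
      cm <- colSums(meth); ct <- colSums(tot)
      mean_curve <- ifelse(ct > 0, cm / ct, NA_real_)
    } else {
      mean_curve <- ifelse(n > 0, colMeans(mat, na.rm = TRUE), NA_real_)
    }
  }
  structure(list(matrix = mat, mean = mean_curve, n = n,
                 flank_bp = flank_bp, body_bins = body_bins,
                 flank_bins = flank_bins,
                 bin_class = rep(c("upstream", "body", "downstream"),
                                 c(flank_bins, body_bins, flank_bins))),
            class = "metaplot")
}

#' Per-region signal statistics
#'
#' For a methylation signal, the per-region value is the pooled
#' methylated/total read ratio of all cytosines of the context in the
#' region; for a coverage track, the mean track value over the region's
#' covered bp. Regions with no data are missing and counted.
#'
#' @inheritParams metaplot
#' @param regions Regions to summarise.
#' @return List with `values` (per region), `n_missing`, and `summary`
#'   (quartiles for box plots).
#' @export
region_stats <- function(signal, regions, context = NULL) {
  stopifnot(nrow(regions) > 0)
  if (inherits(signal, "coverage_track")) {
    rles <- track_rles(signal)
    gr <- regions_to_gr(regions)
    num <- bp_weighted_sum(gr, rles$value, rles$covered)
    vals <- ifelse(num$den > 0, num$num / num$den, NA_real_)
  } else {
    stopifnot(!is.null(context))
    cy <- data.table::as.data.table(signal)
    keep_ctx <- cy[["context"]] == context
    cy <- cy[which(keep_ctx)]
    gr_cy <- GenomicRanges::GRanges(cy$chrom,
                                    IRanges::IRanges(cy$pos, width = 1))
    gr <- regions_to_gr(regions)
    hits <- GenomicRanges::findOverlaps(gr_cy, gr, ignore.strand = TRUE)
    meth <- tapply(cy$count_methylated[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits), sum)
    tot <- tapply(cy$count_total[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    vals <- rep(NA_real_, nrow(regions))
    idx <- as.integer(names(meth))
    vals[idx] <- ifelse(tot > 0, meth / tot, NA_real_)
  }
  ok <- vals[!is.na(vals)]
  list(values = vals,
       n_missing = sum(is.na(vals)),
       summary = if (length(ok)) quantile(ok, c(0, 0.25, 0.5, 0.75, 1))
                 else setNames(rep(NA_real_, 5),
                               c("0%", "25%", "50%", "75%", "100%")))
}

# numerator (sum of values over covered bp) and denominator (covered bp)
# per range
bp_weighted_sum <- function(gr, value_rle, covered_rle) {
  num <- numeric(length(gr)); den <- numeric(length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    if (!(ch %in% names(value_rle))) next
    v <- value_rle[[ch]]; m <- covered_rle[[ch]]
    need <- max(GenomicRanges::end(gr)[idx])
    if (length(v) < need) {
      v <- c(v, S4Vectors::Rle(0, need - length(v)))
      m <- c(m, S4Vectors::Rle(0L, need - length(m)))
    }
    ir <- IRanges::IRanges(GenomicRanges::start(gr)[idx],
                           GenomicRanges::end(gr)[idx])
    num[idx] <- IRanges::viewSums(IRanges::Views(v, ir))
    den[idx] <- IRanges::viewSums(IRanges::Views(m, ir))
  }
  list(num = num, den = den)
}

#' Per-region mark density normalized by H3
#'
#' Ratio of the mark's length-weighted mean to the H3 length-weighted mean
#' over each region; both tracks should be per-million normalized first.
#' Regions with zero H3 signal are missing.
#'
#' @param mark_track,h3_track [coverage_track()]s.
#' @param regions Regions of interest.
#' @return Numeric vector of per-region ratios (NA where H3 is 0).
#' @export
h3_normalized_density <- function(mark_track, h3_track, regions) {
  mv <- region_stats(mark_track, regions)$values
  hv <- region_stats(h3_track, regions)$values
  ifelse(!is.na(hv) & hv > 0, mv / hv, NA_real_)
}

#' Mark association at peaks versus shuffled controls
#'
#' For each mark track, computes log2 of the mean signal over peaks divided
#' by the mean signal over length-matched control sets (control means
#' averaged across sets). Positive values mean the mark is enriched at the
#' peaks. The ratio is invariant to per-million scaling.
#'
#' @param peaks Peak regions (non-empty).
#' @param mark_tracks Named list of [coverage_track()]s.
#' @param control_sets List of control region sets, e.g. from
#'   [shuffle_regions()].
#' @return Data frame per mark: `mean_peaks`, `mean_controls`,
#'   `log2_ratio`.
#' @export
mark_association <- function(peaks, mark_tracks, control_sets) {
  if (nrow(peaks) == 0) stop("empty peak set", call. = FALSE)
  stopifnot(length(control_sets) >= 1)
  region_mean <- function(track, regions) {
    rles <- track_rles(track)
    s <- bp_weighted_sum(regions_to_gr(regions), rles$value, rles$covered)
    sum(s$num) / sum(s$den)
  }
  out <- lapply(names(mark_tracks), function(nm) {
    tr <- mark_tracks[[nm]]
    mp <- region_mean(tr, peaks)
    mc <- mean(vapply(control_sets, function(cs) region_mean(tr, cs),
                      numeric(1)))
    data.frame(mark = nm, mean_peaks = mp, mean_controls = mc,
               log2_ratio = log2(mp / mc), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome-wide correlation between two coverage tracks
#'
#' Bins the genome, averages each track per bin (uncovered bp count as
#' zero signal), drops bins with zero coverage in both tracks, and reports
#' Pearson and Spearman correlations.
#'
#' @param track_a,track_b [coverage_track()]s on the same genome.
#' @param chrom_sizes Chromosome sizes.
#' @param bin Bin width in bp (default 1e4).
#' @return List with `pearson`, `spearman`, `n` bins used.
#' @export
track_correlation <- function(track_a, track_b, chrom_sizes, bin = 10000L) {
  bins <- make_bins(chrom_sizes, bin)
  gr <- regions_to_gr(bins, chrom_sizes)
  mean_in_bins <- function(track) {
    rles <- track_rles(track, chrom_sizes)
    s <- bp_weighted_sum(gr, rles$value, rles$covered)
    list(val = s$num / (bins$end - bins$start), cov = s$den)
  }
  a <- mean_in_bins(track_a)
  b <- mean_in_bins(track_b)
  keep <- a$cov > 0 | b$cov > 0
  list(pearson = cor(a$val[keep], b$val[keep], method = "pearson"),
       spearman = cor(a$val[keep], b$val[keep], method = "spearman"),
       n = sum(keep))
}
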